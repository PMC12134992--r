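# scaffold classification: macro / micro / X / Y / rDNA / mito / satellite /
# unassigned, with PAR detection on the X
#
# label precedence is total and fixed:
#   mito > rDNA > satellite-only > chromosome-scale (macro/micro/X) > Y >
#   unassigned
# so reordering input scaffolds never changes labels.

# union length of 1-based closed intervals
.unionWidth <- function(start, end) {
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start, end))))
}

#' Split chromosome-scale scaffolds into macro and micro by size rank
#'
#' The \code{n_macro_expected} longest scaffolds are macro; the rest are
#' micro. Window-GC medians are used as a consistency check only: a macro
#' with micro-like GC (above \code{gc_threshold}) or a micro with macro-like
#' GC is flagged with a warning, but rank wins.
#'
#' @param scaffold_stats data.frame with \code{scaffold}, \code{length} and
#'   \code{gc_median} columns.
#' @param n_macro_expected expected number of macrochromosomes.
#' @param gc_threshold GC fraction separating macro-like from micro-like.
#' @return the input with \code{class} (\code{macro}/\code{micro}) and
#'   \code{warning} columns.
#' @export
classifySizeGC <- function(scaffold_stats, n_macro_expected,
                           gc_threshold = 0.435) {
  if (nrow(scaffold_stats) < n_macro_expected)
    stop("fewer chromosome-scale scaffolds than n_macro_expected")
  df <- scaffold_stats[order(-scaffold_stats$length), , drop = FALSE]
  df$class <- c(rep("macro", n_macro_expected),
                rep("micro", nrow(df) - n_macro_expected))
  df$warning <- ""
  conflict <- (df$class == "macro" & !is.na(df$gc_median) &
                 df$gc_median > gc_threshold) |
              (df$class == "micro" & !is.na(df$gc_median) &
                 df$gc_median <= gc_threshold)
  if (any(conflict)) {
    df$warning[conflict] <- "GC conflicts with size rank; rank wins"
    warning("GC/rank conflict for: ",
            paste(df$scaffold[conflict], collapse = ", "))
  }
  df[match(scaffold_stats$scaffold, df$scaffold), , drop = FALSE]
}

#' Identify the X scaffold(s) by half depth in a male
#'
#' In an XY male the X has half the autosomal read depth. A scaffold is
#' called X when, on every available platform track, its median window
#' depth divided by the genome-wide median window depth falls inside
#' \code{band} (symmetric around 0.5 by default).
#'
#' @param tracks a \code{\link{WindowTrack}} or list of them (one per
#'   platform), from a male individual.
#' @param candidates scaffold names eligible to be X (e.g. the
#'   chromosome-scale set); defaults to every scaffold in the first track.
#' @param band lower/upper depth-ratio bounds.
#' @return character vector of X scaffold names, with per-scaffold ratios of
#'   the first platform as the \code{ratio} attribute.
#' @export
identifyX <- function(tracks, candidates = NULL, band = c(0.4, 0.6)) {
  if (is(tracks, "WindowTrack")) tracks <- list(tracks)
  ratios <- lapply(tracks, function(tr) {
    gr <- tr@windows
    depth <- S4Vectors::mcols(gr)$depth
    gmed <- lowerMedian(depth)
    if (gmed == 0) stop("genome median depth is zero")
    med <- tapply(depth, as.character(GenomicRanges::seqnames(gr)),
                  lowerMedian)
    med / gmed
  })
  ids <- names(ratios[[1]])
  if (is.null(candidates)) candidates <- ids
  in_band <- Reduce(`&`, lapply(ratios, function(r)
    r[ids] >= band[1] & r[ids] <= band[2]))
  x <- ids[in_band & ids %in% candidates]
  structure(x, ratio = ratios[[1]][x])
}

#' Identify rDNA scaffolds from subunit alignment coverage
#'
#' A scaffold is rDNA when the union of its alignment intervals on the 18S
#' or the 28S subunit reference covers strictly more than \code{min_cov} of
#' that subunit's length.
#'
#' @param hits data.frame of alignment hits with \code{query} (subunit id),
#'   \code{qstart}, \code{qend} (1-based closed on the subunit),
#'   \code{target} (scaffold).
#' @param ref_lengths named lengths of the subunit references.
#' @param min_cov exclusive coverage threshold (default 0.5).
#' @return character vector of rDNA scaffold names, with a coverage matrix
#'   attribute \code{coverage} (scaffold x subunit).
#' @export
identifyRdna <- function(hits, ref_lengths, min_cov = 0.5) {
  scafs <- unique(hits$target)
  subunits <- names(ref_lengths)
  cov <- matrix(0, length(scafs), length(subunits),
                dimnames = list(scafs, subunits))
  for (id in scafs) for (su in subunits) {
    h <- hits[hits$target == id & hits$query == su, , drop = FALSE]
    if (nrow(h))
      cov[id, su] <- .unionWidth(h$qstart, h$qend) / ref_lengths[[su]]
  }
  structure(scafs[apply(cov > min_cov, 1, any)], coverage = cov)
}

#' Identify the mitochondrial scaffold
#'
#' Among scaffolds with a high-identity mitochondrial-reference alignment
#' covering at least \code{min_cov} of their own length, the one with the
#' longest aligned span is retained as the mitochondrial genome; any others
#' are flagged as erroneous duplicates for removal.
#'
#' @param hits data.frame of hits vs the mitochondrial reference
#'   (\code{target}, \code{tstart}, \code{tend}, \code{identity}).
#' @param scaffold_lengths named scaffold lengths.
#' @param min_cov minimum aligned fraction of the scaffold.
#' @param min_identity minimum alignment identity.
#' @return list with \code{retained} (length 0 or 1) and \code{flagged}.
#' @export
identifyMito <- function(hits, scaffold_lengths, min_cov = 0.9,
                         min_identity = 0.9) {
  if (!nrow(hits)) return(list(retained = character(0),
                               flagged = character(0)))
  hits <- hits[hits$identity >= min_identity, , drop = FALSE]
  span <- vapply(split(hits, hits$target), function(h)
    .unionWidth(h$tstart, h$tend), numeric(1))
  frac <- span / scaffold_lengths[names(span)]
  cand <- names(span)[frac >= min_cov]
  if (!length(cand)) return(list(retained = character(0),
                                 flagged = character(0)))
  best <- cand[which.max(span[cand])]
  list(retained = best, flagged = setdiff(cand, best))
}

#' Identify Y scaffolds by subtraction-contig density
#'
#' Applied by elimination, after chromosome-scale, rDNA, satellite and mito
#' labels are fixed: among the remaining scaffolds, those with a density of
#' mapped Y-enriched contigs above \code{min_density} hits/Mb are Y.
#'
#' @param candidates names of still-unassigned scaffolds.
#' @param hits data.frame of Y-contig hits (\code{target} column).
#' @param scaffold_lengths named scaffold lengths.
#' @param min_density hits per Mb, exclusive threshold.
#' @return character vector of Y scaffolds with a \code{density} attribute
#'   (hits/Mb for every candidate).
#' @export
identifyY <- function(candidates, hits, scaffold_lengths, min_density = 5) {
  n <- vapply(candidates, function(id) sum(hits$target == id), numeric(1))
  dens <- n / (scaffold_lengths[candidates] / 1e6)
  structure(candidates[dens > min_density], density = dens)
}

#' Detect the pseudoautosomal region on the X
#'
#' Windows on the X are classified by the male/female depth ratio: the PAR
#' is diploid in both sexes (ratio near 1) while the X-specific region is
#' haploid in the male (ratio near 0.5). The PAR call is the maximal run of
#' PAR-class windows anchored at a scaffold end (the longer run if both ends
#' qualify); its boundary is the end of the last PAR window.
#'
#' @param male_track,female_track \code{\link{WindowTrack}}s on the same
#'   window grid (20-kb windows in the reference analysis).
#' @param x_scaffold name of the X scaffold.
#' @param par_band ratio band classifying a window as pseudoautosomal.
#' @param x_band ratio band classifying a window as X-specific.
#' @return \code{GRanges} of the PAR, or \code{NULL} when no PAR-class run
#'   is anchored at an end.
#' @export
detectPar <- function(male_track, female_track, x_scaffold,
                      par_band = c(0.8, 1.2), x_band = c(0.35, 0.65)) {
  mgr <- male_track@windows
  fgr <- female_track@windows
  msel <- as.character(GenomicRanges::seqnames(mgr)) == x_scaffold
  fsel <- as.character(GenomicRanges::seqnames(fgr)) == x_scaffold
  if (!any(msel) || !any(fsel))
    stop("x_scaffold absent from a track: ", x_scaffold)
  m <- mgr[msel]; f <- fgr[fsel]
  if (length(m) != length(f) ||
      any(GenomicRanges::start(m) != GenomicRanges::start(f)) ||
      any(GenomicRanges::end(m) != GenomicRanges::end(f)))
    stop("male and female tracks are on different window grids")
  ratio <- S4Vectors::mcols(m)$depth / S4Vectors::mcols(f)$depth
  is_par <- !is.na(ratio) & ratio >= par_band[1] & ratio <= par_band[2]
  n <- length(is_par)
  len_start <- which(!c(is_par, FALSE))[1] - 1          # leading PAR run
  len_end <- which(!c(rev(is_par), FALSE))[1] - 1       # trailing PAR run
  if (len_start == 0 && len_end == 0) return(NULL)
  if (len_start >= len_end)
    gr <- GenomicRanges::GRanges(x_scaffold, IRanges::IRanges(
      GenomicRanges::start(m)[1], GenomicRanges::end(m)[len_start]))
  else
    gr <- GenomicRanges::GRanges(x_scaffold, IRanges::IRanges(
      GenomicRanges::start(m)[n - len_end + 1], GenomicRanges::end(m)[n]))
  S4Vectors::mcols(gr)$n_windows <- max(len_start, len_end)
  gr
}

#' Classify every scaffold with the full evidence hierarchy
#'
#' Applies the label precedence mito > rDNA > satellite-only >
#' chromosome-scale (macro/micro/X) > Y > unassigned. Chromosome-scale
#' scaffolds (length at least \code{min_chrom_len}) are split into X (half
#' male depth), then macro/micro by size rank with a GC consistency check.
#' Remaining scaffolds with a high Y-contig hit density become Y.
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or named scaffold lengths.
#' @param depth_tracks male \code{\link{WindowTrack}} or list of them.
#' @param gc_track optional \code{WindowTrack} with a \code{gc} column.
#' @param satellite_arrays optional \code{GRanges} of satellite arrays.
#' @param rdna_hits,mito_hits,y_hits optional alignment-hit data.frames
#'   (see \code{\link{identifyRdna}}, \code{\link{identifyMito}},
#'   \code{\link{identifyY}}).
#' @param rdna_ref_lengths named subunit reference lengths.
#' @param n_macro_expected expected macrochromosome count.
#' @param min_chrom_len chromosome-scale length cutoff (bp).
#' @param x_band depth-ratio band for the X.
#' @param gc_threshold macro/micro GC consistency threshold.
#' @param sat_frac satellite-covered fraction above which a scaffold is
#'   satellite-only.
#' @param min_y_density Y-contig hits/Mb threshold.
#' @return a \code{\link{ClassificationReport}}.
#' @export
classifyScaffolds <- function(scaffolds, depth_tracks, gc_track = NULL,
                              satellite_arrays = NULL,
                              rdna_hits = NULL, mito_hits = NULL,
                              y_hits = NULL, rdna_ref_lengths = NULL,
                              n_macro_expected = 6,
                              min_chrom_len = 1e6,
                              x_band = c(0.4, 0.6), gc_threshold = 0.435,
                              sat_frac = 0.5, min_y_density = 5) {
  lens <- if (is(scaffolds, "ScaffoldSet")) scaffoldLengths(scaffolds)
          else scaffolds
  if (is(depth_tracks, "WindowTrack")) depth_tracks <- list(depth_tracks)
  ids <- names(lens)
  cls <- stats::setNames(rep(NA_character_, length(ids)), ids)
  warn <- stats::setNames(rep("", length(ids)), ids)

  gc_med <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(gc_track)) {
    gr <- gc_track@windows
    med <- tapply(S4Vectors::mcols(gr)$gc,
                  as.character(GenomicRanges::seqnames(gr)),
                  function(x) lowerMedian(x[!is.na(x)]))
    gc_med[names(med)] <- med
  }
  depth_med <- stats::setNames(rep(NA_real_, length(ids)), ids)
  ratio <- stats::setNames(rep(NA_real_, length(ids)), ids)
  gr1 <- depth_tracks[[1]]@windows
  med1 <- tapply(S4Vectors::mcols(gr1)$depth,
                 as.character(GenomicRanges::seqnames(gr1)), lowerMedian)
  depth_med[names(med1)] <- med1
  gmed <- lowerMedian(S4Vectors::mcols(gr1)$depth)
  if (gmed == 0) stop("genome median depth is zero")
  ratio <- depth_med / gmed

  # 1. mitochondrial
  if (!is.null(mito_hits) && nrow(mito_hits)) {
    mt <- identifyMito(mito_hits, lens)
    cls[mt$retained] <- "mito"
    if (length(mt$flagged)) {
      warn[mt$flagged] <- "duplicate mitochondrial copy; flagged for removal"
      cls[mt$flagged] <- "unassigned"
    }
  }
  # 2. rDNA
  rdna_cov <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(rdna_hits) && nrow(rdna_hits)) {
    if (is.null(rdna_ref_lengths))
      stop("rdna_ref_lengths required with rdna_hits")
    rd <- identifyRdna(rdna_hits, rdna_ref_lengths)
    covm <- attr(rd, "coverage")
    rdna_cov[rownames(covm)] <- apply(covm, 1, max)
    cls[intersect(rd, ids[is.na(cls)])] <- "rdna"
  }
  # 3. satellite-only
  sat_cov <- stats::setNames(rep(0, length(ids)), ids)
  if (!is.null(satellite_arrays) && length(satellite_arrays)) {
    sat_cov <- satelliteCoverage(satellite_arrays, lens)
    cls[ids[is.na(cls) & sat_cov > sat_frac]] <- "satellite"
  }
  # 4. chromosome-scale: X, then macro/micro by rank
  chrom <- ids[is.na(cls) & lens >= min_chrom_len]
  x_ids <- identifyX(depth_tracks, candidates = chrom, band = x_band)
  cls[x_ids] <- "X"
  auto <- setdiff(chrom, x_ids)
  if (length(auto)) {
    sg <- withCallingHandlers(
      classifySizeGC(data.frame(scaffold = auto, length = lens[auto],
                                gc_median = gc_med[auto],
                                stringsAsFactors = FALSE),
                     n_macro_expected, gc_threshold),
      warning = function(w) invokeRestart("muffleWarning"))
    cls[sg$scaffold] <- sg$class
    warn[sg$scaffold] <- paste0(warn[sg$scaffold], sg$warning)
  }
  # 5. Y by subtraction-contig density
  y_dens <- stats::setNames(rep(NA_real_, length(ids)), ids)
  rest <- ids[is.na(cls)]
  if (!is.null(y_hits) && length(rest)) {
    yy <- identifyY(rest, y_hits, lens, min_y_density)
    y_dens[rest] <- attr(yy, "density")[rest]
    cls[yy] <- "Y"
  }
  # 6. leftovers
  cls[is.na(cls)] <- "unassigned"

  tab <- data.frame(scaffold = ids, class = unname(cls),
                    length = unname(lens),
                    gc_median = unname(gc_med),
                    depth_median = unname(depth_med),
                    depth_ratio = unname(ratio),
                    y_density = unname(y_dens),
                    rdna_cov = unname(rdna_cov),
                    sat_frac = unname(sat_cov),
                    warning = unname(warn),
                    stringsAsFactors = FALSE)
  new("ClassificationReport", table = tab, par = NULL,
      params = list(n_macro_expected = n_macro_expected,
                    min_chrom_len = min_chrom_len, x_band = x_band,
                    gc_threshold = gc_threshold, sat_frac = sat_frac,
                    min_y_density = min_y_density))
}

#' Assign notional chromosome names by size rank
#'
#' Macro scaffolds are numbered 1..n by decreasing length, micro scaffolds
#' continue the numbering, and X/Y are named explicitly; output names are
#' \code{<prefix>scf<rank>}. A trailing split suffix (\code{.1}, \code{.2})
#' in the input id is preserved on the assigned name. Duplicate lengths are
#' broken by input order with a warning.
#'
#' @param report a \code{\link{ClassificationReport}}.
#' @param prefix name prefix.
#' @return the report with a \code{chrom_name} column added.
#' @export
assignChromosomeNames <- function(report, prefix = "ASM") {
  tab <- report@table
  tab$chrom_name <- NA_character_
  suffix <- sub("^.*(\\.\\d+)$|^.*$", "\\1", tab$scaffold)
  ranked <- which(tab$class %in% c("macro", "micro"))
  if (length(ranked)) {
    if (anyDuplicated(tab$length[ranked]))
      warning("tied scaffold lengths; rank ties broken by input order")
    macro <- ranked[tab$class[ranked] == "macro"]
    micro <- ranked[tab$class[ranked] == "micro"]
    ord <- c(macro[order(-tab$length[macro])],
             micro[order(-tab$length[micro])])
    tab$chrom_name[ord] <- sprintf("%sscf%d%s", prefix, seq_along(ord),
                                   suffix[ord])
  }
  xi <- which(tab$class == "X")
  tab$chrom_name[xi] <- sprintf("%sscfX%s", prefix, suffix[xi])
  yi <- which(tab$class == "Y")
  if (length(yi))
    tab$chrom_name[yi] <- sprintf("%sscfY_%d%s", prefix, seq_along(yi),
                                  suffix[yi])
  new("ClassificationReport", table = tab, par = report@par,
      params = report@params)
}

#' Write a classification report as TSV
#'
#' @param report a \code{\link{ClassificationReport}}.
#' @param filepath output path.
#' @return \code{filepath}, invisibly.
#' @export
writeClassification <- function(report, filepath) {
  utils::write.table(report@table, filepath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(filepath)
}
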