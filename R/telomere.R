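# telomere-array detection, terminal/internal labeling, misjoin detection at
# gaps, and AGP-based scaffold splitting

#' Scan one sequence for tandem motif runs
#'
#' Finds maximal regions composed of tandem copies of a motif on either
#' strand (the motif itself, or its reverse complement -- for TTAGGG that is
#' CCCTAA). Exact copies are chained into runs, allowing interior non-motif
#' stretches up to \code{max_interrupt} bp; a merged run must still contain
#' at least \code{min_content} motif bases overall. Degenerate motif
#' variants are deliberately not matched.
#'
#' @param seq a single sequence (character or \code{DNAString}).
#' @param motif the tandem motif (default the vertebrate telomere motif).
#' @param max_interrupt maximum interior non-motif stretch (bp) bridged
#'   within one run.
#' @param min_content minimum fraction of motif bases over the merged run.
#' @return data.frame with \code{start}, \code{end} (1-based closed),
#'   \code{strand}, \code{copy_number} (matched motif bases / motif length)
#'   and \code{content}.
#' @examples
#' scanMotifRuns(strrep("TTAGGG", 150))
#' @export
scanMotifRuns <- function(seq, motif = TELOMERE_MOTIF, max_interrupt = 50,
                          min_content = 0.9) {
  if (nchar(motif) < 1) stop("motif length must be >= 1")
  s <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") motif else revcompChar(motif)
    mt <- Biostrings::matchPattern(pat, s)
    if (!length(mt)) next
    r <- IRanges::reduce(as(mt, "IRanges"))  # distinct matched stretches
    st <- IRanges::start(r); en <- IRanges::end(r)
    run_id <- cumsum(c(1, (st[-1] - en[-length(en)] - 1) > max_interrupt))
    for (g in unique(run_id)) {
      idx <- run_id == g
      matched <- sum(en[idx] - st[idx] + 1)
      rs <- min(st[idx]); re <- max(en[idx])
      content <- matched / (re - rs + 1)
      if (content >= min_content)
        out[[length(out) + 1]] <- data.frame(
          start = rs, end = re, strand = strand,
          copy_number = matched / nchar(motif), content = content)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), copy_number = numeric(0),
                      content = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Call telomere arrays on a scaffold set
#'
#' Scans every scaffold for tandem TTAGGG runs on both strands, keeps
#' intervals spanning strictly more than \code{min_span} bp (600 bp = 100
#' motif copies), and labels each call terminal if it starts within
#' \code{terminal_dist} of a scaffold end, else internal. Overlapping calls
#' on opposite strands are resolved to the run with more motif bases, so no
#' reported interval overlaps another.
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or \code{DNAStringSet}.
#' @param min_span minimum span in bp, exclusive (default 600).
#' @param terminal_dist distance from a scaffold end (bp) within which a
#'   call is terminal.
#' @param motif tandem motif.
#' @param max_interrupt passed to \code{\link{scanMotifRuns}}.
#' @return \code{GRanges} with columns \code{motif}, \code{run_strand},
#'   \code{copy_number}, \code{placement}.
#' @export
callTelomeres <- function(scaffolds, min_span = 600, terminal_dist = 10000,
                          motif = TELOMERE_MOTIF, max_interrupt = 50) {
  if (min_span <= 0) stop("min_span must be > 0")
  seqs <- asDNAStringSet(scaffolds)
  out <- list()
  for (id in names(seqs)) {
    runs <- scanMotifRuns(seqs[[id]], motif = motif,
                          max_interrupt = max_interrupt)
    runs <- runs[runs$end - runs$start + 1 > min_span, , drop = FALSE]
    if (!nrow(runs)) next
    # resolve overlaps between strands: keep the run with more motif bases
    if (nrow(runs) > 1) {
      ir <- IRanges::IRanges(runs$start, runs$end)
      keep <- rep(TRUE, nrow(runs))
      ov <- IRanges::findOverlaps(ir, ir)
      ov <- ov[S4Vectors::queryHits(ov) < S4Vectors::subjectHits(ov)]
      for (z in seq_along(ov)) {
        a <- S4Vectors::queryHits(ov)[z]; b <- S4Vectors::subjectHits(ov)[z]
        drop <- if (runs$copy_number[a] >= runs$copy_number[b]) b else a
        keep[drop] <- FALSE
      }
      runs <- runs[keep, , drop = FALSE]
    }
    len <- length(seqs[[id]])
    runs$placement <- ifelse(runs$start - 1 < terminal_dist |
                               runs$end > len - terminal_dist,
                             "terminal", "internal")
    runs$scaffold <- id
    out[[id]] <- runs
  }
  if (!length(out)) return(GenomicRanges::GRanges(
    motif = character(0), run_strand = character(0),
    copy_number = numeric(0), placement = character(0)))
  df <- do.call(rbind, out)
  GenomicRanges::GRanges(df$scaffold, IRanges::IRanges(df$start, df$end),
                         motif = motif, run_strand = df$strand,
                         copy_number = df$copy_number,
                         placement = df$placement)
}

#' Write telomere calls as BED
#'
#' BED6 with name = \code{motif:copy_number:placement}.
#'
#' @param telomeres \code{GRanges} from \code{\link{callTelomeres}}.
#' @param filepath output path.
#' @return \code{filepath}, invisibly.
#' @export
writeTelomereBed <- function(telomeres, filepath) {
  mc <- S4Vectors::mcols(telomeres)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(telomeres)),
                   start = GenomicRanges::start(telomeres) - 1L,
                   end = GenomicRanges::end(telomeres),
                   name = sprintf("%s:%.1f:%s", mc$motif, mc$copy_number,
                                  mc$placement),
                   score = 0L, strand = mc$run_strand)
  utils::write.table(df, filepath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(filepath)
}

#' Derive an AGP-style scaffold plan from sequences
#'
#' Decomposes each scaffold into W (sequence) components separated by N-run
#' gaps of at least \code{min_gap} bp, in AGP v2.1 column layout (1-based
#' closed object coordinates; gap rows carry the gap length and type).
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or \code{DNAStringSet}.
#' @param min_gap minimum N-run length treated as a gap.
#' @return data.frame with AGP columns \code{object}, \code{object_beg},
#'   \code{object_end}, \code{part_number}, \code{component_type},
#'   \code{component_id}, \code{component_beg}, \code{component_end},
#'   \code{orientation}.
#' @export
scaffoldPlan <- function(scaffolds, min_gap = 1) {
  seqs <- asDNAStringSet(scaffolds)
  rows <- list()
  for (id in names(seqs)) {
    n <- length(seqs[[id]])
    gaps <- .nRuns(as.character(seqs[[id]]))
    gaps <- gaps[IRanges::width(gaps) >= min_gap]
    comp_st <- sort(c(1L, IRanges::end(gaps) + 1L))
    comp_en <- sort(c(IRanges::start(gaps) - 1L, n))
    part <- 0L; ci <- 0L
    pieces <- list()
    for (z in seq_along(comp_st)) {
      if (comp_st[z] <= comp_en[z]) {
        part <- part + 1L; ci <- ci + 1L
        pieces[[length(pieces) + 1]] <- data.frame(
          object = id, object_beg = comp_st[z], object_end = comp_en[z],
          part_number = part, component_type = "W",
          component_id = sprintf("%s_c%d", id, ci),
          component_beg = 1L, component_end = comp_en[z] - comp_st[z] + 1L,
          orientation = "+", stringsAsFactors = FALSE)
      }
      if (z <= length(gaps)) {
        part <- part + 1L
        pieces[[length(pieces) + 1]] <- data.frame(
          object = id, object_beg = IRanges::start(gaps)[z],
          object_end = IRanges::end(gaps)[z], part_number = part,
          component_type = "N",
          component_id = as.character(IRanges::width(gaps)[z]),
          component_beg = NA_integer_, component_end = NA_integer_,
          orientation = "scaffold", stringsAsFactors = FALSE)
      }
    }
    rows <- c(rows, pieces)
  }
  if (!length(rows))
    return(data.frame(object = character(0), object_beg = integer(0),
                      object_end = integer(0), part_number = integer(0),
                      component_type = character(0),
                      component_id = character(0),
                      component_beg = integer(0), component_end = integer(0),
                      orientation = character(0)))
  do.call(rbind, rows)
}

# maximal runs of N in a character sequence, as IRanges
.nRuns <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1) return(IRanges::IRanges())
  IRanges::IRanges(as.integer(m),
                   width = attr(m, "match.length"))
}

#' Flag assembly gaps with a nearby internal telomere (misjoins)
#'
#' An internal telomere array close to a scaffolding gap is the signature of
#' a false-positive join: the scaffolder fused two chromosome ends. Returns
#' each gap having an internal telomere within \code{near_dist} bp of a gap
#' boundary, once.
#'
#' @param telomeres \code{GRanges} from \code{\link{callTelomeres}}.
#' @param plan AGP-style plan from \code{\link{scaffoldPlan}}.
#' @param near_dist maximum telomere-to-gap distance in bp.
#' @return data.frame with \code{scaffold} and \code{gap_index} (ordinal of
#'   the gap within its scaffold).
#' @export
detectMisjoins <- function(telomeres, plan, near_dist = 100000) {
  internal <- telomeres[S4Vectors::mcols(telomeres)$placement == "internal"]
  missing <- setdiff(unique(as.character(GenomicRanges::seqnames(internal))),
                     unique(plan$object))
  if (length(missing))
    stop("telomere on scaffold absent from plan: ",
         paste(missing, collapse = ", "))
  gaps <- plan[plan$component_type == "N", , drop = FALSE]
  if (!nrow(gaps) || !length(internal))
    return(data.frame(scaffold = character(0), gap_index = integer(0)))
  gaps$gap_index <- stats::ave(seq_len(nrow(gaps)), gaps$object,
                               FUN = seq_along)
  ggr <- GenomicRanges::GRanges(gaps$object,
    IRanges::IRanges(gaps$object_beg, gaps$object_end))
  d <- GenomicRanges::distanceToNearest(ggr, internal)
  hit <- S4Vectors::mcols(d)$distance <= near_dist
  idx <- S4Vectors::queryHits(d)[hit]
  unique(data.frame(scaffold = gaps$object[idx],
                    gap_index = gaps$gap_index[idx]))
}

#' Split scaffolds at selected gaps
#'
#' Each requested gap is removed (its Ns dropped) and the scaffold is split
#' there; the resulting pieces are named \code{<id>.1}, \code{<id>.2}, ...
#' in 5'-to-3' order. Non-N bases are conserved exactly and the returned AGP
#' plan is rebuilt from the split sequences. Requesting the same gap twice
#' is an error.
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or \code{DNAStringSet}.
#' @param gaps data.frame with \code{scaffold} and \code{gap_index} columns
#'   (as returned by \code{\link{detectMisjoins}}); zero rows is the
#'   identity transform.
#' @param min_gap minimum N-run length counted as a gap (must match the
#'   indexing used to pick \code{gaps}).
#' @return list with \code{scaffolds} (new \code{ScaffoldSet}) and
#'   \code{plan} (AGP of the result).
#' @export
splitAtGaps <- function(scaffolds, gaps, min_gap = 1) {
  seqs <- asDNAStringSet(scaffolds)
  if (nrow(gaps) && anyDuplicated(gaps[c("scaffold", "gap_index")]))
    stop("a gap may be split only once")
  out <- character(0)
  for (id in names(seqs)) {
    sel <- gaps[gaps$scaffold == id, , drop = FALSE]
    if (!nrow(sel)) {
      out[[id]] <- as.character(seqs[[id]])
      next
    }
    runs <- .nRuns(as.character(seqs[[id]]))
    runs <- runs[IRanges::width(runs) >= min_gap]
    if (any(sel$gap_index > length(runs)))
      stop("gap index out of range for scaffold ", id)
    cut <- runs[sel$gap_index]
    st <- sort(IRanges::start(cut)); en <- sort(IRanges::end(cut))
    piece_st <- c(1L, en + 1L)
    piece_en <- c(st - 1L, length(seqs[[id]]))
    for (z in seq_along(piece_st)) {
      if (piece_st[z] > piece_en[z])
        stop("splitting gap ", z, " of ", id, " would create an empty scaffold")
      out[[paste0(id, ".", z)]] <-
        as.character(Biostrings::subseq(seqs[[id]], piece_st[z], piece_en[z]))
    }
  }
  ss <- ScaffoldSet(Biostrings::DNAStringSet(out))
  list(scaffolds = ss, plan = scaffoldPlan(ss, min_gap = min_gap))
}

#' Extract W components of a plan / rebuild scaffolds from a plan
#'
#' \code{planComponents} pulls the component sequences named by an AGP plan
#' out of the scaffold set; \code{buildFromPlan} reassembles scaffolds from
#' a plan and a component set (inserting N gaps), so that
#' \code{buildFromPlan(plan, planComponents(x, plan))} round-trips.
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or \code{DNAStringSet}.
#' @param plan AGP-style data.frame.
#' @return \code{planComponents}: named \code{DNAStringSet};
#'   \code{buildFromPlan}: a \code{\link{ScaffoldSet}}.
#' @export
planComponents <- function(scaffolds, plan) {
  seqs <- asDNAStringSet(scaffolds)
  w <- plan[plan$component_type == "W", , drop = FALSE]
  comp <- stats::setNames(vapply(seq_len(nrow(w)), function(z)
    as.character(Biostrings::subseq(seqs[[w$object[z]]],
                                    w$object_beg[z], w$object_end[z])),
    character(1)), w$component_id)
  Biostrings::DNAStringSet(comp)
}

#' @rdname planComponents
#' @param components named \code{DNAStringSet} of W-component sequences.
#' @export
buildFromPlan <- function(plan, components) {
  objs <- unique(plan$object)
  seqs <- vapply(objs, function(id) {
    rows <- plan[plan$object == id, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    paste(vapply(seq_len(nrow(rows)), function(z) {
      if (rows$component_type[z] == "N")
        strrep("N", as.integer(rows$component_id[z]))
      else {
        s <- Biostrings::subseq(components[[rows$component_id[z]]],
                                rows$component_beg[z], rows$component_end[z])
        if (rows$orientation[z] == "-")
          as.character(Biostrings::reverseComplement(s))
        else as.character(s)
      }
    }, character(1)), collapse = "")
  }, character(1))
  ScaffoldSet(Biostrings::DNAStringSet(seqs))
}

#' Read/write an AGP v2.1 file
#'
#' @param plan AGP-style data.frame.
#' @param filepath AGP path.
#' @return \code{writeAGP}: \code{filepath} invisibly; \code{readAGP}: the
#'   plan data.frame.
#' @export
writeAGP <- function(plan, filepath) {
  con <- file(filepath, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  df <- plan
  df$component_beg[df$component_type == "N"] <- "scaffold"
  df$component_end[df$component_type == "N"] <- "yes"
  df$orientation[df$component_type == "N"] <- "proximity_ligation"
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(filepath)
}

#' @rdname writeAGP
#' @export
readAGP <- function(filepath) {
  df <- utils::read.table(filepath, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("object", "object_beg", "object_end",
                                        "part_number", "component_type",
                                        "component_id", "component_beg",
                                        "component_end", "orientation"))
  isN <- df$component_type %in% c("N", "U")
  df$component_beg[isN] <- NA
  df$component_end[isN] <- NA
  df$component_beg <- as.integer(df$component_beg)
  df$component_end <- as.integer(df$component_end)
  df$orientation[isN] <- "scaffold"
  df
}
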