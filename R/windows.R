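# nonoverlapping-window GC and depth tracks

# tile scaffolds with nonoverlapping windows (1-based closed GRanges);
# trailing window may be short
.tileWindows <- function(lens, window) {
  st <- lapply(lens, function(L) seq(1L, L, by = window))
  ids <- rep(names(lens), lengths(st))
  st <- unlist(st, use.names = FALSE)
  en <- pmin(st + window - 1L, unname(lens[ids]))
  GenomicRanges::GRanges(ids, IRanges::IRanges(st, en))
}

#' Windowed GC content
#'
#' GC fraction per nonoverlapping window: (G + C) / (A + C + G + T), with N
#' excluded from the denominator; an all-N window gets \code{NA} rather than
#' zero so gap windows never drag medians. The trailing partial window is
#' kept and flagged \code{full = FALSE}.
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or \code{DNAStringSet}.
#' @param window window size in bp (default 10 kb).
#' @return a \code{\link{WindowTrack}} with a \code{gc} column.
#' @export
gcWindows <- function(scaffolds, window = 10000) {
  if (window <= 0) stop("window must be > 0")
  seqs <- asDNAStringSet(scaffolds)
  if (!length(seqs)) {
    return(new("WindowTrack", windows = GenomicRanges::GRanges(),
               windowSize = window))
  }
  gr <- .tileWindows(stats::setNames(Biostrings::width(seqs), names(seqs)),
                     window)
  gc <- unlist(lapply(names(seqs), function(id) {
    s <- seqs[[id]]
    sel <- as.character(GenomicRanges::seqnames(gr)) == id
    v <- Biostrings::Views(s, start = GenomicRanges::start(gr)[sel],
                           end = GenomicRanges::end(gr)[sel])
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    ifelse(denom == 0, NA_real_, (freq[, "C"] + freq[, "G"]) / denom)
  }), use.names = FALSE)
  S4Vectors::mcols(gr)$gc <- gc
  S4Vectors::mcols(gr)$full <- GenomicRanges::width(gr) == window
  new("WindowTrack", windows = gr, windowSize = window)
}

#' Windowed read depth from a per-base depth track
#'
#' Window depth = (sum of per-base depth over the window) / (window span),
#' i.e. samtools-bedcov semantics. Input is a bedGraph-style table of
#' constant-depth segments; positions not covered by any segment count as
#' depth 0. Results are invariant to how the per-base track is chunked.
#'
#' @param per_base_depth data.frame with columns \code{scaffold},
#'   \code{start}, \code{end} (0-based half-open, bedGraph convention) and
#'   \code{depth}; or a \code{GRanges} with a \code{depth} column (1-based).
#' @param scaffold_lengths named vector of scaffold lengths; defaults to the
#'   furthest segment end per scaffold.
#' @param window window size in bp (default 10 kb).
#' @return a \code{\link{WindowTrack}} with a \code{depth} column.
#' @export
depthWindows <- function(per_base_depth, scaffold_lengths = NULL,
                         window = 10000) {
  if (window <= 0) stop("window must be > 0")
  if (is.data.frame(per_base_depth)) {
    seg <- GenomicRanges::GRanges(per_base_depth$scaffold,
      IRanges::IRanges(per_base_depth$start + 1L, per_base_depth$end),
      depth = per_base_depth$depth)
  } else seg <- per_base_depth
  if (any(S4Vectors::mcols(seg)$depth < 0))
    stop("depth values must be >= 0")
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- vapply(
      split(GenomicRanges::end(seg),
            as.character(GenomicRanges::seqnames(seg))), max, numeric(1))
  } else {
    unknown <- setdiff(unique(as.character(GenomicRanges::seqnames(seg))),
                       names(scaffold_lengths))
    if (length(unknown))
      stop("depth track references unknown scaffold(s): ",
           paste(unknown, collapse = ", "))
  }
  gr <- .tileWindows(scaffold_lengths, window)
  ov <- GenomicRanges::findOverlaps(gr, seg)
  wsum <- rep(0, length(gr))
  if (length(ov)) {
    piece <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(ov)],
                                       seg[S4Vectors::subjectHits(ov)])
    contrib <- GenomicRanges::width(piece) *
      S4Vectors::mcols(seg)$depth[S4Vectors::subjectHits(ov)]
    agg <- tapply(contrib, S4Vectors::queryHits(ov), sum)
    wsum[as.integer(names(agg))] <- agg
  }
  S4Vectors::mcols(gr)$depth <- wsum / GenomicRanges::width(gr)
  S4Vectors::mcols(gr)$full <- GenomicRanges::width(gr) == window
  new("WindowTrack", windows = gr, windowSize = window)
}

#' Median of a window statistic on one scaffold
#'
#' Median over non-missing windows, using the lower-median convention for
#' even counts (the smaller central order statistic).
#'
#' @param track a \code{\link{WindowTrack}}.
#' @param scaffold scaffold name.
#' @param field metadata column to summarize (e.g. \code{"gc"},
#'   \code{"depth"}).
#' @param full_only use only full-width windows.
#' @return the lower median.
#' @export
medianWindowStat <- function(track, scaffold, field, full_only = FALSE) {
  gr <- track@windows
  sel <- as.character(GenomicRanges::seqnames(gr)) == scaffold
  if (full_only) sel <- sel & S4Vectors::mcols(gr)$full
  if (!any(sel)) stop("scaffold not present in track: ", scaffold)
  x <- S4Vectors::mcols(gr)[[field]][sel]
  x <- x[!is.na(x)]
  if (!length(x)) stop("all windows missing for field ", field)
  lowerMedian(x)
}

#' Write a WindowTrack as BED4+ TSV
#'
#' One header line, then scaffold, start, end (0-based half-open) and the
#' track's metadata columns.
#'
#' @param track a \code{\link{WindowTrack}}.
#' @param filepath output path.
#' @return \code{filepath}, invisibly.
#' @export
writeWindowTrack <- function(track, filepath) {
  utils::write.table(as.data.frame(track), filepath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(filepath)
}
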