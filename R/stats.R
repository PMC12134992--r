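# contiguity and composition statistics

#' Contiguity statistics (N50/L50 family)
#'
#' Nx is the length of the sequence at which the cumulative sum of
#' descending-sorted lengths first reaches x% of the total; Lx is how many
#' sequences that takes. The mean is rounded half-up to an integer for
#' reporting; the median uses the lower-median convention.
#'
#' @param lengths numeric vector of sequence lengths (> 0).
#' @return list with \code{total_length}, \code{n_sequences}, \code{mean},
#'   \code{median}, \code{longest}, \code{shortest}, \code{N50}, \code{N90},
#'   \code{L50}, \code{L90}.
#' @examples
#' contiguityStats(c(5, 4, 3, 2, 1))  # N50 4, L50 2, N90 1, L90 5
#' @export
contiguityStats <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("all lengths must be > 0")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  total <- cum[length(cum)]
  nx <- function(x) {
    i <- which(cum >= x / 100 * total)[1]
    c(N = s[i], L = i)
  }
  n50 <- nx(50); n90 <- nx(90)
  list(total_length = total, n_sequences = length(lengths),
       mean = roundHalfUp(total / length(lengths)),
       median = lowerMedian(lengths),
       longest = max(lengths), shortest = min(lengths),
       N50 = unname(n50["N"]), N90 = unname(n90["N"]),
       L50 = unname(n50["L"]), L90 = unname(n90["L"]))
}

#' Gap (N-run) statistics of an assembly
#'
#' Counts maximal runs of N per scaffold. Any run of at least
#' \code{min_gap} N is a gap (default 1; raise it for assemblies that use
#' single Ns as ambiguity codes).
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or \code{DNAStringSet}.
#' @param min_gap minimum run length counted as a gap.
#' @return list with \code{n_gaps}, \code{gap_lengths}, \code{total_n}.
#' @export
gapStats <- function(scaffolds, min_gap = 1) {
  seqs <- asDNAStringSet(scaffolds)
  gl <- unlist(lapply(as.character(seqs), function(s) {
    r <- .nRuns(s)
    IRanges::width(r)[IRanges::width(r) >= min_gap]
  }), use.names = FALSE)
  if (is.null(gl)) gl <- integer(0)
  list(n_gaps = length(gl), gap_lengths = gl, total_n = sum(gl))
}

#' Base composition of a sequence
#'
#' Percentages of A, C, G and T over the ACGT bases (N excluded from that
#' denominator and reported separately over all bases), plus GC%. All
#' percentages rounded half-up to 2 decimals.
#'
#' @param seq a sequence (character or \code{DNAString}).
#' @return named numeric: \code{A}, \code{C}, \code{G}, \code{T}, \code{N},
#'   \code{GC}.
#' @export
baseComposition <- function(seq) {
  s <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  if (length(s) == 0) stop("empty sequence")
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T", "N"))
  acgt <- sum(f[c("A", "C", "G", "T")])
  if (acgt == 0) stop("sequence has no ACGT bases")
  out <- c(roundHalfUp(100 * f[c("A", "C", "G", "T")] / acgt, 2),
           N = roundHalfUp(100 * f[["N"]] / length(s), 2),
           GC = roundHalfUp(100 * (f[["C"]] + f[["G"]]) / acgt, 2))
  out
}

#' Fraction of the assembly inside putative expansion (or collapse) regions
#'
#' @param span_bp total bases in the flagged regions.
#' @param assembly_length assembly length in bp (> 0).
#' @return percentage, rounded half-up to 2 decimals.
#' @examples
#' expansionFraction(309329, 1567894183)  # 0.02
#' @export
expansionFraction <- function(span_bp, assembly_length) {
  if (assembly_length <= 0) stop("assembly_length must be > 0")
  roundHalfUp(100 * span_bp / assembly_length, 2)
}

#' Assemble a summary report of the assembly
#'
#' One row per metric in a stable order: contiguity fields, GC%, gap
#' accounting, and (when a classification is supplied) per-class scaffold
#' counts. Regenerating the report from the same inputs is byte-identical.
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or \code{DNAStringSet}.
#' @param classification optional \code{\link{ClassificationReport}}.
#' @param min_gap minimum N-run length counted as a gap.
#' @return data.frame with \code{metric} and \code{value} columns.
#' @export
summaryReport <- function(scaffolds, classification = NULL, min_gap = 1) {
  seqs <- asDNAStringSet(scaffolds)
  cs <- contiguityStats(Biostrings::width(seqs))
  gs <- gapStats(seqs, min_gap = min_gap)
  freq <- colSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  gc <- roundHalfUp(100 * (freq[["C"]] + freq[["G"]]) / sum(freq), 2)
  rows <- data.frame(
    metric = c("assembly_length", "n_sequences", "gc_percent", "n_count",
               "n_gaps", "mean_length", "median_length", "longest",
               "shortest", "N50", "N90", "L50", "L90"),
    value = c(cs$total_length, cs$n_sequences, gc, gs$total_n, gs$n_gaps,
              cs$mean, cs$median, cs$longest, cs$shortest, cs$N50, cs$N90,
              cs$L50, cs$L90),
    stringsAsFactors = FALSE)
  if (!is.null(classification)) {
    cl <- table(classification@table$class)
    rows <- rbind(rows, data.frame(
      metric = paste0("n_scaffolds_", names(cl)),
      value = as.numeric(cl), stringsAsFactors = FALSE))
  }
  rows
}
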