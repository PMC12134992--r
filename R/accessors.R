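# constructors, accessors and show methods for the core containers

#' Construct a ScaffoldSet
#'
#' @param seqs a named \code{DNAStringSet}, named character vector of
#'   sequences, or path to a FASTA file.
#' @return a \code{\link{ScaffoldSet}}.
#' @examples
#' ScaffoldSet(c(s1 = "ACGTACGT", s2 = "GGGGCCCC"))
#' @export
ScaffoldSet <- function(seqs) {
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs))
    seqs <- Biostrings::readDNAStringSet(seqs)
  new("ScaffoldSet", seqs = asDNAStringSet(seqs))
}

#' @describeIn ScaffoldSet scaffold sequences as a \code{DNAStringSet}.
#' @param x a \code{ScaffoldSet}.
#' @export
scaffoldSeqs <- function(x) x@seqs

#' @describeIn ScaffoldSet named scaffold lengths (bp).
#' @export
scaffoldLengths <- function(x) {
  stats::setNames(Biostrings::width(x@seqs), names(x@seqs))
}

#' Write a ScaffoldSet to FASTA
#'
#' @param x a \code{\link{ScaffoldSet}}.
#' @param filepath output FASTA path.
#' @return \code{filepath}, invisibly.
#' @export
writeScaffolds <- function(x, filepath) {
  Biostrings::writeXStringSet(scaffoldSeqs(x), filepath)
  invisible(filepath)
}

setMethod("show", "ScaffoldSet", function(object) {
  cat("ScaffoldSet with", length(object@seqs), "scaffolds,",
      format(sum(Biostrings::width(object@seqs)), big.mark = ","),
      "bp total\n")
})

setMethod("length", "ScaffoldSet", function(x) length(x@seqs))

setMethod("names", "ScaffoldSet", function(x) names(x@seqs))

#' @describeIn TruthTable planted feature intervals as \code{GRanges}.
#' @param x a \code{TruthTable}.
#' @export
truthFeatures <- function(x) x@features

#' @describeIn TruthTable named character of true scaffold classes.
#' @export
truthClasses <- function(x) x@scaffold_classes

#' @describeIn TruthTable planted satellite monomer sequences.
#' @export
truthMonomers <- function(x) x@monomers

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", length(object@scaffold_classes), "scaffolds,",
      length(object@features), "planted features\n")
  print(table(object@scaffold_classes))
})

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", object@n_macro, "macro +", object@n_micro, "micro",
      if (object@x_len > 0) "+ X" else "",
      if (length(object@y_fragment_lens)) sprintf("+ %d Y fragments",
        length(object@y_fragment_lens)) else "",
      "\n  cen families:", length(object@cen_monomers),
      " misjoins:", object@misjoin_count,
      " seed:", object@seed, "\n")
})

#' @describeIn WindowTrack windows and their metadata as \code{GRanges}.
#' @param x a \code{WindowTrack}.
#' @export
trackWindows <- function(x) x@windows

#' @describeIn WindowTrack nominal window size (bp).
#' @export
windowSize <- function(x) x@windowSize

#' Convert a WindowTrack to a data.frame
#'
#' Coordinates come out 0-based half-open (BED convention) in columns
#' \code{start} and \code{end}.
#'
#' @param x a \code{\link{WindowTrack}}.
#' @param ... unused.
#' @return data.frame with scaffold, start, end and track columns.
#' @export
setMethod("as.data.frame", "WindowTrack", function(x, ...) {
  gr <- x@windows
  df <- data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(S4Vectors::mcols(gr)))
})

setMethod("show", "WindowTrack", function(object) {
  cat("WindowTrack:", length(object@windows), "windows of",
      object@windowSize, "bp on",
      length(unique(GenomicRanges::seqnames(object@windows))),
      "scaffolds; fields:",
      paste(setdiff(colnames(S4Vectors::mcols(object@windows)), "full"),
            collapse = ", "), "\n")
})

#' Construct a KmerHistogram
#'
#' @param k k-mer length.
#' @param counts data.frame with \code{multiplicity} and \code{count}
#'   columns, or a named numeric vector (names = multiplicities).
#' @param total_bases total read bases B (optional).
#' @param mean_read_len mean read length L (optional).
#' @return a \code{\link{KmerHistogram}}.
#' @export
KmerHistogram <- function(k, counts, total_bases = NA_real_,
                          mean_read_len = NA_real_) {
  if (!is.data.frame(counts))
    counts <- data.frame(multiplicity = as.numeric(names(counts)),
                         count = as.numeric(counts))
  counts <- counts[order(counts$multiplicity), , drop = FALSE]
  rownames(counts) <- NULL
  new("KmerHistogram", k = k, counts = counts,
      total_bases = total_bases, mean_read_len = mean_read_len)
}

#' @describeIn KmerHistogram histogram as a two-column data.frame.
#' @param x a \code{KmerHistogram}.
#' @export
kmerCounts <- function(x) x@counts

setMethod("show", "KmerHistogram", function(object) {
  cat("KmerHistogram (k =", object@k, "):",
      nrow(object@counts), "multiplicity bins,",
      format(sum(object@counts$count), big.mark = ","),
      "distinct k-mers\n")
})

setMethod("show", "KmerSet", function(object) {
  cat("KmerSet (k =", object@k,
      if (object@canonical) ", canonical" else "", "):",
      format(length(object@members), big.mark = ","),
      "distinct k-mers\n")
})

#' Read/write a k-mer histogram as two-column TSV
#'
#' The on-disk format is two tab-separated columns, \code{multiplicity} and
#' \code{count}, with a header line.
#'
#' @param x a \code{\link{KmerHistogram}}.
#' @param filepath TSV path.
#' @return \code{writeKmerHistogram}: \code{filepath} invisibly;
#'   \code{readKmerHistogram}: a \code{KmerHistogram}.
#' @param k k-mer length to record on read.
#' @export
writeKmerHistogram <- function(x, filepath) {
  utils::write.table(x@counts, filepath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(filepath)
}

#' @rdname writeKmerHistogram
#' @export
readKmerHistogram <- function(filepath, k) {
  df <- utils::read.table(filepath, header = TRUE, sep = "\t")
  KmerHistogram(k = k, counts = df)
}

#' @describeIn ClassificationReport per-scaffold class/evidence table.
#' @param x a \code{ClassificationReport}.
#' @export
classificationTable <- function(x) x@table

#' @describeIn ClassificationReport detected PAR interval (\code{GRanges})
#'   or \code{NULL}.
#' @export
parInterval <- function(x) x@par

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport for", nrow(object@table), "scaffolds\n")
  print(table(object@table$class))
  if (!is.null(object@par))
    cat("PAR:", as.character(GenomicRanges::seqnames(object@par)), ":",
        GenomicRanges::start(object@par) - 1L, "-",
        GenomicRanges::end(object@par), "\n")
})
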