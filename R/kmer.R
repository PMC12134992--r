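# exact desk-scale k-mer statistics: counting, histogram peak detection,
# genome-size and depth arithmetic, and meryl/Merqury-style completeness / QV

# canonicalize a character vector of k-mers (lexicographic min of the k-mer
# and its reverse complement)
.canonicalize <- function(kmers) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

# all k-mer instances (character vector) of one sequence, skipping any k-mer
# containing a non-ACGT character
.kmerInstances <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, seq_len(n - k + 1), k:n)
  km[!grepl("[^ACGT]", km)]
}

#' Count k-mers exactly at toy scale
#'
#' Enumerates every k-mer instance of the input sequences (skipping k-mers
#' containing non-ACGT characters), canonicalizes by default, and returns
#' both the multiplicity histogram and the distinct k-mer set. Everything is
#' held in memory; this is a desk-scale tool, not a disk-backed counter.
#'
#' @param sequences \code{\link{ScaffoldSet}}, \code{DNAStringSet}, or
#'   character vector of sequences.
#' @param k k-mer length (>= 1).
#' @param canonical collapse each k-mer with its reverse complement.
#' @return list with \code{histogram} (\code{\link{KmerHistogram}}) and
#'   \code{set} (\code{\link{KmerSet}} carrying multiplicities).
#' @examples
#' countKmers("ACGT", k = 4)$histogram
#' @export
countKmers <- function(sequences, k, canonical = TRUE) {
  if (k < 1) stop("k must be >= 1")
  seqs <- as.character(asDNAStringSet(sequences))
  if (!length(seqs)) stop("sequences must be non-empty")
  inst <- unlist(lapply(seqs, .kmerInstances, k = k), use.names = FALSE)
  if (!length(inst)) {
    warning("k exceeds every sequence length; empty k-mer set")
    return(list(histogram = KmerHistogram(k, data.frame(
                  multiplicity = numeric(0), count = numeric(0))),
                set = new("KmerSet", k = k, members = character(0),
                          counts = integer(0), canonical = canonical)))
  }
  if (canonical) inst <- .canonicalize(inst)
  tab <- table(inst)
  members <- names(tab)
  counts <- as.integer(tab)
  hist_tab <- table(counts)
  list(histogram = KmerHistogram(k, data.frame(
         multiplicity = as.numeric(names(hist_tab)),
         count = as.numeric(hist_tab))),
       set = new("KmerSet", k = k, members = members, counts = counts,
                 canonical = canonical))
}

#' Locate the homozygous peak of a k-mer histogram
#'
#' Smooths the counts with a 3-bin moving average, finds local maxima above
#' the error region (\code{multiplicity > min_multiplicity}), and returns the
#' rightmost maximum whose smoothed height is at least 20\% of the global
#' maximum -- the homozygous peak of a diploid histogram (the heterozygous
#' peak sits at half its multiplicity). Ties break toward higher
#' multiplicity.
#'
#' @param hist a \code{\link{KmerHistogram}}.
#' @param min_multiplicity multiplicities at or below this are treated as
#'   sequencing-error noise and ignored.
#' @return the peak multiplicity (numeric).
#' @export
findHomozygousPeak <- function(hist, min_multiplicity = 5) {
  df <- hist@counts
  full <- stats::setNames(rep(0, max(df$multiplicity)),
                          seq_len(max(df$multiplicity)))
  full[as.character(df$multiplicity)] <- df$count
  y <- as.numeric(stats::filter(full, rep(1 / 3, 3), sides = 2))
  y[is.na(y)] <- full[is.na(y)]
  m <- as.numeric(names(full))
  usable <- m > min_multiplicity
  if (!any(usable)) stop("no histogram mass above min_multiplicity")
  # local maxima on the smoothed curve (plateau-tolerant, ties -> rightmost)
  n <- length(y)
  left <- c(Inf, y[-n]); right <- c(y[-1], -Inf)
  is_max <- y >= left & y > right & usable
  if (!any(is_max))
    stop("histogram is monotone above the noise floor; no usable peak")
  cand <- which(is_max)
  cand <- cand[y[cand] >= 0.2 * max(y[cand])]
  m[max(cand)]
}

#' k-mer genome-size estimate
#'
#' G = B (L - k + 1) / (L d): total k-mers in the reads, B(L-k+1)/L, divided
#' by the homozygous-peak k-mer depth d.
#'
#' @param B total sequenced bases.
#' @param L mean read length (must exceed \code{k}).
#' @param k k-mer length.
#' @param d homozygous-peak k-mer multiplicity.
#' @return genome size in bp; the \code{display_gb} attribute carries the
#'   value in Gb rounded half-up to 2 decimals.
#' @examples
#' g <- estimateGenomeSize(110612868725, 241.2, 17, 63)
#' attr(g, "display_gb")  # 1.64
#' @export
estimateGenomeSize <- function(B, L, k, d) {
  if (L <= k) stop("mean read length L must exceed k")
  if (d <= 0) stop("peak depth d must be > 0")
  G <- B * (L - k + 1) / (L * d)
  attr(G, "display_gb") <- roundHalfUp(G / 1e9, 2)
  G
}

#' Sequencing depth from total bases
#'
#' Total platform bases divided by the reference (assembly) length, rounded
#' half-up to 2 decimals for reporting.
#'
#' @param total_bases platform total bases.
#' @param reference_length reference length in bp (> 0).
#' @return x-fold depth, 2 decimals.
#' @examples
#' estimateDepth(110612868725, 1567894183)  # 70.55
#' @export
estimateDepth <- function(total_bases, reference_length) {
  if (reference_length <= 0) stop("reference_length must be > 0")
  roundHalfUp(total_bases / reference_length, 2)
}

#' k-mer completeness of one or more assemblies
#'
#' Percentage of reliable read k-mers (multiplicity above
#' \code{noise_cutoff}) found in the union of the assembly k-mer sets --
#' the Merqury completeness statistic, computed on exact in-memory sets.
#'
#' @param read_set \code{\link{KmerSet}} from reads, carrying multiplicities.
#' @param assembly_sets a \code{KmerSet} or list of them (e.g. two
#'   haplotypes).
#' @param noise_cutoff read k-mers with multiplicity at or below this are
#'   excluded as unreliable.
#' @return completeness percentage in [0, 100].
#' @export
kmerCompleteness <- function(read_set, assembly_sets, noise_cutoff = 1) {
  if (is(assembly_sets, "KmerSet")) assembly_sets <- list(assembly_sets)
  ks <- vapply(assembly_sets, function(s) s@k, numeric(1))
  if (any(ks != read_set@k))
    stop("k mismatch between read and assembly k-mer sets")
  reliable <- read_set@members[read_set@counts > noise_cutoff]
  if (!length(reliable)) stop("no reliable read k-mers above noise_cutoff")
  asm <- unique(unlist(lapply(assembly_sets, function(s) s@members)))
  100 * sum(reliable %in% asm) / length(reliable)
}

#' k-mer quality value (QV) of an assembly
#'
#' Merqury-style per-base quality: with K_err assembly k-mer instances
#' unsupported by the reads out of K_total assembly k-mers, the per-base
#' error rate is E = 1 - (1 - K_err/K_total)^(1/k) and QV = -10 log10(E).
#' K_err = 0 yields \code{Inf}; cap for display.
#'
#' @param assembly_set \code{\link{KmerSet}} of the assembly (with
#'   multiplicities).
#' @param read_set \code{\link{KmerSet}} of the reads.
#' @param k k-mer length.
#' @param assembly_kmer_total total assembly k-mer instances K_total;
#'   defaults to the sum of the assembly set's multiplicities.
#' @return list with \code{qv}, \code{error_rate}, \code{k_err},
#'   \code{k_total}.
#' @export
estimateQV <- function(assembly_set, read_set, k = assembly_set@k,
                       assembly_kmer_total = sum(assembly_set@counts)) {
  if (assembly_kmer_total <= 0) stop("assembly_kmer_total must be > 0")
  if (assembly_set@k != read_set@k)
    stop("k mismatch between assembly and read k-mer sets")
  miss <- !(assembly_set@members %in% read_set@members)
  k_err <- sum(assembly_set@counts[miss])
  E <- 1 - (1 - k_err / assembly_kmer_total)^(1 / k)
  qv <- if (E <= 0) Inf else -10 * log10(E)
  list(qv = qv, error_rate = E, k_err = k_err, k_total = assembly_kmer_total)
}
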