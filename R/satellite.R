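# de novo tandem-satellite discovery: repetitive-window candidates, monomer
# period inference by shift-match score, consensus building, centromere
# prioritization, higher-order-repeat testing, template-guided re-annotation

#' Flag repetitive candidate windows
#'
#' A window is a tandem-repeat candidate when more than
#' \code{min_repetitiveness} of its k-mer positions carry a k-mer occurring
#' at least twice within the window. Adjacent candidate windows are merged.
#' Random sequence almost never repeats a 12-mer within a few kb, so the
#' detector is specific at the defaults.
#'
#' @param seq a single sequence (character or \code{DNAString}).
#' @param k k-mer length for the repetitiveness screen.
#' @param window window size in bp.
#' @param min_repetitiveness minimum repeated-k-mer fraction.
#' @return data.frame of merged candidate regions (\code{start}, \code{end},
#'   1-based closed) with mean repetitiveness.
#' @export
detectRepetitiveWindows <- function(seq, k = 12, window = 2000,
                                    min_repetitiveness = 0.5) {
  if (k >= window) stop("k must be smaller than window")
  s <- as.character(seq)
  n <- nchar(s)
  st <- seq(1L, n, by = window)
  en <- pmin(st + window - 1L, n)
  rep_frac <- vapply(seq_along(st), function(z) {
    sub <- substr(s, st[z], en[z])
    km <- .kmerInstances(sub, k)
    if (!length(km)) return(0)
    tab <- table(km)
    sum(tab[tab >= 2]) / length(km)
  }, numeric(1))
  hit <- rep_frac > min_repetitiveness
  if (!any(hit))
    return(data.frame(start = integer(0), end = integer(0),
                      repetitiveness = numeric(0)))
  r <- IRanges::reduce(IRanges::IRanges(st[hit], en[hit]))
  ov <- IRanges::findOverlaps(IRanges::IRanges(st[hit], en[hit]), r)
  data.frame(start = IRanges::start(r), end = IRanges::end(r),
             repetitiveness = as.numeric(tapply(
               rep_frac[hit], S4Vectors::subjectHits(ov), mean)))
}

#' Infer the fundamental monomer period of a tandem array
#'
#' Computes the shift-match score S(p) = fraction of positions i with
#' seq[i] == seq[i + p] for every candidate period p, and returns the
#' smallest p whose score is within \code{tie_tol} of the global maximum --
#' the fundamental period rather than one of its multiples.
#'
#' @param array_seq the array sequence (character or \code{DNAString}).
#' @param max_period largest period considered.
#' @param min_score minimum acceptable S(p); below this the sequence is not
#'   considered tandem and an error is raised.
#' @param tie_tol relative tolerance within which maxima are tied (smallest
#'   period wins).
#' @return the period in bp, with attribute \code{score}.
#' @export
inferMonomerPeriod <- function(array_seq, max_period = 500,
                               min_score = 0.6, tie_tol = 0.01) {
  s <- as.character(array_seq)
  n <- nchar(s)
  if (n < 2 * max_period)
    stop("array must be at least twice max_period long")
  v <- charToRaw(s)
  score <- vapply(2:max_period, function(p)
    mean(v[seq_len(n - p)] == v[(p + 1):n]), numeric(1))
  best <- max(score)
  if (best < min_score)
    stop("no period with shift-match score >= ", min_score,
         "; sequence does not look tandem")
  p <- (2:max_period)[which(score >= best * (1 - tie_tol))[1]]
  structure(p, score = score[p - 1])
}

#' Majority-vote consensus monomer of a tandem array
#'
#' Phase is anchored at the array start: the array is cut into consecutive
#' full copies of \code{period} bp and each consensus column is the majority
#' base over copies (ties resolved alphabetically).
#'
#' @param array_seq the array sequence.
#' @param period monomer period from \code{\link{inferMonomerPeriod}}.
#' @return consensus monomer (character of length \code{period}).
#' @export
buildConsensusMonomer <- function(array_seq, period) {
  s <- as.character(array_seq)
  ncop <- nchar(s) %/% period
  if (ncop < 3) stop("need at least 3 full monomer copies for a consensus")
  mat <- matrix(strsplit(substr(s, 1, ncop * period), "")[[1]],
                nrow = ncop, ncol = period, byrow = TRUE)
  cons <- apply(mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    nm <- names(tab)[tab == max(tab)]
    sort(nm)[1]
  })
  paste(cons, collapse = "")
}

#' Flag centromeric-candidate satellite families
#'
#' A family is a centromere candidate when the genome-wide span of its
#' arrays strictly exceeds \code{min_total_span} (default 100 kb).
#'
#' @param families data.frame with at least \code{family} and
#'   \code{total_span} columns (see \code{\link{summarizeSatellites}}).
#' @param min_total_span prioritization threshold in bp.
#' @return the input with a logical \code{centromeric_candidate} column.
#' @export
classifyCentromeric <- function(families, min_total_span = 100000) {
  families$centromeric_candidate <- families$total_span > min_total_span
  families
}

#' Test a tandem array for higher-order repeat structure
#'
#' Cuts the array into monomer copies and computes the mean per-position
#' identity between copies at lag m for m = 1..\code{max_order}. A
#' higher-order repeat of order m* > 1 is reported when identity at lag m*
#' exceeds identity at lag 1 by more than \code{margin}; otherwise
#' \code{"none"}. The statistic is this package's definition of the
#' negative/positive HOR finding and is returned alongside the call.
#'
#' @param array_seq the array sequence.
#' @param period monomer period in bp.
#' @param max_order largest HOR order tested.
#' @param margin identity advantage over lag 1 required to call a HOR.
#' @return list with \code{order} (\code{"none"} or the integer order) and
#'   \code{identity_by_lag}.
#' @export
detectHOR <- function(array_seq, period, max_order = 8, margin = 0.05) {
  s <- as.character(array_seq)
  ncop <- nchar(s) %/% period
  if (ncop < 2 * max_order)
    stop("array too short: need at least 2 x max_order monomer copies")
  mat <- matrix(strsplit(substr(s, 1, ncop * period), "")[[1]],
                nrow = ncop, ncol = period, byrow = TRUE)
  ident <- vapply(seq_len(max_order), function(m) {
    i <- seq_len(ncop - m)
    mean(mat[i, , drop = FALSE] == mat[i + m, , drop = FALSE])
  }, numeric(1))
  better <- which(ident[-1] > ident[1] + margin) + 1
  list(order = if (length(better)) better[which.max(ident[better])] else "none",
       identity_by_lag = ident)
}

#' Re-annotate satellite arrays with monomer templates
#'
#' Seed-and-extend scan for tandem stretches of each template monomer, on
#' both strands. An exact seed (the template's first 15 bp) locates
#' candidate copies and fixes the phase; copies are then counted by stepping
#' one period at a time in both directions while the per-copy identity to
#' the template stays at or above \code{min_identity}. Runtime is linear in
#' sequence length, and array boundaries are recovered to within one period.
#'
#' @param scaffolds \code{\link{ScaffoldSet}} or \code{DNAStringSet}.
#' @param templates named character vector or \code{DNAStringSet} of monomer
#'   templates (non-empty).
#' @param min_identity minimum per-copy identity to the template.
#' @return \code{GRanges} with columns \code{family}, \code{period},
#'   \code{copy_number}, \code{run_strand}.
#' @export
refineWithTemplates <- function(scaffolds, templates, min_identity = 0.8) {
  if (length(templates) == 0) stop("templates must be non-empty")
  seqs <- asDNAStringSet(scaffolds)
  tset <- asDNAStringSet(templates)
  out <- list()
  for (fam in names(tset)) {
    for (id in names(seqs)) {
      for (strand in c("+", "-")) {
        tpl <- if (strand == "+") tset[[fam]]
               else Biostrings::reverseComplement(tset[[fam]])
        arr <- .templateArrays(seqs[[id]], as.character(tpl), min_identity)
        if (!nrow(arr)) next
        arr$scaffold <- id
        arr$family <- fam
        arr$period <- length(tpl)
        arr$run_strand <- strand
        out[[length(out) + 1]] <- arr
      }
    }
  }
  if (!length(out)) return(GenomicRanges::GRanges(
    family = character(0), period = integer(0), copy_number = numeric(0),
    run_strand = character(0)))
  df <- do.call(rbind, out)
  GenomicRanges::GRanges(df$scaffold, IRanges::IRanges(df$start, df$end),
                         family = df$family, period = df$period,
                         copy_number = df$copies, run_strand = df$run_strand)
}

# phase-locked array discovery for one oriented template on one sequence
.templateArrays <- function(seq, tpl, min_identity) {
  p <- nchar(tpl)
  seed_len <- min(15L, p)
  seed <- substr(tpl, 1, seed_len)
  hits <- Biostrings::matchPattern(seed, seq)
  empty <- data.frame(start = integer(0), end = integer(0),
                      copies = integer(0))
  if (!length(hits)) return(empty)
  sv <- charToRaw(as.character(seq))
  tv <- charToRaw(tpl)
  n <- length(sv)
  copyIdent <- function(pos) {  # identity of the copy starting at pos
    if (pos < 1 || pos + p - 1 > n) return(-1)
    mean(sv[pos:(pos + p - 1)] == tv)
  }
  st <- sort(Biostrings::start(hits))
  claimed_to <- 0L
  rows <- list()
  for (h in st) {
    if (h <= claimed_to) next
    if (copyIdent(h) < min_identity) next
    left <- h
    while (copyIdent(left - p) >= min_identity) left <- left - p
    right <- h
    while (copyIdent(right + p) >= min_identity) right <- right + p
    copies <- (right - left) / p + 1
    if (copies >= 2) {
      rows[[length(rows) + 1]] <- data.frame(
        start = left, end = right + p - 1L, copies = copies)
    }
    claimed_to <- right + p - 1L
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' Summarize satellite arrays into per-family totals
#'
#' @param arrays \code{GRanges} from \code{\link{refineWithTemplates}}.
#' @return data.frame with \code{family}, \code{period}, \code{n_arrays},
#'   \code{total_span}.
#' @export
summarizeSatellites <- function(arrays) {
  if (!length(arrays))
    return(data.frame(family = character(0), period = integer(0),
                      n_arrays = integer(0), total_span = numeric(0)))
  fam <- S4Vectors::mcols(arrays)$family
  df <- data.frame(family = fam,
                   period = S4Vectors::mcols(arrays)$period,
                   span = GenomicRanges::width(arrays))
  agg <- do.call(rbind, lapply(split(df, df$family), function(d)
    data.frame(family = d$family[1], period = d$period[1],
               n_arrays = nrow(d), total_span = sum(d$span))))
  rownames(agg) <- NULL
  agg
}

#' Per-scaffold fraction covered by satellite arrays
#'
#' Used to flag "satellite-only" scaffolds (more than half their length in
#' centromeric-family arrays).
#'
#' @param arrays \code{GRanges} of satellite arrays.
#' @param scaffold_lengths named lengths in bp.
#' @return named numeric of covered fractions per scaffold (0 where none).
#' @export
satelliteCoverage <- function(arrays, scaffold_lengths) {
  out <- stats::setNames(rep(0, length(scaffold_lengths)),
                         names(scaffold_lengths))
  if (!length(arrays)) return(out)
  red <- GenomicRanges::reduce(arrays)
  cov <- tapply(GenomicRanges::width(red),
                as.character(GenomicRanges::seqnames(red)), sum)
  ids <- intersect(names(cov), names(out))
  out[ids] <- cov[ids] / scaffold_lengths[ids]
  out
}
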