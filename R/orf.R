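# full-length ORF selection from transcript-vs-protein alignment tables and
# greedy representative clustering

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Best protein hit per transcript
#'
#' Maximal bitscore; ties broken by longer protein alignment, then
#' lexicographic protein id.
#'
#' @param hits data.frame of blastx-style hits with columns
#'   \code{transcript}, \code{protein}, \code{frame}, \code{tstart},
#'   \code{tend}, \code{pstart}, \code{pend}, \code{plen}, \code{bitscore}.
#' @return one best-hit row per transcript.
#' @export
bestHit <- function(hits) {
  if (!nrow(hits)) stop("need at least one hit")
  pick <- function(h) {
    alen <- h$pend - h$pstart + 1
    h[order(-h$bitscore, -alen, h$protein), , drop = FALSE][1, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(hits, hits$transcript), pick))
  rownames(out) <- NULL
  out
}

# codon vector of the oriented sequence in reading frame f (1-3)
.codons <- function(seq, f) {
  n <- nchar(seq)
  if (n - f + 1 < 3) return(character(0))
  st <- seq(f, n - 2, by = 3)
  substring(seq, st, st + 2)
}

#' Extract the ORF implied by a protein alignment
#'
#' Orients the transcript by the hit's frame, then extends the aligned
#' region upstream to the nearest in-frame ATG (stopping at an in-frame stop
#' codon or the 5' end, in which case \code{has_start} is \code{FALSE}) and
#' downstream to the nearest in-frame stop. A stop codon inside the aligned
#' region marks the call \code{partial} with a warning. The amino-acid
#' sequence is translated with the standard genetic code.
#'
#' @param transcript_seq transcript sequence (character or \code{DNAString}).
#' @param hit one row as returned by \code{\link{bestHit}}; \code{frame} in
#'   1..3 (forward) or -1..-3 (reverse), \code{tstart}/\code{tend} 1-based
#'   closed on the forward strand.
#' @return list with \code{transcript}, \code{aa}, \code{nt},
#'   \code{has_start}, \code{has_stop}, \code{length} (aa) and
#'   \code{status} (\code{aligned_orf} or \code{partial}).
#' @export
extractOrf <- function(transcript_seq, hit) {
  s <- toupper(as.character(transcript_seq))
  n <- nchar(s)
  fr <- hit$frame
  if (abs(fr) < 1 || abs(fr) > 3) stop("invalid frame: ", fr)
  if (hit$tstart < 1 || hit$tend > n) stop("hit interval outside transcript")
  if (fr < 0) {
    s <- revcompChar(s)
    astart <- n - hit$tend + 1
    aend <- n - hit$tstart + 1
  } else {
    astart <- hit$tstart
    aend <- hit$tend
  }
  f <- abs(fr)
  if ((astart - f) %% 3 != 0)
    stop("hit interval is not in the stated frame")
  cod <- .codons(s, f)
  c0 <- (astart - f) %/% 3 + 1       # codon index of alignment start
  ce <- (aend + 1 - f) %/% 3          # last codon fully inside the alignment
  # upstream extension to the nearest in-frame ATG
  has_start <- FALSE
  start_i <- c0
  for (i in seq(c0, 1)) {
    if (cod[i] %in% STOP_CODONS && i < c0) break
    if (cod[i] == "ATG") { has_start <- TRUE; start_i <- i; break }
  }
  # downstream to the nearest in-frame stop
  stops <- which(cod %in% STOP_CODONS)
  stops <- stops[stops >= start_i]
  status <- "aligned_orf"
  if (length(stops) && stops[1] <= ce && stops[1] >= c0) {
    warning("internal stop codon inside the aligned region of ",
            hit$transcript)
    status <- "partial"
  }
  has_stop <- length(stops) > 0
  end_i <- if (has_stop) stops[1] - 1 else length(cod)
  nt <- paste(cod[start_i:end_i], collapse = "")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
  list(transcript = hit$transcript, aa = aa, nt = nt,
       has_start = has_start, has_stop = has_stop,
       length = nchar(aa), status = status)
}

#' Full-length status of an extracted ORF
#'
#' Full length requires both a start and a stop codon and a translated
#' length between 95\% and 105\% (inclusive) of the best-hit protein.
#'
#' @param orf list from \code{\link{extractOrf}}.
#' @param protein_len full length (aa) of the best-hit protein (> 0).
#' @return the orf with \code{ratio_to_hit} and updated \code{status}
#'   (\code{full_length} or \code{partial}).
#' @export
classifyFullLength <- function(orf, protein_len) {
  if (protein_len <= 0) stop("protein length must be > 0")
  ratio <- orf$length / protein_len
  orf$ratio_to_hit <- ratio
  orf$status <- if (orf$has_start && orf$has_stop &&
                    ratio >= 0.95 && ratio <= 1.05) "full_length"
                else "partial"
  orf
}

#' Six-frame ORF scan for unaligned transcripts
#'
#' Every ATG...stop pair in any of the six frames whose translated length
#' strictly exceeds \code{min_len} amino acids (the stop codon is not
#' counted). Used for transcripts with no protein hit.
#'
#' @param transcript_seq transcript sequence.
#' @param min_len exclusive minimum ORF length in aa (default 50).
#' @return data.frame with \code{strand}, \code{frame}, \code{start}
#'   (1-based nt position on the oriented sequence), \code{length} (aa),
#'   \code{aa} and \code{status = "unaligned_orf"}.
#' @export
findOrfsUnaligned <- function(transcript_seq, min_len = 50) {
  s_fwd <- toupper(as.character(transcript_seq))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") s_fwd else revcompChar(s_fwd)
    for (f in 1:3) {
      cod <- .codons(s, f)
      stops <- which(cod %in% STOP_CODONS)
      for (a in which(cod == "ATG")) {
        nxt <- stops[stops > a]
        if (!length(nxt)) next
        len <- nxt[1] - a
        if (len > min_len) {
          nt <- paste(cod[a:(nxt[1] - 1)], collapse = "")
          out[[length(out) + 1]] <- data.frame(
            strand = strand, frame = f, start = f + (a - 1) * 3,
            length = len,
            aa = as.character(Biostrings::translate(
              Biostrings::DNAString(nt))),
            status = "unaligned_orf", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), length = integer(0),
                      aa = character(0), status = character(0)))
  do.call(rbind, out)
}

# constant match/mismatch substitution matrix over the AA alphabet
.aaMatrix <- function(match = 1, mismatch = -1) {
  letters <- c(LETTERS, "*")
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Greedy length-sorted clustering of amino-acid sequences
#'
#' CD-HIT-style greedy clustering by exhaustive pairwise alignment:
#' sequences are sorted by decreasing length and each joins the first
#' existing cluster whose representative it matches at
#' \code{min_identity} identity (identical positions / length of the
#' shorter sequence) with at least \code{min_short_coverage} of the shorter
#' sequence aligned; otherwise it founds a new cluster. Representatives are
#' the founding (longest) members. Alignment is ends-free pairwise
#' alignment, acceptable at desk scale.
#'
#' @param aa_seqs named character vector of amino-acid sequences.
#' @param min_identity minimum pairwise identity.
#' @param min_short_coverage minimum aligned fraction of the shorter
#'   sequence.
#' @return list of clusters, each with \code{representative} and
#'   \code{members} (names in joining order, representative first).
#' @export
greedyCluster <- function(aa_seqs, min_identity = 0.8,
                          min_short_coverage = 0.9) {
  if (!length(aa_seqs)) stop("sequences must be non-empty")
  if (is.null(names(aa_seqs)))
    names(aa_seqs) <- paste0("seq", seq_along(aa_seqs))
  ord <- order(-nchar(aa_seqs))
  mat <- .aaMatrix()
  clusters <- list()
  for (i in ord) {
    nm <- names(aa_seqs)[i]
    sq <- aa_seqs[[i]]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_seq <- aa_seqs[[clusters[[ci]]$representative]]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(sq), Biostrings::AAString(rep_seq),
        type = "overlap", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      short_len <- min(nchar(sq), nchar(rep_seq))
      ident <- Biostrings::nmatch(aln) / short_len
      pat <- Biostrings::pattern(aln)
      covered <- (IRanges::end(pat) - IRanges::start(pat) + 1) / nchar(sq)
      if (ident >= min_identity && covered >= min_short_coverage) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, nm)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1]] <- list(representative = nm,
                                               members = nm)
  }
  clusters
}

#' Simulate coding transcripts with a known protein truth
#'
#' Generates random proteins (Met start, no internal stops), reverse
#' translates them through random synonymous codons, wraps the CDS in
#' untranslated ends, and returns the transcripts together with a
#' blastx-style best-hit table pointing at the true CDS interval. Used to
#' exercise ORF extraction against a known answer.
#'
#' @param n number of transcripts.
#' @param aa_len_range protein length range (aa).
#' @param utr_len_range UTR length range (nt) on each side.
#' @param seed RNG seed.
#' @param revcomp_some reverse-complement a random half of the transcripts
#'   (hits get negative frames).
#' @return list with \code{transcripts} (named character), \code{proteins}
#'   (named character) and \code{hits} (data.frame for
#'   \code{\link{extractOrf}}).
#' @export
simulateTranscripts <- function(n = 10, aa_len_range = c(80, 200),
                                utr_len_range = c(10, 60), seed = 1,
                                revcomp_some = TRUE) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  aas <- setdiff(unique(unname(code)), "*")
  withSeed(seed, {
    tx <- character(n); pr <- character(n)
    hits <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(seq(aa_len_range[1], aa_len_range[2]), 1)
      aa <- c("M", sample(aas, len - 1, replace = TRUE))
      cds <- paste(c(vapply(aa, function(a) sample(by_aa[[a]], 1),
                            character(1)), sample(STOP_CODONS, 1)),
                   collapse = "")
      u5 <- randomDNA(sample(seq(utr_len_range[1], utr_len_range[2]), 1), 0.5)
      # keep the upstream UTR free of in-frame ATG/stop so the planted start
      # is the nearest one
      repeat {
        cod_u <- .codons(u5, nchar(u5) %% 3 + 1)
        if (!any(cod_u %in% c("ATG", STOP_CODONS))) break
        u5 <- randomDNA(nchar(u5), 0.5)
      }
      u3 <- randomDNA(sample(seq(utr_len_range[1], utr_len_range[2]), 1), 0.5)
      t_fwd <- paste0(u5, cds, u3)
      cds_start <- nchar(u5) + 1
      cds_end <- nchar(u5) + nchar(cds) - 3   # aligned interval excludes stop
      strand_neg <- revcomp_some && stats::runif(1) < 0.5
      if (strand_neg) {
        tx[i] <- revcompChar(t_fwd)
        nlen <- nchar(t_fwd)
        hits[[i]] <- data.frame(
          transcript = sprintf("tx%03d", i), protein = sprintf("prot%03d", i),
          frame = -(((cds_start - 1) %% 3) + 1),
          tstart = nlen - cds_end + 1, tend = nlen - cds_start + 1,
          pstart = 1L, pend = length(aa), plen = length(aa),
          bitscore = round(stats::runif(1, 100, 500)))
      } else {
        tx[i] <- t_fwd
        hits[[i]] <- data.frame(
          transcript = sprintf("tx%03d", i), protein = sprintf("prot%03d", i),
          frame = ((cds_start - 1) %% 3) + 1,
          tstart = cds_start, tend = cds_end,
          pstart = 1L, pend = length(aa), plen = length(aa),
          bitscore = round(stats::runif(1, 100, 500)))
      }
      pr[i] <- paste(aa, collapse = "")
    }
    names(tx) <- sprintf("tx%03d", seq_len(n))
    names(pr) <- sprintf("prot%03d", seq_len(n))
    list(transcripts = tx, proteins = pr, hits = do.call(rbind, hits))
  })
}
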