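# shared fixtures, built once per test run

# compact full-feature genome used by several suites (~4 Mb, every class)
smallSpec <- function(seed = 101) {
  GenomeSpec(n_macro = 3, n_micro = 3,
             macro_len_range = c(5e5, 8e5),
             micro_len_range = c(1.5e5, 2.5e5),
             x_len = 4e5, y_fragment_lens = c(8e4, 6e4),
             telomere_copies = 150,
             cen_monomers = list(c(187, 112200), c(199, 111440)),
             gap_len = 200, misjoin_count = 1, benign_gap_count = 1,
             rdna_scaffolds = 1, mito_len = 17506, par_len = 1e5,
             seed = seed)
}

smallGenome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generateGenome(smallSpec())
    cache
  }
})

# brute-force oracles, independent of the implementation paths they check

bruteGC <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  acgt <- ch %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  sum(ch %in% c("G", "C")) / sum(acgt)
}

bruteNx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  tot <- sum(s)
  run <- 0
  for (i in seq_along(s)) {
    run <- run + s[i]
    if (run >= x / 100 * tot) return(c(N = s[i], L = i))
  }
}

bruteShiftScore <- function(seq, p) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  mean(ch[seq_len(n - p)] == ch[(p + 1):n])
}

bruteKmers <- function(seq, k, canonical = TRUE) {
  n <- nchar(seq)
  km <- vapply(seq_len(n - k + 1), function(i) substr(seq, i, i + k - 1),
               character(1))
  km <- km[!grepl("[^ACGT]", km)]
  if (canonical) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- vapply(km, function(x) paste(rev(comp[strsplit(x, "")[[1]]]),
                                       collapse = ""), character(1))
    km <- ifelse(km <= rc, km, rc)
  }
  km
}
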