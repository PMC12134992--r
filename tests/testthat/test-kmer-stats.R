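# k-mer counting, peak detection, genome-size/depth arithmetic, QV

test_that("countKmers matches hand and brute-force enumeration", {
  # ACGT is its own reverse complement: one canonical 4-mer, count 1
  r <- countKmers("ACGT", 4)
  expect_equal(r$set@members, "ACGT")
  expect_equal(kmerCounts(r$histogram),
               data.frame(multiplicity = 1, count = 1))
  # AAAA: three overlapping 2-mers, canonical AA
  r2 <- countKmers("AAAA", 2)
  expect_equal(r2$set@members, "AA")
  expect_equal(r2$set@counts, 3L)
  # random sequence: total k-mer mass = L - k + 1, set equals brute force
  set.seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
             collapse = "")
  r3 <- countKmers(s, 11)
  df <- kmerCounts(r3$histogram)
  expect_equal(sum(df$multiplicity * df$count), 5000 - 11 + 1)
  brute <- table(bruteKmers(s, 11))
  expect_setequal(r3$set@members, names(brute))
  expect_equal(r3$set@counts[match(names(brute), r3$set@members)],
               unname(as.integer(brute)))
})

test_that("non-ACGT k-mers are skipped and oversized k warns", {
  r <- countKmers("ACGTNACGT", 4)
  df <- kmerCounts(r$histogram)
  expect_equal(sum(df$multiplicity * df$count), 2)  # only the two clean ends
  expect_warning(countKmers("ACG", 10), "exceeds")
})

test_that("homozygous peak is the rightmost major mode", {
  mk <- function(mu1, mu2, n1 = 2e5, n2 = 4e5) {
    m <- 1:120
    KmerHistogram(17, data.frame(multiplicity = m,
      count = round(n1 * dpois(m, mu1) + n2 * dpois(m, mu2) +
                    1e5 * dgeom(m - 1, 0.7))))
  }
  expect_equal(findHomozygousPeak(mk(31, 63)), 63)
  # single mode
  h1 <- KmerHistogram(17, data.frame(multiplicity = 1:100,
    count = round(3e5 * dpois(1:100, 40))))
  expect_equal(findHomozygousPeak(h1), 40)
  # monotone histogram: no usable peak
  h2 <- KmerHistogram(17, data.frame(multiplicity = 1:50,
    count = round(1e5 * 0.8^(1:50))))
  expect_error(findHomozygousPeak(h2), "peak")
})

test_that("peak recovery across simulated depths is within one unit", {
  depths <- round(seq(20, 80, length.out = 20))
  for (i in seq_along(depths)) {
    h <- simulateKmerHistogram(3e5, homozygous_depth = depths[i],
                               seed = 1000 + i)
    expect_lte(abs(findHomozygousPeak(h) - depths[i]), 1)
  }
})

test_that("genome-size formula reproduces the printed estimate and scales", {
  G <- estimateGenomeSize(110612868725, 241.2, 17, 63)
  expect_equal(attr(G, "display_gb"), 1.64)
  # homogeneity: doubling B doubles G; doubling d halves G
  g1 <- as.numeric(estimateGenomeSize(1e9, 100, 21, 30))
  expect_equal(as.numeric(estimateGenomeSize(2e9, 100, 21, 30)), 2 * g1)
  expect_equal(as.numeric(estimateGenomeSize(1e9, 100, 21, 60)), g1 / 2)
  # k = 1 degenerates to B / d
  expect_equal(as.numeric(estimateGenomeSize(1000, 50, 1, 10)), 100)
  expect_error(estimateGenomeSize(1e9, 17, 17, 30), "exceed")
})

test_that("genome size is recovered from reads simulated off a known genome", {
  # 100-kb genome read at 30x with 250-bp reads; truth known by construction
  set.seed(11)
  genome <- paste(sample(c("A", "C", "G", "T"), 1e5, replace = TRUE),
                  collapse = "")
  read_len <- 250
  n_reads <- round(30 * 1e5 / read_len)
  starts <- sample(1e5 - read_len + 1, n_reads, replace = TRUE)
  reads <- substring(genome, starts, starts + read_len - 1)
  cnt <- countKmers(reads, 17)
  d <- findHomozygousPeak(cnt$histogram)
  G <- as.numeric(estimateGenomeSize(B = n_reads * read_len, L = read_len,
                                     k = 17, d = d))
  expect_lt(abs(G - 1e5) / 1e5, 0.05)
})

test_that("platform depth arithmetic matches the published table", {
  expect_equal(estimateDepth(110612868725, 1567894183), 70.55)
  expect_equal(estimateDepth(52437383684, 1567894183), 33.44)
  expect_equal(estimateDepth(104472064570, 1567894183), 66.63)
})

test_that("completeness is 100 for identical sets and monotone in unions", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
             collapse = "")
  rk <- countKmers(s, 15)$set
  expect_equal(kmerCompleteness(rk, rk, noise_cutoff = 0), 100)
  # assembly with only the first half of the sequence covers fewer k-mers
  half <- countKmers(substr(s, 1, 2000), 15)$set
  c_half <- kmerCompleteness(rk, half, noise_cutoff = 0)
  expect_lt(c_half, 100)
  other <- countKmers(substr(s, 1900, 4000), 15)$set
  c_union <- kmerCompleteness(rk, list(half, other), noise_cutoff = 0)
  expect_gte(c_union, c_half)
  expect_gte(c_union, kmerCompleteness(rk, other, noise_cutoff = 0))
  # deliberately missing half the distinct reliable k-mers -> 50%
  keep <- rk@members[seq(1, length(rk@members), by = 2)]
  half_set <- new("KmerSet", k = 15, members = keep,
                  counts = rep(1L, length(keep)), canonical = TRUE)
  got <- kmerCompleteness(rk, half_set, noise_cutoff = 0)
  expect_equal(got, 100 * length(keep) / length(rk@members))
  expect_error(kmerCompleteness(rk, countKmers(s, 13)$set), "mismatch")
})

test_that("QV follows the k-mer survival formula and its limits", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  reads <- countKmers(s, 17)$set
  # perfect assembly: no unsupported k-mers, infinite QV
  expect_equal(estimateQV(reads, reads)$qv, Inf)
  # one substituted base: K_err from brute-force set difference
  s2 <- s
  old <- substr(s2, 5000, 5000)
  substr(s2, 5000, 5000) <- setdiff(c("A", "C", "G", "T"), old)[1]
  asm <- countKmers(s2, 17)$set
  brute_err <- sum(!(bruteKmers(s2, 17) %in% bruteKmers(s, 17)))
  res <- estimateQV(asm, reads)
  expect_equal(res$k_err, brute_err)
  expected <- -10 * log10(1 - (1 - brute_err / res$k_total)^(1 / 17))
  expect_lt(abs(res$qv - expected), 0.5)
  # QV decreases as K_err grows at fixed K_total
  aliens <- vapply(0:199, function(i)
    paste0(strrep("A", 13), c("A", "C", "G", "T")[i %% 4 + 1],
           c("A", "C", "G", "T")[i %/% 4 %% 4 + 1],
           c("A", "C", "G", "T")[i %/% 16 %% 4 + 1],
           c("A", "C", "G", "T")[i %/% 64 %% 4 + 1]), character(1))
  aliens <- setdiff(unique(c(aliens)), reads@members)
  qvs <- vapply(c(1, 5, 20, 100), function(ke) {
    asm_ke <- new("KmerSet", k = 17, members = aliens[seq_len(ke)],
                  counts = rep(1L, ke), canonical = TRUE)
    estimateQV(asm_ke, reads, assembly_kmer_total = 1000)$qv
  }, numeric(1))
  expect_true(all(diff(qvs) < 0))
  # total failure: every assembly k-mer unsupported -> QV 0
  alien <- new("KmerSet", k = 17,
               members = paste0(strrep("C", 16), c("A", "G")),
               counts = c(1L, 1L), canonical = TRUE)
  res0 <- estimateQV(alien, reads, assembly_kmer_total = 2)
  expect_equal(res0$qv, 0)
})

test_that("histogram TSV round-trips", {
  h <- simulateKmerHistogram(1e5, seed = 4)
  f <- tempfile(fileext = ".tsv")
  writeKmerHistogram(h, f)
  h2 <- readKmerHistogram(f, k = 17)
  expect_equal(kmerCounts(h2), kmerCounts(h))
})
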