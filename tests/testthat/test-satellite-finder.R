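# satellite discovery: candidates, period inference, consensus, HOR,
# template refinement

# build a mutated tandem array from a given monomer
mutArray <- function(monomer, copies, rate, seed) {
  set.seed(seed)
  alt <- c("A", "C", "G", "T")
  paste(vapply(seq_len(copies), function(i) {
    ch <- strsplit(monomer, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    if (length(hit))
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(alt, b), 1),
                        character(1))
    paste(ch, collapse = "")
  }, character(1)), collapse = "")
}

randMonomer <- function(p, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), p, replace = TRUE), collapse = "")
}

test_that("repetitive windows flag arrays, not random sequence", {
  set.seed(31)
  rnd <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
  expect_equal(nrow(detectRepetitiveWindows(rnd)), 0)
  arr <- strrep(randMonomer(187, 1), 60)  # ~11 kb perfect array
  hit <- detectRepetitiveWindows(arr)
  expect_equal(nrow(hit), 1)
  expect_lte(hit$start, 2001)
  expect_gte(hit$end, nchar(arr) - 2000)
  # half random, half array: only array-overlapping windows flagged; a
  # brute-force k-mer multiplicity oracle agrees window by window
  s <- paste0(rnd, arr)
  cand <- detectRepetitiveWindows(s, k = 12, window = 2000,
                                  min_repetitiveness = 0.5)
  st <- seq(1, nchar(s), by = 2000)
  en <- pmin(st + 1999, nchar(s))
  brute <- vapply(seq_along(st), function(i) {
    km <- bruteKmers(substr(s, st[i], en[i]), 12, canonical = FALSE)
    tab <- table(km)
    sum(tab[tab >= 2]) / length(km)
  }, numeric(1))
  flagged <- IRanges::overlapsAny(
    IRanges::IRanges(st, en),
    IRanges::IRanges(cand$start, cand$end))
  expect_equal(flagged, brute > 0.5)
})

test_that("period inference returns the fundamental period", {
  m187 <- randMonomer(187, 7)
  m199 <- randMonomer(199, 8)
  p1 <- inferMonomerPeriod(strrep(m187, 600))
  expect_equal(as.integer(p1), 187)  # not 374
  expect_equal(as.integer(inferMonomerPeriod(strrep(m199, 600))), 199)
  # random sequence is not tandem
  set.seed(9)
  rnd <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  expect_error(inferMonomerPeriod(rnd), "tandem")
  expect_error(inferMonomerPeriod(strrep(m187, 2), max_period = 500),
               "twice")
})

test_that("period survives 2% monomer divergence across 20 seeds", {
  for (sd in 1:20) {
    set.seed(400 + sd)
    p <- sample(c(187, 199), 1)
    arr <- mutArray(randMonomer(p, 100 + sd), copies = 300, rate = 0.02,
                    seed = 200 + sd)
    expect_equal(as.integer(inferMonomerPeriod(arr)), p)
  }
})

test_that("shift-match score agrees with the brute-force oracle", {
  arr <- mutArray(randMonomer(150, 3), copies = 30, rate = 0.05, seed = 33)
  p <- inferMonomerPeriod(arr, max_period = 400)
  brute <- vapply(2:400, function(q) bruteShiftScore(arr, q), numeric(1))
  best <- max(brute)
  expect_equal(as.integer(p),
               (2:400)[which(brute >= best * (1 - 0.01))[1]])
  expect_equal(attr(p, "score"), brute[as.integer(p) - 1])
})

test_that("consensus equals the planted monomer, even at 2% noise", {
  m <- randMonomer(187, 55)
  perfect <- strrep(m, 10)
  expect_equal(buildConsensusMonomer(perfect, 187), m)
  noisy <- mutArray(m, copies = 600, rate = 0.02, seed = 77)
  cons <- buildConsensusMonomer(noisy, 187)
  expect_equal(nchar(cons), 187)
  expect_equal(cons, m)
  expect_error(buildConsensusMonomer(strrep(m, 2), 187), "3 full")
})

test_that("centromeric prioritization is a strict 100-kb rule", {
  fam <- data.frame(family = c("a", "b", "c"),
                    total_span = c(112200, 99999, 100000))
  out <- classifyCentromeric(fam)
  expect_equal(out$centromeric_candidate, c(TRUE, FALSE, FALSE))
})

test_that("HOR statistic separates dimeric arrays from mutated ones", {
  m <- randMonomer(100, 12)
  # identical monomers: no lag beats lag 1
  expect_equal(detectHOR(strrep(m, 40), 100)$order, "none")
  # alternating A/B variants differing at 10% of positions: order 2
  chB <- strsplit(m, "")[[1]]
  set.seed(13)
  pos <- sample(100, 10)
  chB[pos] <- vapply(chB[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  dimer <- strrep(paste0(m, paste(chB, collapse = "")), 20)
  hor <- detectHOR(dimer, 100)
  expect_equal(hor$order, 2)
  # brute-force identity matrix oracle for the lag-identity curve
  copies <- substring(dimer, seq(1, 39 * 100 + 1, by = 100),
                      seq(100, 40 * 100, by = 100))
  bm <- vapply(1:8, function(lag) {
    mean(vapply(seq_len(40 - lag), function(i) {
      a <- strsplit(copies[i], "")[[1]]; b <- strsplit(copies[i + lag], "")[[1]]
      mean(a == b)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(hor$identity_by_lag, bm, tolerance = 1e-12)
  # randomly mutated (non-HOR) arrays stay "none" across seeds
  for (sd in 1:20) {
    arr <- mutArray(m, copies = 30, rate = 0.03, seed = 300 + sd)
    expect_equal(detectHOR(arr, 100)$order, "none")
  }
})

test_that("template refinement recovers planted families end to end", {
  g <- smallGenome()
  truth <- g$truth
  arr <- refineWithTemplates(g$scaffolds, truthMonomers(truth))
  fam <- summarizeSatellites(arr)
  expect_setequal(fam$family, c("cen_family_1", "cen_family_2"))
  expect_setequal(fam$period, c(187, 199))
  # both planted families exceed the centromeric threshold; boundary error
  # at most one period against the truth intervals
  fam <- classifyCentromeric(fam)
  expect_true(all(fam$centromeric_candidate))
  feats <- truthFeatures(truth)
  for (fid in fam$family) {
    tr <- feats[S4Vectors::mcols(feats)$class == fid]
    got <- arr[S4Vectors::mcols(arr)$family == fid]
    expect_equal(length(got), length(tr))
    p <- fam$period[fam$family == fid]
    expect_lte(abs(GenomicRanges::start(got) - GenomicRanges::start(tr)), p)
    expect_lte(abs(GenomicRanges::end(got) - GenomicRanges::end(tr)), p)
  }
  # genome containing only one family, given both templates, reports one
  only187 <- ScaffoldSet(c(a = strrep(as.character(
    truthMonomers(truth)[["cen_family_1"]]), 50)))
  r <- refineWithTemplates(only187, truthMonomers(truth))
  expect_equal(unique(S4Vectors::mcols(r)$family), "cen_family_1")
  expect_error(refineWithTemplates(only187, character(0)), "non-empty")
})

test_that("template refinement contains the de novo period calls", {
  # the de novo route (candidate windows -> period -> consensus) feeds the
  # template route; on the same array both agree on the family footprint
  m <- randMonomer(187, 21)
  arr_seq <- mutArray(m, copies = 400, rate = 0.02, seed = 55)
  set.seed(56)
  pad <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
               collapse = "")
  scf <- ScaffoldSet(c(s = paste0(pad, arr_seq, pad)))
  cand <- detectRepetitiveWindows(as.character(scaffoldSeqs(scf)[["s"]]))
  expect_equal(nrow(cand), 1)
  sub <- substr(as.character(scaffoldSeqs(scf)[["s"]]), cand$start, cand$end)
  p <- inferMonomerPeriod(sub)
  expect_equal(as.integer(p), 187)
  cons <- buildConsensusMonomer(sub, p)
  ref <- refineWithTemplates(scf, c(denovo = cons))
  expect_equal(length(ref), 1)
  expect_lte(abs(GenomicRanges::start(ref) - (20001)), 187)
  expect_lte(abs(GenomicRanges::end(ref) - (20000 + nchar(arr_seq))), 187)
})
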