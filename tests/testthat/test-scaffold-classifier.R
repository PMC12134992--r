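# scaffold classification and PAR detection

classifierInputs <- function(g, depth_seed = 51, hit_seed = 52,
                             noise_cv = 0.05) {
  truth <- g$truth
  dep <- simulateDepth(truth, 34.5, "male", noise_cv = noise_cv,
                       seed = depth_seed)
  gct <- gcWindows(g$scaffolds)
  hits <- simulateAlignmentHits(truth, seed = hit_seed)
  arr <- refineWithTemplates(g$scaffolds, truthMonomers(truth))
  rl <- stats::setNames(Biostrings::width(rdnaSeedSequences()),
                        names(rdnaSeedSequences()))
  list(dep = dep, gct = gct, hits = hits, arr = arr, rl = rl)
}

test_that("size-rank macro/micro split follows rank with GC warnings", {
  st <- data.frame(scaffold = paste0("s", 1:14),
                   length = c(seq(3e6, 2e6, length.out = 6),
                              seq(9e5, 4e5, length.out = 8)),
                   gc_median = c(rep(0.42, 6), rep(0.45, 8)))
  out <- classifySizeGC(st, 6)
  expect_equal(out$class, c(rep("macro", 6), rep("micro", 8)))
  expect_true(all(out$warning == ""))
  # a long scaffold with micro-like GC stays macro, with a warning
  st2 <- st
  st2$gc_median[1] <- 0.465
  expect_warning(out2 <- classifySizeGC(st2, 6), "conflict")
  expect_equal(out2$class[1], "macro")
  expect_match(out2$warning[1], "rank wins")
  expect_error(classifySizeGC(st[1:3, ], 6), "fewer")
})

test_that("X is the scaffold at half the genome median depth", {
  # the published numbers: scaffold median 17.5x vs genome median 34.49x
  expect_equal(round(17.5 / 34.49, 3), 0.507)
  g <- smallGenome()
  cls <- truthClasses(g$truth)
  x_id <- names(cls)[cls == "X"]
  chrom <- names(cls)[cls %in% c("macro", "micro", "X")]
  for (sd in 1:20) {
    dep <- simulateDepth(g$truth, 34.5, "male", noise_cv = 0.05,
                         seed = 600 + sd)
    got <- identifyX(dep, candidates = chrom)
    expect_equal(as.character(got), x_id)
  }
  # a diploid scaffold (ratio ~1) is never X
  dep <- simulateDepth(g$truth, 34.5, "male", noise_cv = 0, seed = 1)
  r <- attr(identifyX(dep, candidates = chrom), "ratio")
  expect_false(any(names(cls)[cls == "macro"] %in% names(r)))
})

test_that("rDNA calls need strictly more than half a subunit covered", {
  rl <- c(`18S` = 1000, `28S` = 2000)
  hits <- data.frame(
    query = c("18S", "18S", "18S"),
    qstart = c(1, 1, 350), qend = c(600, 400, 500),
    target = c("a", "b", "b"))
  out <- identifyRdna(hits, rl)
  expect_equal(as.character(out), "a")    # 60% vs 50% (union of b's hits)
  # two partial hits covering 30% + 30% with 10% overlap = exactly 50%:
  # excluded by the strict rule
  h2 <- data.frame(query = "18S", qstart = c(1, 201), qend = c(300, 500),
                   target = "c")
  expect_equal(length(identifyRdna(h2, rl)), 0)
  cov <- attr(identifyRdna(h2, rl), "coverage")
  expect_equal(cov["c", "18S"], 0.5)
})

test_that("a single mitochondrial scaffold is retained", {
  lens <- c(m1 = 17500, m2 = 9000, big = 2e6)
  hits <- data.frame(target = c("m1", "m2", "big"),
                     tstart = c(100, 1, 1), tend = c(17400, 8900, 17000),
                     identity = c(0.99, 0.99, 0.99))
  out <- identifyMito(hits, lens)
  expect_equal(out$retained, "m1")
  expect_equal(out$flagged, "m2")   # truncated duplicate
  expect_equal(identifyMito(hits[0, ], lens)$retained, character(0))
})

test_that("Y calls use subtraction-contig density on leftover scaffolds", {
  lens <- c(y1 = 2e6, other = 2e6)
  hits <- data.frame(target = c(rep("y1", 40), rep("other", 2)))
  got <- identifyY(c("y1", "other"), hits, lens, min_density = 5)
  expect_equal(as.character(got), "y1")
  expect_equal(unname(attr(got, "density")["y1"]), 20)
})

test_that("full classification recovers every truth label", {
  g <- smallGenome()
  truth <- g$truth
  for (sd in 1:3) {
    inp <- classifierInputs(g, depth_seed = 700 + sd, hit_seed = 800 + sd)
    rep <- classifyScaffolds(g$scaffolds, inp$dep, gc_track = inp$gct,
                             satellite_arrays = inp$arr,
                             rdna_hits = inp$hits$rdna_hits,
                             mito_hits = inp$hits$mito_hits,
                             y_hits = inp$hits$y_hits,
                             rdna_ref_lengths = inp$rl,
                             n_macro_expected = 3, min_chrom_len = 1.4e5)
    tab <- classificationTable(rep)
    tc <- truthClasses(truth)
    expect_equal(tab$class, unname(tc[tab$scaffold]))
  }
})

test_that("classification is invariant to scaffold input order", {
  g <- smallGenome()
  inp <- classifierInputs(g)
  run <- function(lens) {
    classifyScaffolds(lens, inp$dep, gc_track = inp$gct,
                      satellite_arrays = inp$arr,
                      rdna_hits = inp$hits$rdna_hits,
                      mito_hits = inp$hits$mito_hits,
                      y_hits = inp$hits$y_hits, rdna_ref_lengths = inp$rl,
                      n_macro_expected = 3, min_chrom_len = 1.4e5)
  }
  lens <- scaffoldLengths(g$scaffolds)
  t1 <- classificationTable(run(lens))
  set.seed(1)
  t2 <- classificationTable(run(sample(lens)))
  m <- match(t1$scaffold, t2$scaffold)
  expect_equal(t1$class, t2$class[m])
})

test_that("PAR boundary is recovered within two windows across seeds", {
  g <- smallGenome()   # PAR planted over the first 100 kb of the X
  cls <- truthClasses(g$truth)
  x_id <- names(cls)[cls == "X"]
  win <- 20000
  for (sd in 1:20) {
    m <- simulateDepth(g$truth, 34.5, "male", noise_cv = 0.05,
                       window = win, seed = 900 + sd)
    f <- simulateDepth(g$truth, 34.5, "female", noise_cv = 0.05,
                       window = win, seed = 950 + sd)
    p <- detectPar(m, f, x_id)
    expect_false(is.null(p))
    expect_equal(GenomicRanges::start(p), 1)
    expect_lte(abs(GenomicRanges::end(p) - 1e5), 2 * win)
  }
  # ratio 0.5 everywhere: no PAR
  spec0 <- smallSpec(seed = 303)
  spec0@par_len <- 0
  g0 <- generateGenome(spec0)
  x0 <- names(truthClasses(g0$truth))[truthClasses(g0$truth) == "X"]
  m0 <- simulateDepth(g0$truth, 34.5, "male", noise_cv = 0, window = win,
                      seed = 1)
  f0 <- simulateDepth(g0$truth, 34.5, "female", noise_cv = 0, window = win,
                      seed = 1)
  expect_null(detectPar(m0, f0, x0))
  # mismatched grids are rejected
  f_bad <- simulateDepth(g$truth, 34.5, "female", window = 10000, seed = 1)
  expect_error(detectPar(m0, f_bad, x_id), "grids")
})

test_that("chromosome names rank by size and preserve split suffixes", {
  tab <- data.frame(
    scaffold = c("a", "b.2", "c", "x1", "y9", "u"),
    class = c("macro", "macro", "micro", "X", "Y", "unassigned"),
    length = c(300, 200, 100, 150, 50, 10))
  rep <- new("ClassificationReport", table = tab, par = NULL,
             params = list())
  out <- classificationTable(assignChromosomeNames(rep, prefix = "TST"))
  expect_equal(out$chrom_name,
               c("TSTscf1", "TSTscf2.2", "TSTscf3", "TSTscfX", "TSTscfY_1",
                 NA))
  # permutation stability (no ties here)
  set.seed(2)
  perm <- sample(nrow(tab))
  rep2 <- new("ClassificationReport", table = tab[perm, ], par = NULL,
              params = list())
  out2 <- classificationTable(assignChromosomeNames(rep2, prefix = "TST"))
  expect_equal(out2$chrom_name[match(out$scaffold, out2$scaffold)],
               out$chrom_name)
  # ties are broken by input order with a warning
  tabt <- tab; tabt$length[1:2] <- 200
  rept <- new("ClassificationReport", table = tabt, par = NULL,
              params = list())
  expect_warning(assignChromosomeNames(rept), "tie")
})
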