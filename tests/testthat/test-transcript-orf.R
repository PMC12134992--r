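# best-hit selection, ORF extraction, full-length classification, clustering

test_that("best hit maximizes bitscore with documented tie-breaks", {
  hits <- data.frame(transcript = "t1", protein = c("p1", "p2", "p3"),
                     frame = 1, tstart = 1, tend = 300,
                     pstart = 1, pend = c(100, 100, 100), plen = 100,
                     bitscore = c(50, 90, 70))
  expect_equal(bestHit(hits)$protein, "p2")
  # single hit is its own best
  expect_equal(bestHit(hits[1, , drop = FALSE])$protein, "p1")
  # bitscore tie: longer protein alignment wins
  tie <- data.frame(transcript = "t1", protein = c("pA", "pB"),
                    frame = 1, tstart = 1, tend = 300, pstart = 1,
                    pend = c(80, 95), plen = 100, bitscore = c(90, 90))
  expect_equal(bestHit(tie)$protein, "pB")
  # full tie: lexicographic protein id
  tie$pend <- c(95, 95)
  expect_equal(bestHit(tie)$protein, "pA")
})

test_that("ORF extraction finds starts, stops and flags internal stops", {
  # ATG + 99 sense codons + TAA -> 100 aa with start and stop
  set.seed(41)
  sense <- c("GCT", "GAA", "TTC", "GGT", "CAT", "ATC", "AAA", "CTG")
  cds <- paste0("ATG", paste(sample(sense, 99, replace = TRUE),
                             collapse = ""), "TAA")
  hit <- data.frame(transcript = "t", frame = 1, tstart = 1,
                    tend = nchar(cds) - 3)
  o <- extractOrf(cds, hit)
  expect_true(o$has_start)
  expect_true(o$has_stop)
  expect_equal(o$length, 100)
  expect_equal(substr(o$aa, 1, 1), "M")
  # translation round-trips
  expect_equal(as.character(Biostrings::translate(
    Biostrings::DNAString(o$nt))), o$aa)
  # no ATG upstream of the alignment
  cds2 <- paste0("CCC", paste(sample(sense, 50, replace = TRUE),
                              collapse = ""), "TAA")
  o2 <- extractOrf(cds2, data.frame(transcript = "t", frame = 1,
                                    tstart = 4, tend = 30))
  expect_false(o2$has_start)
  # internal stop inside the aligned region: partial with warning
  cds3 <- paste0("ATG", "GCTGAA", "TAA", "GCTGCT", "TAA")
  expect_warning(
    o3 <- extractOrf(cds3, data.frame(transcript = "t", frame = 1,
                                      tstart = 1, tend = 18)),
    "internal stop")
  expect_equal(o3$status, "partial")
})

test_that("planted proteins are recovered from simulated transcripts", {
  st <- simulateTranscripts(n = 12, seed = 61)
  for (i in seq_len(nrow(st$hits))) {
    h <- st$hits[i, ]
    o <- extractOrf(st$transcripts[[h$transcript]], h)
    expect_true(o$has_start)
    expect_true(o$has_stop)
    expect_equal(o$aa, unname(st$proteins[[h$protein]]))
    o <- classifyFullLength(o, h$plen)
    expect_equal(o$status, "full_length")
    expect_equal(o$ratio_to_hit, 1)
  }
})

test_that("the full-length band is inclusive at 95% and 105%", {
  mk <- function(len) list(transcript = "t", aa = strrep("A", len),
                           has_start = TRUE, has_stop = TRUE, length = len,
                           status = "aligned_orf")
  expect_equal(classifyFullLength(mk(100), 100)$status, "full_length")
  expect_equal(classifyFullLength(mk(95), 100)$status, "full_length")
  expect_equal(classifyFullLength(mk(105), 100)$status, "full_length")
  expect_equal(classifyFullLength(mk(94), 100)$status, "partial")
  expect_equal(classifyFullLength(mk(106), 100)$status, "partial")
  # missing codons disqualify regardless of ratio
  o <- mk(100); o$has_stop <- FALSE
  expect_equal(classifyFullLength(o, 100)$status, "partial")
  expect_error(classifyFullLength(mk(100), 0), "> 0")
})

test_that("unaligned ORF scan is a strict >50 aa six-frame enumeration", {
  mkorf <- function(naa) paste0("ATG", strrep("GCT", naa - 1), "TAA")
  # 50 aa rejected, 51 aa reported
  expect_equal(nrow(findOrfsUnaligned(mkorf(50))), 0)
  got <- findOrfsUnaligned(mkorf(51))
  expect_equal(nrow(got), 1)
  expect_equal(got$length, 51)
  # reverse-strand ORFs are seen
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mkorf(60))))
  expect_equal(findOrfsUnaligned(rc)$strand, "-")
  # random sequence matches a brute-force regex enumeration per frame
  set.seed(43)
  s <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
             collapse = "")
  got2 <- findOrfsUnaligned(s, min_len = 10)
  brute <- 0
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    for (f in 1:3) {
      n <- nchar(ss)
      st <- seq(f, n - 2, by = 3)
      cod <- substring(ss, st, st + 2)
      stops <- which(cod %in% c("TAA", "TAG", "TGA"))
      for (a in which(cod == "ATG")) {
        nxt <- stops[stops > a]
        if (length(nxt) && nxt[1] - a > 10) brute <- brute + 1
      }
    }
  }
  expect_equal(nrow(got2), brute)
})

test_that("greedy clustering groups planted families, not strangers", {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(47)
  mkprot <- function(len) paste(sample(aa, len, replace = TRUE),
                                collapse = "")
  mutprot <- function(p, rate) {
    ch <- strsplit(p, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(aa, b), 1),
                      character(1))
    paste(ch, collapse = "")
  }
  # identical pair -> one cluster; unrelated pair -> two singletons
  p <- mkprot(120)
  expect_equal(length(greedyCluster(c(a = p, b = p))), 1)
  expect_equal(length(greedyCluster(c(a = p, b = mkprot(120)))), 2)
  # three families of mutated copies (5% per copy, ~10% pairwise
  # divergence) cluster by family,
  # and a brute-force all-pairs identity matrix agrees with the grouping
  fams <- lapply(1:3, function(i) mkprot(sample(90:140, 1)))
  seqs <- unlist(lapply(seq_along(fams), function(i)
    stats::setNames(
      vapply(1:4, function(j) mutprot(fams[[i]], 0.05), character(1)),
      paste0("f", i, "_", 1:4))))
  cl <- greedyCluster(seqs)
  expect_equal(length(cl), 3)
  for (c1 in cl) {
    fam_of <- sub("_.*", "", c1$members)
    expect_equal(length(unique(fam_of)), 1)
    expect_equal(length(c1$members), 4)
    # representative is the longest member
    expect_true(all(nchar(seqs[c1$representative]) >=
                      nchar(seqs[c1$members])))
  }
  # every sequence lands in exactly one cluster
  all_members <- unlist(lapply(cl, `[[`, "members"))
  expect_setequal(all_members, names(seqs))
  expect_equal(anyDuplicated(all_members), 0)
  # brute-force within/between identity: families are separable at 80%
  ident <- function(x, y) {
    cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
    n <- min(length(cx), length(cy))
    sum(cx[1:n] == cy[1:n]) / n
  }
  within <- ident(seqs[["f1_1"]], seqs[["f1_2"]])
  between <- ident(seqs[["f1_1"]], seqs[["f2_1"]])
  expect_gt(within, 0.8)
  expect_lt(between, 0.8)
})
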