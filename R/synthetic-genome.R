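# truth-labeled synthetic genome generator
#
# The generator emulates the structure of a male (XY) squamate assembly:
# GC-poor macrochromosomes and GC-rich microchromosomes, an X at half male
# depth with a pseudoautosomal region, fragmented Y scaffolds, terminal
# TTAGGG arrays, centromeric satellite families of fixed monomer period,
# 200-N assembly gaps including planted misjoins (internal telomere abutting
# a gap), rDNA scaffolds and a mitochondrial scaffold. Background sequence is
# i.i.d. with per-scaffold GC targets so every planted feature is the only
# structure present and truth labels are unambiguous.

TELOMERE_MOTIF <- "TTAGGG"

#' Construct a GenomeSpec
#'
#' Defaults describe a desk-scale male skink-like genome: 6 macrochromosomes
#' (GC 0.42), 8 microchromosomes (GC 0.45), an X with a 200-kb PAR, 3
#' fragmented Y scaffolds, two centromeric satellite families with monomer
#' periods 187 and 199 bp each spanning >100 kb, terminal telomere arrays of
#' 150 TTAGGG copies, 200-N gaps, one planted misjoin, 2 rDNA scaffolds and a
#' 17,506-bp mitochondrial scaffold.
#'
#' @param n_macro,n_micro numbers of macro/micro scaffolds.
#' @param macro_len_range,micro_len_range length ranges in bp.
#' @param macro_gc,micro_gc background GC targets (macro < micro).
#' @param x_len X scaffold length (0 = none).
#' @param y_fragment_lens numeric vector of Y fragment lengths.
#' @param telomere_copies TTAGGG copies per planted array.
#' @param cen_monomers list of \code{c(period, span)} pairs; one array is
#'   planted per entry. Spans may be set above or below the 100-kb
#'   centromere-prioritization threshold to create positive and negative
#'   cases.
#' @param cen_mut_rate per-copy satellite substitution rate.
#' @param gap_len assembly gap length (Ns).
#' @param misjoin_count number of planted misjoins.
#' @param benign_gap_count ordinary gaps with no nearby telomere.
#' @param rdna_scaffolds number of rDNA scaffolds.
#' @param mito_len mitochondrial scaffold length (0 = none).
#' @param par_len PAR length at the 5' end of the X (0 = none).
#' @param seed integer RNG seed; the whole genome is a deterministic
#'   function of the spec including this seed.
#' @return a validated \code{\link{GenomeSpec}}.
#' @examples
#' spec <- GenomeSpec(n_macro = 2, n_micro = 2, seed = 1,
#'                    macro_len_range = c(3e5, 4e5),
#'                    micro_len_range = c(5e4, 8e4), x_len = 2e5,
#'                    par_len = 4e4, cen_monomers = list(c(187, 2e4)))
#' @export
GenomeSpec <- function(n_macro = 6, n_micro = 8,
                       macro_len_range = c(1.2e6, 2.2e6),
                       micro_len_range = c(2.5e5, 6e5),
                       macro_gc = 0.42, micro_gc = 0.45,
                       x_len = 1.5e6,
                       y_fragment_lens = c(1.5e5, 1.2e5, 9e4),
                       telomere_copies = 150,
                       cen_monomers = list(c(187, 112200), c(199, 111440)),
                       cen_mut_rate = 0.02,
                       gap_len = 200, misjoin_count = 1,
                       benign_gap_count = 2,
                       rdna_scaffolds = 2, mito_len = 17506,
                       par_len = 2e5, seed = 1) {
  new("GenomeSpec", n_macro = n_macro, n_micro = n_micro,
      macro_len_range = macro_len_range, micro_len_range = micro_len_range,
      macro_gc = macro_gc, micro_gc = micro_gc,
      x_len = x_len, y_fragment_lens = as.numeric(y_fragment_lens),
      telomere_copies = telomere_copies,
      cen_monomers = cen_monomers, cen_mut_rate = cen_mut_rate,
      gap_len = gap_len, misjoin_count = misjoin_count,
      benign_gap_count = benign_gap_count,
      rdna_scaffolds = rdna_scaffolds, mito_len = mito_len,
      par_len = par_len, seed = seed)
}

# fixed synthetic stand-ins for 18S/28S subunit references (NOT the real
# SILVA sequences; generated once from a hard-coded seed so they are stable
# across sessions)
#' Synthetic 18S/28S seed sequences
#'
#' Returns the two synthetic ribosomal-subunit seed sequences the generator
#' embeds (mutated) into rDNA scaffolds. They are random sequences of
#' realistic length (1,800 and 3,000 bp) fixed by an internal seed, not real
#' subunit references.
#'
#' @return named \code{DNAStringSet} with elements \code{18S} and \code{28S}.
#' @export
rdnaSeedSequences <- function() {
  withSeed(181818L, {
    Biostrings::DNAStringSet(c(`18S` = randomDNA(1800, 0.52),
                               `28S` = randomDNA(3000, 0.55)))
  })
}

# assemble a scaffold from labeled segments; returns sequence + feature rows
.assembleScaffold <- function(segments, scaffold) {
  seqs <- vapply(segments, `[[`, character(1), "seq")
  w <- nchar(seqs)
  ends <- cumsum(w)
  starts <- ends - w + 1L
  lab <- vapply(segments, function(s)
    if (is.null(s$class)) NA_character_ else s$class, character(1))
  pay <- vapply(segments, function(s)
    if (is.null(s$payload)) "" else s$payload, character(1))
  keep <- which(!is.na(lab))
  feat <- data.frame(scaffold = rep(scaffold, length(keep)),
                     start = starts[keep], end = ends[keep],
                     class = lab[keep], payload = pay[keep],
                     stringsAsFactors = FALSE)
  list(seq = paste(seqs, collapse = ""), features = feat)
}

# split a background budget into n chunks of positive length
.splitBg <- function(total, n) {
  if (n == 0) return(integer(0))
  if (total < n) stop("scaffold too short for its planted features")
  base <- total %/% n
  out <- rep(base, n)
  out[n] <- out[n] + total - base * n
  out
}

#' Generate a truth-labeled synthetic genome
#'
#' Builds the scaffold set described by a \code{\link{GenomeSpec}} and the
#' matching \code{\link{TruthTable}}. Macro and micro scaffolds carry
#' terminal telomere arrays (TTAGGG at the 3' end, its reverse complement at
#' the 5' end); each centromeric family is planted as one tandem array of a
#' random monomer of the stated period, mutated per copy; misjoined scaffolds
#' carry an internal telomere array directly abutting an N gap; the X has a
#' PAR at its 5' end and one missing telomere; rDNA scaffolds embed mutated
#' copies of the synthetic 18S/28S seeds.
#'
#' @param spec a \code{\link{GenomeSpec}}.
#' @return list with elements \code{scaffolds} (\code{\link{ScaffoldSet}})
#'   and \code{truth} (\code{\link{TruthTable}}).
#' @examples
#' g <- generateGenome(GenomeSpec(n_macro = 1, n_micro = 1, seed = 7,
#'                                macro_len_range = c(2e5, 2e5),
#'                                micro_len_range = c(5e4, 5e4),
#'                                x_len = 0, y_fragment_lens = numeric(0),
#'                                cen_monomers = list(), misjoin_count = 0,
#'                                benign_gap_count = 0, rdna_scaffolds = 0,
#'                                mito_len = 0, par_len = 0))
#' g$truth
#' @export
generateGenome <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, .generateGenomeImpl(spec))
}

.generateGenomeImpl <- function(spec) {
  telo_end <- strrep(TELOMERE_MOTIF, spec@telomere_copies)
  telo_start <- revcompChar(telo_end)
  gapN <- strrep("N", spec@gap_len)

  n_fam <- length(spec@cen_monomers)
  monomers <- character(n_fam)
  if (n_fam > 0) {
    for (j in seq_len(n_fam))
      monomers[j] <- randomDNA(spec@cen_monomers[[j]][1], 0.40)
    names(monomers) <- paste0("cen_family_", seq_len(n_fam))
  }
  # which macro hosts satellite family j / misjoin m / benign gap b
  if (n_fam > 0 && spec@n_macro == 0)
    stop("cen_monomers planted but no macro scaffolds to host them")
  fam_host <- if (n_fam) ((seq_len(n_fam) - 1L) %% spec@n_macro) + 1L else integer(0)
  mis_host <- if (spec@misjoin_count) ((seq_len(spec@misjoin_count) - 1L) %%
                                         max(spec@n_macro, 1L)) + 1L else integer(0)
  gap_host <- if (spec@benign_gap_count) (spec@n_macro -
      ((seq_len(spec@benign_gap_count) - 1L) %% max(spec@n_macro, 1L))) else integer(0)

  seqs <- character(0)
  feats <- list()
  classes <- character(0)

  addScaffold <- function(id, segments, class) {
    built <- .assembleScaffold(segments, id)
    seqs[[id]] <<- built$seq
    feats[[id]] <<- built$features
    classes[[id]] <<- class
  }

  scf_i <- 0L
  nextId <- function() {
    scf_i <<- scf_i + 1L
    sprintf("synscf%02d", scf_i)
  }

  # --- macrochromosomes -----------------------------------------------------
  for (i in seq_len(spec@n_macro)) {
    len <- round(stats::runif(1, spec@macro_len_range[1], spec@macro_len_range[2]))
    segs <- list(list(seq = telo_start, class = "telomere",
                      payload = "terminal:start"))
    # groups of segments that must stay contiguous; background sequence is
    # interleaved between groups, never inside one
    groups <- list()
    fams <- which(fam_host == i)
    for (j in fams) {
      per <- spec@cen_monomers[[j]][1]
      span <- spec@cen_monomers[[j]][2]
      ncop <- round(span / per)
      copies <- vapply(seq_len(ncop),
                       function(z) mutateDNA(monomers[j], spec@cen_mut_rate),
                       character(1))
      groups <- c(groups, list(list(list(
        seq = paste(copies, collapse = ""),
        class = names(monomers)[j],
        payload = sprintf("period=%d;copies=%d", per, ncop)))))
    }
    if (i %in% gap_host)
      groups <- c(groups, list(list(list(seq = gapN, class = NULL))))
    if (i %in% mis_host) {
      itel <- strrep(TELOMERE_MOTIF, spec@telomere_copies)
      groups <- c(groups, list(list(
        list(seq = itel, class = "telomere", payload = "internal:planted"),
        list(seq = gapN, class = "misjoin_gap", payload = "planted misjoin"))))
    }
    groups <- c(groups, list(list(list(seq = telo_end, class = "telomere",
                                       payload = "terminal:end"))))
    fixed <- sum(vapply(unlist(groups, recursive = FALSE),
                        function(s) nchar(s$seq), numeric(1))) +
      nchar(telo_start)
    bg <- .splitBg(len - fixed, length(groups))
    segs <- c(segs, do.call(c, lapply(seq_along(groups), function(z)
      c(list(list(seq = randomDNA(bg[z], spec@macro_gc), class = NULL)),
        groups[[z]]))))
    addScaffold(nextId(), segs, "macro")
  }

  # --- X --------------------------------------------------------------------
  if (spec@x_len > 0) {
    id <- nextId()
    segs <- list(list(seq = telo_start, class = "telomere",
                      payload = "terminal:start"),
                 list(seq = randomDNA(spec@x_len - nchar(telo_start),
                                      spec@macro_gc), class = NULL))
    built <- .assembleScaffold(segs, id)
    if (spec@par_len > 0)
      built$features <- rbind(built$features,
        data.frame(scaffold = id, start = 1L, end = as.integer(spec@par_len),
                   class = "par", payload = "planted PAR",
                   stringsAsFactors = FALSE))
    seqs[[id]] <- built$seq
    feats[[id]] <- built$features
    classes[[id]] <- "X"
  }

  # --- microchromosomes -----------------------------------------------------
  for (i in seq_len(spec@n_micro)) {
    len <- round(stats::runif(1, spec@micro_len_range[1], spec@micro_len_range[2]))
    segs <- list(list(seq = telo_start, class = "telomere",
                      payload = "terminal:start"),
                 list(seq = randomDNA(len - 2 * nchar(telo_end), spec@micro_gc),
                      class = NULL),
                 list(seq = telo_end, class = "telomere",
                      payload = "terminal:end"))
    addScaffold(nextId(), segs, "micro")
  }

  # --- Y fragments ----------------------------------------------------------
  for (len in spec@y_fragment_lens)
    addScaffold(nextId(),
                list(list(seq = randomDNA(len, spec@macro_gc), class = NULL)),
                "Y")

  # --- rDNA scaffolds -------------------------------------------------------
  if (spec@rdna_scaffolds > 0) {
    seeds <- as.character(rdnaSeedSequences())
    for (i in seq_len(spec@rdna_scaffolds)) {
      s18 <- mutateDNA(seeds[["18S"]], 0.02)
      s28 <- mutateDNA(seeds[["28S"]], 0.02)
      segs <- list(list(seq = randomDNA(4000, 0.5), class = NULL),
                   list(seq = s18, class = "rdna", payload = "18S"),
                   list(seq = randomDNA(3000, 0.5), class = NULL),
                   list(seq = s28, class = "rdna", payload = "28S"),
                   list(seq = randomDNA(4000, 0.5), class = NULL))
      addScaffold(nextId(), segs, "rdna")
    }
  }

  # --- mitochondrial scaffold ----------------------------------------------
  if (spec@mito_len > 0)
    addScaffold(nextId(),
                list(list(seq = randomDNA(spec@mito_len, 0.40), class = NULL)),
                "mito")

  fdf <- do.call(rbind, c(feats, list(data.frame(
    scaffold = character(0), start = integer(0), end = integer(0),
    class = character(0), payload = character(0)))))
  gr <- GenomicRanges::GRanges(fdf$scaffold,
                               IRanges::IRanges(fdf$start, fdf$end),
                               class = fdf$class, payload = fdf$payload)
  lens <- vapply(seqs, nchar, numeric(1))
  truth <- new("TruthTable", features = gr,
               scaffold_classes = unlist(classes),
               scaffold_lengths = lens,
               monomers = if (n_fam) Biostrings::DNAStringSet(monomers)
                          else Biostrings::DNAStringSet())
  list(scaffolds = ScaffoldSet(Biostrings::DNAStringSet(unlist(seqs))),
       truth = truth)
}

#' Simulate a windowed depth track from truth labels
#'
#' Window-level depth simulation: each window's nominal depth is the
#' autosomal mean scaled by the scaffold's copy number in the given sex
#' (X at 0.5x in a male, Y at 0.5x in a male and 0 in a female, PAR windows
#' at 1x in both sexes), optionally dipped over satellite/rDNA features to
#' mimic the mapping-difficulty artifact seen over centromeres, then jittered
#' with truncated normal noise of coefficient of variation \code{noise_cv}.
#'
#' @param truth a \code{\link{TruthTable}}.
#' @param autosomal_mean autosomal depth (x-fold), > 0.
#' @param sex \code{"male"} (XY) or \code{"female"} (XX).
#' @param noise_cv coefficient of variation of the per-window noise.
#' @param window window size in bp.
#' @param seed RNG seed.
#' @param dip logical; dip depth over satellite/rDNA windows.
#' @param dip_factor multiplicative dip applied when \code{dip = TRUE}.
#' @return a \code{\link{WindowTrack}} with a \code{depth} column.
#' @export
simulateDepth <- function(truth, autosomal_mean, sex = c("male", "female"),
                          noise_cv = 0.05, window = 10000, seed = 1,
                          dip = TRUE, dip_factor = 0.6) {
  sex <- match.arg(sex)
  if (window <= 0) stop("window must be > 0")
  if (autosomal_mean <= 0) stop("autosomal_mean must be > 0")
  lens <- truth@scaffold_lengths
  cls <- truth@scaffold_classes
  withSeed(seed, {
    gr <- .tileWindows(lens, window)
    scaf <- as.character(GenomicRanges::seqnames(gr))
    mult <- rep(1, length(gr))
    if (sex == "male") {
      mult[cls[scaf] == "X"] <- 0.5
      mult[cls[scaf] == "Y"] <- 0.5
    } else {
      mult[cls[scaf] == "Y"] <- 0
    }
    feats <- truth@features
    halfCovered <- function(sel) {
      if (!length(sel)) return(logical(length(gr)))
      ov <- GenomicRanges::findOverlaps(gr, sel)
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        gr[S4Vectors::queryHits(ov)], sel[S4Vectors::subjectHits(ov)]))
      hit <- rep(FALSE, length(gr))
      cov <- tapply(w, S4Vectors::queryHits(ov), sum)
      idx <- as.integer(names(cov))
      hit[idx] <- cov >= GenomicRanges::width(gr)[idx] / 2
      hit
    }
    par_w <- halfCovered(feats[S4Vectors::mcols(feats)$class == "par"])
    mult[par_w] <- 1
    nominal <- autosomal_mean * mult
    if (dip) {
      dip_sel <- feats[grepl("^cen_family_", S4Vectors::mcols(feats)$class) |
                         S4Vectors::mcols(feats)$class == "rdna"]
      nominal[halfCovered(dip_sel)] <-
        nominal[halfCovered(dip_sel)] * dip_factor
    }
    depth <- nominal
    if (noise_cv > 0) {
      depth <- stats::rnorm(length(nominal), nominal, noise_cv * nominal)
      depth <- pmax(depth, 0)
      depth[nominal == 0] <- 0
    }
    S4Vectors::mcols(gr)$depth <- depth
    S4Vectors::mcols(gr)$full <- GenomicRanges::width(gr) == window
    new("WindowTrack", windows = gr, windowSize = window)
  })
}

#' Simulate tabular alignment-hit evidence from truth labels
#'
#' Produces the three hit tables the scaffold classifier consumes, in a
#' BLAST/PAF-like layout (\code{query}, \code{qstart}, \code{qend},
#' \code{target}, \code{tstart}, \code{tend}, \code{identity}; 1-based
#' closed): Y-enriched subtraction contigs mapped densely onto Y scaffolds
#' (with sparse background noise on autosomes), 18S/28S subunit hits covering
#' most of each subunit on rDNA scaffolds, and a near-full-length
#' mitochondrial reference hit on the mito scaffold.
#'
#' @param truth a \code{\link{TruthTable}}.
#' @param seed RNG seed.
#' @param y_density Y-contig hits per Mb on true Y scaffolds. Genome
#'   subtraction yields thousands of short contigs tiling the Y, so the
#'   default is dense enough that even a 50-kb Y fragment receives many
#'   hits.
#' @param bg_density background (spurious) hits per Mb on non-Y scaffolds.
#' @param rdna_cov fraction of each subunit covered by simulated hits.
#' @return list of data.frames \code{y_hits}, \code{rdna_hits},
#'   \code{mito_hits}.
#' @export
simulateAlignmentHits <- function(truth, seed = 1, y_density = 200,
                                  bg_density = 0.5, rdna_cov = 0.75) {
  lens <- truth@scaffold_lengths
  cls <- truth@scaffold_classes
  refs <- stats::setNames(Biostrings::width(rdnaSeedSequences()),
                          names(rdnaSeedSequences()))
  withSeed(seed, {
    mkhits <- function(id, n, qpfx) {
      if (n == 0) return(NULL)
      w <- round(stats::runif(n, 500, 5000))
      st <- round(stats::runif(n, 1, pmax(1, lens[[id]] - w)))
      data.frame(query = sprintf("%s_%03d", qpfx, seq_len(n)),
                 qstart = 1L, qend = w,
                 target = id, tstart = st, tend = st + w - 1L,
                 identity = round(stats::runif(n, 0.92, 0.99), 3),
                 stringsAsFactors = FALSE)
    }
    y_hits <- do.call(rbind, lapply(names(lens), function(id) {
      dens <- if (cls[[id]] == "Y") y_density else bg_density
      mkhits(id, stats::rpois(1, dens * lens[[id]] / 1e6), "ycontig")
    }))
    if (is.null(y_hits))
      y_hits <- data.frame(query = character(0), qstart = integer(0),
                           qend = integer(0), target = character(0),
                           tstart = integer(0), tend = integer(0),
                           identity = numeric(0))
    rdna_hits <- do.call(rbind, lapply(names(lens)[cls == "rdna"], function(id) {
      do.call(rbind, lapply(names(refs), function(su) {
        # two partial hits jointly covering ~rdna_cov of the subunit
        L <- refs[[su]]
        c1 <- round(L * rdna_cov * 0.55)
        c2 <- round(L * rdna_cov * 0.45)
        data.frame(query = su,
                   qstart = c(1L, L - c2 + 1L), qend = c(c1, L),
                   target = id, tstart = c(1000L, 3000L),
                   tend = c(1000L + c1 - 1L, 3000L + c2 - 1L),
                   identity = 0.95, stringsAsFactors = FALSE)
      }))
    }))
    if (is.null(rdna_hits))
      rdna_hits <- data.frame(query = character(0), qstart = integer(0),
                              qend = integer(0), target = character(0),
                              tstart = integer(0), tend = integer(0),
                              identity = numeric(0))
    mito_ids <- names(lens)[cls == "mito"]
    mito_hits <- do.call(rbind, lapply(mito_ids, function(id) {
      L <- lens[[id]]
      data.frame(query = "mito_ref", qstart = 1L, qend = as.integer(L * 0.98),
                 target = id, tstart = round(L * 0.01),
                 tend = round(L * 0.99), identity = 0.99,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(mito_hits))
      mito_hits <- data.frame(query = character(0), qstart = integer(0),
                              qend = integer(0), target = character(0),
                              tstart = integer(0), tend = integer(0),
                              identity = numeric(0))
    list(y_hits = y_hits, rdna_hits = rdna_hits, mito_hits = mito_hits)
  })
}

#' Simulate a diploid k-mer multiplicity histogram
#'
#' Builds a three-component mixture: sequencing-error k-mers piled at
#' multiplicity 1-2, a heterozygous peak centered at half the homozygous
#' depth, and the homozygous peak at \code{homozygous_depth}, with Poisson
#' sampling noise per bin. The recorded read statistics are set so that the
#' k-mer genome-size formula recovers \code{genome_size} at the true peak.
#'
#' @param genome_size haploid genome size in bp.
#' @param het_fraction fraction of positions that are heterozygous.
#' @param homozygous_depth k-mer multiplicity of the homozygous peak.
#' @param k k-mer length.
#' @param read_len mean read length (must exceed \code{k}).
#' @param error_rate per-base sequencing error rate.
#' @param seed RNG seed.
#' @return a \code{\link{KmerHistogram}}.
#' @export
simulateKmerHistogram <- function(genome_size, het_fraction = 0.005,
                                  homozygous_depth = 63, k = 17,
                                  read_len = 250, error_rate = 0.002,
                                  seed = 1) {
  if (het_fraction < 0 || het_fraction > 1)
    stop("het_fraction must be in [0, 1]")
  if (homozygous_depth <= 0) stop("homozygous_depth must be > 0")
  if (k > read_len) stop("k must not exceed read_len")
  d <- homozygous_depth
  het_mass <- 2 * k * het_fraction * genome_size
  hom_mass <- max(genome_size - het_mass / 2, 0)
  B <- genome_size * d * read_len / (read_len - k + 1)
  err_mass <- B * error_rate * k / 3
  mmax <- ceiling(2.5 * d)
  m <- seq_len(mmax)
  lambda <- hom_mass * stats::dpois(m, d) +
    het_mass * stats::dpois(m, d / 2) +
    err_mass * stats::dgeom(m - 1, 0.7)
  withSeed(seed, {
    counts <- stats::rpois(length(m), lambda)
    KmerHistogram(k = k,
                  counts = data.frame(multiplicity = m, count = counts),
                  total_bases = B, mean_read_len = read_len)
  })
}

#' Write truth labels to BED and TSV
#'
#' Emits \code{<prefix>.features.bed} (0-based half-open; columns chrom,
#' start, end, name = feature class, score = 0, strand), and
#' \code{<prefix>.classes.tsv} (header + one row per scaffold: scaffold,
#' class, length). BED carries no header line (the format defines none); the
#' TSV is header-only for an empty truth table.
#'
#' @param truth a \code{\link{TruthTable}}.
#' @param out_prefix path prefix for the output files.
#' @return named character vector of the written paths, invisibly.
#' @export
writeTruth <- function(truth, out_prefix) {
  bed <- paste0(out_prefix, ".features.bed")
  tsv <- paste0(out_prefix, ".classes.tsv")
  gr <- truth@features
  bed_df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       name = S4Vectors::mcols(gr)$class,
                       score = rep(0L, length(gr)),
                       strand = rep(".", length(gr)))
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  nm <- names(truth@scaffold_classes)
  if (is.null(nm)) nm <- character(0)
  cl <- data.frame(scaffold = nm,
                   class = unname(truth@scaffold_classes),
                   length = unname(truth@scaffold_lengths[
                     names(truth@scaffold_classes)]))
  utils::write.table(cl, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(features = bed, classes = tsv))
}
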