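#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet DNAString
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' Parameters of a synthetic truth-labeled genome
#'
#' A \code{GenomeSpec} fixes every knob of the synthetic genome generator: the
#' karyotype (numbers and length ranges of macro- and microchromosomes), the
#' GC targets of the two size classes, the X length and Y fragment lengths,
#' the planted telomere and centromeric-satellite arrays, gap length, planted
#' misjoins, rDNA and mitochondrial scaffolds, and the RNG seed. Identical
#' specs (including the seed) generate byte-identical genomes.
#'
#' @slot n_macro number of macrochromosome scaffolds.
#' @slot n_micro number of microchromosome scaffolds.
#' @slot macro_len_range length range (bp) for macro scaffolds.
#' @slot micro_len_range length range (bp) for micro scaffolds.
#' @slot macro_gc target GC fraction of macro background sequence.
#' @slot micro_gc target GC fraction of micro background sequence
#'   (must exceed \code{macro_gc}).
#' @slot x_len X scaffold length (bp); 0 for no X.
#' @slot y_fragment_lens lengths (bp) of fragmented Y scaffolds.
#' @slot telomere_copies TTAGGG copies per planted terminal array.
#' @slot cen_monomers list of \code{c(period, span)} pairs, one planted
#'   satellite array per family.
#' @slot cen_mut_rate per-base substitution rate applied independently to each
#'   satellite monomer copy.
#' @slot gap_len length of assembly gaps (run of N).
#' @slot misjoin_count number of planted misjoins (internal telomere abutting
#'   a gap).
#' @slot benign_gap_count number of ordinary gaps without nearby telomeres.
#' @slot rdna_scaffolds number of rDNA-carrying scaffolds.
#' @slot mito_len mitochondrial scaffold length (bp); 0 for none.
#' @slot par_len pseudoautosomal region length (bp) at the 5' end of X;
#'   0 for none.
#' @slot seed integer RNG seed.
#' @export
setClass("GenomeSpec", representation(
  n_macro = "numeric", n_micro = "numeric",
  macro_len_range = "numeric", micro_len_range = "numeric",
  macro_gc = "numeric", micro_gc = "numeric",
  x_len = "numeric", y_fragment_lens = "numeric",
  telomere_copies = "numeric",
  cen_monomers = "list", cen_mut_rate = "numeric",
  gap_len = "numeric", misjoin_count = "numeric",
  benign_gap_count = "numeric",
  rdna_scaffolds = "numeric", mito_len = "numeric",
  par_len = "numeric", seed = "numeric"))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  if (object@n_macro < 0 || object@n_micro < 0)
    msg <- c(msg, "chromosome counts must be >= 0")
  if (any(object@macro_len_range <= 0) || any(object@micro_len_range <= 0))
    msg <- c(msg, "all lengths must be > 0")
  if (object@macro_gc >= object@micro_gc)
    msg <- c(msg, "macro_gc must be < micro_gc")
  if (object@gap_len <= 0)
    msg <- c(msg, "gap_len must be > 0")
  if (length(object@cen_monomers) &&
      !all(vapply(object@cen_monomers,
                  function(m) length(m) == 2 && all(m > 0), logical(1))))
    msg <- c(msg, "cen_monomers entries must be positive (period, span) pairs")
  if (object@x_len > 0 && object@n_macro + object@n_micro == 0)
    msg <- c(msg, paste("spec plants an X but no autosomes;",
                        "depth normalization would be impossible"))
  if (object@x_len == 0 && object@par_len > 0)
    msg <- c(msg, "par_len > 0 requires an X scaffold")
  if (object@par_len >= object@x_len && object@x_len > 0)
    msg <- c(msg, "par_len must be smaller than x_len")
  if (length(msg)) msg else TRUE
})

#' Truth labels for a synthetic genome
#'
#' Records everything the generator planted: located features (telomeres,
#' centromeric satellite arrays by family, misjoin gaps, rDNA segments, the
#' PAR), the true class of every scaffold, scaffold lengths, and the planted
#' satellite monomer sequences. Feature coordinates are held as 1-based
#' closed \code{GRanges} and serialized to 0-based half-open BED by
#' \code{\link{writeTruth}}.
#'
#' @slot features \code{GRanges} with metadata columns \code{class} (one of
#'   \code{telomere}, \code{cen_family_<i>}, \code{misjoin_gap}, \code{rdna},
#'   \code{par}) and \code{payload} (free-text evidence).
#' @slot scaffold_classes named character; truth class per scaffold
#'   (\code{macro}, \code{micro}, \code{X}, \code{Y}, \code{rdna},
#'   \code{mito}).
#' @slot scaffold_lengths named numeric; scaffold lengths in bp.
#' @slot monomers \code{DNAStringSet} of planted satellite monomers, named
#'   by family.
#' @export
setClass("TruthTable", representation(
  features = "GRanges",
  scaffold_classes = "character",
  scaffold_lengths = "numeric",
  monomers = "DNAStringSet"))

setValidity("TruthTable", function(object) {
  msg <- character()
  if (!setequal(names(object@scaffold_classes),
                names(object@scaffold_lengths)))
    msg <- c(msg, "scaffold_classes and scaffold_lengths must name the same scaffolds")
  feat_scaf <- as.character(GenomicRanges::seqnames(object@features))
  if (length(feat_scaf) && !all(feat_scaf %in% names(object@scaffold_lengths)))
    msg <- c(msg, "feature on a scaffold absent from scaffold_lengths")
  if (length(feat_scaf)) {
    lens <- object@scaffold_lengths[feat_scaf]
    if (any(GenomicRanges::start(object@features) < 1) ||
        any(GenomicRanges::end(object@features) > lens))
      msg <- c(msg, "feature interval outside its scaffold")
  }
  if (length(msg)) msg else TRUE
})

#' A set of assembly scaffolds
#'
#' Thin S4 container around a named \code{DNAStringSet}. Gap (N-run)
#' structure and the AGP-style \code{\link{scaffoldPlan}} are derived from the
#' sequence on demand rather than stored.
#'
#' @slot seqs named \code{DNAStringSet} of scaffold sequences.
#' @export
setClass("ScaffoldSet", representation(seqs = "DNAStringSet"))

setValidity("ScaffoldSet", function(object) {
  if (length(object@seqs) && is.null(names(object@seqs)))
    return("scaffold sequences must be named")
  if (anyDuplicated(names(object@seqs)))
    return("scaffold names must be unique")
  TRUE
})

#' Nonoverlapping window track of GC and depth
#'
#' Windows tile each scaffold without overlap; the trailing window may be
#' shorter than \code{windowSize} and is flagged \code{full = FALSE}.
#' Metadata columns carry \code{gc} (fraction in [0,1], \code{NA} for all-N
#' windows) and/or one or more depth columns (x-fold).
#'
#' @slot windows \code{GRanges} of windows with track metadata columns.
#' @slot windowSize nominal window size in bp.
#' @export
setClass("WindowTrack", representation(
  windows = "GRanges", windowSize = "numeric"))

setValidity("WindowTrack", function(object) {
  gr <- object@windows
  if (any(GenomicRanges::width(gr) > object@windowSize))
    return("window wider than windowSize")
  idx <- split(seq_along(gr), as.character(GenomicRanges::seqnames(gr)))
  ok <- vapply(idx, function(ii)
    IRanges::isDisjoint(IRanges::ranges(gr)[ii]), logical(1))
  if (!all(ok)) return("windows overlap within a scaffold")
  TRUE
})

#' k-mer multiplicity histogram
#'
#' Maps k-mer multiplicity (copy number in the reads) to the number of
#' distinct k-mers at that multiplicity, together with the read statistics
#' (total bases B, mean read length L) used by the genome-size estimator.
#'
#' @slot k k-mer length.
#' @slot counts data.frame with columns \code{multiplicity} and \code{count}.
#' @slot total_bases total sequenced bases B (may be \code{NA}).
#' @slot mean_read_len mean read length L (may be \code{NA}).
#' @export
setClass("KmerHistogram", representation(
  k = "numeric", counts = "data.frame",
  total_bases = "numeric", mean_read_len = "numeric"))

setValidity("KmerHistogram", function(object) {
  msg <- character()
  if (object@k < 1) msg <- c(msg, "k must be >= 1")
  if (!all(c("multiplicity", "count") %in% names(object@counts)))
    msg <- c(msg, "counts needs multiplicity and count columns")
  else {
    if (nrow(object@counts) && any(object@counts$multiplicity < 1))
      msg <- c(msg, "multiplicities must be >= 1")
    if (nrow(object@counts) && any(object@counts$count < 0))
      msg <- c(msg, "counts must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Exact in-memory set of canonical k-mers
#'
#' Desk-scale analogue of a meryl database: the distinct (by default
#' canonical) k-mers of a sequence set, with their multiplicities. Canonical
#' form is the lexicographic minimum of a k-mer and its reverse complement.
#'
#' @slot k k-mer length.
#' @slot members character vector of distinct k-mers.
#' @slot counts integer multiplicities parallel to \code{members}.
#' @slot canonical logical; whether members are canonicalized.
#' @export
setClass("KmerSet", representation(
  k = "numeric", members = "character", counts = "integer",
  canonical = "logical"))

setValidity("KmerSet", function(object) {
  msg <- character()
  if (length(object@members) &&
      !all(nchar(object@members) == object@k))
    msg <- c(msg, "every member must have length k")
  if (length(object@counts) != length(object@members))
    msg <- c(msg, "counts must parallel members")
  if (anyDuplicated(object@members))
    msg <- c(msg, "members must be distinct")
  if (length(msg)) msg else TRUE
})

#' Per-scaffold classification with quantitative evidence
#'
#' One row per scaffold with the assigned class (\code{macro}, \code{micro},
#' \code{X}, \code{Y}, \code{rdna}, \code{mito}, \code{satellite},
#' \code{unassigned}) and the evidence the rules used: length, median window
#' GC and depth, depth ratio to the genome median, Y-contig hit density, and
#' rDNA subunit coverage. Holds the detected PAR interval, if any.
#'
#' @slot table data.frame of per-scaffold calls and evidence.
#' @slot par \code{GRanges} of the pseudoautosomal region on X, or
#'   \code{NULL}.
#' @slot params list of thresholds used.
#' @export
setClass("ClassificationReport", representation(
  table = "data.frame", par = "GRangesOrNULL", params = "list"))

setValidity("ClassificationReport", function(object) {
  if (!all(c("scaffold", "class") %in% names(object@table)))
    return("table needs scaffold and class columns")
  if (anyDuplicated(object@table$scaffold))
    return("exactly one class per scaffold")
  TRUE
})
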