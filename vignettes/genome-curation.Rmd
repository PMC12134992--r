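---
title: "Curation computations for chromosome-scale reptile assemblies"
author: "scaffcurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation computations for chromosome-scale reptile assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffcurate)
```

# Scope and model

When a long-read assembly of a squamate genome is scaffolded and hand-curated,
a recurring set of small, well-defined computations carries most of the
decisions: where the telomeres are and whether any sit internally next to a
scaffolding gap (a misjoin signature), which tandem monomer builds each
putative centromere, which scaffold is the X, which fragments are Y, rDNA or
mitochondrial, how contiguous the assembly is, and how large the genome
should have been in the first place. `scaffcurate` implements those
computations as a tested, reusable package, and pairs them with a synthetic
genome generator that plants every feature with truth labels so the whole
chain is verifiable end to end without any sequencing data.

The biological template is a male (XY) skink-like karyotype: six GC-poorer
macrochromosomes, eight GC-richer microchromosomes, a differentiated X with
a pseudoautosomal region (PAR) at one end, and a Y that assembles only as
fragments. All coordinates inside the package are Bioconductor-native
(1-based closed `GRanges`/`IRanges`); every BED/bedGraph file read or
written is 0-based half-open, converted at the boundary.

# k-mer statistics

Genome size is estimated from a read set by the standard k-mer argument:
a read of length $L$ contains $L - k + 1$ k-mers, so $B$ total read bases
contain $B (L - k + 1) / L$ k-mers; dividing by the homozygous-peak k-mer
multiplicity $d$ gives

$$ G = \frac{B\,(L - k + 1)}{L\,d}. $$

```{r}
G <- estimateGenomeSize(B = 110612868725, L = 241.2, k = 17, d = 63)
attr(G, "display_gb")
```

The peak $d$ comes from `findHomozygousPeak()`: counts are smoothed with a
3-bin moving average, local maxima below multiplicity 5 are discarded as the
sequencing-error region, and the homozygous peak is the *rightmost* maximum
whose height is at least 20% of the largest (a diploid histogram has a
heterozygous mode at $d/2$ and a homozygous mode at $d$; the rightmost major
mode is the homozygous one). Ties break toward higher multiplicity. These
three constants are the package's own definition of the finder: published
analyses report only the peak value, not the algorithm that located it.

`countKmers()`/`KmerSet` keep exact, in-memory, canonical k-mer sets
(canonical = lexicographic minimum of a k-mer and its reverse complement).
They are deliberately desk-scale: completeness
(`kmerCompleteness()`, the percentage of reliable read k-mers present in the
union of assembly sets) and the quality value

$$ E = 1 - \left(1 - \frac{K_{err}}{K_{total}}\right)^{1/k},
\qquad QV = -10 \log_{10} E $$

(`estimateQV()`, with $K_{err}$ the assembly k-mer instances unsupported by
reads) follow the same definitions a meryl/Merqury evaluation uses, but on
toy inputs where a brute-force enumeration can confirm every number.
Reported depths and percentages round half away from zero to 2 decimals
(`roundHalfUp()`), matching how assembly tables print values such as
70.55×; base `round()` would give 70.54 on ties.

# Window profiling

`gcWindows()` and `depthWindows()` produce non-overlapping 10-kb windows by
default. GC is $(G+C)/(A+C+G+T)$ with N excluded from the denominator; a
window that is entirely N gets a missing value rather than zero so gap
windows cannot drag scaffold medians. Depth uses coverage-sum semantics
(sum of per-base depth over the window divided by the window span), the
arithmetic performed by `samtools bedcov`; window values are therefore
invariant to how the per-base track was chunked on input. The trailing
partial window is kept and flagged `full = FALSE`; downstream medians can
exclude it, and whether the original analyses did is unknowable, so the
default includes it. Scaffold medians use the lower-median convention
(the smaller central order statistic for even counts).

# Telomeres and misjoins

A telomere call is a maximal run of exact TTAGGG copies (or its reverse
complement CCCTAA) spanning strictly more than 600 bp — 100 motif copies —
with interior interruptions up to 50 bp bridged and at least 90% motif
content over the merged run. Degenerate variants are not matched: the
decision rule is defined on the canonical vertebrate motif, and widening it
would change the 600-bp semantics silently. The 90% content and 50-bp
interrupt values approximate the tolerance of an alignment-scored tandem
repeat finder without reimplementing one; both are arguments.

Placement is terminal when the run starts within 10 kb of a scaffold end
(configurable; the distance is far below any feature spacing the generator
produces), otherwise internal. An internal telomere within 100 kb of an
assembly gap flags that gap as a misjoin (`detectMisjoins()`): the
scaffolder has joined two chromosome ends. `splitAtGaps()` then removes the
gap and splits the scaffold into ordinal pieces (`<id>.1`, `<id>.2`),
conserving every non-gap base; `scaffoldPlan()`, `writeAGP()` and
`buildFromPlan()` round-trip the AGP v2.1 representation.

# Centromeric satellites

Candidate regions come from a k-mer repetitiveness screen
(`detectRepetitiveWindows()`: a 2-kb window is a candidate when more than
half of its 12-mers occur at least twice within it — random sequence
essentially never does). The monomer period of a candidate array is the
smallest shift $p$ whose shift-match score
$S(p) = \Pr[\,s_i = s_{i+p}\,]$ is within 1% of the global maximum over
$p \in [2, 500]$; taking the smallest tied shift returns the fundamental
period rather than a multiple. `buildConsensusMonomer()` majority-votes the
phase-anchored copies (ties alphabetical), and `refineWithTemplates()`
re-annotates the genome with those consensus monomers by seed-and-extend:
an exact 15-bp seed fixes position and phase, then copies are counted
stepping one period at a time while per-copy identity (Hamming, no indels)
stays at or above 80%. Indel-free identity is the deliberate desk-scale
simplification; arrays with frequent indels would need a banded alignment
the package does not attempt. Families whose arrays span strictly more than
100 kb genome-wide are flagged as centromeric candidates.

Higher-order repeat (HOR) structure is tested by the lag-identity curve:
mean identity between monomer copies at lag $m$, $m = 1..8$. An order-$m$
HOR is called when identity at some lag $m > 1$ exceeds identity at lag 1
by more than 0.05; a published negative HOR finding comes with no test
statistic attached, so this margin is the package's own, reported with the
curve itself so a reader can re-draw the conclusion.

# Scaffold classification

Labels follow a fixed precedence so input order can never matter:
mitochondrial > rDNA > satellite-only > chromosome-scale (macro/micro/X) >
Y > unassigned.

* **Mitochondrial**: among scaffolds aligned to a mitochondrial reference at
  ≥ 90% of their own length, the longest aligned span is retained; other
  copies are flagged as assembly duplicates.
* **rDNA**: the union of a scaffold's hits must cover strictly more than
  half of the 18S or 28S subunit reference.
* **Satellite-only**: more than half the scaffold length inside
  centromeric-family arrays.
* **X**: in an XY male the X carries half the autosomal depth, so a
  chromosome-scale scaffold whose median window depth is 0.4–0.6 of the
  genome-wide median on every platform is X. The band is symmetric about
  0.5 and configurable; the principle ("half depth") is published, the
  width is this package's default.
* **Macro/micro**: the expected number of macrochromosomes are the longest
  chromosome-scale scaffolds; the rest are micro. Window-GC medians serve
  as a consistency check (macro ≲ 0.435 ≲ micro, the midpoint of the two
  GC bands the generator emulates); a conflict warns but rank wins.
* **Y**: by elimination — remaining scaffolds with more than 5 Y-contig
  hits per Mb (subtraction contigs mapped back) are Y. The published
  analysis states "high density" without a number; 5/Mb is the package
  default and is logged in the report.

Chromosome-scale means ≥ 1 Mb by default (the scale at which the original
curation inspected scaffolds); analyses of the desk-scale synthetic genome
pass `min_chrom_len` matched to its smaller chromosomes.

The PAR is found from male and female depth tracks on a shared 20-kb
window grid: windows with male/female ratio 0.8–1.2 are PAR-like (diploid
in both sexes), 0.35–0.65 X-specific. The PAR call is the maximal PAR-class
run anchored at a scaffold end — hard ratio bands rather than a changepoint
model, which is simple, testable and sufficient at the noise levels the
generator produces.

# Contiguity and ORF selection

`contiguityStats()` uses the standard Nx convention: the length at which
the cumulative sum of descending-sorted lengths first reaches x% of the
total, Lx the number of sequences that takes, boundary ties included. The
assembly median is a lower median; means round half-up to integers. A gap
is any maximal N-run (length ≥ 1 by default; `min_gap` exists because some
assemblies use single Ns as ambiguity codes).

Full-length transcript selection reproduces the annotation-training rule:
the best protein hit per transcript (bitscore, then longer alignment, then
lexicographic id), ORF extension from the aligned frame upstream to the
*nearest* in-frame ATG and downstream to the nearest stop, and a
full-length call when both codons are present and the translated length is
between 95% and 105% of the hit protein — bounds inclusive, since
"between" does not exclude its endpoints and the boundary behavior is
tested explicitly. An in-frame stop inside the aligned region downgrades
the call to partial with a warning, the conservative reading of an
unspecified case. Transcripts without hits get a strict >50-aa six-frame
ATG-to-stop scan. `greedyCluster()` mirrors greedy incremental clustering
at 80% identity with 90% coverage of the shorter sequence: identity is
identical positions over the shorter length from an ends-free pairwise
alignment — exhaustive comparison replacing a k-mer prescreen, which is the
right trade at hundreds of sequences.

# The synthetic genome generator

`generateGenome()` plants, deterministically from a `GenomeSpec` seed:
terminal TTAGGG arrays on every chromosome (reverse complement at 5' ends),
one tandem satellite array per family built by per-copy mutation of a
random monomer (periods 187 and 199 bp, spans above 100 kb, 2% per-copy
substitution by default), 200-N gaps including one misjoin (an internal
telomere directly abutting a gap), an X at half male depth with a PAR at
its 5' end and a missing telomere, Y fragments, rDNA scaffolds embedding
mutated copies of synthetic 18S/28S seed sequences (random fixed-seed
stand-ins, not real subunit references), and a 17,506-bp mitochondrial
scaffold. Background sequence is i.i.d. at per-class GC targets (0.42
macro, 0.45 micro), so planted features are the only structure and truth
labels are unambiguous.

Defaults are fixed at desk scale — macro 1.2–2.2 Mb, micro 0.25–0.6 Mb,
X 1.5 Mb, PAR 200 kb, total around 15 Mb — large enough that window
medians, satellite spans and density rules behave as they do at full scale,
small enough that the whole test suite runs in minutes on one CPU. The test
fixtures use a 3+3-chromosome variant of about 4 Mb for the same reason.
Depth is simulated at window level: truncated-normal noise with a chosen
coefficient of variation around class-determined multipliers (X and Y at
0.5 in a male, Y at 0 in a female, PAR at 1 in both), with an optional
depth dip over satellite/rDNA windows mimicking the mapping-difficulty
artifact real centromeres show. Alignment evidence is simulated from the
truth labels directly: Y-contig hits at 200/Mb on Y scaffolds (subtraction
produces thousands of contigs, so even a 50-kb fragment is densely hit)
against 0.5/Mb background noise, partial subunit hits covering 75% of each
rDNA reference, and a near-full-length mitochondrial hit. The PAR length is
a parameter, not a biological default, because its true length in the
emulated system is unknown.

What the generator does **not** emulate bounds what green tests mean: there
is no repeat landscape beyond the planted arrays, no read-level error or
mappability structure (depth noise is i.i.d. per window), no indels inside
satellite arrays, no heterozygosity outside the k-mer histogram
abstraction, and hit tables are drawn from truth rather than from an
aligner. Passing recovery tests therefore demonstrates the decision rules
are implemented and calibrated as stated — not that the thresholds are
optimal on real data, where mappability artifacts and repeat families
interact.

# Numerical conventions and degenerate inputs

Half-away-from-zero rounding for every reported number; lower medians
throughout; strict inequalities exactly where the source rules are strict
(telomere span > 600 bp, satellite span > 100 kb, rDNA coverage > 50%,
ORF length > 50 aa) and inclusive where stated ("between 95% and 105%").
Empty inputs error early with messages naming the precondition
(no sequences, empty length list, zero genome median, k exceeding every
sequence); a monotone k-mer histogram (no usable peak) is an error rather
than a guess. A `GenomeSpec` with an X but no autosomes is invalid because
depth normalization would be undefined. Seeds are explicit arguments on
every stochastic function and the generator restores the caller's RNG
state.
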