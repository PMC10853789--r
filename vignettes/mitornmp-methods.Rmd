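---
title: "Methods: mapping and characterizing rNMPs embedded in circular mitochondrial DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping and characterizing rNMPs embedded in circular mitochondrial DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitornmp)
```

## The problem and the data model

Mitochondrial DNA replication and repair leave single ribonucleotides
(rNMPs) embedded in the DNA, and in mitochondria they are not removed by
RNase H2-initiated excision repair. Capture protocols (ribose-seq and
relatives) reduce a sequencing experiment to a set of *stranded,
single-nucleotide coordinates*: one record per captured rNMP, with the
observed base identity. `mitornmp` starts from exactly that product. It does
not trim, align or call coordinates from reads; those steps belong to the
upstream mapping toolchain.

Three conventions run through the package:

* **Circular 1-based coordinates.** The genome is a single circular
  sequence; `wrap_position()` maps any integer onto `[1, L]`, and a region
  with `start > end` wraps the origin. This matters because the control
  region — the one long non-coding region, containing the heavy-strand
  replication origin (OriH), the conserved sequence blocks, and the 7S DNA —
  spans the origin in the standard human mitochondrial reference.
* **Plus strand = light strand.** In the human reference (GRCh38 chrM) 12 of
  13 coding sequences are annotated on "+", which is the light strand; the
  heavy strand is its complement. All strand-aware operations (window
  extraction, neighbour contexts, background counts) read sequence 5'→3' on
  the record's strand.
* **rU is stored as T.** Every record is compared against the DNA alphabet
  of the reference (mismatch filtering, background normalization), so the
  uracil identity is represented by its DNA counterpart and rendered as rU
  only in reports.

Ambiguous reference bases are rejected rather than masked: the human
mitochondrial reference contains none, and silently masking them would
corrupt the background k-mer counts that every normalization divides by.
Background k-mers are counted circularly (origin-spanning k-mers included),
so counts always sum to `L` per strand.

## Filters applied before analysis

1. **Circular-origin recovery.** Aligners treat the circular genome as
   linear; records can carry positions outside `[1, L]`. Every position is
   wrapped; the operation is idempotent and preserves multiplicity.
2. **Mismatch removal.** A record whose observed base differs from the
   reference base *on its strand* is almost certainly a sequencing error and
   is dropped. On synthetic libraries this filter removes exactly the
   records the generator flipped (the truth table makes that testable).
3. **Restriction-site noise removal.** Libraries fragmented with restriction
   enzymes produce fragment-end artifacts at cut sites. The exact masking
   protocol used by upstream pipelines is not fully standardized, so the
   package implements an explicit, configurable rule: both strands are
   scanned for each recognition motif, and for every cut the single terminal
   nucleotide 5' of the cut on each strand becomes a removal slot; records
   at removal slots are dropped. Enzyme cut offsets are part of the run
   configuration, so wider masks can be emulated by listing additional
   offsets.

Both filters are per-record predicates, so they commute and conserve
`kept + removed = input` — properties the test suite checks directly.

## Normalized metrics

For a region *G* and library *L* with `R_G` records in the region and
`R_total` in total:

* `PPB = R_G / (Length(G) × R_total)` — the probability that a given
  captured rNMP sits on any one nucleotide of *G*; comparable across regions
  and libraries.
* `EF = (R_G / R_total) × (len_basis / Length(G))` — the density of *G*
  relative to the genome-average density. `len_basis` is the number of
  positions over which `R_total` is counted: `2L` when both strands are
  analysed (bins, hotspots, genes), `L` for a single-strand analysis. This
  interpretation makes EF a pure density ratio: `EF ≡ PPB × len_basis`, the
  length-weighted mean EF over any partition of the counted positions is
  exactly 1, and `EF > 1` means "denser than average", which is what the
  enriched-zone rule needs. The identity is also the cross-check between the
  two implementations in the test suite.

Moving-average PPB tracks use a centred circular window. The 51-nt default
is the standard smoothing width for control-region profiles; circular
boundary handling (never truncating at the origin) is required because the
control region wraps it.

## Statistical primitives

Strand-bias and pattern-preference comparisons use the Mann–Whitney U test
(two-tailed for strand bias across libraries of a cell type with N ≥ 3,
one-tailed against a fixed expectation for patterns), at a significance
level of 0.05 with no multiple-testing correction — results report raw
p-values. The implementation delegates to `stats::wilcox.test`: exact
p-values by full enumeration whenever `min(n, m) ≤ 8` and the combined
sample is tie-free, otherwise the normal approximation with midranks, tie
correction and continuity correction. An independent brute-force
enumeration over all label assignments lives in the test suite and pins the
exact path for all sample sizes ≤ 7.

The test "frequency vs expectation (0.25 dinucleotide, 0.0625
trinucleotide)" is stated in the field without specifying the one-sample
construction. The package's default reading executes a Mann–Whitney U test
between the per-library frequencies and a constant pseudo-sample of the
expectation, with midrank ties; a one-sample Wilcoxon signed-rank test is
available behind the same function (`method = "signed_rank"`) for users who
prefer that formalization. Both reject comfortably on genuinely preferred
patterns; the constant-pseudo-sample reading is the default because it is
the literal reading of "compare the normalized frequency and the
expectation value with a Mann–Whitney U test".

Spearman correlations are Pearson correlations of midranks with the
t-approximation on `n − 2` degrees of freedom (`stats::cor.test`,
`exact = FALSE`).

## Enriched zones, hotspots, contexts

**Bins.** Both strands are tiled from position 1 into 200-nt bins with the
remainder as a short last bin (83 per strand, last bin 169 nt, 166 total on
the human mitochondrial genome). The alternative — merging the remainder
into the last full bin — would change the advertised bin count; the short
last bin is the tiling that reproduces it. Bins are not origin-spanning:
wrap handling belongs to coordinate recovery, not to the grid.

**REZ calling.** A bin is an enriched zone in a library iff `EF > 1`
(strict). A bin is a *common* REZ iff (a) in every cell category the mean EF
across the category's libraries exceeds 1, and (b) at least 80 % of all
libraries (`≥`, not `>`) flag the bin. "Enriched in a category" is not
defined more precisely in the field; category-mean EF is the package's
operationalization, and `category_rule = "any_library"` provides the obvious
alternative. Raising the library fraction can only remove common bins
(monotonicity is tested).

One behaviour worth knowing: under a strong *global* strand bias with little
within-strand structure, most bins of the preferred strand have EF above 1,
so the common-REZ list is long. That is the rule working as defined — real
libraries have much more within-strand variation, which is what confines
common REZs to a handful of zones.

**Hotspots.** A hotspot is a (position, strand) slot with at least one rNMP
in *every* library of the set; ranking is by median single-nucleotide EF
(`len_G = 1`, `len_basis = 2L`), ties broken by ascending position then
light before heavy — a documented deterministic order. High-frequency sites
are the top 1 % of covered slots per library; the denominator is the number
of slots with ≥ 1 rNMP (that is how "locations with the presence of at least
one rNMP" is counted), selection size is `ceiling`-rounded, and slots tied
with the cutoff count are all included so the selection is deterministic and
scale-invariant.

**Contexts.** `context_pfm()` extracts ±3 bp windows (minus-strand windows
reverse-complemented so the rNMP sits at the centre reading 5'→3') and
tabulates per-column base probabilities, in a layout consumable by logo
tools. NR / RN / NNR pattern frequencies divide each raw pattern count by
the circular background count of the same k-mer on the same strand scope,
then renormalize within each rNMP column. "Upstream" is the 5' neighbour on
the record's strand. Backgrounds are computed on the full genome (not
excluding rNMP positions; the difference is O(`R_total`/L)). Patterns whose
background count is zero are reported as 0 and flagged, keeping matrix
shapes stable across libraries.

**Strand-bias contribution.** Per rNMP type, the embedment rate on a strand
is count divided by the background count of that base on that strand. Types
with a positive preferred-minus-other rate difference split the contribution
proportionally, and the split is rescaled by the overall share difference
Δ (kept as a fraction, not percentage points — report writers scale for
display), so contributions sum to Δ when all differences are positive.

## Gene-level and control-region analyses

For each coding sequence the *non-template* strand is the annotated (sense)
strand and *template* its complement; per-gene PPB/EF are computed for both
roles, along with the dC/dG content of the non-template sequence.
Size-correlation analysis is the Spearman correlation of gene length with
non-template PPB (and with dC/dG counts). tRNA genes are processed
identically but are low-powered: they are short (∼58–74 nt) and similar in
length, so few records land in them and the correlation is generally not
significant.

Control-region profiling restricts the smoothed per-strand PPB tracks to the
(origin-wrapping) region and calls peaks as maximal runs above
`peak_factor × 1/(2L)` — `1/(2L)` being the genome-wide per-base mean PPB.
Peak calling against a visual standard is necessarily a formalization; the
run-based rule with a default factor of 1.5 is deliberately simple,
configurable, and scale-invariant (duplicating every record changes
nothing). 7S-DNA abundance is the mean depth of the annotated 7S region over
the genome-wide mean depth; depth enters as a precomputed per-base track,
not from alignments. Control-region, OriH and 7S coordinates always come
from the user's annotation — the package hardcodes no control-region
boundaries, since published coordinates exist only for OriH (110–441) and
the CSBs.

## The synthetic-data generator

`sim_library()` emulates the statistical structure the analyses assume:
strand drawn as Bernoulli(light fraction), position drawn from per-position
weights (composition weight of the strand-correct reference base × planted
zone multiplier × `1 + s·len/max_len` inside light-strand CDSs), identity
equal to the strand-correct reference base, then flipped with the mismatch
rate to model sequencing error only — mirroring the interpretation that
mismatching rNMPs *are* sequencing errors, which is why the mismatch filter
must remove exactly the flipped records. Planted hotspots are topped up
after sampling, so their counts are minima rather than exact values; that
keeps the sampler simple and the planted invariant (count ≥ minimum)
directly testable. Uniform random libraries (the size-study control) draw
uniformly over all `2L` slots, with the canonical sizes 10,000 / 100,000 /
1,000,000.

Default generator settings encode the study conditions the analyses target:
a 16,569-nt genome, 12 plus-strand CDSs of 300–1800 nt packed outside a
human-proportioned control region, a 75 % light-strand fraction
(representative of the strong light bias of most cell types), composition
weights favouring rC and disfavouring rU (A:C:G:T = 1:1.5:1:0.5, the
qualitative composition ranking), 50,000 records per library and 6 libraries
for demo runs, and a 1 % mismatch rate. What the generator does *not*
emulate: fragmentation-dependent capture efficiency, read-level error
structure, copy-number heterogeneity (beyond a single depth-track
multiplier), and within-strand correlation of embedment beyond the planted
zones. Passing tests therefore demonstrate that the *computations* recover
planted structure under the stated sampling model, not that real libraries
look like the simulator.

`debruijn_genome()` builds a circular de Bruijn sequence (every k-mer
exactly once per cycle) via an Eulerian circuit; with one record per slot it
constructs inputs whose context counts are exactly proportional to the
background, pinning the normalization constants (0.25 per dinucleotide
column cell, 0.0625 per trinucleotide cell) with zero tolerance.

## Numerical and design choices

* Degenerate Mann–Whitney inputs (all values identical) return p = 1 with U
  at its null mean rather than 0/0.
* `spearman_cor` refuses constant input (rank correlation undefined).
* Empty libraries and empty regions are errors, not NaN propagation.
* Pattern matrices with zero-background cells stay full-shaped with an
  explicit flag.
* All generators are pure functions of (inputs, seed); the pipeline's
  outputs are byte-identical across reruns with the same config and seed.
* Problem sizes used by the validation suites: libraries of 10,000–100,000
  records on the 16,569-nt genome for recovery checks (the acceptance script
  uses 50,000 for the EF-partition identity and 100,000 × 3 for the
  length-coupling recovery), 1,000,000 for the largest uniform control —
  sizes chosen to match the study conditions while keeping a desk-scale run
  in seconds.
* The three uniform control libraries for the size-correlation null are
  *frozen* datasets (fixed canonical seeds), like deposited control
  libraries: with only 12 genes a single Spearman correlation has a null
  standard deviation near 0.3, so the control is meaningful as a fixed
  dataset, not as a per-run draw.

## Known limitations

* Single circular chromosome only; no multi-contig genomes or liftover.
* The restriction-site filter is an explicit stand-in for upstream masking
  protocols; its slot rule is configurable but not guaranteed to match any
  specific external pipeline.
* Peak calling is threshold-based; no significance is attached to peaks,
  bins, or hotspots (none is standard for these analyses).
* Depth must be supplied as a per-base track; the package does not pile up
  BAMs.
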