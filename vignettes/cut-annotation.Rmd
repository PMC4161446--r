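---
title: "Annotating cryptic unstable transcripts from two-condition binned coverage"
author: "cutcaller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating cryptic unstable transcripts from two-condition binned coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutcaller)
```

## The biological problem

Cryptic unstable transcripts (CUTs) are short RNA polymerase II products that
are polyadenylated by the TRAMP complex (whose main catalytic component is
Trf4) and degraded so rapidly by the nuclear exosome that they are nearly
undetectable in wild-type budding yeast. Deleting *TRF4* stabilizes them.
Immunoprecipitating the nuclear cap-binding complex subunit Cbc2 enriches
capped, nascent Pol II transcripts, so RNA-seq of Cbc2-associated RNA from
wild-type versus *trf4*Δ cells turns CUT stabilization into a simple
two-library coverage comparison: genomic intervals whose coverage is strongly
over-represented in the mutant library are CUTs under active degradation.

`cutcaller` implements that comparison as a reusable, tested pipeline, along
with the two companion analyses usually reported with it: direction-averaged
overlap between CUT catalogues (for Venn diagrams) and the fraction of each
library's reads attributable to CUT sites.

## The calling procedure

1. **Binning** (`bin_reads()`): mapped reads are summed in fixed-width bins
   (default 100 bp) by their start position; bin $i$ covers
   $[iw, (i+1)w)$ in 0-based half-open coordinates and the last bin of a
   chromosome may be partial. Whether the upstream mapper kept only uniquely
   mapping reads or placed multi-mappers randomly is an upstream choice; the
   pipeline consumes mapped positions either way.
2. **Contaminant filtering** (`apply_blacklist()`): bins overlapping a
   blacklist — in the motivating experiment, the 37S pre-rRNA locus, an
   abundant contaminant of the immunoprecipitation — are zeroed and removed
   from the effective library total. Zeroed bins can never contribute to a
   call because their criterion flags are forced to fail.
3. **Total read-count normalization** (`normalize_pair()`): each library is
   scaled by `reference / own_effective_total`, the reference being the larger
   of the two effective totals, so the shallower library is scaled up. For the
   published depths of 16 and 21 million mapped reads this applies a factor of
   $21/16 = 1.3125$ to the wild-type library and leaves the mutant library on
   its raw scale, which keeps the noise cut-off interpretable as a read count.
4. **Per-bin enrichment** (`compute_enrichment()`): with pseudocount $p$
   (default 1 read) each bin receives
   $\log_2\!\frac{t + p}{u + p}$, where $t$ and $u$ are the normalized mutant
   and wild-type counts. A bin passes the **fold** criterion when
   $(t+p) \ge F\,(u+p)$ with $F = 4$, and the **noise** criterion when
   $t \ge 10$ normalized reads.
5. **Calling** (`call_cuts()`): a CUT is a maximal run of three or more
   consecutive bins, all passing both criteria, spanning more than 200 bp.
   Runs never cross chromosome boundaries, adjacent runs separated by a
   failing bin are not merged, and a run may end on a terminal partial bin.
6. **Annotation** (`annotate_calls()`): each call is annotated with
   $\log_2\!\frac{\sum t + pn}{\sum u + pn}$ over its $n$ bins, and with its
   maximum normalized mutant bin count.

### Parameter choices that matter

| parameter | default | units | why |
|---|---|---|---|
| `bin_width` | 100 | bp | resolution at which the annotation rule is defined |
| `fold_threshold` | 4 | ratio | "at least 4-fold over-represented" |
| `min_consecutive_bins` | 3 | bins | three consecutive bins, i.e. ≥ 300 bp of support |
| `min_length` | 200 | bp | strict `>` on genomic span; with the defaults the run rule dominates |
| `noise_min_count` | 10 | normalized reads/bin | removes calls from near-empty regions |
| `pseudocount` | 1 | reads | keeps ratios finite over zero wild-type bins |

The noise cut-off deserves comment: the original analysis states that one was
applied but not its value, so it is an exposed parameter here. The default of
10 normalized reads per bin is justified by two properties that are part of
the test suite: identical libraries yield zero calls at any setting, and on
planted-truth simulations the default loses essentially no true CUTs (mutant
CUT coverage in realistic regimes is an order of magnitude above it) while
suppressing calls from single-digit-count regions where a 4-fold ratio is
meaningless. Raising either threshold can only shrink the called territory
(a monotonicity property, also tested).

Two readings of the published rule differ in strictness (">4-fold" versus "at
least 4-fold"); the package uses `>=`, and with pseudocounts the distinction
essentially never binds. The fold criterion is evaluated per bin — every bin
of a run must individually pass — not on the region average, which matches
the stated "bins over-represented by at least 4-fold". Calls are reported on
the bin lattice; there is no sub-bin boundary refinement, no merging across
single failing bins, and no statistical significance testing (the original
analysis used none).

## Overlap comparison and occupancy

`directional_overlap(a, b)` counts features of `a` overlapping at least one
feature of `b` by ≥ 1 bp (unstranded; no minimum-overlap fraction). The count
is asymmetric because several features of one catalogue can map to a single
locus in the other, so `averaged_overlap()` reports both directions and their
arithmetic mean — the direction-averaged count used for Venn diagrams — plus
the percentage of each set overlapped. For three sets, `venn_counts()` derives
the seven Venn regions by inclusion–exclusion over the averaged pairwise
counts with the triple overlap taken as the mean of the three directional
triple counts. How to build a three-way Venn centre from asymmetric counts is
genuinely underdetermined; this construction is one consistent reading, it is
labelled in the output, and any negative derived region is clamped to zero
with a warning rather than silently hidden.

`occupancy_fraction()` reports the fraction of a library's blacklist-filtered
reads falling in an annotation, computed on raw counts (a within-library
fraction is depth-invariant). Bins partially overlapping an annotation are
attributed wholly to it, so fractions over a partition of the genome sum to
exactly one. `scatter_table()` produces the paired log-count table per 500 bp
region behind the usual two-library scatter plot; the log base (default 10)
and its pseudocount are exposed because the original figure's base is not
recoverable from the text.

## The synthetic-data generator

Because the deposited sequencing data are not desk-scale inputs, every stage
is exercised against `synthetic_config()` / `generate_truth()` /
`simulate_tracks()`: a genome of equal-length chromosomes carrying

* **background genes** — contiguous multi-bin blocks expressed equally in both
  conditions (up to the depth ratio), emulating the mRNA background;
* **planted CUTs** — lattice-aligned intervals, placed uniformly with
  rejection of overlaps, with a low wild-type mean and a per-CUT fold drawn
  uniformly from a configured range;
* **one contaminant locus** — 7 kb (the scale of the 37S pre-rRNA precursor)
  receiving a fixed fraction of each library, for exercising the blacklist;
* **negative-binomial noise** — per-bin counts with variance
  $\mu + \mu^2/\theta$ (default $\theta = 20$, mild RNA-seq-typical
  overdispersion); $\theta = \infty$ recovers Poisson for limit tests.

The defaults emulate the study conditions: a 21:16 mutant:wild-type depth
ratio; CUT folds of 12–32 (mean 22, the typical enrichment implied by a
~40%/~3% read-occupancy contrast); a wild-type CUT signal of 6.5 reads/bin,
low against a 30 reads/bin gene background ("just visible", as no
quantitative wild-type level is recoverable from the text); and a contaminant
holding 10% of each library. At these defaults the closed-form expected
occupancy of planted CUTs (`expected_occupancy()`) is ~40% of mutant and ~3%
of wild-type reads, so the headline occupancy contrast is reproduced by
construction and the simulation only has to agree with its own design within
sampling error.

Planted features are aligned to the bin lattice and placed mutually disjoint
(CUTs are modelled as intergenic, matching the observed dominance of
intergenic peaks). This makes recovery exactly scorable, at the price of not
modelling overlapping transcription. The generator also does not model
sequencing error, mappability, fragment-length effects or strandedness —
passing tests therefore certify the analysis logic under idealized coverage,
not robustness to those artefacts.

## Benchmark regimes and problem sizes

Two standing benchmarks are part of the test suite and the acceptance script:

* **Recovery**: 1 Mb genomes with 50 planted CUTs of 300–1500 bp, folds 12–36
  over a 4 reads/bin wild-type CUT signal (mutant CUT coverage 63–189
  reads/bin), gene background mean 60, replicated over 20 seeds. A planted CUT
  counts as recovered at 50% reciprocal overlap. The regime was designed
  analytically before testing: folds are centred near the study-implied
  typical CUT fold (~22), the wild-type CUT signal is kept near the detection
  limit but non-zero so region enrichments are estimable past the pseudocount,
  and CUTs are kept to a minor share of library mass so total-count
  normalization is well-conditioned. At the literal corner of fold 8 with 20
  reads/bin of mutant coverage, the wild-type negative-binomial upper tail
  alone fails the per-bin 4-fold flag in ~20% of bins, so no caller using this
  per-bin rule can reach 95% recall there; that corner is a property of the
  rule, not of the implementation.
* **Occupancy**: the default two-chromosome 1 Mb genome; realized occupancy
  must match the closed-form planted expectation within 3 delta-method
  standard errors.

These sizes keep the full suite in the low minutes on one CPU while leaving
hundreds of planted features per regime.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open throughout; BED output is native.
* Reads are assigned to bins by start position only, the simplest reproducible
  rule given that the original per-segment quantitation is not further
  specified.
* The analysis is unstranded (the libraries were not strand-specific).
* Blacklisted bins are zeroed rather than masked-missing, flagged, and barred
  from calls; vector shapes stay simple and the effective total honours the
  filter's purpose.
* Empty inputs are explicit: zero reads give all-zero tracks; an empty
  blacklist is the identity; empty libraries are rejected at normalization and
  occupancy; zero planted CUTs is a valid configuration.
* An overcrowded synthetic genome (features unplaceable without overlap) is
  rejected as infeasible rather than silently truncated.
* Ties at the fold or noise thresholds are inclusive (`>=`), matching the
  "at least 4-fold" wording.

## Known limitations

* **Depth-scale dependence.** The noise cut-off and pseudocount are absolute
  read counts, so calling is not exactly invariant to multiplying one
  library's counts by a constant: the common reference total rescales and
  threshold-marginal bins can flip. This is intrinsic to any dimensionful
  threshold — a deeper-sequenced experiment legitimately supports calls in
  regions that were previously below the noise floor. The ratio structure
  *is* exactly invariant (the normalized pair changes only by one shared
  constant), and in study-scale simulations over 95% of call boundaries are
  unchanged under a 10× rescaling; users comparing runs across very different
  depths should rescale `noise_min_count` accordingly.
* **Compositional bias of total-count normalization.** When CUTs carry a
  large share of the mutant library (as in the motivating experiment, where
  ~40% of mutant reads derive from CUT sites), scaling to total depth
  compresses all enrichment ratios by the differential mass. The calls
  themselves are robust (folds far exceed the threshold), but reported
  enrichments are conservative by roughly the mass ratio. A reference-gene or
  median-of-ratios scheme would avoid this at the cost of departing from the
  published method.
* The 3-or-more-consecutive-bins rule cannot represent transcripts shorter
  than 300 bp at the default bin width, and call boundaries are quantized to
  the lattice.
* The three-way Venn construction is approximate by design (see above).

## A minimal run

```{r, eval = FALSE}
cfg <- synthetic_config(seed = 1)
res <- run_pipeline(cfg, outdir = "cutcall_out")
glance(res$calls)
res$benchmark
res$occupancy
autoplot(res$scatter)
```

`run_pipeline()` writes all tables as plain-text BED/bedGraph/TSV plus a JSON
manifest recording parameters, seeds, normalization factors and per-stage
counts; two runs with identical configuration and seed are byte-identical.
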