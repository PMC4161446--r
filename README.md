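# cutcaller

Annotation of cryptic unstable transcripts (CUTs) from two-condition binned
RNA-seq coverage.

CUTs are short RNA polymerase II transcripts that the TRAMP complex (Trf4)
marks for degradation by the nuclear exosome; in wild-type yeast they are
nearly undetectable, while in a *trf4*Δ mutant they accumulate. Sequencing
cap-binding-complex (Cbc2) immunoprecipitated RNA from both genotypes turns
CUT discovery into a coverage comparison, and `cutcaller` implements that
comparison end to end:

* sum mapped reads in fixed-width genomic bins (default *w* = 100 bp,
  half-open, by read start);
* zero out a contaminant blacklist (e.g. the 37S pre-rRNA locus) and drop it
  from the effective library totals;
* total read-count normalization: scale each library by
  *reference / own effective total*, the reference being the larger effective
  total (16 vs 21 million mapped reads gives a 21/16 = 1.3125 factor on the
  shallower library);
* per bin, with pseudocount *p* = 1, compute log₂((t+p)/(u+p)) for normalized
  mutant count *t* and wild-type count *u*; a bin passes when
  (t+p) ≥ 4(u+p) **and** t ≥ 10 (the noise cut-off);
* call a CUT for every maximal run of ≥ 3 consecutive passing bins spanning
  > 200 bp, and annotate it with log₂((Σt + pn)/(Σu + pn));
* compare CUT catalogues by directional interval overlap and the
  direction-averaged counts used in Venn diagrams, and report the fraction of
  each library's reads in CUT sites.

A negative-binomial synthetic-data generator with planted ground truth
(`synthetic_config()`, `generate_truth()`, `simulate_tracks()`) emulates the
study design — unequal library depths, shared gene background, mutant-specific
CUT enrichment, one abundant contaminant locus — so the whole pipeline is
testable without external data. See the methods vignette
(`vignettes/cut-annotation.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

```r
library(cutcaller)

cfg      <- synthetic_config(seed = 1)          # study-emulating defaults
truth    <- generate_truth(cfg)
tracks   <- simulate_tracks(truth, cfg)
filtered <- lapply(tracks, apply_blacklist, truth$contaminant)
normed   <- normalize_pair(filtered$wt, filtered$trf4)
calls    <- annotate_cuts(normed[[2]], normed[[1]])   # trf4 vs wt

truth
#> <synthetic_truth> 2 chromosome(s) of 500000 bases: 60 planted CUTs, 300 genes, 1 contaminant locus(es); seed 1

head(tidy(calls), 3)
#> # A tibble: 3 × 8
#>   name     chrom start   end length n_bins max_bin_count region_log2_enrichment
#>   <chr>    <chr> <dbl> <dbl>  <dbl>  <int>         <dbl>                  <dbl>
#> 1 CUT_0001 chr1   8300  8800    500      5           276                   4.37
#> 2 CUT_0002 chr1  21800 22700    900      9           149                   2.88
#> 3 CUT_0003 chr1  36800 37600    800      8           172                   3.56

glance(calls)
#> # A tibble: 1 × 4
#>   n_calls total_bases median_length median_log2_enrichment
#>     <int>       <dbl>         <dbl>                  <dbl>
#> 1      63       51000           800                   3.52

benchmark_calls(calls, truth)
#> # A tibble: 1 × 6
#>   n_calls n_true n_matched recall precision frac_enrichment_within_1
#>     <int>  <int>     <int>  <dbl>     <dbl>                    <dbl>
#> 1      63     60        57   0.95     0.905                    0.912

dplyr::bind_rows(occupancy_fraction(filtered$trf4, calls),
                 occupancy_fraction(filtered$wt, calls))
#> # A tibble: 2 × 4
#>   library reads_in_set effective_total fraction
#>   <chr>          <dbl>           <dbl>    <dbl>
#> 1 trf4           87721          237666   0.369
#> 2 wt              3293          116895   0.0282
```

Reading the output: 63 CUTs are called against 60 planted (recall 0.95 at 50%
reciprocal overlap), with a median region enrichment of 3.5 log₂ units;
36.9% of the mutant library's filtered reads but only 2.8% of the wild-type
library's fall in the called CUT sites — the hallmark contrast between active
degradation and stabilization. `run_pipeline(cfg, outdir = ...)` performs the
same analysis and writes BED/bedGraph/TSV outputs plus a JSON manifest;
`autoplot()` methods draw the log-count scatter, chromosome coverage tracks
and enrichment tracks.

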