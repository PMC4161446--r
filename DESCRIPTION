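Package: cutcaller
Title: Annotation of Cryptic Unstable Transcripts from Two-Condition Binned RNA-Seq Coverage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates cryptic unstable transcripts (CUTs) from two-condition
    cap-binding-complex immunoprecipitation RNA-seq coverage, as in exosome-pathway
    mutant versus wild-type comparisons in budding yeast. Mapped reads are summed
    in fixed-width genomic bins, an abundant-contaminant blacklist (such as the 37S
    pre-rRNA locus) is filtered out, libraries are depth-matched by total read-count
    normalization, and CUTs are called as runs of three or more consecutive bins
    enriched at least four-fold in the degradation mutant, subject to a low-count
    noise cut-off. Also provides direction-averaged annotation-set overlap summaries
    (Venn counts), CUT read-occupancy fractions, figure-ready scatter and chromosome
    track tables, and a negative-binomial synthetic-data generator with planted
    ground truth for benchmarking recall, precision and enrichment recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse,
    withr
Config/testthat/edition: 3
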