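Package: traitboost
Title: Resampled Gradient-Boosting Variant Selection and F4 Allele-Sharing
    Statistics for Genotype-Phenotype Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for associating genomic variants with binary traits by
    refitting a tuned gradient-boosted tree classifier on many resampled
    training sets and selecting variants by the number of fits in which they
    contribute split gain, with a majority-class baseline and the 5x2cv
    paired t-test for model validation. Includes VCF ingestion with
    GATK-style hard filtering, additive genotype recoding, windowed LD
    pruning, Pearson-correlation expansion of selected variants, gene-model
    annotation of variants from GFF3, genotype-distribution clustering for
    heatmaps, F4 allele-sharing statistics with weighted block-jackknife
    standard errors for gene-flow hypotheses, and a synthetic cohort
    generator with planted causal variants and admixture events for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    vcfR,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
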