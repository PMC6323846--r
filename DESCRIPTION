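Package: gselexmine
Title: Integrated Mining of Genomic SELEX-Seq and Differential Expression
    Data for Transcription-Factor Regulon Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses genomic SELEX-Seq (gSELEX-Seq)
    experiments for fungal Zn(II)2Cys6 transcription factors such as
    Aspergillus oryzae XlnR, and integrates the resulting binding-site
    catalogue with differential-expression data. Provides a synthetic-data
    generator (genome, promoters with planted IUPAC motifs, linker-flanked
    fragment libraries, expression tables tied to motif content), an
    affinity-weighted multi-round selection model with paired-end read
    emission, adapter trimming, exact read mapping, Poisson local-lambda
    peak calling with fold-enrichment ranking and summit-window extraction,
    upstream-1000 promoter annotation, IUPAC motif counting and k-mer
    over-representation ranking, Fisher and Spearman/Pearson mining of
    motif counts and coexistence against expression ratios, and a 1:1
    Langmuir binding-kinetics module for biolayer-interferometry
    sensorgrams with global fitting of ka, kd and KD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
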