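Package: riceqx
Title: Selection and Regulatory Architecture of Gene Expression Under
    Salinity Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative- and population-genetic analysis of gene expression
    variation in a structured crop population grown in two field environments
    (normal and saline). Implements variance partitioning of transcript
    abundance into genotype, environment and genotype-by-environment
    components with broad-sense heritability; univariate phenotypic selection
    analysis on transcripts (linear and quadratic selection differentials,
    variance- and mean-standardized variants, conditional-neutrality and
    antagonistic-pleiotropy classification, GO-term selection tests);
    multivariate selection on expression principal components with G-matrix
    estimation by REML and breeder's-equation response prediction;
    environment-dependent loss of pairwise expression correlation
    (decoherence) via the correlation-by-individual-level-product test;
    and eQTL architecture analysis (cis/trans classification, environment
    overlap, GxE eQTL, trans-eQTL hotspots, cis-trans
    compensation/reinforcement, LD permutation tests, and site-frequency
    spectrum and nucleotide-diversity selection scans). Includes a synthetic
    data generator with planted ground truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
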