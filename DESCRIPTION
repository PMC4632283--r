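Package: hccstats
Title: Copy-Number Clonality Testing and Molecular Subtyping for Liver Cancer Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for hepatocellular carcinoma (HCC) genomics
    built around five reusable stages: threshold-based aberration calling from
    aCGH log2-ratio probe profiles, a permutation test for the clonality of
    paired tumor/metastasis aberration profiles (with an exact enumeration
    oracle), marker-panel hierarchical clustering of expression cohorts with
    Golub-style signal-to-noise-ratio subtype scoring, Kolmogorov-Smirnov
    differential expression and Pearson gene-gene correlation, and promoter
    methylation averaging within a fixed window of the transcription start
    site. Includes synthetic-data generators with planted ground truth for
    every stage, tidy readers/writers for the tabular formats involved, and a
    small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
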