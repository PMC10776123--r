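Package: metaboaging
Title: Time-Course Metabolomics Trend Classification, Co-Abundance
    Networks and Mortality Deceleration Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for time-course (three ordered age group)
    metabolomics studies of aging in short-lived vertebrates.  Classifies
    per-metabolite abundance profiles into a 17-type / 5-group trend
    taxonomy using one-way ANOVA with Tukey HSD post hoc tests, infers
    metabolite co-abundance networks from Pearson correlations with
    Benjamini-Hochberg adjustment, partitions networks into modules with
    a from-scratch Markov Clustering implementation, ranks node influence
    with the Integrated Value of Influence (IVI) composite centrality,
    locates mortality-deceleration inflection points on log10 cumulative
    mortality curves with the extremum surface estimator, aggregates
    lipid classes and acylcarnitine chain-length bins, categorizes muscle
    fiber cross-sectional areas, and generates fully synthetic data sets
    (planted trends, correlation modules and hubs, Gompertz-plateau
    survival cohorts, lognormal fiber areas) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
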