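Package: chromogrowth
Title: Growth Fitness, Gene Expression, and Chromosomal Periodicity in
    Single-Gene Knockout Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking the growth rates of single-gene
    knockout bacterial strains to wild-type gene expression and to
    chromosomal position. Provides exponential growth-rate estimation
    from plate-reader OD600 time series with a sliding five-interval
    window rule, box-plot (1.5 IQR) fitness classification with binomial
    category-enrichment tests, rank-product identification of
    differentially expressed genes and differentially growing strains
    between media, growth-expression Spearman correlation with a
    randomization null, and circular-genome Fourier periodicity analysis
    (1-kb sliding positional signals, periodogram, Fisher's g test,
    least-squares sinusoid fit). A synthetic-data generator emulates the
    annotation, expression, and plate-assay inputs so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
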