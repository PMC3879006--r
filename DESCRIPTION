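Package: mrewas
Title: Mendelian Randomization Scans of Epigenome-Wide Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-locus two-stage least squares (2SLS) Mendelian randomization
    across an Infinium methylation array, using an additive MTHFR variant
    count as the instrument for red-blood-cell folate. Provides a classed
    2SLS estimator with corrected second-stage standard errors, beta-value
    preprocessing (intensity conversion, probe restriction, arcsine
    square-root transformation, Shapiro-Wilk normality filtering), genotype
    quality control (Hardy-Weinberg, additive coding, nested F tests),
    pairs-bootstrap percentile confidence intervals on the untransformed
    beta-value scale, an unmeasured-confounding simulation study comparing
    2SLS with ordinary least squares, hypergeometric gene-set enrichment,
    and a synthetic-cohort generator that emulates the statistical structure
    of a folate methylation birth-cohort study so the whole pipeline is
    testable without access to subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
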