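Package: chorusim
Title: Spatially Explicit Simulation of Female Mate Choice in a Treefrog Chorus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based model of a single night of mate choice in a gray
    treefrog (Hyla versicolor) chorus. Female agents search a rectangular
    swamp for calling males using one of three decision rules (best-of-n with
    or without mid-course switching, a minimum acceptance threshold on call
    pulse number, or random choice), with males placed under Gaussian,
    inverse-Gaussian or uniform spatial regimes. Provides a factorial sweep
    runner with reproducible per-cell seeds, grouped summaries with confidence
    intervals, Cohen's d, ANOVA reporting, and an alpha-weighted fitness
    measure trading mate quality against travel distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
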