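Package: unmetci
Title: Income-Related Inequality in Unmet Health Care Needs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring and decomposing income-related inequality in
    binary health outcomes such as unmet health care needs. Implements
    weighted fractional income ranks with midpoint tie handling, the
    concentration index and its generalized (unscaled) form, concentration
    curve coordinates, percentile-bootstrap confidence intervals, a
    Newton-Raphson probit engine with marginal effects evaluated at covariate
    means, and the Wagstaff-style decomposition of the concentration index
    into per-covariate contributions (elasticity times covariate
    concentration index) plus a residual. Includes a schema-driven cohort
    reader with listwise-deletion reporting, consumer-price-index deflation
    and log-income transforms, a seeded synthetic-cohort generator with a
    probit data-generating process and large-sample oracle truths for
    parameter-recovery testing, and a one-config analysis pipeline that emits
    incidence, concentration-index, decomposition and curve tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
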