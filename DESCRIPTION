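Package: tsrdecomp
Title: Decomposition and Beta-Convergence Analysis of Regional Population Aging
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study regional convergence in population aging through
    the total support ratio (TSR), the ratio of the working-age (15-64) to the
    non-working-age population. Computes TSR series from age-structured
    regional panels, decomposes TSR change over an interval into non-working-age
    and working-age effects (symmetric two-factor Das Gupta decomposition) and
    further into cohort-turnover, migration and mortality effects via the
    demographic balance identity, and estimates unit-weighted beta-convergence
    regressions whose coefficients decompose additively by demographic
    component and by time. Includes a one-sex cohort-component simulator that
    generates multi-region synthetic panels with clustered working-age
    mortality, demographic waves and regime-switching migration, plus a
    command-line pipeline orchestrating simulation, decomposition and
    convergence analysis with CSV interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
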