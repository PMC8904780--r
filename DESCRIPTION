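Package: aridpulse
Title: Rainfall Pulses, Critical Windows and Trophic Cascades in Arid-Savannah Arthropod Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-year pitfall-trap studies of
    ground-dwelling arthropods in arid savannahs. Provides a seeded
    synthetic-data generator emulating a 30-plot, six-year, two-round
    trapping design driven by highly seasonal daily rainfall; a Spearman
    collinearity screen; community ordination (Bray-Curtis dissimilarity,
    non-metric multidimensional scaling, permutation-tested environmental
    vector fitting and sequential-sum-of-squares PERMANOVA); a
    moving-window critical-rainfall-window scan built on negative-binomial
    random-intercept mixed models with a deviance-based adjusted R-squared;
    and a bottom-up trophic-cascade model suite with a starred summary
    table. All stochastic stages are reproducible from a single seed.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmmTMB,
    lme4,
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
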