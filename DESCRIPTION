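Package: vocrank
Title: Grunt-Call Acoustics and Dominance Hierarchy Analysis for Social Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the role of grunt-like calls in hierarchically
    organised mammal herds. Infers dominance hierarchies from agonistic
    interaction logs (Landau's linearity index with a randomisation correction
    for unknown relationships, I&SI rank ordering, directional consistency
    index), detects grunt elements in recordings and measures twelve spectral
    and temporal parameters per element, prepares call feature tables for
    multivariate analysis (Yeo-Johnson transformation, robust multivariate
    outlier screening, stepwise variance-inflation-factor elimination), and
    tests vocal signatures of caller identity and sex with conventional and
    permuted discriminant function analysis on balanced subsamples. A
    synthetic-herd generator produces interaction logs, per-call feature
    tables and grunt waveforms with known hierarchy, rank-dependent call
    rates and rank-dependent acoustic signatures, so the whole pipeline can
    be exercised and validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
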