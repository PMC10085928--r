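Package: acetage
Title: Bayesian Age-at-Death Estimation from Acetabular Ordinal Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates adult age at death from ordinal stage scores of seven
    age-related acetabular variables using Bayesian inference over 5-year
    age-at-death classes, with the prior and the stage likelihoods taken from
    the observed frequencies of a documented reference collection. Includes
    inaccuracy evaluation (bias and absolute error, globally and by age band),
    exact and approximate rank tests (Wilcoxon signed-rank, Mann-Whitney U),
    weighted kappa for ordinal rater agreement, per-stage age-timing summaries
    for comparing the aging rate of different populations, a cumulative-logit
    simulator of documented-collection-like skeletal samples, and an
    orchestrator for crossed reference/test designs that quantifies the cost
    of using a geographically distant reference sample.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
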