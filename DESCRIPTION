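Package: hybridnorm
Title: Genotype-Specific Reaction Norms for a Poplar Hybrid Zone from
    Replicated Common Gardens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models growth and mortality of clonally replicated Populus
    trichocarpa x P. balsamifera hybrid-zone genotypes planted across
    replicated common gardens spanning a wide winter-temperature gradient.
    Fits a zero-inflated Gaussian mixed model (quadratic response of
    log growth increment to garden mean coldest month temperature, home
    climate and genomic principal components as genotype covariates,
    crossed random intercepts) by maximizing a Laplace-approximated
    marginal likelihood, evaluates it by leave-one-garden-out
    cross-validation and transfer to novel genotypes and sites, predicts
    per-genotype reaction norms over a continuous temperature grid, and
    projects which ancestry is favored per climate-grid cell under
    historic and future winter temperatures. Includes a synthetic-data
    generator that emulates the common-garden design with known truth,
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    ggplot2
Config/testthat/edition: 3
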