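Package: cladal
Title: Phylogenetic Clade Agglomeration and Negative Binomial Modelling of
    Microbiome Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cladal (phylogeny-aware) differential abundance analysis
    of 16S amplicon sequence variant (ASV) tables. Enumerates every monophyletic
    clade of a rooted phylogeny and sums member-tip counts into a clade-by-sample
    abundance matrix; fits per-clade negative binomial generalized linear models
    and mixed models (host random intercept, adaptive Gauss-Hermite quadrature)
    with Wald tests, Benjamini-Hochberg false discovery rate control and
    intercept-sign screening; provides genus-level nonparametric screens
    (Wilcoxon rank-sum, Kruskal-Wallis), prevalence filtering, exact
    without-replacement rarefaction, placeholder genus naming, and a synthetic
    data generator that emulates a two-study, two-age, two-timepoint murine
    dietary-zinc design with an LPS-induced IL-6 covariate.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phytools,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    MASS,
    glmmTMB,
    lme4,
    phangorn,
    vegan,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
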