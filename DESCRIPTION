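Package: strainshare
Title: Safety, Strain Tracking and Functional-Contribution Analysis for
    Multi-Strain Fermented-Milk Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for randomized fermented-milk (probiotic)
    trials: relative risk with log-scale (Katz) confidence intervals and
    Cohen's d for safety endpoints; strain-specific qPCR summaries with
    Mann-Whitney dose comparisons; genus-level alpha/beta diversity
    (Bray-Curtis, Jensen-Shannon divergence, weighted and unweighted UniFrac)
    with Kruskal-Wallis screening and centered log-ratio PCA; a longitudinal
    zero-inflated beta regression screen with subject random intercepts fitted
    by adaptive Gauss-Hermite quadrature; KEGG-ortholog functional-contribution
    scoring of product strains against a universal single-copy marker baseline;
    and a sparse co-abundance network (neighborhood-selection lasso with StARS
    stability selection) relating network distance from product strains to
    shared contributed functions. Includes synthetic-data generators with
    known ground truth for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    glmnet,
    igraph,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    lme4,
    yaml
Config/testthat/edition: 3
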