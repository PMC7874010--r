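Package: fsorprog
Title: Feature Selection with Orthogonal Regression for Prognostic Gene Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supervised feature selection with orthogonal regression (FSOR) for
    building prognostic gene signatures from expression and survival data. The
    solver alternates a generalized power iteration on the Stiefel manifold with
    an augmented-Lagrangian nonnegative simplex quadratic program to learn
    per-gene importance weights. Around the solver the package provides a
    random-effects meta-analysis filter for differentially expressed genes
    (Hedges' g, DerSimonian-Laird pooling, Benjamini-Hochberg FDR), univariate
    and BIC-guided stepwise multivariate Cox modelling, linear risk scores with
    Kaplan-Meier/log-rank validation and Kaplan-Meier-based time-dependent ROC
    curves, a cross-validated LASSO-Cox comparator, maximal clique centrality
    ranking on protein-protein interaction networks, and seeded generators of
    multi-study expression and survival cohorts with planted structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
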