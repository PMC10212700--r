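Package: ecogeoiso
Title: Ecogeographic Isolation from Ensemble Niche Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies ecogeographic isolation between closely related
    species from ecological niche models. Builds ensemble habitat
    suitability surfaces (GLM, MARS-style hinge regression, and a
    Maxent-style penalized background-contrast model) from presence
    records and gridded environmental layers, evaluates replicates by
    ROC/AUC and the True Skill Statistic, gates ensemble members by TSS,
    binarizes ranges at TSS-maximizing cutoffs, and computes the pairwise
    asymmetric isolation index RI = 1 - S/(S+U) across baseline and
    shifted climate scenarios. Includes niche overlap (Schoener's D,
    Warren's I), Levins' niche breadth with bootstrap comparison, a Monte
    Carlo niche identity test, collinearity screening (Pearson r, VIF),
    habitat ordinations (PCA, DFA), and a virtual-landscape simulator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
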