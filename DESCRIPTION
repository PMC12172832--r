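Package: tbinet
Title: Meso-Scale Brain-Network Prognostics for Critically Ill TBI Patients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for resting-state fMRI brain-network
    prognostication in critically ill traumatic brain injury patients:
    Gaussian-mixture voxel quality control on mean BOLD intensity,
    parcel-level Pearson connectivity with detrending and band-pass
    filtering, participation-coefficient and module-degree z-score
    topographical summaries over the seven canonical functional networks,
    weighted Louvain community detection scored against the template
    partition by adjusted mutual information, and a pre-registered
    logistic-regression protocol (collinearity screening, nuisance
    regressors, Nagelkerke R-squared, AUROC, AIC, likelihood-ratio and
    Wald tests, Benjamini-Hochberg correction). Includes a synthetic BOLD
    cohort generator with planted community structure, signal-dropout
    voxels and a logistic outcome model, so the full analysis is
    reproducible without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    mclust,
    pROC
Config/testthat/edition: 3
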