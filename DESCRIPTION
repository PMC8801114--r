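Package: ndsteps
Title: Multistep Incidence-Age Modelling and Genealogy Trees of
    Neurodegenerative Diseases
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the multistep (Armitage-Doll-type) model of disease onset
    to age-stratified incidence tables of neurodegenerative diseases:
    log-log incidence-age regression with an age-80 truncation rule, step
    counts n = m + 1 from the regression slope, background-risk parameters
    u = exp(c) and mu = u^(1/n), and an explicit linearity gate for
    non-multistep controls. Harmonizes heterogeneous studies onto a common
    age grid with natural cubic splines into a diseases-by-ages incidence
    matrix (a SummarizedExperiment), embeds incidence profiles with PCA and
    UMAP, computes onset age-range intervals, the years-per-step statistic
    and the steps-versus-range regression, and allocates common versus
    disease-specific steps into an extended genealogy tree by an
    ordinal-preserving, sharing-maximizing parsimony criterion with trunk
    widths in years per step. Includes a synthetic incidence-panel
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    igraph,
    uwot
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
biocViews: Epidemiology, Regression, DimensionReduction, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'incidenceIO.R'
    'multistepModel.R'
    'ageRange.R'
    'trajectoryIntegration.R'
    'dimReduction.R'
    'genealogyTree.R'
    'ndsteps-package.R'
    'syntheticData.R'
    'pipeline.R'
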