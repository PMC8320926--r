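Package: MetaboKnockoffs
Title: Aggregated Model-X Knockoff Filtering for Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for untargeted LC-MS metabolomics with finite-sample
    false discovery rate control. Implements missingness-threshold prefiltering
    (the t% rule), K-nearest-neighbour imputation, per-metabolite standardization,
    second-order Gaussian model-X knockoff generation, random-forest out-of-bag
    permutation importance on the knockoff-augmented matrix, knockoff-adjusted
    scores, intermediate empirical p-values aggregated over multiple knockoff
    draws by gamma-quantile aggregation, and Benjamini-Hochberg selection.
    Includes a simulator of metabolomics-like feature tables with known ground
    truth so that empirical FDR and power of the whole pipeline can be measured.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'MetaboKnockoffs-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'MetaboSet-methods.R'
    'utils.R'
    'simulate.R'
    'io.R'
    'preprocess.R'
    'knockoff.R'
    'importance.R'
    'aggregate.R'
    'pipeline.R'
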