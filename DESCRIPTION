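Package: restconn
Title: Resting-State fMRI Connectivity via Group ICA and Granger Causality
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A combined independent component analysis (ICA) and Granger
    causality framework for two-condition resting-state fMRI studies.
    Provides a seeded synthetic cohort generator with planted spatial
    networks, vector-autoregressive causal structure and condition-specific
    amplitude effects; temporal and spatial preprocessing; group ICA with
    staged PCA reduction, Infomax unmixing, ICASSO stability selection and
    back-reconstruction; voxelwise one-sample and paired t statistics with
    false-discovery-rate control, cluster extraction and 27-voxel region
    definition; and multi-segment vector-autoregression Granger causality
    with BIC order selection, directed causal graphs and out-in degree
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    lmtest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
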