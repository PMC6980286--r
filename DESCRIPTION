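Package: tkdce
Title: Tracer-Kinetic-Model-Constrained Reconstruction of Undersampled
    DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dynamic contrast-enhanced (DCE) MRI of brain tumors
    in which tracer-kinetic models act as temporal constraints during
    reconstruction of undersampled (k,t)-space data. Libraries of
    concentration-time profiles are simulated from the Patlak and extended
    Tofts-Kety models driven by a Parker population arterial input
    function, reduced to a compact temporal dictionary with k-SVD, and
    used via orthogonal matching pursuit as a fixed-sparsity constraint
    inside an iterative multiscale reconstruction. Includes the spoiled
    gradient-echo signal model and DESPOT1 T1 mapping, a multicoil
    Cartesian forward model with golden-angle Cartesian undersampling, a
    synthetic brain-tumor digital reference object, a temporal
    finite-difference ADMM baseline, kinetic parameter estimation, and
    Monte-Carlo / Bland-Altman evaluation utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
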