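Package: cardialt
Title: Cardiac Alternans Analysis by Fourier Transformation Imaging and
    Tissue-Heterogeneity Assimilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the closed loop between cardiac optical-mapping
    experiments, frequency-domain image analysis, and monodomain tissue
    simulation.  Implements pixel-wise Fourier transformation imaging (FFI)
    of voltage-sensitive fluorescence movies, action potential duration
    (APD) alternans maps with nodal-line detection, a four-variable minimal
    ventricular action potential model on two-dimensional anisotropic
    heterogeneous tissue with phase-field boundaries, assimilation of the
    low-frequency optical ultrastructure into heterogeneous model parameter
    fields, and a synthetic optical-mapping data generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, grDevices, utils, tools, Rcpp, jsonlite, tiff, png, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), knitr, rmarkdown, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'RcppExports.R'
    'alternans.R'
    'apModel.R'
    'assimilation.R'
    'cardialt-package.R'
    'ffi.R'
    'io.R'
    'synthdata.R'
    'tissueSim.R'
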