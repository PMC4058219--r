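Package: epress
Title: Energy-Preserving k-Space Sampling and Iterative Thresholding
    Reconstruction for Compressed Sensing MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design of Cartesian k-space undersampling patterns for
    compressed sensing MRI from the energy distribution of reference
    scans (ePRESS), together with classical variable-density and
    power-spectrum random patterns and low-resolution sampling as
    comparators.  Reconstructs undersampled acquisitions by iterative
    wavelet hard thresholding with exact k-space data consistency,
    partial-Fourier phase correction and region-of-support projection,
    and provides a FISTA baseline for the conventional l1 cost
    function.  Includes a randomized Shepp-Logan phantom generator,
    energy-preserving-ratio and median-error evaluation metrics, and
    reproducible experiment drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    EBImage
Suggests:
    png,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
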