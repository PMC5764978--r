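Package: xdtomo
Title: X-Ray Diffraction Tomography Simulation and Interior Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and reconstruction toolkit for pencil-beam X-ray
    diffraction tomography (XDT). Simulates diffraction scans of 2D phantoms
    (detector frames or sinograms with Poisson counting noise, beam stop and
    background), rearranges measurements into the 3D sinogram g(r,s,phi),
    reconstructs the spatially resolved coherent-scatter form factor f(x,y,q)
    globally with a modified FDK filtered backprojection for the parallel-fan
    geometry, and inside a region of interest from truncated projections with a
    Poisson maximum-likelihood estimator under total-variation regularization.
    Includes form-factor material classification with calibrated one-vs-rest
    support vector machines and a pencil-beam absorbed-dose model for
    comparing global and interior scan plans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    rmarkdown
Config/testthat/edition: 3
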