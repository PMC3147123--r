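Package: dcedot
Title: Dynamic Contrast-Enhanced Diffuse Optical Tomography on Arbitrary 2-D Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates frequency-domain diffuse optical tomography (DOT)
    measurements on arbitrarily shaped two-dimensional phantoms and
    reconstructs absorption maps with four analysis methods: simultaneous
    absorption/scattering inversion, amplitude-only absorption inversion,
    inversion with explicit source-detector coupling unknowns, and
    inversion with an MRI-derived Laplacian structural prior.  A linear
    triangular finite-element solver for the frequency-domain diffusion
    equation with Robin boundary conditions provides the forward model;
    the inverse problem is solved by Levenberg-Marquardt iteration with an
    adjoint-method Jacobian.  Tools for dynamic contrast-enhanced (DCE)
    analysis form enhancement difference images, extract regions of
    interest, quantify enhancement linearity across a contrast series and
    recover indocyanine-green uptake kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    deldir,
    mgcv,
    EBImage,
    signal,
    minpack.lm,
    igraph,
    jsonlite,
    methods,
    png,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
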