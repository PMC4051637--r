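Package: autopmri
Title: Automatic Autocalibrating Parallel MRI Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameter-free reconstruction of arbitrarily sampled (Cartesian or
    non-Cartesian, 2D or 3D, possibly sub-Nyquist) multi-coil magnetic resonance
    imaging data. From raw k-space coordinates and samples alone the package
    estimates the noise level (robust MAD estimate on the outer k-space),
    the signal level (two-component Gaussian mixture on a crude reconstruction),
    the supported field of view (Voronoi tessellation of the sampling pattern
    with Chebyshev cell extents), and the autocalibration region (greedy
    whitelist/blacklist sweep over Voronoi cells). Smooth high-bandwidth coil
    sensitivity profiles are estimated by a convex regularized least-squares fit
    with L-curve selection of the smoothness weight, and the image is
    reconstructed by a sparsity-regularized MAP estimator (Gaussian likelihood,
    Laplacian prior on undecimated wavelet frame coefficients) solved with a
    primal-dual algorithm. Includes non-uniform Fourier transform operators,
    synthetic phantom/coil/trajectory generators, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
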