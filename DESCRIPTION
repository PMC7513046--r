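Package: nssfuse
Title: Multi-Modal Image Fusion with the Nonsubsampled Contourlet Transform and Sparse Representation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses pairs of co-registered grayscale or color images (multi-modal
    medical, multi-focus) in the nonsubsampled contourlet transform (NSCT)
    domain. Low-pass bands are fused by sparse coding with simultaneous
    orthogonal matching pursuit over a compact dictionary learned by joint
    patch clustering and per-cluster PCA, using the Max-L1 selection rule;
    directional high-pass bands are fused by the Sum-Modified-Laplacian
    maximum rule. Includes exact-reconstruction nonsubsampled filter banks,
    objective fusion-quality metrics (mutual information, the Xydeas-Petrovic
    gradient index, and Yang's structural index), deterministic synthetic
    multi-focus and multi-modal phantom generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    png,
    tiff,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
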