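Package: sstfpo
Title: Spatial-Spectral Transformer for Foreign Plastic Object Classification in NIR Hyperspectral Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Pixel-level classification of foreign plastic objects (FPOs) on meat
    surfaces from near-infrared hyperspectral image cubes (171 bands, 1000-1700 nm).
    Implements a parameter- and compute-efficient spatial-spectral transformer with
    center-focused linear attention (CFLA), patch-local mixed-axis two-dimensional
    rotary position embedding (RoPE) with learnable frequencies, and low-rank
    factorized query/key/value/output projections (LRP), together with the full
    supporting pipeline: a seeded synthetic NIR scene simulator, ENVI-style raster
    input/output, white/dark reflectance calibration, patch extraction with
    class-balanced splits, a hand-authored training loop (Adam, early stopping),
    classification metrics (overall accuracy, average accuracy, Cohen's kappa,
    per-class precision/recall/F1), and closed-form efficiency accounting
    (parameters, MACs, FLOPs, serialized size) with an inference timing harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
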