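Package: interpsplit
Title: Multi-Scale Interpolation-Split Tiling for 2D Airway Segmentation in CT
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data-centric multi-scale tiling pipeline for slice-based airway
    tree segmentation in volumetric CT. Slices are up-sampled by bilinear
    interpolation at integer interpolation ratios (masks by nearest neighbour),
    split into fixed-size tiles for prediction by any pluggable 2D segmenter,
    then merged and down-sampled back to source resolution; per-ratio binary
    masks are fused by voxelwise union followed by largest-connected-component
    extraction. Includes the Dice/BCE combined loss and evaluation metrics,
    a bilinear-interpolation mathematical model with seam-discontinuity and
    diagonal-Laplacian sharpness analyses of crop-then-upscale artefacts,
    window/level CT intensity normalisation with NIfTI/TIFF I/O, a synthetic
    airway-tree phantom generator with exact ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
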