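# interpsplit

Multi-scale **interpolation-split** tiling for 2D slice-based airway tree
segmentation in volumetric CT.

Segmenting the airway tree on chest CT is hard because airway calibre spans
two orders of magnitude across generations: a 2D model working at native
512 × 512 resolution captures the trachea and bronchi but misses bronchioles
that are only a few pixels wide. This package implements a *data-centric*
remedy: keep the model fixed and enrich the data's scale instead.

For an integer interpolation ratio *ir*, each axial slice is up-sampled by
bilinear interpolation (masks by nearest neighbour) to *ir* times its side
length and split into non-overlapping fixed-size tiles (*T* = 512 in
production), each predicted by any pluggable 2D segmenter. Prediction
inverts the transform — merge tiles, nearest-neighbour down-sample — and the
per-ratio binary masks (threshold θ = 0.5) are fused by voxelwise union
followed by largest-connected-component extraction:

```
mask_ir = downsample_nn( merge( predict( split( upsample(slice, ir), T ))), ir ) > θ
final   = LCC( ∪_ir mask_ir )
```

Tile counts follow `ceil(h·ir/T) · ceil(w·ir/T)` = *ir*² for 512 × 512
slices, so a dataset of *n* slices over ratios {1, 2, 4, 8} yields 85 *n*
training tiles.

The package also provides:

* the closed-form bilinear interpolant (the four-corner cell of the method's
  mathematical model) and its artefact analyses: seam-discontinuity
  statistics and diagonal-Laplacian sharpness, comparing interpolation-split
  against the crop-then-upscale "existing technique";
* the combined training loss, `0.5·BCE + 0.5·(1 − soft Dice)`, and
  volume-level DSC evaluation with gain/ablation summaries (Dice
  `DSC = 2|y ∩ ŷ| / (|y| + |ŷ|)`);
* CT window/level normalisation (`g = clamp((I − (L − W/2))/W, 0, 1)·255`,
  default W = 1500 HU, L = −500 HU) and NIfTI / TIFF-stack I/O;
* a synthetic airway-tree phantom generator with exact ground truth, so the
  whole pipeline is testable without clinical data;
* a command-line interface (`inst/cli/interpsplit`).

See `vignettes/interpolation-split-methods.Rmd` for the full methods
account, including every numerical convention.

## Worked example

```r
library(interpsplit)

spec <- phantom_spec(grid_shape = c(48, 48, 48), G = 3, root_radius = 5,
                     length_root = 14, seed = 7)
phantom <- generate_phantom(spec)
phantom
#> <phantom_volume> 48 x 48 x 48 voxels, 7 branches (generations 0-2), 2128 lumen voxels

volume <- window_level_normalize(phantom$image)      # HU -> [0, 255]
cfg <- ensemble_config(irs = c(1, 2, 4), tile_size = 64)
result <- run_interpolation_split(volume, threshold_opening_backend(),
                                  cfg, gt_mask = phantom$lumen_mask)
result
#> <interpsplit_result> backend threshold-opening(tau=55, r=1), irs {1, 2, 4}, final mask 1007 voxels
#>   configuration   dsc    gain
#> 1           ir1 62.89  0.0000
#> 2           ir2 60.78 -2.1081
#> 3           ir4 63.11  0.2205
#> 4   ir1+ir2+ir4 64.24  1.3558
```

Reading the output: `dsc` is the volume-level Dice coefficient (%) of each
per-ratio mask against the phantom's exact lumen ground truth; `gain` is the
difference in percentage points from the ir = 1 baseline. The three-ratio
ensemble (64.24 %) beats the baseline (62.89 %) because higher ratios
recover branches that are sub-resolution for the scale-sensitive reference
backend at ir = 1; individual high ratios may score *below* baseline (ir2
here) while still contributing true voxels to the union — which is exactly
why the fusion is a union rather than a vote.

Dataset bookkeeping and the published aggregation arithmetic:

```r
count_dataset_tiles(7552, c(1, 2, 4, 8))
#> [1] 641920
tab <- airway_dsc_table("nnunet_in_lrelu")
mean(tab$ensemble)                    # 90.55
mean(tab$ensemble - tab$baseline)     # 2.89
```

## Command line

```sh
Rscript inst/cli/interpsplit phantom --seed 1 --out phantom/ --grid 96 --generations 4
Rscript inst/cli/interpsplit preprocess --in phantom/image.nii.gz --out norm.nii.gz
Rscript inst/cli/interpsplit run --in norm.nii.gz --mask phantom/mask.nii.gz \
    --out run/ --irs 1,2,4,8 --tile-size 64 --backend threshold-opening
Rscript inst/cli/interpsplit mathmodel-demo --out demo/   # seam/profile reports
```

Every subcommand writes a `provenance.json` (config, versions, seed) next to
its outputs; exit codes are 0 (success), 2 (usage error), 1 (runtime
failure).

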