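# canovol — canopy volume measurement from UAV digital surface models

`canovol` measures orchard canopy volume from a photogrammetric digital
surface model (DSM), for researchers and practitioners in orchard
phenotyping and precision spraying who have UAV imagery but no terrain
model and no labeled training data.

A DSM mixes two surfaces — bare ground and canopy tops — so volume
measurement is a segmentation problem first. The toolkit partitions the
orchard into square plots (default 4.5 m, one tree row per plot; the
ground inside a plot is assumed planar even on a hillside), classifies
each pixel as ground or canopy, and integrates the canopy height model
per plot:

```
V_canopy = Σ over canopy pixels of GSD² · (h_pix − h̄_ground)
```

with GSD the pixel size (m/pixel) and `h̄_ground` the mean altitude of
the plot's ground-labeled pixels. Two annotation-free segmentation
backends are provided:

* **OTSU** — per-plot elevation-histogram thresholding maximizing the
  between-class variance; pixels above the threshold are canopy;
* **RANSAC** — robust per-plot ground-plane fitting (50 sampling points,
  10,000 iterations, 0.2 m distance threshold); pixels more than the
  threshold above the fitted plane are canopy.

Around the core estimator the package provides tree-height extraction
(max − min surface height within 0.25 m of a surveyed base), a voxelized
point-cloud reference volume (0.1 m voxels, the standard mobile-laser-scan
baseline), segmentation scores (mean IoU, mean pixel accuracy) and volume
error metrics (RMSE, relative RMSE, MAPE), plus a synthetic-orchard
generator with analytically known ground truth that validates every stage
end to end.

## Worked example

A synthetic orchard with the survey geometry (4.5 m rows, 1.5 m tree
spacing, ~4 m trees, gentle slope, weedy ground, 0.016 m/pixel), segmented
with the OTSU backend and scored against the scene's exact truth. Rows are
laid out for the nominal 22.5 m field and rasterized to a whole number of
281-pixel plots:

```r
library(canovol)

set.seed(1)
trees <- layout_trees(c(22.5, 13.488))
scene <- generate_orchard(extent = c(22.48, 13.488), trees = trees,
                          gsd = 0.016, seed = 1)
plots <- partition_plots(scene$dsm, 4.5)

cfg  <- segmentation_config("otsu", seed = 1)
mask <- segment_raster(scene$dsm, cfg, plots)
vols <- measure_all(scene$dsm, mask, plots)
head(vols, 3)
#>   plot_i plot_j   volume mean_ground_alt n_canopy_px n_ground_px error
#> 1      0      0 16.28378        50.17459       20738       58223  <NA>
#> 2      0      1 18.36228        50.26645       21911       57050  <NA>
#> 3      0      2 13.00157        50.35361       17761       61200  <NA>

evaluate_run(vols, scene$true_volumes, mask, scene$truth_mask,
             backend = "otsu")
#> | Method | MIoU | MPA | n | RMSE (m^3) | rRMSE | MAPE |
#> |---|---|---|---|---|---|---|
#> | otsu | 98.15% | 98.77% | 15 | 0.362 | 1.74% | 1.65% |
```

Each `vols` row is one 4.5 m plot: its canopy volume in m³, the estimated
mean ground altitude used as the terrain reference, and the pixel counts
behind the integral. The report line says the OTSU mask agrees with the
truth mask at 98.15 % mean IoU, and the 15 per-plot volumes match the
exact truth volumes within 1.74 % relative RMSE.

A thin command-line wrapper over the same functions ships in
`inst/cli/canovol.R` (subcommands `simulate`, `segment`, `volume`,
`treeheight`, `voxelvol`, `evaluate`, `run`), driven by the same YAML
configuration as `run_pipeline()`.

## Vignette

`vignettes/canopy-volume-methods.Rmd` documents the model and its
assumptions, the two backends' numerical choices and failure modes, what
the synthetic generator does and does not emulate, and known limitations.
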