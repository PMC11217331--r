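---
title: "Measuring orchard canopy volume from UAV surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring orchard canopy volume from UAV surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canovol)
```

## The measurement problem

Photogrammetric reconstruction from overlapping UAV images yields a digital
surface model (DSM): a raster whose cell values are the altitude of the
highest surface visible from above, vegetation included. In an orchard the
DSM mixes two surfaces — bare ground and canopy tops — and canopy volume can
only be computed after the two are separated. `canovol` implements the
per-plot workflow for this:

1. partition the orchard DSM into square plots (default 4.5 m, matching a
   4.5 m row spacing so each plot holds one row segment), within which the
   ground is assumed planar even when the whole orchard sits on a hillside;
2. classify each pixel of each plot as *ground* or *canopy*;
3. integrate the canopy height model implicitly, per plot:

$$V_\text{canopy} = \sum_{\text{canopy pixels}} \mathrm{GSD}^2 \,
  (h_\text{pix} - \bar h_\text{ground}),$$

where GSD is the pixel edge length in meters and
$\bar h_\text{ground}$ is the mean altitude of the plot's ground-labeled
pixels. No digital terrain model is needed: the per-plot ground mean stands
in for it under the plot-planarity assumption.

A voxelized, ground-free canopy point cloud (such as a mobile laser scan)
provides the reference volume: occupied 0.1 m voxels times the single-voxel
volume. Segmentation quality is scored with two-class mean
intersection-over-union (MIoU) and mean pixel accuracy (MPA); volume and
height accuracy with RMSE, relative RMSE (RMSE divided by the mean true
value) and MAPE.

## Segmentation backends

**Otsu elevation thresholding.** Ground elevations cluster low and canopy
elevations high, so a plot's elevation histogram is roughly bimodal. The
threshold maximizing the between-class variance
$\sigma_b^2 = \omega_0 \omega_1 (\mu_0 - \mu_1)^2$ over a 256-bin histogram
separates the modes; pixels strictly above it are canopy. Two numerical
choices matter:

* *Degenerate-plot guard.* Otsu always returns a threshold, even for a
  treeless plot whose histogram is pure ground roughness. If a plot's
  elevation range is below twice `ground_roughness_floor` (default 0.1 m)
  the whole plot is labeled ground instead.
* *Tie-break.* When several bin edges attain the maximal variance the
  lowest qualifying edge is returned, which errs toward labeling more
  pixels canopy.

Otsu is variance-driven, not gap-driven: when canopy elevations spread over
several meters while ground is tight, the maximizing threshold can sit
*inside* the canopy distribution rather than in the ground–canopy gap,
dropping the lowest crown flanks. The clean-separation regime — and the one
our ≥ 99 % agreement tests target — is crowns starting ≥ 1.5 m above
ground.

**RANSAC plane fitting.** Plot pixels are lifted to $(x, y, z)$ points at
pixel centers and the ground plane is fitted robustly: each of 10,000
iterations draws 50 points, fits their total-least-squares plane, and
counts points within the 0.2 m distance threshold; the candidate with the
most inliers wins and is refit by least squares on its inliers, iterated to
a fixed point (the refit changes the inlier set; iterating is the standard
local-optimization step and costs almost nothing). Pixels more than 0.2 m
*above* the final plane are canopy; plane inliers and below-plane points
are ground, because canopy is physically above ground. The upward-oriented
unit normal makes "above" well defined on slopes. Sampling uses R's RNG,
so a seed makes every fit reproducible; `segment_raster()` derives one
seed per plot from the configuration seed so plots can be re-segmented in
isolation.

The 50-point candidate fit (rather than the 3-point minimum) is the
semantics of the widely used point-cloud library this parameterization
comes from, and it has a practical consequence: every candidate plane is a
least-squares compromise over its sample, so when canopy covers much more
than ~30 % of a plot, no candidate lands on the ground plane and the fit
degrades sharply. Within its working regime (< 30 % canopy cover, crowns
at least twice the threshold above ground) the fitted planes match
least-squares fits on the true ground points to better than $10^{-2}$ in
every coefficient.

**Failure modes by construction.** The two backends fail differently, and
the package's tests reproduce both: RANSAC's fixed 0.2 m threshold labels
any ground bump above 0.2 m (tall weeds, surface-reconstruction thickness)
as canopy, which Otsu absorbs into the ground mode; Otsu in turn drops low
crown flanks when the histogram is not cleanly bimodal. Masks are
deliberately *not* post-filtered — segmentation differences propagate
unaltered into the volumes so that backends can be compared fairly; a
morphological-filter hook exists in the configuration but is off and
unimplemented.

No deep-learning backend is included: the package targets the two
annotation-free classical methods, which need no labeled training data.
`make_training_tiles()` still provides the tile sampling protocol (281-px
tiles from three disjoint subregions, 400/50/100 per split) for users who
want to train an external semantic-segmentation model on synthetic scenes;
it returns window specifications plus an `extract_tile()` materializer
rather than pre-extracted arrays, because the default counts would hold
about 1.4 GB of pixels.

## The synthetic orchard and what "truth" means

Real validation data for this pipeline (a surveyed orchard plus a
registered laser scan) is not distributable, so the package generates
orchard scenes with known truth. The generator emulates the target survey:
rows 4.5 m apart, trees 1.5 m apart along the row, total tree heights
around 4 m (trunk 0.8–1.2 m plus crown 2.6–3.2 m, crown semi-axes
0.8–1.1 m), rasterized at 0.016 m/pixel; ground is a global plane with a
gentle default gradient of (0.02, 0.01), carrying "weed" bumps — zero-mean
Gaussian perturbations truncated at zero, SD 0.05 m, on 20 % of ground
pixels — so that ground is rough the way an SFM reconstruction of weedy
ground is. These defaults were fixed once, from the survey geometry they
emulate, and are not tuned per test.

Crowns are upper surfaces of half-ellipsoids (or cones): a nadir-looking
DSM sees only the upper canopy surface, so the scene's *true* per-plot
volume is deliberately defined as the DSM-visible volume computed from the
truth mask with the exact estimator formula. Two consequences:

* with a perfect mask the estimator reproduces the truth to floating-point
  identity, so in end-to-end experiments segmentation is the *only* error
  source;
* the closed-form crown volume $\tfrac{2}{3}\pi abc$ is used only in
  resolution-convergence checks (where the rasterized volume must approach
  it as GSD shrinks), never as the end-to-end reference.

The generator does not model SFM radiometry, occlusion, or reconstruction
noise beyond the optional `treetop_erosion` parameter (off by default; real
photogrammetric DSMs tend to clip thin treetops, and the parameter lets a
user emulate that bias). Passing tests on these scenes therefore validates
the *algorithms and their contracts*, not robustness to photogrammetric
artifacts.

Tree heights are measured as max − min surface height within a 0.25 m disc
around the surveyed base. On a DSM this only recovers total height when
both the apex and bare ground fall inside the disc, i.e. for narrow-crowned
trees; the height tests use crowns of 0.12–0.2 m radius for that reason.
On broad-crowned trees the disc sees only canopy and the measure degrades
to apex-minus-flank — a limitation of the disc definition itself, shared
with any implementation of it.

## Numerical and design choices

* **Plot span rounding.** A plot spans `round(plot_side / gsd)` pixels
  (281 px at the defaults); edge plots are truncated, not dropped, so plot
  volumes conserve the total.
* **Negative heights.** A mislabeled canopy pixel can lie below the plot
  ground mean; its contribution is clamped to zero by default so volumes
  stay physical (`clamp_negative = FALSE` restores the strict signed sum).
* **Plots without ground.** A fully canopied plot has no ground mean; it
  is flagged (`NoGround`) rather than fatal, and `neighbor_fallback = TRUE`
  borrows the mean of the up-to-8 neighboring plots.
* **MAPE denominator.** The conventional MAPE divides by the true value;
  the printed form this toolkit mirrors divides by the *measured* value.
  Both are available (`denominator = "truth"` is the default, `"measured"`
  the strict printed form).
* **Voxel anchoring.** Per-plot voxel grids anchor at each plot's cloud
  minimum corner, making plot volumes independent of one another and of
  global coordinates; surface-sampled synthetic clouds under-fill interior
  voxels, so convergence checks use the generator's solid sampling mode.
* **Raster storage.** Elevation rasters are stored as ESRI ASCII grids
  (text, georeference in the header, exact doubles); masks and RGB as
  8-bit PNG/TIFF with ESRI world files. Geographic (degree) coordinates
  are refused unless a meters-per-unit scale is supplied, because the
  volume integral needs metric pixel areas.
* **Determinism.** One configuration seed fans out by fixed offsets to the
  generator and to each plot's RANSAC draw; identical seeds give
  bit-identical scenes, masks and volume tables.

## Problem sizes used in the shipped experiments

The package's own validation (test suite and `scripts/acceptance.R`) runs
on: 100 random histograms for the Otsu-vs-exhaustive check; 20 seeded
plane scenes of 220–285 points; half-ellipsoid rasters at GSD 0.04/0.02/
0.01; a 10 × 10-plot orchard at 0.03 m GSD for the exactness check; and a
50-plot orchard (10 × 5 plots of 281 px) at the survey GSD of 0.016 m for
the end-to-end comparison, where both classical backends run with their
full default parameters (10,000 RANSAC iterations per plot). These sizes
were chosen as the smallest that exercise every code path at the survey's
native resolution.

## Worked example

```{r example, eval = FALSE}
library(canovol)

scene <- generate_orchard(extent = c(22.5, 13.5), gsd = 0.016, seed = 1)
plots <- partition_plots(scene$dsm, 4.5)

cfg  <- segmentation_config("otsu", seed = 1)
mask <- segment_raster(scene$dsm, cfg, plots)
vols <- measure_all(scene$dsm, mask, plots, trees = scene$trees)

report <- evaluate_run(vols, scene$true_volumes, mask, scene$truth_mask,
                       backend = "otsu")
report
```

## Known limitations

* The generator's flat-textured RGB is sufficient for tile plumbing but
  carries no photogrammetric realism; nothing here validates RGB-driven
  segmentation.
* RANSAC accuracy collapses when canopy cover exceeds roughly 30 % of a
  plot (see above); the end-to-end comparison reports this honestly rather
  than working around it, since the fixed-sample-size fit is part of the
  method being evaluated.
* Binary PLY clouds are not read (ascii PLY and XYZ text are); clouds must
  already be ground-free and georeferenced to the raster CRS.
* Plots are anchored at the raster origin; no sub-pixel grid registration
  is attempted.
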