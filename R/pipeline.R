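# Reproducible pipeline driver: config handling, staged execution,
# manifest writing. All defaults equal the survey parameters (4.5 m plots,
# RANSAC 50/10000/0.2 m, 0.1 m voxels, 0.25 m tree-height radius).
#
# One global seed fans out to fixed per-stage offsets so any stage can be
# rerun in isolation with the same result:
#   simulation seed        = seed
#   segmentation seed      = seed + 1000 (then + plot index per plot)

#' Default run configuration
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    dsm = NULL, rgb = NULL, cloud = NULL, trees = NULL,
    truth_mask = NULL, truth_volumes = NULL,
    backend = "otsu", plot_side = 4.5,
    ransac_n_samples = 50L, ransac_iterations = 10000L, ransac_distance = 0.2,
    otsu_bins = 256L, ground_roughness_floor = 0.1,
    voxel_size = 0.1, tree_radius = 0.25,
    mape_denominator = "truth",
    seed = 1L, out_dir = "canovol_out",
    simulate = NULL   # list of generate_orchard arguments
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and fills unset fields with [default_config]
#' defaults. Values passed in `...` override the file (CLI-flag
#' precedence).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param ... Overrides applied after the file.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL, ...) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

config_to_seg <- function(cfg) {
  segmentation_config(
    backend = cfg$backend, plot_side = cfg$plot_side,
    ransac_n_samples = cfg$ransac_n_samples,
    ransac_iterations = cfg$ransac_iterations,
    ransac_distance = cfg$ransac_distance,
    otsu_bins = cfg$otsu_bins,
    ground_roughness_floor = cfg$ground_roughness_floor,
    seed = as.integer(cfg$seed) + 1000L)
}

require_path <- function(cfg, field) {
  p <- cfg[[field]]
  if (is.null(p)) stop("config field `", field, "` is required for this stage")
  if (!file.exists(p)) stop("config field `", field, "` points to a missing file: ", p)
  p
}

#' Generate a synthetic scene from a configuration
#'
#' Runs [generate_orchard] with the arguments in `config$simulate`
#' (plus the global seed) and writes the scene to `out_dir` via
#' [write_scene].
#'
#' @param config Configuration list (see [load_config]).
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return The `orchard_scene`, invisibly; files on disk as side effect.
#' @export
simulate_scene <- function(config = default_config(),
                           out_dir = config$out_dir) {
  args <- config$simulate
  if (is.null(args)) args <- list()
  if (is.null(args$seed)) args$seed <- as.integer(config$seed)
  if (is.null(args$plot_side)) args$plot_side <- config$plot_side
  if (!is.null(args$extent)) args$extent <- as.numeric(unlist(args$extent))
  if (!is.null(args$ground_slope))
    args$ground_slope <- as.numeric(unlist(args$ground_slope))
  scene <- do.call(generate_orchard, args)
  write_scene(scene, out_dir)
  invisible(scene)
}

#' Run the full measurement pipeline
#'
#' Stages: read the DSM, segment it plot by plot, integrate per-plot
#' canopy volumes, optionally voxelize a reference point cloud (or read
#' a reference volume table), optionally score against the reference,
#' and write every artifact plus a manifest (`manifest.json`: files with
#' MD5 checksums, the seed, the configuration, package version). Stage
#' errors that only affect scoring are recorded in the manifest instead
#' of aborting the run.
#'
#' @param config Configuration list (see [load_config]); `config$dsm`
#'   must point to an existing raster.
#' @param out_dir Output directory; defaults to `config$out_dir`.
#' @return Invisible list with the in-memory artifacts (`mask`,
#'   `volumes`, `reference`, `report`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir = config$out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  errors <- character(0)
  p <- function(f) file.path(out_dir, f)

  raster <- read_raster(require_path(config, "dsm"))
  seg_cfg <- config_to_seg(config)
  plots <- partition_plots(raster, config$plot_side)

  mask <- segment_raster(raster, seg_cfg, plots)
  write_mask(mask, p("mask.png"), raster = raster)
  files <- c(files, p("mask.png"))

  trees <- if (!is.null(config$trees))
    read.csv(require_path(config, "trees")) else NULL
  volumes <- measure_all(raster, mask, plots, trees = trees,
                         radius = config$tree_radius)
  write.csv(volumes, p("volumes.csv"), row.names = FALSE)
  files <- c(files, p("volumes.csv"))
  if (!is.null(trees)) {
    write.csv(attr(volumes, "trees"), p("trees_out.csv"), row.names = FALSE)
    files <- c(files, p("trees_out.csv"))
  }

  reference <- NULL
  if (!is.null(config$truth_volumes)) {
    reference <- read.csv(require_path(config, "truth_volumes"))
  } else if (!is.null(config$cloud)) {
    cloud <- read_point_cloud(require_path(config, "cloud"))
    reference <- plot_reference_volumes(cloud, raster, plots,
                                        config$voxel_size)
    write.csv(reference, p("reference_volumes.csv"), row.names = FALSE)
    files <- c(files, p("reference_volumes.csv"))
  }

  report <- NULL
  if (!is.null(reference)) {
    truth_mask <- if (!is.null(config$truth_mask))
      read_mask(require_path(config, "truth_mask")) else NULL
    report <- tryCatch(
      evaluate_run(volumes, reference, pred_mask = mask,
                   truth_mask = truth_mask, backend = config$backend,
                   denominator = config$mape_denominator),
      error = function(e) {
        errors <<- c(errors, paste("evaluate:", conditionMessage(e)))
        NULL
      })
    if (!is.null(report)) {
      write_report(report, p("report.json"), p("report.md"))
      files <- c(files, p("report.json"), p("report.md"))
    }
  }

  manifest <- list(
    package = "canovol",
    version = as.character(utils::packageVersion("canovol")),
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))),
    errors = errors)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(mask = mask, volumes = volumes, reference = reference,
                 report = report, manifest = manifest))
}
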