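# Segmentation scores and volume/height error metrics.
#
# Canopy is the positive class throughout. Over the two classes
# (canopy, ground):
#   MIoU = 100 * ((TP/(TP+FP+FN)) + (TN/(TN+FP+FN))) / 2
#   MPA  = 100 * ((TP/(TP+FN)) + (TN/(TN+FP))) / 2
# For paired volume (or height) vectors V (measured) and V' (true):
#   RMSE  = sqrt(mean((V - V')^2))
#   rRMSE = 100 * RMSE / mean(V')
#   MAPE  = 100 * mean(|V' - V| / denominator)
# The MAPE denominator defaults to the true value (conventional MAPE);
# `denominator = "measured"` uses the measured value instead.

#' Pixel confusion counts between two masks
#'
#' Canopy is the positive class: `tp` counts pixels canopy in both masks,
#' `tn` ground in both, `fp` predicted canopy but truly ground, `fn`
#' predicted ground but truly canopy. Pixels that are nodata in either
#' mask are excluded.
#'
#' @param pred,truth [class_mask] objects of equal shape.
#' @return Object of class `confusion_counts` (fields `tp`, `tn`, `fp`,
#'   `fn`).
#' @export
confusion <- function(pred, truth) {
  p <- if (inherits(pred, "class_mask")) pred$labels else as.matrix(pred)
  t <- if (inherits(truth, "class_mask")) truth$labels else as.matrix(truth)
  if (!identical(dim(p), dim(t)))
    stop("prediction and truth masks have different shapes")
  valid <- p != MASK_NODATA & t != MASK_NODATA
  p <- p[valid]; t <- t[valid]
  confusion_counts(tp = sum(p == MASK_CANOPY & t == MASK_CANOPY),
                   tn = sum(p == MASK_GROUND & t == MASK_GROUND),
                   fp = sum(p == MASK_CANOPY & t == MASK_GROUND),
                   fn = sum(p == MASK_GROUND & t == MASK_CANOPY))
}

#' @rdname confusion
#' @param tp,tn,fp,fn Non-negative pixel counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  if (any(c(tp, tn, fp, fn) < 0)) stop("confusion counts must be >= 0")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %d fp %d fn %d tn %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Mean intersection over union (percent)
#'
#' Mean of the canopy IoU `tp/(tp+fp+fn)` and the ground IoU
#' `tn/(tn+fp+fn)`, times 100.
#'
#' @param c A [confusion_counts].
#' @return Percentage in `[0, 100]`.
#' @export
miou <- function(c) {
  d1 <- c$tp + c$fp + c$fn
  d2 <- c$tn + c$fp + c$fn
  if (d1 == 0 || d2 == 0)
    cond_error("canovol_undefined_metric",
               "MIoU undefined: a class denominator is zero")
  100 * (c$tp / d1 + c$tn / d2) / 2
}

#' Mean pixel accuracy (percent)
#'
#' Mean over the two classes of the proportion of that class's pixels
#' classified correctly: `(tp/(tp+fn) + tn/(tn+fp)) / 2`, times 100.
#'
#' @param c A [confusion_counts].
#' @return Percentage in `[0, 100]`.
#' @export
mpa <- function(c) {
  if (c$tp + c$fn == 0 || c$tn + c$fp == 0)
    cond_error("canovol_undefined_metric",
               "MPA undefined: one class has no pixels in the truth")
  100 * (c$tp / (c$tp + c$fn) + c$tn / (c$tn + c$fp)) / 2
}

#' Volume/height error metrics
#'
#' RMSE, relative RMSE and MAPE between measured and true value vectors.
#' Metrics whose denominator vanishes are returned as `NA` with a
#' warning; the others are still reported.
#'
#' @param measured,truth Equal-length numeric vectors (pairs with `NA`
#'   on either side are dropped).
#' @param denominator MAPE denominator: `"truth"` (conventional) or
#'   `"measured"`.
#' @return Object of class `error_report`: `rmse` (input units), `rrmse`
#'   and `mape` (percent), `n`, `residuals` (measured minus truth).
#' @examples
#' error_metrics(c(1, 2, 3), c(2, 2, 2))
#' @export
error_metrics <- function(measured, truth,
                          denominator = c("truth", "measured")) {
  denominator <- match.arg(denominator)
  if (length(measured) != length(truth))
    stop("`measured` and `truth` must have equal length")
  ok <- !is.na(measured) & !is.na(truth)
  measured <- measured[ok]; truth <- truth[ok]
  n <- length(measured)
  if (n < 1L) stop("no complete measured/truth pairs")
  res <- measured - truth
  rmse <- sqrt(mean(res^2))
  tbar <- mean(truth)
  rrmse <- if (tbar == 0) {
    warning("rRMSE undefined: mean true value is zero"); NA_real_
  } else 100 * rmse / tbar
  den <- if (denominator == "truth") truth else measured
  mape <- if (any(den == 0)) {
    warning("MAPE undefined: zero ", denominator, " value present"); NA_real_
  } else 100 * mean(abs(truth - measured) / abs(den))
  structure(list(rmse = rmse, rrmse = rrmse, mape = mape, n = n,
                 residuals = res, denominator = denominator),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> n = %d: RMSE %.4f, rRMSE %.2f%%, MAPE %.2f%% (/%s)\n",
              x$n, x$rmse, x$rrmse, x$mape, x$denominator))
  invisible(x)
}

#' Score a pipeline run against reference data
#'
#' Joins measured and reference per-plot volume tables on
#' `(plot_i, plot_j)` (unmatched plots are dropped with a warning) and
#' computes volume error metrics; if a predicted and a truth mask are
#' supplied, segmentation scores are added.
#'
#' @param pred_volumes,truth_volumes data.frames with columns `plot_i`,
#'   `plot_j`, `volume` (as written by [measure_all] /
#'   [plot_reference_volumes]).
#' @param pred_mask,truth_mask Optional [class_mask] pair.
#' @param backend Label stored in the report (e.g. `"otsu"`).
#' @param denominator MAPE denominator, see [error_metrics].
#' @return List of class `canovol_report` with elements `backend`, `n`,
#'   `volume` ([error_metrics] result) and optionally `segmentation`
#'   (`miou`, `mpa`, `confusion`).
#' @export
evaluate_run <- function(pred_volumes, truth_volumes,
                         pred_mask = NULL, truth_mask = NULL,
                         backend = NA_character_,
                         denominator = c("truth", "measured")) {
  m <- merge(pred_volumes[, c("plot_i", "plot_j", "volume")],
             truth_volumes[, c("plot_i", "plot_j", "volume")],
             by = c("plot_i", "plot_j"), suffixes = c("_pred", "_true"))
  n_un <- nrow(pred_volumes) + nrow(truth_volumes) - 2L * nrow(m)
  if (n_un > 0)
    warning(n_un, " plot id(s) without a match were dropped")
  if (nrow(m) == 0L) stop("no matching plot ids between the volume tables")
  m <- m[order(m$plot_i, m$plot_j), ]
  rep <- list(backend = backend, n = nrow(m),
              volume = error_metrics(m$volume_pred, m$volume_true,
                                     denominator = match.arg(denominator)),
              plots = m)
  if (!is.null(pred_mask) && !is.null(truth_mask)) {
    cc <- confusion(pred_mask, truth_mask)
    rep$segmentation <- list(miou = miou(cc), mpa = mpa(cc), confusion = cc)
  }
  structure(rep, class = "canovol_report")
}

#' @export
print.canovol_report <- function(x, ...) {
  cat(report_markdown(x), sep = "\n")
  invisible(x)
}

#' Render a report as a markdown table
#'
#' Percentages and volumes shown to 2 decimal places; use
#' [write_report] for full-precision JSON.
#'
#' @param report A `canovol_report` (or list of them, one per backend).
#' @return Character vector of markdown lines.
#' @export
report_markdown <- function(report) {
  reports <- if (inherits(report, "canovol_report")) list(report) else report
  lines <- c("| Method | MIoU | MPA | n | RMSE (m^3) | rRMSE | MAPE |",
             "|---|---|---|---|---|---|---|")
  fmtp <- function(v) if (is.null(v) || is.na(v)) "-" else sprintf("%.2f%%", v)
  for (r in reports) {
    s <- r$segmentation
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %d | %.3f | %s | %s |",
      ifelse(is.na(r$backend), "?", r$backend),
      fmtp(if (is.null(s)) NA else s$miou), fmtp(if (is.null(s)) NA else s$mpa),
      r$n, r$volume$rmse, fmtp(r$volume$rrmse), fmtp(r$volume$mape)))
  }
  lines
}

#' Write a report to JSON (and optionally markdown)
#'
#' @param report A `canovol_report` or list of them.
#' @param json_path Output JSON file (full precision).
#' @param md_path Optional markdown table file.
#' @return `json_path`, invisibly.
#' @export
write_report <- function(report, json_path, md_path = NULL) {
  reports <- if (inherits(report, "canovol_report")) list(report) else report
  as_plain <- function(r) {
    out <- list(backend = r$backend, n = r$n,
                volume = list(rmse = r$volume$rmse, rrmse = r$volume$rrmse,
                              mape = r$volume$mape,
                              denominator = r$volume$denominator))
    if (!is.null(r$segmentation))
      out$segmentation <- list(miou = r$segmentation$miou,
                               mpa = r$segmentation$mpa,
                               confusion = unclass(r$segmentation$confusion))
    out
  }
  jsonlite::write_json(lapply(reports, as_plain), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(md_path)) writeLines(report_markdown(report), md_path)
  invisible(json_path)
}
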