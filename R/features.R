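#' Fixed-bin SUV discretisation settings
#'
#' Grey-value discretisation uses a fixed bin width on the absolute SUV
#' scale with no further normalisation. Bin edges sit at
#' `anchor + k * bin_width_suv`; a value on an edge falls in the upper bin,
#' and each bin is represented by its centre (`edge + width/2`).
#'
#' @param bin_width_suv Bin width in SUV; default 0.3.
#' @param anchor Bin-edge anchor in SUV; default 0, so edges at k * width
#'   are comparable across scans and timepoints.
#' @param values Compute the cumulative histogram on `"binned"` SUVs
#'   (bin centres; the default, matching discretisation-first extraction) or
#'   on `"raw"` voxel values (sensitivity analysis).
#' @param integration `"step"` integrates the cumulative SUV-volume
#'   histogram exactly as the step function it is; `"trapezoid"` is offered
#'   for cross-tool comparison.
#' @return An object of class `discretisation_config`.
#' @export
discretisation_config <- function(bin_width_suv = 0.3, anchor = 0,
                                  values = c("binned", "raw"),
                                  integration = c("step", "trapezoid")) {
  if (!is.numeric(bin_width_suv) || length(bin_width_suv) != 1L ||
      !is.finite(bin_width_suv) || bin_width_suv <= 0)
    stopf("bin_width_suv must be a single positive number")
  structure(list(bin_width_suv = bin_width_suv, anchor = anchor,
                 values = match.arg(values),
                 integration = match.arg(integration)),
            class = "discretisation_config")
}

#' Discretise SUV values into fixed-width bins
#'
#' Maps each value v to the 0-based index `floor((v - anchor) / width)`,
#' i.e. half-open bins `[edge, edge + width)` with edge values falling in
#' the upper bin.
#'
#' @param suvs Non-empty numeric vector of SUVs (>= anchor).
#' @param config A [discretisation_config()].
#' @return Integer vector of 0-based bin indices.
#' @examples
#' discretise(c(0, 0.29, 0.3, 0.95), discretisation_config(0.3))
#' @export
discretise <- function(suvs, config = discretisation_config()) {
  if (length(suvs) == 0L) stopf("no SUV values to discretise")
  if (anyNA(suvs) || any(!is.finite(suvs))) stopf("non-finite SUV values")
  if (any(suvs < config$anchor))
    stopf("SUV values below the bin anchor (%g)", config$anchor)
  as.integer(floor((suvs - config$anchor) / config$bin_width_suv))
}

# Centre of the bin with 0-based index k.
bin_centre <- function(idx, config) {
  config$anchor + (idx + 0.5) * config$bin_width_suv
}

#' First-order SUV features of a masked volume
#'
#' SUVmax and SUVmean are computed on the raw (undiscretised) voxel values;
#' metabolic tumour volume (MTV) is the foreground voxel count times the
#' voxel volume in mL; total lesion glycolysis is TLG = SUVmean x MTV.
#'
#' @param volume An [suv_volume()].
#' @param mask A non-empty [roi_mask()] congruent with `volume`.
#' @return List with `suv_max`, `suv_mean`, `mtv_ml`, `tlg`.
#' @export
first_order_features <- function(volume, mask) {
  check_mask_for_features(volume, mask)
  suvs <- volume$voxels[mask$voxels]
  mtv_ml <- length(suvs) * voxel_volume_ml(volume)
  suv_mean <- mean(suvs)
  list(suv_max = max(suvs), suv_mean = suv_mean, mtv_ml = mtv_ml,
       tlg = suv_mean * mtv_ml)
}

#' Cumulative SUV-volume histogram of a masked volume
#'
#' The CSH plots the fraction of the ROI volume with uptake at or above
#' each fraction of the maximum uptake. SUVs are first discretised per
#' `config` and represented by bin centres; the x grid is the occupied bin
#' centres divided by the top occupied centre, with x = 0 prepended
#' (y(0) = 1 by construction).
#'
#' @inheritParams first_order_features
#' @param config A [discretisation_config()].
#' @return An object of class `csh_curve` with ascending `x` in \[0, 1\] and
#'   non-increasing `y` in \[0, 1\].
#' @export
csh_curve <- function(volume, mask, config = discretisation_config()) {
  check_mask_for_features(volume, mask)
  suvs <- volume$voxels[mask$voxels]
  if (max(suvs) <= 0) stopf("SUVmax is not positive; CSH undefined")
  vals <- if (config$values == "binned")
    bin_centre(discretise(suvs, config), config) else suvs
  m <- max(vals)
  levels <- sort(unique(vals))
  x <- c(0, levels / m)
  y <- c(1, vapply(levels, function(l) mean(vals >= l), numeric(1)))
  structure(list(x = x, y = y, config = config, n_voxels = length(suvs)),
            class = "csh_curve")
}

#' @export
print.csh_curve <- function(x, ...) {
  cat(sprintf("<csh_curve> %d threshold(s) over %d voxel(s), AUC-CSH = %.4f\n",
              length(x$x) - 1L, x$n_voxels, auc_csh(x)))
  invisible(x)
}

#' Plot a cumulative SUV-volume histogram
#'
#' @param x A [csh_curve()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.csh_curve <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "fraction of SUVmax",
                 ylab = "fraction of tumour volume", ...)
  invisible(x)
}

#' Area under the cumulative SUV-volume histogram (AUC-CSH)
#'
#' The heterogeneity score: 1 corresponds to perfectly homogeneous uptake,
#' lower values to greater intra-tumoural heterogeneity. Between successive
#' thresholds x_{i-1} < x <= x_i the volume fraction above x is y_i, so the
#' exact area of the step curve is `sum(y_i * (x_i - x_{i-1}))`; a
#' homogeneous ROI (single occupied bin) gives exactly 1.
#'
#' @param curve A [csh_curve()] (or any list with ascending `x` in \[0,1\],
#'   `x[1] = 0`, `x[last] = 1`, and non-increasing `y` with `y[1] = 1`).
#' @param integration Override the curve's configured integration rule.
#' @return Numeric in (0, 1\].
#' @export
auc_csh <- function(curve, integration = NULL) {
  x <- curve$x; y <- curve$y
  if (length(x) < 2L || length(x) != length(y))
    stopf("malformed CSH curve: need matching x/y with >= 2 points")
  if (any(diff(x) <= 0) || x[1] != 0 || abs(x[length(x)] - 1) > 1e-12 ||
      any(x < 0) || any(x > 1 + 1e-12))
    stopf("malformed CSH curve: x must ascend from 0 to 1")
  if (any(diff(y) > 1e-12) || abs(y[1] - 1) > 1e-12 || any(y < 0))
    stopf("malformed CSH curve: y must be non-increasing from 1")
  rule <- integration %||%
    (if (!is.null(curve$config)) curve$config$integration else "step")
  if (rule == "trapezoid")
    sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  else
    sum(diff(x) * utils::tail(y, -1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the five mid-treatment PET parameters of an ROI
#'
#' Combines [first_order_features()] with the CSH heterogeneity score:
#' SUVmax, SUVmean, MTV (mL), TLG (SUV x mL) and AUC-CSH, plus the CSH
#' curve itself.
#'
#' @inheritParams csh_curve
#' @return An object of class `feature_set`.
#' @examples
#' v <- suv_volume(array(5, c(5, 5, 5)), spacing = c(2, 2, 2))
#' m <- roi_mask(array(1, c(5, 5, 5)), reference = v)
#' extract_features(v, m)
#' @export
extract_features <- function(volume, mask, config = discretisation_config()) {
  fo <- first_order_features(volume, mask)
  curve <- csh_curve(volume, mask, config)
  structure(c(fo, list(auc_csh = auc_csh(curve), csh = curve,
                       scan_id = volume$scan_id,
                       timepoint = volume$timepoint,
                       config = config)),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %s [%s]\n",
              if (nzchar(x$scan_id)) x$scan_id else "(unnamed)", x$timepoint))
  cat(sprintf("  SUVmax %.3f  SUVmean %.3f  MTV %.3f mL  TLG %.3f  AUC-CSH %.4f\n",
              x$suv_max, x$suv_mean, x$mtv_ml, x$tlg, x$auc_csh))
  invisible(x)
}

#' @export
as.data.frame.feature_set <- function(x, ...) {
  data.frame(scan_id = x$scan_id, timepoint = x$timepoint,
             suv_max = x$suv_max, suv_mean = x$suv_mean,
             mtv_ml = x$mtv_ml, tlg = x$tlg, auc_csh = x$auc_csh,
             bin_width = x$config$bin_width_suv, anchor = x$config$anchor,
             stringsAsFactors = FALSE)
}
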