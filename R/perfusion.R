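# Perfusion metrics from dynamic contrast-enhanced CT.
#
# A dynamic contrast study repeatedly scans the same region while a
# contrast bolus flows through the pulmonary vasculature.  The mean HU in
# a vessel or parenchyma ROI per frame forms a time-attenuation curve;
# its baseline (pre-injection mean), peak enhancement (max minus
# baseline) and baseline-subtracted area under the curve summarise how
# much contrast reached the region.

#' Dynamic contrast frame series
#'
#' @param frames ordered list of grid-congruent HU [image_volume()]s.
#' @param times acquisition time of each frame in seconds, strictly
#'   increasing.
#' @param breathhold whether the series was acquired in breath hold.
#' @export
contrast_series <- function(frames, times, breathhold = TRUE) {
  if (length(frames) < 3L)
    stop("contrast_series: need at least 3 frames", call. = FALSE)
  if (length(times) != length(frames) || any(diff(times) <= 0))
    stop("contrast_series: times must be strictly increasing, one per frame",
         call. = FALSE)
  for (f in frames) stop_if_incongruent(f, frames[[1]], "contrast frames")
  structure(list(frames = frames, times = as.numeric(times),
                 breathhold = isTRUE(breathhold)),
            class = "contrast_series")
}

#' Extract an ROI time-attenuation curve
#'
#' @param series a [contrast_series()].
#' @param roi `roi_mask` congruent with the frames.
#' @param n_precontrast number of frames acquired before contrast
#'   injection, or `NULL` to detect it as the frames preceding the first
#'   frame whose value exceeds baseline + 3 baseline standard deviations
#'   (the injection frame is rarely recorded explicitly).
#' @return object of class `contrast_curve` with fields `times`, `values`
#'   (mean HU per frame), `roi_label`, `n_precontrast`.
#' @export
extract_curve <- function(series, roi, n_precontrast = NULL) {
  stopifnot(inherits(series, "contrast_series"))
  if (!identical(dim(roi$mask), dim(series$frames[[1]]$data)))
    stop("geometry error: ROI not congruent with frames", call. = FALSE)
  if (!any(roi$mask))
    stop("empty-ROI error: ROI has no voxels", call. = FALSE)
  vals <- vapply(series$frames, function(f) mean(f$data[roi$mask]),
                 numeric(1))
  n <- length(vals)
  if (is.null(n_precontrast)) {
    b0 <- vals[1:min(3L, n)]
    thr <- mean(b0) + 3 * max(stats::sd(b0), 1e-6)
    first_up <- which(vals > thr)[1]
    n_precontrast <- if (is.na(first_up)) n - 1L else max(first_up - 1L, 1L)
  }
  n_precontrast <- as.integer(n_precontrast)
  if (n_precontrast < 1L || n_precontrast >= n)
    stop("extract_curve: n_precontrast must be in [1, n_frames)",
         call. = FALSE)
  structure(list(times = series$times, values = vals, roi_label = roi$label,
                 n_precontrast = n_precontrast),
            class = "contrast_curve")
}

#' Build a contrast curve from raw vectors
#'
#' Convenience constructor used when curves come from tables rather than
#' volumes (e.g. exported CSV curves).
#' @param times,values equal-length numeric vectors.
#' @param roi_label contour label.
#' @param n_precontrast pre-injection frame count.
#' @export
contrast_curve <- function(times, values, roi_label = "vessel-bin",
                           n_precontrast = 1L) {
  if (length(times) != length(values))
    stop("contrast_curve: times and values must have equal length",
         call. = FALSE)
  if (n_precontrast < 1L || n_precontrast >= length(values))
    stop("contrast_curve: n_precontrast must be in [1, n_frames)",
         call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 roi_label = roi_label,
                 n_precontrast = as.integer(n_precontrast)),
            class = "contrast_curve")
}

#' Baseline HU of a curve
#'
#' Mean of the pre-injection frames.
#' @param curve a `contrast_curve`.
#' @export
baseline_hu <- function(curve) {
  mean(curve$values[seq_len(curve$n_precontrast)])
}

#' Peak enhancement of a curve
#'
#' Maximum curve value minus baseline; the vessel-side measure of how
#' much contrast arrived.
#' @param curve a `contrast_curve`.
#' @export
peak_enhancement <- function(curve) {
  max(curve$values) - baseline_hu(curve)
}

#' Area under the baseline-subtracted curve
#'
#' Trapezoidal integral of `value - baseline` over time from the first
#' post-injection frame to the last frame (HU s).  Baseline subtraction
#' makes the area contrast-specific rather than anatomy-specific; set
#' `baseline_subtract = FALSE` for the raw-curve area.  Negative
#' excursions are included as-is.
#'
#' @param curve a `contrast_curve`.
#' @param baseline_subtract subtract the pre-injection baseline (default).
#' @export
curve_auc <- function(curve, baseline_subtract = TRUE) {
  i0 <- curve$n_precontrast + 1L
  t <- curve$times[i0:length(curve$times)]
  if (length(t) < 2L)
    stop("insufficient-data error: need at least 2 post-injection frames",
         call. = FALSE)
  v <- curve$values[i0:length(curve$values)]
  if (baseline_subtract) v <- v - baseline_hu(curve)
  sum(diff(t) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' All scalar perfusion metrics of a curve
#' @param curve a `contrast_curve`.
#' @inheritParams curve_auc
#' @return list with `baseline`, `peak`, `peak_enhancement`, `auc`,
#'   `roi_label`.
#' @export
perfusion_metrics <- function(curve, baseline_subtract = TRUE) {
  b <- baseline_hu(curve)
  list(baseline = b, peak = max(curve$values),
       peak_enhancement = max(curve$values) - b,
       auc = curve_auc(curve, baseline_subtract),
       roi_label = curve$roi_label)
}

#' Signed pre- to post-treatment change of a perfusion metric
#'
#' @param metric_pre,metric_post metric lists from [perfusion_metrics()]
#'   for the same ROI.
#' @param which `"baseline"`, `"peak_enhancement"` or `"auc"`.
#' @return `post - pre` for the chosen metric.
#' @export
delta_pre_post <- function(metric_pre, metric_post,
                           which = c("baseline", "peak_enhancement", "auc")) {
  which <- match.arg(which)
  if (!identical(metric_pre$roi_label, metric_post$roi_label))
    stop("pairing error: metrics come from different ROIs (",
         metric_pre$roi_label, " vs ", metric_post$roi_label, ")",
         call. = FALSE)
  metric_post[[which]] - metric_pre[[which]]
}

#' Dose bin edges used throughout the analysis
#'
#' Half-open 10-Gy bins `[0,10), ..., [40,50)` with the last bin closed
#' `[50,60]`.
#' @export
dose_bin_edges <- function() seq(0, 60, by = 10)

dose_bin_of <- function(dose) {
  edges <- dose_bin_edges()
  b <- findInterval(dose, edges, rightmost.closed = TRUE)
  b[b < 1L | b > 6L] <- NA_integer_
  b
}

#' Dose-binned pre/post perfusion change table
#'
#' For each 10-Gy dose bin, vessels contribute the change in peak
#' enhancement and the surrounding parenchyma the change in baseline HU.
#' A vessel ROI's bin is decided by its mean dose; bins with no ROI are
#' omitted with a log notice.
#'
#' @param pre,post [contrast_series()] acquired before and after
#'   treatment, on congruent grids.
#' @param vessel_rois,parenchyma_rois lists of `roi_mask` (one or more per
#'   bin; membership decided by mean dose over the ROI).
#' @param dose a [dose_grid()] congruent with the series.
#' @param n_precontrast passed to [extract_curve()].
#' @param pair_by_vessel when the parenchyma ROIs are one-to-one
#'   counterparts of the vessel ROIs (e.g. surrounding shells), bin each
#'   parenchyma ROI with its vessel rather than by its own mean dose, so
#'   both tissues describe the same dose neighbourhoods.
#' @return data frame with columns `bin_lo`, `bin_hi`, `tissue`,
#'   `delta_metric`, `n_rois`.
#' @export
dose_binned_deltas <- function(pre, post, vessel_rois, parenchyma_rois,
                               dose, n_precontrast = NULL,
                               pair_by_vessel = FALSE) {
  stop_if_incongruent(dose, pre$frames[[1]], "dose grid and frames")
  if (pair_by_vessel && length(parenchyma_rois) != length(vessel_rois))
    stop("dose_binned_deltas: pair_by_vessel needs one parenchyma ROI ",
         "per vessel ROI", call. = FALSE)
  edges <- dose_bin_edges()
  vessel_bins <- vapply(vessel_rois, function(r) {
    dose_bin_of(mean(dose$data[r$mask]))
  }, integer(1))
  rows <- list()
  for (tissue in c("vessel", "parenchyma")) {
    rois <- if (tissue == "vessel") vessel_rois else parenchyma_rois
    which_metric <- if (tissue == "vessel") "peak_enhancement" else "baseline"
    if (length(rois) == 0L) next
    bin_of_roi <- if (tissue == "vessel" || pair_by_vessel) {
      vessel_bins
    } else {
      vapply(rois, function(r) {
        dose_bin_of(mean(dose$data[r$mask]))
      }, integer(1))
    }
    for (b in 1:6) {
      members <- which(bin_of_roi == b)
      if (length(members) == 0L) {
        lfx_log("perfusion", sprintf(
          "dose bin [%g, %g) has no %s ROI; row omitted",
          edges[b], edges[b + 1], tissue))
        next
      }
      deltas <- vapply(members, function(i) {
        mpre <- perfusion_metrics(extract_curve(pre, rois[[i]],
                                                n_precontrast))
        mpost <- perfusion_metrics(extract_curve(post, rois[[i]],
                                                 n_precontrast))
        delta_pre_post(mpre, mpost, which_metric)
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        bin_lo = edges[b], bin_hi = edges[b + 1], tissue = tissue,
        delta_metric = mean(deltas), n_rois = length(members))
    }
  }
  do.call(rbind, rows)
}

#' Correlation of vessel and parenchyma HU changes across dose bins
#'
#' Least-squares fit of the parenchyma baseline change against the vessel
#' peak-enhancement change over bins whose lower edge is at or above
#' `min_dose`; contrast leaking from damaged vessels shows up as an
#' anticorrelation, strongest above roughly 25 Gy.
#'
#' @param table output of [dose_binned_deltas()].
#' @param min_dose only bins with `bin_lo >= min_dose` qualify.
#' @return list with `slope`, `intercept`, `pearson_r`, `n_bins`,
#'   `degenerate` (TRUE when a variable has zero variance, in which case
#'   slope and r are reported as 0).
#' @export
vessel_parenchyma_correlation <- function(table, min_dose = 25) {
  v <- table[table$tissue == "vessel" & table$bin_lo >= min_dose, ]
  p <- table[table$tissue == "parenchyma" & table$bin_lo >= min_dose, ]
  m <- merge(v, p, by = c("bin_lo", "bin_hi"), suffixes = c("_v", "_p"))
  if (nrow(m) < 2L)
    stop("insufficient-data error: fewer than 2 qualifying dose bins",
         call. = FALSE)
  x <- m$delta_metric_v; y <- m$delta_metric_p
  if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    return(list(slope = 0, intercept = mean(y), pearson_r = 0,
                n_bins = nrow(m), degenerate = TRUE))
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = stats::cor(x, y), n_bins = nrow(m), degenerate = FALSE)
}

#' Export a curve as a two-column table
#' @param curve a `contrast_curve`.
#' @export
curve_as_table <- function(curve) {
  data.frame(time_s = curve$times, mean_hu = curve$values)
}
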