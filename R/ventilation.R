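# Voxel-wise ventilation from multi-phase breathing CT.
#
# Each breathing phase registered to end exhale yields a displacement
# field; its Jacobian determinant J is the local volume-change factor of
# that phase relative to exhale (J > 1 = expansion).  Over the N phases of
# the cycle the local expansion ratio LER-N at a voxel is the ratio of the
# largest to the smallest expansion state seen during the cycle, with the
# exhale reference itself (J = 1) always part of that set, so LER-N >= 1
# by construction and typical lung values fall in roughly [1, 1.6].

#' Jacobian determinant map of a displacement field
#'
#' Computes `J(v) = det(I + grad u(v))` voxel-wise, with the displacement
#' gradient taken by central differences in physical (mm) units and
#' one-sided differences at the grid boundary.
#'
#' @param field a [displacement_field()].
#' @param smooth_sigma Gaussian sigma in voxels applied to the computed
#'   determinant map.  Estimated (registered) fields carry voxel-level
#'   noise that inflates the voxelwise max/min expansion ratio; a light
#'   smoothing (about 1 voxel) is the conventional remedy.  Leave at 0
#'   for analytic or bypass fields.
#' @return `image_volume` of Jacobian determinants (dimensionless), with
#'   attribute `n_nonpositive` counting voxels where J <= 0 (physically
#'   implausible foldings; those voxels are flagged invalid downstream).
#' @export
jacobian_map <- function(field, smooth_sigma = 0) {
  sp <- field$spacing
  gx <- gradient_phys(field$ux, sp)
  gy <- gradient_phys(field$uy, sp)
  gz <- gradient_phys(field$uz, sp)
  a11 <- 1 + gx$x; a12 <- gx$y; a13 <- gx$z
  a21 <- gy$x; a22 <- 1 + gy$y; a23 <- gy$z
  a31 <- gz$x; a32 <- gz$y; a33 <- 1 + gz$z
  J <- a11 * (a22 * a33 - a23 * a32) -
       a12 * (a21 * a33 - a23 * a31) +
       a13 * (a21 * a32 - a22 * a31)
  if (smooth_sigma > 0) J <- gaussian_smooth(J, smooth_sigma)
  out <- image_volume(J, spacing = sp, origin = field$origin,
                      frame_label = field$phase_label)
  attr(out, "n_nonpositive") <- sum(J <= 0)
  out
}

#' Local expansion ratio over N breathing phases (LER-N)
#'
#' Per voxel, over the set `{1} U {J_k}` of Jacobian determinants of all
#' registered phases together with the exhale reference (J = 1), LER-N is
#' the ratio of the maximum to the minimum of that set.  The result is
#' >= 1 everywhere, invariant to phase ordering, and can only grow when a
#' phase is added.  Voxels where any phase has J <= 0 are flagged invalid
#' (NA) and excluded from ROI statistics.
#'
#' @param jacobians list of Jacobian maps from [jacobian_map()] (at least
#'   one), all grid-congruent.
#' @param tidal_volume tidal volume (L) at which the series was acquired,
#'   recorded for later effort correction.
#' @return `image_volume` of LER-N values with fields `effort_corrected`
#'   (FALSE) and `tidal_volume_reference`.
#' @export
ler_n <- function(jacobians, tidal_volume = 1.0) {
  if (length(jacobians) < 1L)
    stop("ler_n: need at least one Jacobian map", call. = FALSE)
  for (jmap in jacobians)
    stop_if_incongruent(jmap, jacobians[[1]], "Jacobian maps")
  d <- dim(jacobians[[1]]$data)
  jmax <- array(1, d); jmin <- array(1, d)
  invalid <- array(FALSE, d)
  for (jmap in jacobians) {
    J <- jmap$data
    invalid <- invalid | J <= 0 | !is.finite(J)
    jmax <- pmax(jmax, J)
    jmin <- pmin(jmin, J)
  }
  v <- jmax / jmin
  v[invalid] <- NA_real_
  out <- image_volume(ifelse(is.na(v), 1, v), jacobians[[1]]$spacing,
                      jacobians[[1]]$origin, frame_label = "LER-N")
  out$data[invalid] <- NA_real_
  out$effort_corrected <- FALSE
  out$tidal_volume_reference <- tidal_volume
  out
}

#' Tidal-volume effort correction of a ventilation map
#'
#' Breathing effort differs between imaging sessions; to compare maps they
#' are rescaled to a common reference tidal volume.  The voxel excess
#' expansion (LER-N - 1), whose lung sum is to first order proportional to
#' the inhaled volume, is scaled by the single global factor
#' `reference_tv / measured_tv`, and the result is clipped below at 1.
#'
#' @param map LER-N `image_volume` from [ler_n()].
#' @param lung `roi_mask` of the lung (used to validate the map's support;
#'   the scaling itself is global).
#' @param measured_tv tidal volume (L) at acquisition.
#' @param reference_tv tidal volume (L) to correct to (default 1 L).
#' @return corrected ventilation map with `effort_corrected = TRUE`.
#' @export
effort_correct <- function(map, lung, measured_tv,
                           reference_tv = 1.0) {
  if (measured_tv <= 0 || reference_tv <= 0)
    stop("effort_correct: tidal volumes must be > 0", call. = FALSE)
  if (!identical(dim(lung$mask), dim(map$data)))
    stop("geometry error: lung mask not congruent with map", call. = FALSE)
  if (!any(lung$mask))
    stop("mask error: lung mask has no voxels", call. = FALSE)
  f <- reference_tv / measured_tv
  out <- map
  out$data <- pmax(1 + (map$data - 1) * f, 1)
  out$effort_corrected <- TRUE
  out$tidal_volume_reference <- reference_tv
  out
}

#' Classify absolute ventilation level
#'
#' `High` at LER-N >= 1.2, `Low` at LER-N <= 1.1, `Moderate` strictly in
#' between.  Moderate values are hard to interpret without a consensus
#' high-ventilation threshold and are kept as their own class.
#'
#' @param value LER-N value(s), vectorised.
#' @param high_min,low_max classification thresholds.
#' @return factor with levels `High`, `Moderate`, `Low`.
#' @export
classify_ventilation <- function(value, high_min = 1.2, low_max = 1.1) {
  if (any(!is.finite(value)))
    stop("value error: non-finite ventilation value", call. = FALSE)
  cls <- ifelse(value >= high_min, "High",
                ifelse(value <= low_max, "Low", "Moderate"))
  factor(cls, levels = c("High", "Moderate", "Low"))
}

#' Classify pre- to post-treatment ventilation change
#'
#' The change ratio is `post / pre`.  A ratio strictly below 0.94 (at
#' least 6\% ventilation reduction, a conservative repeatability-based
#' threshold) is `Decline`; strictly above 1.06 is `Increase`; otherwise
#' `Stable`.  Both comparisons are strict, so ratios of exactly 0.94 or
#' 1.06 are Stable.
#'
#' @param pre_value,post_value LER-N values (vectorised; `pre_value > 0`).
#' @param decline_max,increase_min change thresholds.
#' @return data frame with columns `ratio` and `class` (factor with levels
#'   `Decline`, `Stable`, `Increase`).
#' @export
classify_change <- function(pre_value, post_value,
                            decline_max = 0.94, increase_min = 1.06) {
  if (any(!is.finite(pre_value)) || any(pre_value <= 0))
    stop("value error: pre_value must be finite and > 0", call. = FALSE)
  ratio <- post_value / pre_value
  cls <- ifelse(ratio < decline_max, "Decline",
                ifelse(ratio > increase_min, "Increase", "Stable"))
  data.frame(ratio = ratio,
             class = factor(cls, levels = c("Decline", "Stable", "Increase")))
}

#' ROI summary of a ventilation map
#'
#' Mean and standard deviation over the valid (non-NA) voxels of the ROI.
#'
#' @param map ventilation `image_volume`.
#' @param roi `roi_mask` congruent with the map.
#' @return list with `mean`, `sd`, `n_valid`.
#' @export
roi_ventilation <- function(map, roi) {
  if (!identical(dim(roi$mask), dim(map$data)))
    stop("geometry error: ROI not congruent with map", call. = FALSE)
  vals <- map$data[roi$mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0L)
    stop("empty-ROI error: no valid voxels in ROI", call. = FALSE)
  list(mean = mean(vals), sd = stats::sd(vals), n_valid = length(vals))
}

#' Per-contour ventilation change ratio
#'
#' The contour-level change ratio is by default the ratio of ROI means,
#' `mean(post) / mean(pre)` over the same ROI, which is robust to
#' voxel-level registration noise; `method = "mean_of_ratios"` averages
#' the voxel-wise ratios instead.  Both are provided because published
#' contour ratios do not state which convention was used.
#'
#' @param pre_map,post_map ventilation maps on a common grid.
#' @param roi `roi_mask`.
#' @param method `"ratio_of_means"` (default) or `"mean_of_ratios"`.
#' @inheritParams classify_change
#' @return one-row data frame with `mean_pre`, `mean_post`, `ratio`,
#'   `change_class`.
#' @export
roi_change <- function(pre_map, post_map, roi,
                       method = c("ratio_of_means", "mean_of_ratios"),
                       decline_max = 0.94, increase_min = 1.06) {
  method <- match.arg(method)
  pre <- roi_ventilation(pre_map, roi)
  post <- roi_ventilation(post_map, roi)
  ratio <- if (method == "ratio_of_means") {
    post$mean / pre$mean
  } else {
    ok <- roi$mask & is.finite(pre_map$data) & is.finite(post_map$data)
    mean(post_map$data[ok] / pre_map$data[ok])
  }
  cls <- classify_change(1, ratio, decline_max, increase_min)$class
  data.frame(contour = roi$label, mean_pre = pre$mean, mean_post = post$mean,
             ratio = ratio, change_class = as.character(cls))
}
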