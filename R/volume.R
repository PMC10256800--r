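#' Image volume on a regular grid
#'
#' The basic container of the package: a 3D scalar grid together with the
#' physical geometry needed to relate voxel indices to scanner coordinates.
#' CT volumes carry Hounsfield units (HU), dose grids carry Gy and
#' ventilation maps are dimensionless.  The array is indexed `[i, j, k]`
#' with the first index (x) fastest in memory; the physical position of
#' voxel `(i, j, k)` (1-based) is `origin + (c(i, j, k) - 1) * spacing`.
#' All inter-volume operations (resampling, warping, registration) work in
#' these physical coordinates, never in raw indices.
#'
#' @param data numeric 3D array of voxel values.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical position of voxel (1,1,1) in mm.
#' @param frame_label free-text label (breathing phase id, contrast frame
#'   index, ...).
#' @return An object of class `image_volume`.
#' @examples
#' v <- image_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 3))
#' dim(v$data)
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         frame_label = "") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3D array, got ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  if (any(dim(data) < 2L))
    stop("image_volume: grid must have at least 2 voxels per axis",
         call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: 'spacing' must be 3 positive finite values",
         call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("image_volume: 'origin' must be 3 finite values", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 frame_label = as.character(frame_label)[1]),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume %s: %s voxels, spacing [%s] mm, origin [%s] mm\n",
              if (nzchar(x$frame_label)) sQuote(x$frame_label) else "",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  rng <- range(x$data, finite = TRUE)
  cat(sprintf("  value range [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
is_image_volume <- function(x) inherits(x, "image_volume")

#' Test that two volumes live on the same grid
#'
#' Congruence means identical array dimensions, spacing and origin (to a
#' small absolute tolerance on the geometry), so that voxel `(i, j, k)`
#' refers to the same physical location in both.
#'
#' @param a,b `image_volume` objects.
#' @param tol absolute tolerance in mm for spacing/origin comparison.
#' @export
grids_congruent <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_incongruent <- function(a, b, what = "volumes") {
  if (!grids_congruent(a, b))
    stop("geometry error: ", what, " are not grid-congruent", call. = FALSE)
  invisible(TRUE)
}

#' Region-of-interest mask
#'
#' A boolean grid congruent with a reference volume, labelled with one of
#' the controlled contour names used throughout the analysis.
#'
#' @param mask logical 3D array (or coercible) with at least one `TRUE`.
#' @param reference `image_volume` the mask refers to (geometry is copied).
#' @param label contour label; one of
#'   `r paste(lungfx_contour_vocab(), collapse = ", ")` or a generic
#'   `parenchyma-bin` / `vessel-bin` name.
#' @param tissue `"vessel"` or `"parenchyma"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, reference, label = "parenchyma-bin",
                     tissue = c("parenchyma", "vessel")) {
  tissue <- match.arg(tissue)
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(mask), dim(reference$data)))
    stop("roi_mask: mask shape must equal reference shape", call. = FALSE)
  if (!any(mask))
    stop("empty-ROI error: mask has no TRUE voxel", call. = FALSE)
  if (!label %in% lungfx_contour_vocab())
    stop("roi_mask: unknown label ", sQuote(label), "; accepted: ",
         paste(lungfx_contour_vocab(), collapse = ", "), call. = FALSE)
  structure(list(mask = mask, spacing = reference$spacing,
                 origin = reference$origin, label = label, tissue = tissue),
            class = "roi_mask")
}

#' Controlled vocabulary of contour labels
#'
#' The nine per-subject analysis contours plus generic bin labels used by
#' the dose-binned perfusion measurements and lung/PTV bookkeeping.
#' @export
lungfx_contour_vocab <- function() {
  c("MD", "LDF", "LDNF", "NDF", "NDNF", "CON", "HHV", "HLV", "LLV",
    "parenchyma-bin", "vessel-bin", "lung", "lung-ipsi", "lung-contra",
    "PTV")
}

#' Dose grid
#'
#' An [image_volume()] in Gy plus the prescription dose.  Values must be
#' non-negative and are capped (for synthetic data) at 1.25 times the
#' prescription, a conventional hot-spot limit.
#'
#' @param volume `image_volume` of dose values in Gy.
#' @param prescription total prescribed dose in Gy (default 60, i.e. five
#'   fractions of 12 Gy).
#' @export
dose_grid <- function(volume, prescription = 60) {
  stopifnot(is_image_volume(volume))
  if (any(volume$data < 0))
    stop("dose_grid: dose values must be >= 0", call. = FALSE)
  if (max(volume$data) > 1.25 * prescription)
    stop("dose_grid: values exceed 1.25 x prescription hot-spot cap",
         call. = FALSE)
  volume$prescription <- prescription
  class(volume) <- c("dose_grid", class(volume))
  volume
}

#' Per-subject record of available contours
#'
#' Group A animals were analysed at the maximum-dose and contralateral
#' points only; group B animals carry the full nine-contour set (the four
#' indirect dose/fed contours and three ventilation-selected points in
#' addition).
#'
#' @param subject_id subject identifier, e.g. `"A"`.
#' @param group `"A"` or `"B"`.
#' @export
subject_record <- function(subject_id, group = c("B", "A")) {
  group <- match.arg(group)
  contours <- if (group == "A") c("MD", "CON") else
    c("MD", "LDF", "LDNF", "NDF", "NDNF", "CON", "HHV", "HLV", "LLV")
  structure(list(subject_id = subject_id, group = group, contours = contours),
            class = "subject_record")
}

# ---- physical <-> index coordinate helpers ---------------------------------

#' Convert physical coordinates (mm) to fractional 1-based voxel indices.
#' @param vol `image_volume` (or any object with `spacing` and `origin`).
#' @param xyz n x 3 matrix of physical points.
#' @keywords internal
phys_to_index <- function(vol, xyz) {
  sweep(sweep(xyz, 2, vol$origin, "-"), 2, vol$spacing, "/") + 1
}

#' @rdname phys_to_index
#' @keywords internal
index_to_phys <- function(vol, ijk) {
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Full grid of physical coordinates of a volume, as three arrays.
#' @keywords internal
grid_coords <- function(vol) {
  d <- dim(vol$data)
  list(x = vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1],
       y = vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
       z = vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3])
}

# ---- interpolation core ----------------------------------------------------

#' Sample a 3D array at fractional voxel indices
#'
#' Vectorised trilinear or nearest-neighbour sampling.  Points outside the
#' grid receive `fill`.  This single routine backs resampling, image
#' warping during synthesis and registration.
#'
#' @param data 3D numeric array.
#' @param ijk n x 3 matrix of fractional 1-based indices.
#' @param method `"linear"` or `"nearest"`.
#' @param fill value for out-of-domain points.
#' @return numeric vector of length n.
#' @keywords internal
sample_at_index <- function(data, ijk, method = c("linear", "nearest"),
                            fill = 0) {
  method <- match.arg(method)
  d <- dim(data)
  i <- ijk[, 1]; j <- ijk[, 2]; k <- ijk[, 3]
  if (method == "nearest") {
    ii <- round(i); jj <- round(j); kk <- round(k)
    inside <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    out <- rep(fill, length(i))
    idx <- cbind(ii[inside], jj[inside], kk[inside])
    out[inside] <- data[idx]
    return(out)
  }
  inside <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  out <- rep(fill, length(i))
  if (!any(inside)) return(out)
  i <- i[inside]; j <- j[inside]; k <- k[inside]
  i0 <- pmin(pmax(floor(i), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(j), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(k), 1), d[3] - 1)
  fx <- i - i0; fy <- j - j0; fz <- k - k0
  # linear index arithmetic avoids building eight n x 3 index matrices
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (i0) + (j0 - 1) * n1 + (k0 - 1) * n12  # index of (i0, j0, k0)
  v000 <- data[base];            v100 <- data[base + 1]
  v010 <- data[base + n1];       v110 <- data[base + n1 + 1]
  v001 <- data[base + n12];      v101 <- data[base + n12 + 1]
  v011 <- data[base + n1 + n12]; v111 <- data[base + n1 + n12 + 1]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[inside] <- c0 * (1 - fz) + c1 * fz
  out
}

#' Sample a volume at physical points
#' @param vol `image_volume`.
#' @param xyz n x 3 matrix of physical coordinates in mm.
#' @inheritParams sample_at_index
#' @keywords internal
sample_at_phys <- function(vol, xyz, method = "linear", fill = 0) {
  sample_at_index(vol$data, phys_to_index(vol, xyz), method, fill)
}
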