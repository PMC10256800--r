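#' Resample a volume onto the grid of a reference volume
#'
#' Values are interpolated in physical space, so the two volumes may differ
#' in shape, spacing and origin.  Voxels of the reference grid that fall
#' outside the moving volume's physical domain receive `fill` (-1000 HU,
#' i.e. air, is the conventional fill for CT).
#'
#' @param moving `image_volume` supplying the values.
#' @param reference `image_volume` supplying the output grid.
#' @param interpolation `"linear"` or `"nearest"` (use nearest for masks).
#' @param fill out-of-domain fill value; default -1000 for CT context,
#'   pass 0 for dose or ventilation maps.
#' @return `image_volume` congruent with `reference`.
#' @export
resample_like <- function(moving, reference,
                          interpolation = c("linear", "nearest"),
                          fill = -1000) {
  interpolation <- match.arg(interpolation)
  for (v in list(moving, reference))
    if (any(!is.finite(v$spacing)) || any(v$spacing <= 0))
      stop("metadata error: degenerate spacing", call. = FALSE)
  g <- grid_coords(reference)
  d <- dim(reference$data)
  xyz <- cbind(rep(g$x, times = d[2] * d[3]),
               rep(rep(g$y, each = d[1]), times = d[3]),
               rep(g$z, each = d[1] * d[2]))
  vals <- sample_at_phys(moving, xyz, method = interpolation, fill = fill)
  image_volume(array(vals, d), spacing = reference$spacing,
               origin = reference$origin, frame_label = moving$frame_label)
}

#' Displacement field on the exhale grid
#'
#' A vector field `u` (in mm, physical units) defined on the end-exhale
#' grid that maps exhale-frame coordinates `x` to the corresponding
#' phase-frame coordinates `x + u(x)`: sampling the phase volume at
#' `x + u(x)` reproduces the exhale volume.
#'
#' @param ux,uy,uz 3D arrays of the displacement components in mm.
#' @param reference `image_volume` defining the grid (the exhale phase).
#' @param phase_label label of the phase this field registers.
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(ux, uy, uz, reference, phase_label = "") {
  d <- dim(reference$data)
  for (u in list(ux, uy, uz)) {
    if (!identical(dim(u), d))
      stop("geometry error: displacement component not grid-congruent",
           call. = FALSE)
    if (any(!is.finite(u)))
      stop("displacement_field: non-finite components", call. = FALSE)
  }
  structure(list(ux = ux, uy = uy, uz = uz,
                 spacing = reference$spacing, origin = reference$origin,
                 phase_label = as.character(phase_label)[1]),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$ux^2 + x$uy^2 + x$uz^2)
  cat(sprintf("displacement_field %s: %s, |u| mean %.3f mm, max %.3f mm\n",
              sQuote(x$phase_label), paste(dim(x$ux), collapse = " x "),
              mean(mag), max(mag)))
  invisible(x)
}

#' Warp a volume by a displacement field
#'
#' Returns `warped(x) = vol(x + u(x))` on the field's grid; with `vol` a
#' phase volume and `u` its registration to exhale, the result is the
#' phase pulled back onto the exhale frame.
#'
#' @param vol `image_volume` to sample (the moving image).
#' @param field `displacement_field`.
#' @param fill out-of-domain fill value.
#' @export
warp_volume <- function(vol, field, fill = -1000) {
  ref <- image_volume(field$ux, field$spacing, field$origin)
  g <- grid_coords(ref)
  d <- dim(ref$data)
  xyz <- cbind(rep(g$x, times = d[2] * d[3]) + as.vector(field$ux),
               rep(rep(g$y, each = d[1]), times = d[3]) + as.vector(field$uy),
               rep(g$z, each = d[1] * d[2]) + as.vector(field$uz))
  vals <- sample_at_phys(vol, xyz, method = "linear", fill = fill)
  image_volume(array(vals, d), field$spacing, field$origin,
               frame_label = vol$frame_label)
}
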