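# Deformable registration of breathing phases to end exhale.
#
# The registration backend is a multi-resolution intensity-based demons
# scheme: at each iteration the residual between the warped phase and the
# exhale image drives a force along the image gradient, the force is
# smoothed (fluid regularisation) before being added to the field, and the
# accumulated field is smoothed again (diffusion regularisation).  The
# backend is pluggable: precomputed fields can be passed straight through
# (bypass mode), which is how ground-truth fields from the synthetic
# generator enter the pipeline for oracle testing.

# ---- small array utilities -------------------------------------------------

# shift a 3D array by t voxels along an axis, replicating edges
shift_array <- function(a, t, axis) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + t, 1L), d[axis])
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# separable Gaussian smoothing, sigma in voxels (scalar or per-axis)
gaussian_smooth <- function(a, sigma) {
  sigma <- rep(sigma, length.out = 3)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (t in -r:r) acc <- acc + w[t + r + 1] * shift_array(a, t, ax)
    a <- acc
  }
  a
}

# central-difference gradient in physical units (one-sided at boundaries)
gradient_phys <- function(a, spacing) {
  d <- dim(a)
  g <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] < 3L)
      stop("gradient error: axis ", ax, " has fewer than 3 voxels",
           call. = FALSE)
    fwd <- shift_array(a, 1L, ax)
    bwd <- shift_array(a, -1L, ax)
    den <- array(2 * spacing[ax], d)
    # replicate-edge shifts turn the boundary differences into one-sided
    # differences over a single spacing
    edge <- switch(ax,
                   slice.index(a, 1) %in% c(1L, d[1]),
                   slice.index(a, 2) %in% c(1L, d[2]),
                   slice.index(a, 3) %in% c(1L, d[3]))
    den[edge] <- spacing[ax]
    g[[ax]] <- (fwd - bwd) / den
  }
  names(g) <- c("x", "y", "z")
  g
}

# downsample a volume by an integer factor per axis (with pre-smoothing)
downsample_volume <- function(vol, factor = 2L) {
  sm <- vol
  sm$data <- gaussian_smooth(vol$data, sigma = factor / 2)
  d <- dim(vol$data)
  nd <- pmax(ceiling(d / factor), 2L)
  ref <- image_volume(array(0, nd), spacing = vol$spacing * factor,
                      origin = vol$origin)
  resample_like(sm, ref, "linear", fill = sm$data[1])
}

# ---- 4D phase series -------------------------------------------------------

#' Multi-phase breathing series
#'
#' An ordered set of grid-congruent CT phase volumes spanning one breathing
#' cycle, with the index of the end-exhale phase and the ventilation
#' settings under which the cycle was acquired (mechanically ventilated
#' subjects: 1 L tidal volume at 15 breaths per minute by default).
#'
#' @param phases list of [image_volume()], one per breathing phase.
#' @param exhale_index index (1-based) of the end-exhale phase.
#' @param tidal_volume tidal volume in litres.
#' @param respiratory_rate breaths per minute.
#' @export
phase_series <- function(phases, exhale_index, tidal_volume = 1.0,
                         respiratory_rate = 15) {
  if (length(phases) < 2L)
    stop("phase_series: need at least 2 phases", call. = FALSE)
  if (exhale_index < 1L || exhale_index > length(phases))
    stop("phase_series: exhale_index out of range", call. = FALSE)
  for (p in phases) stop_if_incongruent(p, phases[[1]], "phases")
  if (tidal_volume <= 0)
    stop("phase_series: tidal_volume must be > 0", call. = FALSE)
  structure(list(phases = phases, exhale_index = as.integer(exhale_index),
                 tidal_volume = tidal_volume,
                 respiratory_rate = respiratory_rate),
            class = "phase_series")
}

#' Register all breathing phases to the end-exhale phase
#'
#' Estimates, for every non-exhale phase, the displacement field on the
#' exhale grid that maps exhale coordinates to the corresponding phase
#' coordinates (so warping the phase volume by the field reproduces the
#' exhale volume).  When `fields` is supplied the registration step is
#' bypassed and the given fields are returned unchanged; this is the
#' oracle-testing path for fields with known analytic Jacobians.
#'
#' @param series a [phase_series()].
#' @param config registration settings; see [registration_config()].
#' @param fields optional list of precomputed [displacement_field()]s
#'   (one per non-exhale phase, in phase order) for bypass mode.
#' @return list of `displacement_field`, one per non-exhale phase, each
#'   carrying a `residual` attribute (mean absolute intensity residual
#'   after warping) and a `converged` flag.
#' @export
register_to_exhale <- function(series, config = registration_config(),
                               fields = NULL) {
  stopifnot(inherits(series, "phase_series"))
  if (!is.null(fields)) {
    for (f in fields)
      if (!identical(dim(f$ux), dim(series$phases[[series$exhale_index]]$data)))
        stop("geometry error: bypass field not congruent with exhale grid",
             call. = FALSE)
    return(fields)
  }
  fixed <- series$phases[[series$exhale_index]]
  out <- list()
  init <- NULL
  for (k in seq_along(series$phases)) {
    if (k == series$exhale_index) next
    moving <- series$phases[[k]]
    stop_if_incongruent(moving, fixed, "phases")
    # phase chaining: adjacent phases differ little, so the previous
    # phase's field is a strong initialisation for the next one
    f <- demons_register(fixed, moving, config,
                         init = if (isTRUE(config$chain)) init else NULL)
    f$phase_label <- series$phases[[k]]$frame_label
    init <- f
    out[[length(out) + 1L]] <- f
  }
  out
}

#' Registration settings
#'
#' @param levels number of multi-resolution pyramid levels.
#' @param iterations iterations per level, coarse to fine.
#' @param sigma_fluid Gaussian sigma (voxels) applied to each force update.
#' @param sigma_diffusion Gaussian sigma (voxels) applied to the
#'   accumulated field.
#' @param step_mm maximum displacement update per iteration in mm.
#' @param compositive compose each update with the current field instead
#'   of adding it; markedly better for large expansions.
#' @param presmooth Gaussian sigma (voxels) applied to the fixed image at
#'   each level (half of it to the moving image) so both images carry
#'   comparable smoothness; resampling low-passes the moving image during
#'   warping, and a sharp fixed image against a softened moving one
#'   biases the recovered expansion.
#' @param tol_residual mean absolute residual (HU) below which the solver
#'   reports convergence.
#' @details Phase chaining (`chain = TRUE` in the returned list) makes
#'   [register_to_exhale()] initialise each phase's registration from the
#'   previous phase's field, exploiting the temporal continuity of a
#'   breathing cycle.
#' @export
registration_config <- function(levels = 3L, iterations = c(100L, 80L, 80L),
                                sigma_fluid = 1.2, sigma_diffusion = 0.5,
                                step_mm = 3.0, compositive = TRUE,
                                presmooth = 0, refine_iterations = 30L,
                                refine_diffusion = 0.25,
                                tol_residual = 15) {
  list(levels = levels,
       iterations = rep(iterations, length.out = levels),
       sigma_fluid = sigma_fluid, sigma_diffusion = sigma_diffusion,
       step_mm = step_mm, compositive = compositive, chain = TRUE,
       presmooth = presmooth, refine_iterations = refine_iterations,
       refine_diffusion = refine_diffusion, tol_residual = tol_residual)
}

demons_register <- function(fixed, moving, config, init = NULL) {
  # build pyramids, coarse first
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(config$levels - 1L)) {
    pyr_f <- c(list(downsample_volume(pyr_f[[1]])), pyr_f)
    pyr_m <- c(list(downsample_volume(pyr_m[[1]])), pyr_m)
  }
  u <- NULL
  if (!is.null(init)) {
    coarse <- pyr_f[[1]]
    u <- lapply(list(init$ux, init$uy, init$uz), function(comp) {
      cv <- image_volume(comp, init$spacing, init$origin)
      resample_like(cv, coarse, "linear", fill = 0)$data
    })
    names(u) <- c("x", "y", "z")
  }
  resid <- NA_real_
  for (l in seq_len(config$levels)) {
    f <- pyr_f[[l]]; m <- pyr_m[[l]]
    if (config$presmooth > 0) {
      f$data <- gaussian_smooth(f$data, config$presmooth)
      m$data <- gaussian_smooth(m$data, config$presmooth)
    }
    d <- dim(f$data)
    if (is.null(u)) {
      u <- list(x = array(0, d), y = array(0, d), z = array(0, d))
    } else if (l > 1L) {
      # upsample previous-level field (mm units carry over directly)
      u <- lapply(u, function(comp) {
        cv <- image_volume(comp, pyr_f[[l - 1L]]$spacing,
                           pyr_f[[l - 1L]]$origin)
        resample_like(cv, f, "linear", fill = 0)$data
      })
    }
    g <- grid_coords(f)
    xs <- rep(g$x, times = d[2] * d[3])
    ys <- rep(rep(g$y, each = d[1]), times = d[3])
    zs <- rep(g$z, each = d[1] * d[2])
    n_main <- config$iterations[l]
    n_ref <- if (l == config$levels) config$refine_iterations else 0L
    for (it in seq_len(n_main + n_ref)) {
      # final refinement: a short, lightly regularised stage that lets
      # sharp expansion ramps form (voxel noise is handled downstream by
      # Jacobian-map smoothing)
      sig_d <- if (it > n_main) config$refine_diffusion else
        config$sigma_diffusion
      xyz <- cbind(xs + as.vector(u$x), ys + as.vector(u$y),
                   zs + as.vector(u$z))
      w <- array(sample_at_phys(m, xyz, fill = m$data[1]), d)
      diffim <- w - f$data
      resid <- mean(abs(diffim))
      gr <- gradient_phys(w, f$spacing)
      gf <- gradient_phys(f$data, f$spacing)
      gx <- 0.5 * (gr$x + gf$x); gy <- 0.5 * (gr$y + gf$y)
      gz <- 0.5 * (gr$z + gf$z)
      g2 <- gx^2 + gy^2 + gz^2
      # Thirion normalisation: bounds the update magnitude by step_mm
      den <- g2 + (diffim / config$step_mm)^2
      den[den < 1e-12] <- Inf
      s <- -diffim / den
      vx <- gaussian_smooth(s * gx, config$sigma_fluid)
      vy <- gaussian_smooth(s * gy, config$sigma_fluid)
      vz <- gaussian_smooth(s * gz, config$sigma_fluid)
      if (isTRUE(config$compositive)) {
        # compose: u(x) <- v(x) + u(x + v(x)); handles large expansions
        pxyz <- cbind(xs + as.vector(vx), ys + as.vector(vy),
                      zs + as.vector(vz))
        ii <- phys_to_index(f, pxyz)
        ux <- vx + array(sample_at_index(u$x, ii, fill = 0), d)
        uy <- vy + array(sample_at_index(u$y, ii, fill = 0), d)
        uz <- vz + array(sample_at_index(u$z, ii, fill = 0), d)
      } else {
        ux <- u$x + vx; uy <- u$y + vy; uz <- u$z + vz
      }
      u$x <- gaussian_smooth(ux, sig_d)
      u$y <- gaussian_smooth(uy, sig_d)
      u$z <- gaussian_smooth(uz, sig_d)
    }
  }
  fld <- displacement_field(u$x, u$y, u$z, fixed)
  attr(fld, "residual") <- resid
  converged <- resid <= config$tol_residual
  if (!converged)
    lfx_log("register", sprintf(
      "non-convergence: mean |residual| %.2f HU exceeds tolerance %.2f",
      resid, config$tol_residual))
  attr(fld, "converged") <- converged
  fld
}
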