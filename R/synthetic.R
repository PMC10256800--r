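# Synthetic study generator.
#
# Everything the pipeline consumes can be generated here with seeded
# reproducibility: a thoracic phantom (two ellipsoidal lungs, an embedded
# bifurcating vessel tree, textured parenchyma), breathing-phase series
# whose displacement fields carry closed-form Jacobians, gamma-variate
# contrast kinetics per vessel, a Gaussian SBRT-like dose distribution
# with a contralateral sparing constraint, and ordinal pathology outcomes
# statistically coupled to dose, vessel topology and ventilation change.

#' Phantom specification
#'
#' @param shape grid dimensions (voxels per axis).
#' @param spacing voxel size in mm.
#' @param lung_semi semi-axes (mm) of each lung ellipsoid.
#' @param lung_center_x unsigned lateral lung-centre offset in mm; the
#'   ipsilateral (treated) lung sits at -x, the contralateral at +x.
#' @param vessel_depth branching generations below the subtree roots.
#' @param texture_sd,texture_sigma amplitude (HU) and smoothing (voxels)
#'   of the parenchymal intensity texture (vascular mottle stand-in; it
#'   also gives intensity-driven registration something to lock onto).
#' @param seed integer seed fixing all randomness of the phantom.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(3, 3, 3),
                         lung_semi = c(32, 38, 55), lung_center_x = 40,
                         vessel_depth = 3L, texture_sd = 60,
                         texture_sigma = 1.2, seed = 1L) {
  list(shape = as.integer(shape), spacing = as.numeric(spacing),
       lung_semi = as.numeric(lung_semi), lung_center_x = lung_center_x,
       vessel_depth = as.integer(vessel_depth), texture_sd = texture_sd,
       texture_sigma = texture_sigma, seed = as.integer(seed))
}

# rasterize the vessel tree as capsules on the grid of `ref`; returns an
# integer array mapping vessel voxels to their nearest node's row index
rasterize_tree <- function(nodes, pidx, ref) {
  sh <- dim(ref$data); sp <- ref$spacing; origin <- ref$origin
  g <- grid_coords(ref)
  lab <- array(0L, sh)
  for (i in seq_len(nrow(nodes))) {
    if (is.na(pidx[i])) next
    p0 <- as.numeric(nodes[pidx[i], c("x", "y", "z")])
    p1 <- as.numeric(nodes[i, c("x", "y", "z")])
    r <- nodes$radius[i]
    lo <- pmin(p0, p1) - r - sp; hi <- pmax(p0, p1) + r + sp
    i0 <- pmax(ceiling((lo - origin) / sp) + 1, 1)
    i1 <- pmin(floor((hi - origin) / sp) + 1, sh)
    if (any(i0 > i1)) next
    xs <- g$x[i0[1]:i1[1]]; ys <- g$y[i0[2]:i1[2]]; zs <- g$z[i0[3]:i1[3]]
    nx <- length(xs); ny <- length(ys); nz <- length(zs)
    px <- rep(xs, times = ny * nz)
    py <- rep(rep(ys, each = nx), times = nz)
    pz <- rep(zs, each = nx * ny)
    v <- p1 - p0; vv <- sum(v^2)
    t <- ((px - p0[1]) * v[1] + (py - p0[2]) * v[2] +
            (pz - p0[3]) * v[3]) / max(vv, 1e-9)
    t <- pmin(pmax(t, 0), 1)
    d2 <- (px - (p0[1] + t * v[1]))^2 + (py - (p0[2] + t * v[2]))^2 +
      (pz - (p0[3] + t * v[3]))^2
    hit <- d2 <= r^2
    if (!any(hit)) next
    sub <- lab[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]]
    # voxels in the distal half of the segment belong to the child node
    sub[hit & t >= 0.5] <- i
    sub[hit & t < 0.5 & sub == 0L] <- pidx[i]
    lab[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
  }
  lab
}

ellipsoid_mask <- function(g, center, semi) {
  dx2 <- ((g$x - center[1]) / semi[1])^2
  dy2 <- ((g$y - center[2]) / semi[2])^2
  dz2 <- ((g$z - center[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# place a point at exact distance D from `anchor` in direction `dir`
# (+ jitter), pulled inside the lung ellipsoid if necessary
place_radial <- function(anchor, dir, D, lung_center, lung_semi,
                         jitter = 4) {
  for (try in 1:25) {
    d <- dir / sqrt(sum(dir^2)) +
      stats::rnorm(3, 0, jitter / max(try, 1)) / D
    d <- d / sqrt(sum(d^2))
    p <- anchor + D * d
    if (sum(((p - lung_center) / (0.92 * lung_semi))^2) <= 1) return(p)
  }
  # fall back: shrink toward the lung centre until inside
  p <- anchor + D * dir / sqrt(sum(dir^2))
  for (s in seq(1, 0.3, by = -0.05)) {
    q <- lung_center + s * (p - lung_center)
    if (sum(((q - lung_center) / (0.92 * lung_semi))^2) <= 1) return(q)
  }
  lung_center
}

#' Generate the thoracic lung phantom
#'
#' Builds the HU volume (air -1000, parenchyma about -750 with smooth
#' texture, vessels about 50, soft tissue 0), the two disjoint lung
#' masks, the embedded vessel tree (with a per-voxel map from vessel
#' voxels to their nearest tree node) and a thin airway rasterization
#' paralleling the proximal tree.
#'
#' The tree is laid out so that the fed subtree below the designated
#' maximum-dose node spans prescribed radial distances from it: one
#' generation inside the high-dose fall-off, one in the 5-20 Gy shell and
#' one below 5 Gy (for the default dose model), and the not-fed branches
#' sample the same shells on the other side; this guarantees that the
#' five vessel contour classes exist on every phantom.
#'
#' @param spec a [phantom_spec()].
#' @return list with `ct` ([image_volume()]), `scene` (the same anatomy
#'   at twice the resolution; breathing phases are sampled from it so all
#'   frames share one interpolation footprint), `lung_ipsi`,
#'   `lung_contra`, `lung_both` (`roi_mask`), `tree` ([vessel_tree()]),
#'   `md_node` (id of the designated maximum-dose vessel), `vessel_label`
#'   (integer array; 0 outside vessels, otherwise the row index of the
#'   nearest tree node), `airway` (logical array), and `spec`.
#' @export
make_lung_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  sh <- spec$shape; sp <- spec$spacing
  origin <- -(sh - 1) * sp / 2
  ref <- image_volume(array(0, sh), spacing = sp, origin = origin)
  g <- grid_coords(ref)
  lc_i <- c(-spec$lung_center_x, 0, 5)   # ipsilateral (treated) lung
  lc_c <- c(spec$lung_center_x, 0, 5)
  if (2 * spec$lung_center_x < 2 * spec$lung_semi[1])
    stop("spec error: lungs overlap under this specification",
         call. = FALSE)
  body <- ellipsoid_mask(g, c(0, 0, 0), c(88, 80, 72))
  lung_i <- ellipsoid_mask(g, lc_i, spec$lung_semi) & body
  lung_c <- ellipsoid_mask(g, lc_c, spec$lung_semi) & body

  # ---- vessel tree ----------------------------------------------------
  nodes <- list()
  addn <- function(id, pos, radius, parent) {
    nodes[[length(nodes) + 1L]] <<- data.frame(
      id = id, x = pos[1], y = pos[2], z = pos[3], radius = radius,
      parent = parent, stringsAsFactors = FALSE)
  }
  addn("root", c(0, 0, 38), 7, NA_character_)
  addn("M-ipsi", c(-20, 0, 26), 6, "root")
  addn("M-contra", c(20, 0, 26), 6, "root")
  target <- lc_i + c(0, 0, 20)
  addn("MD", target, 5, "M-ipsi")
  # fed subtree: generations at ~17 / 31 / 44 mm from the max-dose node
  Dg <- c(17, 31, 44, 56)[seq_len(spec$vessel_depth)]
  rg <- 5 * 0.8^seq_len(spec$vessel_depth)
  grow <- function(parent_id, parent_pos, anchor, gen, prefix) {
    if (gen > spec$vessel_depth) return(invisible())
    base_dir <- parent_pos - anchor
    if (sum(base_dir^2) < 1e-6) base_dir <- c(-0.3, 0.3, -0.9)
    for (b in 1:2) {
      swing <- if (b == 1) c(0.45, 0.35, -0.3) else c(-0.2, -0.5, -0.45)
      dir <- base_dir / sqrt(sum(base_dir^2)) + swing
      pos <- place_radial(anchor, dir, Dg[gen], lc_i, spec$lung_semi)
      id <- paste0(prefix, gen, letters[b], length(nodes))
      addn(id, pos, rg[gen], parent_id)
      grow(id, pos, anchor, gen + 1L, prefix)
    }
  }
  grow("MD", target, target, 1L, "F")
  # not-fed lateral branch: sits in the 5-20 Gy shell of the default dose
  mid_pos <- place_radial(target, c(0.1, 0.8, -0.55), 33, lc_i,
                          spec$lung_semi)
  addn("N-mid", mid_pos, 4.5, "M-ipsi")
  grow_nf <- function(parent_id, parent_pos, gen, prefix) {
    if (gen > spec$vessel_depth) return(invisible())
    for (b in 1:2) {
      dirb <- (parent_pos - target) + c(stats::rnorm(2, 0, 3),
                                        -abs(stats::rnorm(1, 4, 2)))
      pos <- place_radial(target, dirb, 44 + 12 * (gen - 1), lc_i,
                          spec$lung_semi)
      id <- paste0(prefix, gen, letters[b], length(nodes))
      addn(id, pos, 4.5 * 0.8^gen, parent_id)
      grow_nf(id, pos, gen + 1L, prefix)
    }
  }
  grow_nf("N-mid", mid_pos, 1L, "N")
  inf_pos <- lc_i + c(0, -6, -30)
  addn("I-inf", inf_pos, 4.5, "M-ipsi")
  grow_nf("I-inf", inf_pos, 1L, "I")
  # contralateral: mirror of the MD node plus a small subtree
  addn("C-MD", c(-target[1], target[2], target[3]), 5, "M-contra")
  addn("C-inf", c(-inf_pos[1], inf_pos[2], inf_pos[3]), 4.5, "M-contra")
  for (b in 1:2) {
    pos <- place_radial(c(-target[1], target[2], target[3]),
                        c(0.4 * (-1)^b, 0.5, -0.7), 25, lc_c,
                        spec$lung_semi)
    addn(paste0("C", b), pos, 4, "C-MD")
  }
  nodes <- do.call(rbind, nodes)
  tree <- vessel_tree(nodes)

  # ---- rasterization --------------------------------------------------
  pidx <- tree_parent_index(tree)
  vessel_label <- rasterize_tree(nodes, pidx,
                                 image_volume(array(0, sh), sp, origin))
  airway <- array(FALSE, sh)  # thin proximal airway: offset copy of trunk
  for (i in which(nodes$id %in% c("root", "M-ipsi", "M-contra", "MD",
                                  "C-MD", "N-mid", "I-inf"))) {
    if (is.na(pidx[i])) next
    p0 <- as.numeric(nodes[pidx[i], c("x", "y", "z")]) + c(0, 8, 0)
    p1 <- as.numeric(nodes[i, c("x", "y", "z")]) + c(0, 8, 0)
    n <- ceiling(sqrt(sum((p1 - p0)^2)) / min(sp)) + 1
    for (t in seq(0, 1, length.out = n)) {
      q <- round((p0 + t * (p1 - p0) - origin) / sp) + 1
      if (all(q >= 1) && all(q <= sh)) airway[q[1], q[2], q[3]] <- TRUE
    }
  }

  lung_both <- lung_i | lung_c

  # ---- high-resolution HU scene ---------------------------------------
  # The HU scene is built once at twice the grid resolution; the exhale
  # frame and every warped breathing phase are then sampled from this one
  # scene, so all frames carry the same interpolation footprint and none
  # is artificially sharper than another.
  hs <- 2L * sh
  hsp <- sp / 2
  horigin <- origin   # aligned: analysis voxels coincide with scene voxels
  href <- image_volume(array(0, hs), spacing = hsp, origin = horigin)
  hg <- grid_coords(href)
  hbody <- ellipsoid_mask(hg, c(0, 0, 0), c(88, 80, 72))
  hlung <- (ellipsoid_mask(hg, lc_i, spec$lung_semi) |
              ellipsoid_mask(hg, lc_c, spec$lung_semi)) & hbody
  hu <- array(-1000, hs)
  # mild soft-tissue texture (muscle/fat heterogeneity) so the chest wall
  # and mediastinum carry trackable structure as well
  btex <- gaussian_smooth(array(stats::rnorm(prod(hs)), hs),
                          4 * spec$texture_sigma)
  hu[hbody] <- (btex / stats::sd(btex) * 0.5 * spec$texture_sd)[hbody]
  # two-scale mottle: fine vascular speckle plus coarse density variation
  # (the coarse component keeps the registration pyramid informative)
  tex_f <- gaussian_smooth(array(stats::rnorm(prod(hs)), hs),
                           2 * spec$texture_sigma)
  tex_c <- gaussian_smooth(array(stats::rnorm(prod(hs)), hs),
                           6 * spec$texture_sigma)
  texture <- tex_f / stats::sd(tex_f) * spec$texture_sd +
    tex_c / stats::sd(tex_c) * 0.6 * spec$texture_sd
  hu[hlung] <- -750 + texture[hlung]
  hvessel <- rasterize_tree(nodes, pidx, href)
  hu[hvessel > 0L & hlung] <- 50
  aidx <- which(airway & lung_both, arr.ind = TRUE)
  if (nrow(aidx)) {
    for (off in list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                     c(1, 1, 0), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))) {
      hidx <- sweep(2L * (aidx - 1L) + 1L, 2, as.integer(off), "+")
      hu[hidx] <- -950
    }
  }
  scene <- image_volume(hu, spacing = hsp, origin = horigin,
                        frame_label = "scene")
  ct <- resample_like(scene, image_volume(array(0, sh), sp, origin),
                      "linear", fill = -1000)
  ct$frame_label <- "phantom"
  list(ct = ct, scene = scene,
       lung_ipsi = roi_mask(lung_i, ct, label = "lung-ipsi"),
       lung_contra = roi_mask(lung_c, ct, label = "lung-contra"),
       lung_both = roi_mask(lung_both, ct, label = "lung"),
       tree = tree, md_node = "MD", vessel_label = vessel_label,
       airway = airway, spec = spec)
}

#' ROI over the rasterized voxels of one vessel node
#' @param phantom output of [make_lung_phantom()].
#' @param node_id tree node id.
#' @param label contour label for the ROI.
#' @export
vessel_node_roi <- function(phantom, node_id, label = "vessel-bin") {
  i <- match(node_id, phantom$tree$nodes$id)
  if (is.na(i))
    stop("lookup error: unknown node id ", sQuote(node_id), call. = FALSE)
  m <- phantom$vessel_label == i
  if (!any(m)) {
    # proximal nodes can be fully claimed by children; fall back to a
    # small sphere at the node position
    pos <- as.numeric(phantom$tree$nodes[i, c("x", "y", "z")])
    return(sphere_roi(phantom$ct, pos, max(phantom$tree$nodes$radius[i],
                                           1.5 * max(phantom$ct$spacing)),
                      label = label, tissue = "vessel"))
  }
  roi_mask(m, phantom$ct, label = label, tissue = "vessel")
}

#' Synthetic SBRT-like dose distribution
#'
#' Isotropic Gaussian fall-off centred on the target vessel node with the
#' prescription dose at its peak.  The contralateral lung is constrained
#' to a maximum below 5 Gy by down-scaling any spill inside it, mirroring
#' the planning constraint of keeping the contralateral maximum dose
#' point under 5 Gy.
#'
#' @param phantom output of [make_lung_phantom()].
#' @param target_node vessel node id at the dose centre (default the
#'   phantom's designated maximum-dose node).
#' @param prescription peak dose in Gy (default 60; five 12-Gy fractions).
#' @param sigma_mm Gaussian fall-off sigma in mm.
#' @return a [dose_grid()]; the phantom tree with per-node doses is
#'   attached as attribute `tree`.
#' @export
make_dose <- function(phantom, target_node = phantom$md_node,
                      prescription = 60, sigma_mm = 18) {
  i <- match(target_node, phantom$tree$nodes$id)
  if (is.na(i))
    stop("lookup error: unknown target node ", sQuote(target_node),
         call. = FALSE)
  centre <- as.numeric(phantom$tree$nodes[i, c("x", "y", "z")])
  g <- grid_coords(phantom$ct)
  d2 <- outer(outer((g$x - centre[1])^2, (g$y - centre[2])^2, "+"),
              (g$z - centre[3])^2, "+")
  dose <- prescription * exp(-d2 / (2 * sigma_mm^2))
  contra <- phantom$lung_contra$mask
  mx <- max(dose[contra])
  if (mx >= prescription / 2)
    stop("spec error: sigma_mm so large that the fall-off floods the ",
         "contralateral lung; sparing by masking would be meaningless",
         call. = FALSE)
  if (mx >= 5) {
    f <- 4.5 / mx
    dose[contra] <- dose[contra] * f
    lfx_log("dose", sprintf(
      "contralateral spill scaled by %.3f to keep max below 5 Gy", f))
  }
  dg <- dose_grid(image_volume(dose, phantom$ct$spacing, phantom$ct$origin,
                               frame_label = "dose"), prescription)
  tree <- phantom$tree
  pts <- as.matrix(tree$nodes[, c("x", "y", "z")])
  tree$nodes$dose <- sample_at_phys(dg, pts, method = "linear", fill = 0)
  attr(dg, "tree") <- tree
  dg
}

#' Regional expansion model for the breathing series
#'
#' Builds the pre- and post-treatment target LER-N fields.  The lung
#' background expands moderately; three parenchymal regions are planted
#' for the ventilation-selected points (consistently high 1.28-1.45,
#' consistently low 1.03-1.09, and high 1.21-1.26 declining to
#' 1.04-1.09), the maximum-dose region declines by 10-16\%, and regions
#' around fed vessels decline by a milder subject-dependent factor.
#' Region values are drawn per subject from those ranges under the model
#' seed.
#'
#' @param phantom output of [make_lung_phantom()].
#' @param dose output of [make_dose()] (for fed-subtree identification).
#' @param seed integer seed.
#' @param region_radius radius (mm) of the planted parenchymal regions.
#' @return list with `pre` and `post` target [image_volume()]s, and
#'   `regions` (data frame of centre/radius/values per planted region).
#' @export
make_expansion_model <- function(phantom, dose, seed = 1L,
                                 region_radius = 13) {
  set.seed(seed + 7L)
  sp <- phantom$ct$spacing
  lc <- c(-phantom$spec$lung_center_x, 0, 5)
  tree <- attr(dose, "tree")
  ti <- match(phantom$md_node, tree$nodes$id)
  md_pos <- as.numeric(tree$nodes[ti, c("x", "y", "z")])
  # place the three parenchymal regions so that (a) they stay inside the
  # lung, clear of each other and of the maximum-dose region, and (b) at
  # least one vessel node of each dose/fed class keeps enough clearance
  # for its contour not to overlap a planted region
  fed_ids <- tree_descendants(tree, phantom$md_node)
  ipsi_ids <- setdiff(tree$nodes$id[tree$nodes$x < -5], "M-ipsi")
  node_pos <- as.matrix(tree$nodes[, c("x", "y", "z")])
  rownames(node_pos) <- tree$nodes$id
  nd <- stats::setNames(tree$nodes$dose, tree$nodes$id)
  classes <- list(
    LDF = intersect(fed_ids, names(nd)[nd >= 5 & nd <= 20]),
    NDF = intersect(fed_ids, names(nd)[nd < 5]),
    LDNF = setdiff(intersect(ipsi_ids, names(nd)[nd >= 5 & nd <= 20]),
                   c(fed_ids, phantom$md_node)),
    NDNF = setdiff(intersect(ipsi_ids, names(nd)[nd < 5]),
                   c(fed_ids, phantom$md_node)))
  base_centres <- list(HHV = lc + c(12, -20, -5),
                       LLV = lc + c(5, 24, -30),
                       HLV = lc + c(-8, -14, -30))
  clearance <- region_radius + 8
  centres <- NULL
  for (try in 1:200) {
    cand <- lapply(base_centres, function(p)
      p + stats::rnorm(3, 0, 1 + try / 12))
    cm <- do.call(rbind, cand)
    ok <- all(stats::dist(cm) > 2 * region_radius + 1) &&
      all(sqrt(colSums((t(cm) - md_pos)^2)) > 14 + region_radius + 1) &&
      all(apply(cm, 1, function(p)
        sum(((p - lc) / (0.88 * phantom$spec$lung_semi))^2) <= 1))
    if (ok)
      ok <- all(vapply(classes, function(ids) {
        if (!length(ids)) return(FALSE)
        any(vapply(ids, function(id) {
          all(sqrt(colSums((t(cm) - node_pos[id, ])^2)) > clearance)
        }, logical(1)))
      }, logical(1)))
    if (ok) { centres <- cand; break }
  }
  if (is.null(centres))
    stop("spec error: could not place ventilation regions clear of the ",
         "vessel contour candidates", call. = FALSE)
  vals <- list(HHV = c(pre = stats::runif(1, 1.28, 1.45)),
               LLV = c(pre = stats::runif(1, 1.03, 1.09)),
               HLV = c(pre = stats::runif(1, 1.21, 1.26),
                       post = stats::runif(1, 1.04, 1.09)))
  base <- array(1, dim(phantom$ct$data))
  lungm <- phantom$lung_both$mask
  base[lungm] <- 1.15
  pre <- base; post <- base
  paint <- function(field, centre, radius, value) {
    rr <- sphere_roi(phantom$ct, centre, radius)$mask
    field[rr & lungm] <- value
    field
  }
  # fed-vessel regions decline mildly, subject-dependent
  fed <- tree_descendants(tree, phantom$md_node)
  fed_ratio <- stats::runif(1, 0.93, 0.99)
  for (id in fed) {
    i <- match(id, tree$nodes$id)
    pos <- as.numeric(tree$nodes[i, c("x", "y", "z")])
    pre <- paint(pre, pos, 10, 1.16)
    post <- paint(post, pos, 10, 1.16 * fed_ratio)
  }
  md_ratio <- stats::runif(1, 0.84, 0.90)
  pre <- paint(pre, md_pos, 14, 1.18)
  post <- paint(post, md_pos, 14, 1.18 * md_ratio)
  for (nm in names(centres)) {
    pre <- paint(pre, centres[[nm]], region_radius, vals[[nm]]["pre"])
    pv <- if (nm == "HLV") vals[[nm]]["post"] else vals[[nm]]["pre"]
    post <- paint(post, centres[[nm]], region_radius, pv)
  }
  pre <- gaussian_smooth(pre, 0.75); post <- gaussian_smooth(post, 0.75)
  pre[!lungm] <- 1; post[!lungm] <- 1
  regions <- data.frame(
    region = names(centres),
    x = vapply(centres, `[`, numeric(1), 1),
    y = vapply(centres, `[`, numeric(1), 2),
    z = vapply(centres, `[`, numeric(1), 3),
    radius = region_radius,
    target_pre = vapply(names(centres), function(n) vals[[n]]["pre"],
                        numeric(1)),
    target_post = vapply(names(centres), function(n)
      if (n == "HLV") vals[[n]]["post"] else vals[[n]]["pre"], numeric(1)))
  list(pre = image_volume(pre, sp, phantom$ct$origin, "target-pre"),
       post = image_volume(post, sp, phantom$ct$origin, "target-post"),
       regions = regions, md_ratio = md_ratio, fed_ratio = fed_ratio)
}

#' Breathing-phase series with closed-form Jacobians
#'
#' The displacement construction is uni-axial: the superior-inferior
#' component is the cumulative integral (from the top of the grid
#' downwards) of `target - 1`, so the deformation gradient is identity
#' except in one row and the analytic Jacobian determinant equals the
#' target field exactly.  Phase fields scale that peak field by a raised
#' cosine waveform that is 0 at end exhale (phase 1); phase images are
#' produced by inverting the forward map (fixed-point iteration) and
#' resampling the exhale image, so that warping a phase volume by its
#' true field reproduces the exhale volume.
#'
#' @param phantom output of [make_lung_phantom()].
#' @param target [image_volume()] of target LER-N values (>= 1; values
#'   above 1.6 leave the small-deformation regime and trigger a warning).
#' @param n_phases number of breathing phases (default 10).
#' @param tidal_volume recorded tidal volume in litres.
#' @param render generate the warped phase images (default).  With
#'   `render = FALSE` the returned series repeats the exhale frame and
#'   only the true fields and analytic Jacobians are built; sufficient
#'   (and much faster) for field-level / bypass testing.
#' @return list with `series` ([phase_series()], exhale first), `fields`
#'   (true [displacement_field()]s, one per non-exhale phase),
#'   `analytic_jacobians` (closed-form J per non-exhale phase) and
#'   `waveform`.
#' @export
make_breathing_series <- function(phantom, target, n_phases = 10,
                                  tidal_volume = 1.0, render = TRUE) {
  if (n_phases < 2L)
    stop("make_breathing_series: need at least 2 phases", call. = FALSE)
  stop_if_incongruent(target, phantom$ct, "target and phantom")
  t <- target$data
  if (max(abs(t - 1)) > 0.6)
    warning("construction warning: |J - 1| > 0.6 leaves the ",
            "small-deformation regime", call. = FALSE)
  sh <- dim(t); h <- phantom$ct$spacing[3]
  tm1 <- t - 1
  # cumulative trapezoid from the superior end down: U[, , K] = 0
  U <- array(0, sh)
  for (k in (sh[3] - 1):1)
    U[, , k] <- U[, , k + 1] - h * (tm1[, , k] + tm1[, , k + 1]) / 2
  w <- (1 - cos(2 * pi * (seq_len(n_phases) - 1) / n_phases)) / 2
  exhale <- phantom$ct
  exhale$frame_label <- "phase01"
  phases <- list(exhale)
  fields <- list(); jacs <- list()
  zero <- array(0, sh)
  g <- grid_coords(exhale)
  d <- dim(exhale$data)
  ys <- cbind(rep(g$x, times = d[2] * d[3]),
              rep(rep(g$y, each = d[1]), times = d[3]),
              rep(g$z, each = d[1] * d[2]))
  uvol <- image_volume(U, exhale$spacing, exhale$origin)
  for (k in 2:n_phases) {
    lab <- sprintf("phase%02d", k)
    uk <- w[k] * U
    if (w[k] == 0 || !render) {
      ph <- exhale; ph$frame_label <- lab
    } else {
      # invert y = x + u(x) e_z by fixed point: v <- -u(y + v e_z)
      v <- -w[k] * as.vector(U)
      for (it in 1:6) {
        pts <- ys; pts[, 3] <- pts[, 3] + v
        v <- -w[k] * sample_at_phys(uvol, pts, fill = 0)
      }
      pts <- ys; pts[, 3] <- pts[, 3] + v
      # sample from the high-resolution scene when available so every
      # phase (including exhale) shares one interpolation footprint
      src <- phantom$scene %||% exhale
      ph <- image_volume(array(sample_at_phys(src, pts, fill = -1000), d),
                         exhale$spacing, exhale$origin, frame_label = lab)
    }
    phases[[k]] <- ph
    fields[[k - 1L]] <- displacement_field(zero, zero, uk, exhale,
                                           phase_label = lab)
    jacs[[k - 1L]] <- image_volume(1 + w[k] * tm1, exhale$spacing,
                                   exhale$origin, frame_label = lab)
  }
  list(series = phase_series(phases, exhale_index = 1L,
                             tidal_volume = tidal_volume),
       fields = fields, analytic_jacobians = jacs, waveform = w)
}

#' Gamma-variate contrast kinetics model
#'
#' Vessel enhancement follows a peak-normalised gamma-variate bolus:
#' `A * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0)/beta)`,
#' whose maximum is exactly `A` at `t = t0 + alpha * beta`, so `A` is the
#' injected peak enhancement.  Parenchyma receives a delayed, scaled copy
#' of the bolus on top of its baseline.  Post-treatment effects are a
#' dose-dependent vessel peak reduction (`k_vessel` HU per Gy above
#' `dose_knee`), a matching parenchymal baseline rise (`par_slope` of the
#' vessel reduction, modelling contrast/blood leakage), and a
#' supply-side multiplier `fed_mult` on every vessel fed by (downstream
#' of) the maximally irradiated vessel.
#'
#' @param A peak enhancement in HU.
#' @param t0 bolus arrival time (s).
#' @param alpha,beta gamma-variate shape and scale (s).
#' @param vessel_base,par_base baseline HU of vessels and parenchyma.
#' @param par_frac,par_delay parenchymal bolus fraction and delay (s).
#' @param noise_sd additive Gaussian noise sd in HU.
#' @param k_vessel dose sensitivity of the vessel peak (HU/Gy).
#' @param dose_knee dose threshold (Gy) above which vessel damage starts.
#' @param par_slope parenchymal baseline rise per unit vessel reduction.
#' @param fed_mult supply multiplier in (0, 1] for fed vessels.
#' @export
kinetic_model <- function(A = 250, t0 = 8, alpha = 2, beta = 3,
                          vessel_base = 50, par_base = -750,
                          par_frac = 0.10, par_delay = 2, noise_sd = 5,
                          k_vessel = 4, dose_knee = 25, par_slope = 0.6,
                          fed_mult = 0.6) {
  stopifnot(A >= 0, alpha > 0, beta > 0, fed_mult > 0, fed_mult <= 1)
  as.list(environment())
}

gamma_variate <- function(t, t0, alpha, beta) {
  s <- pmax(t - t0, 0)
  ifelse(s <= 0, 0, (s / (alpha * beta))^alpha * exp(alpha - s / beta))
}

#' Synthetic dynamic contrast study
#'
#' Generates one frame per time point: the phantom CT plus vessel and
#' parenchymal enhancement under [kinetic_model()], plus seeded Gaussian
#' noise.  For a post-treatment study supply the dose grid; vessel
#' effects then follow the model's dose and fed-status terms.
#'
#' @param phantom output of [make_lung_phantom()].
#' @param kinetics a [kinetic_model()].
#' @param times frame acquisition times in s (>= 3 frames before `t0`).
#' @param post logical; apply post-treatment effects.
#' @param dose [make_dose()] output; required when `post = TRUE`.
#' @param seed seed for the noise.
#' @return a [contrast_series()]; per-node effect multipliers attached as
#'   attribute `effects`.
#' @export
make_contrast_study <- function(phantom, kinetics = kinetic_model(),
                                times = seq(0, 40, by = 2), post = FALSE,
                                dose = NULL, seed = 1L) {
  if (kinetics$t0 < times[1])
    stop("timeline error: bolus arrival t0 precedes the first frame",
         call. = FALSE)
  if (sum(times < kinetics$t0) < 3L)
    stop("timeline error: need at least 3 pre-injection frames",
         call. = FALSE)
  if (post && is.null(dose))
    stop("make_contrast_study: post-treatment study needs a dose grid",
         call. = FALSE)
  set.seed(seed + if (post) 500000L else 0L)
  nodes <- phantom$tree$nodes
  par_shift <- 0
  lung <- phantom$lung_both$mask
  vessel <- phantom$vessel_label > 0L
  parench <- lung & !vessel
  eff_vox <- array(1, dim(phantom$ct$data))
  eff <- rep(1, nrow(nodes))
  if (post) {
    tree <- attr(dose, "tree")
    fed <- tree_descendants(tree, phantom$md_node)
    # dose damage acts on the local (voxel) dose; the supply-side fed
    # multiplier acts per vessel branch
    eff_vox[vessel] <- pmax(0.05, 1 - kinetics$k_vessel *
                              pmax(0, dose$data[vessel] -
                                     kinetics$dose_knee) / kinetics$A)
    fed_vox <- phantom$vessel_label > 0L &
      array(nodes$id[pmax(phantom$vessel_label, 1L)] %in% fed,
            dim(phantom$vessel_label))
    eff_vox[fed_vox] <- eff_vox[fed_vox] * kinetics$fed_mult
    eff <- pmax(0.05, 1 - kinetics$k_vessel *
                  pmax(0, tree$nodes$dose - kinetics$dose_knee) /
                  kinetics$A)
    eff[tree$nodes$id %in% fed] <- eff[tree$nodes$id %in% fed] *
      kinetics$fed_mult
    par_shift <- kinetics$par_slope * kinetics$k_vessel *
      pmax(0, dose$data - kinetics$dose_knee)
  }
  base <- phantom$ct$data
  if (post) base[parench] <- base[parench] + par_shift[parench]
  frames <- vector("list", length(times))
  for (f in seq_along(times)) {
    tt <- times[f]
    gv <- gamma_variate(tt, kinetics$t0, kinetics$alpha, kinetics$beta)
    gp <- gamma_variate(tt, kinetics$t0 + kinetics$par_delay,
                        kinetics$alpha, kinetics$beta)
    a <- base
    a[vessel] <- kinetics$vessel_base +
      kinetics$A * gv * eff_vox[vessel]
    a[parench] <- a[parench] + kinetics$par_frac * kinetics$A * gp
    if (kinetics$noise_sd > 0)
      a <- a + array(stats::rnorm(length(a), 0, kinetics$noise_sd), dim(a))
    frames[[f]] <- image_volume(a, phantom$ct$spacing, phantom$ct$origin,
                                frame_label = sprintf("frame%02d", f))
  }
  out <- contrast_series(frames, times, breathhold = TRUE)
  attr(out, "effects") <- stats::setNames(eff, nodes$id)
  out
}

#' Pathology effect model
#'
#' Maps (dose level, fed status, ventilation change, ventilation class
#' pair) to an expected collagen grade and diagnosis probabilities.  The
#' expected grade is monotone non-decreasing in dose level; `effect_scale
#' = 0` is the null model (no collagen, no diagnoses).
#'
#' @param effect_scale global multiplier on all effects.
#' @param grade_sd sd of the Gaussian jitter on the latent grade.
#' @export
pathology_effect_model <- function(effect_scale = 1, grade_sd = 0.35) {
  list(effect_scale = effect_scale, grade_sd = grade_sd,
       dose_term = c(NoDose = 0.15, LowDose = 0.9, MaxDose = 2.7),
       fed_term = c(Fed = 0.5, NotFed = 0),
       decline_term = c(Decline = 1.1, Stable = 0, Increase = 0),
       vent_term = c(HHV = -0.3, LLV = 0.7, HLV = 2.4),
       con_term = -0.6)
}

grade_to_label <- function(g) {
  labs <- names(collagen_scale)
  g <- pmin(pmax(g, 0), 5)
  lo <- floor(g); frac <- g - lo
  ifelse(frac < 0.25, labs[lo + 1],
         ifelse(frac > 0.75, labs[pmin(lo + 2, 6)],
                paste0(labs[lo + 1], "-", labs[pmin(lo + 2, 6)])))
}

#' Sample pathology outcomes for a set of contour assignments
#'
#' @param assignments data frame with columns `subject`, `contour`,
#'   `dose_level` (`NoDose`/`LowDose`/`MaxDose`), `fed_status`
#'   (`Fed`/`NotFed`/`NA`), `change_class`.
#' @param model a [pathology_effect_model()].
#' @param seed seed for sampling.
#' @return list with `collagen` (subject, contour, grade_label,
#'   artifact_suspect) and `diagnoses` (subject, contour, diagnosis,
#'   strength_label) data frames.
#' @export
make_pathology <- function(assignments, model = pathology_effect_model(),
                           seed = 1L) {
  set.seed(seed + 13L)
  n <- nrow(assignments)
  mu <- numeric(n)
  for (r in seq_len(n)) {
    a <- assignments[r, ]
    m <- model$dose_term[[a$dose_level %||na% "NoDose"]]
    if (!is.na(a$fed_status) && a$fed_status %in% names(model$fed_term))
      m <- m + model$fed_term[[a$fed_status]]
    if (a$change_class %in% names(model$decline_term))
      m <- m + model$decline_term[[a$change_class]]
    if (a$contour %in% names(model$vent_term))
      m <- m + model$vent_term[[a$contour]]
    if (a$contour == "CON") m <- m + model$con_term
    mu[r] <- m * model$effect_scale
  }
  g <- mu + stats::rnorm(n, 0, model$grade_sd * model$effect_scale)
  g <- pmin(pmax(round(g * 2) / 2, 0), 5)
  collagen <- data.frame(subject = assignments$subject,
                         contour = assignments$contour,
                         grade_label = grade_to_label(g),
                         artifact_suspect = FALSE)
  diag_p <- function(name, p) {
    keep <- stats::runif(n) < p * model$effect_scale
    if (!any(keep)) return(NULL)
    strength <- pmin(pmax(round((g[keep] + stats::rnorm(sum(keep), 0,
                                                        0.3)) * 2) / 2,
                          0.5), 5)
    data.frame(subject = assignments$subject[keep],
               contour = assignments$contour[keep], diagnosis = name,
               strength_label = grade_to_label(strength))
  }
  dg <- rbind(
    diag_p("fibrosis", stats::plogis(2 * (mu - 1.2))),
    diag_p("inflammation", stats::plogis(2 * (mu - 1.0))),
    diag_p("chondrocyte_necrosis",
           ifelse(assignments$change_class == "Decline" |
                    assignments$contour == "LLV", 0.85, 0.15)),
    diag_p("type2_pneumocyte_hyperplasia",
           ifelse(assignments$dose_level %in% "MaxDose", 0.9, 0.05)),
    diag_p("multinucleated_macrophages",
           ifelse(assignments$contour == "LDNF", 0.9, 0.1)))
  list(collagen = collagen,
       diagnoses = if (is.null(dg))
         data.frame(subject = character(0), contour = character(0),
                    diagnosis = character(0),
                    strength_label = character(0)) else dg)
}

`%||na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
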