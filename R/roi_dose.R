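# Construction and classification of the nine analysis contours: the
# maximum-dose vessel (MD), the four indirect contours crossing dose level
# (low 5-20 Gy / no < 5 Gy) with vessel-tree topology (fed = downstream of
# the maximally irradiated vessel), the mirrored contralateral control
# (CON), and the three ventilation-selected parenchymal points (HHV, HLV,
# LLV).

#' Vessel tree
#'
#' Rooted tree of vessel segments: node positions and radii in mm, parent
#' links, and (once a dose grid exists) a per-node mean dose.
#'
#' @param nodes data frame with columns `id`, `x`, `y`, `z` (physical mm),
#'   `radius` (mm), `parent` (id of the parent node, `NA` for the single
#'   root) and optionally `dose` (Gy).
#' @return object of class `vessel_tree`.
#' @export
vessel_tree <- function(nodes) {
  need <- c("id", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes)))
    stop("vessel_tree: nodes need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(nodes$id))
    stop("vessel_tree: duplicate node ids", call. = FALSE)
  roots <- which(is.na(nodes$parent))
  if (length(roots) != 1L)
    stop("vessel_tree: exactly one root (parent = NA) required",
         call. = FALSE)
  if (any(nodes$radius <= 0))
    stop("vessel_tree: radii must be > 0", call. = FALSE)
  idx <- match(nodes$parent, nodes$id)
  bad <- which(!is.na(nodes$parent) & is.na(idx))
  if (length(bad))
    stop("vessel_tree: unknown parent id for node ", nodes$id[bad[1]],
         call. = FALSE)
  # connectivity + acyclicity: every node must reach the root in <= n steps
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    cur <- i; steps <- 0L
    while (!is.na(nodes$parent[cur])) {
      cur <- idx[cur]; steps <- steps + 1L
      if (steps > n)
        stop("vessel_tree: cycle detected at node ", nodes$id[i],
             call. = FALSE)
    }
  }
  ok <- is.na(nodes$parent) | nodes$radius <= nodes$radius[idx] + 1e-9
  if (!all(ok))
    stop("vessel_tree: child radius exceeds parent radius at node ",
         nodes$id[which(!ok)[1]], call. = FALSE)
  structure(list(nodes = nodes, root = nodes$id[roots]),
            class = "vessel_tree")
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("vessel_tree: %d nodes, root %s\n", nrow(x$nodes),
              sQuote(x$root)))
  invisible(x)
}

tree_parent_index <- function(tree) match(tree$nodes$parent, tree$nodes$id)

#' Descendants of a vessel node
#' @param tree a [vessel_tree()].
#' @param node_id node id.
#' @return character vector of strict-descendant ids.
#' @export
tree_descendants <- function(tree, node_id) {
  ids <- tree$nodes$id
  if (!node_id %in% ids)
    stop("lookup error: unknown node id ", sQuote(node_id), call. = FALSE)
  pidx <- tree_parent_index(tree)
  desc <- character(0)
  frontier <- node_id
  while (length(frontier)) {
    children <- ids[which(ids[pidx] %in% frontier)]
    desc <- c(desc, children)
    frontier <- children
  }
  desc
}

#' Fed / not-fed status of a vessel
#'
#' A vessel is Fed when it branches downstream of the vessel irradiated to
#' the maximum dose, i.e. when it is a strict descendant of the max-dose
#' node (the max-dose node itself is not "fed").
#'
#' @param tree a [vessel_tree()].
#' @param vessel_id id of the vessel being classified.
#' @param max_dose_id id of the maximally irradiated vessel.
#' @return `"Fed"` or `"NotFed"`.
#' @export
fed_status <- function(tree, vessel_id, max_dose_id) {
  ids <- tree$nodes$id
  for (id in c(vessel_id, max_dose_id))
    if (!id %in% ids)
      stop("lookup error: unknown node id ", sQuote(id), call. = FALSE)
  pidx <- tree_parent_index(tree)
  cur <- match(vessel_id, ids)
  repeat {
    cur <- pidx[cur]
    if (is.na(cur)) return("NotFed")
    if (ids[cur] == max_dose_id) return("Fed")
  }
}

#' Classify the dose level of an ROI
#'
#' `MaxDose` when the ROI intersects the PTV (rule precedence over the
#' dose statistic); otherwise by the ROI dose: < 5 Gy is `NoDose`,
#' 5-20 Gy inclusive is `LowDose`, and an ROI above 20 Gy outside the PTV
#' is flagged `Unclassified` (excluded and logged).  The ROI dose
#' statistic is the mean by default (`stat = "max"` is available because
#' the receiving-dose convention for small ROIs is not standardised).
#'
#' @param roi `roi_mask`.
#' @param dose a [dose_grid()].
#' @param ptv `roi_mask` of the planning target volume.
#' @param stat `"mean"` or `"max"`.
#' @return `"MaxDose"`, `"LowDose"`, `"NoDose"` or `"Unclassified"`.
#' @export
classify_dose_level <- function(roi, dose, ptv, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  if (!identical(dim(roi$mask), dim(dose$data)))
    stop("geometry error: ROI not congruent with dose grid", call. = FALSE)
  if (!any(roi$mask))
    stop("empty-ROI error: ROI has no voxels", call. = FALSE)
  if (any(roi$mask & ptv$mask)) return("MaxDose")
  d <- if (stat == "mean") mean(dose$data[roi$mask]) else
    max(dose$data[roi$mask])
  if (d < 5) return("NoDose")
  if (d <= 20) return("LowDose")
  lfx_log("roi_dose", sprintf(
    "ROI %s: %s dose %.1f Gy outside PTV exceeds 20 Gy; Unclassified",
    roi$label, stat, d))
  "Unclassified"
}

#' Spherical ROI around a physical point
#'
#' @param reference `image_volume` defining the grid.
#' @param center_mm physical centre (length 3).
#' @param radius_mm sphere radius in mm.
#' @param within optional logical array; the sphere is clipped to it.
#' @param label,tissue passed to [roi_mask()].
#' @export
sphere_roi <- function(reference, center_mm, radius_mm, within = NULL,
                       label = "parenchyma-bin", tissue = "parenchyma") {
  g <- grid_coords(reference)
  d <- dim(reference$data)
  dx2 <- (g$x - center_mm[1])^2
  dy2 <- (g$y - center_mm[2])^2
  dz2 <- (g$z - center_mm[3])^2
  m <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius_mm^2
  if (!is.null(within)) m <- m & within
  roi_mask(m, reference, label = label, tissue = tissue)
}

roi_centroid <- function(roi) {
  idx <- which(roi$mask, arr.ind = TRUE)
  colMeans(sweep(sweep(idx - 1, 2, roi$spacing, "*"), 2, roi$origin, "+"))
}

#' Mirror an ROI into the contralateral lung
#'
#' Reflects the ROI centroid across the mid-sagittal plane of the combined
#' lung bounding box, snaps the reflected point to the nearest
#' contralateral-lung voxel, and emits a sphere of equivalent volume
#' clipped to the contralateral lung.  A reflection landing more than
#' 30 mm from the contralateral lung raises a placement warning with the
#' distance.
#'
#' @param roi `roi_mask` inside the ipsilateral lung.
#' @param ipsi_lung,contra_lung disjoint lung `roi_mask`s.
#' @param label label for the mirrored ROI (default `"CON"`).
#' @export
mirror_contralateral <- function(roi, ipsi_lung, contra_lung,
                                 label = "CON") {
  if (any(ipsi_lung$mask & contra_lung$mask))
    stop("mirror_contralateral: lungs are not disjoint", call. = FALSE)
  cen <- roi_centroid(roi)
  both <- ipsi_lung$mask | contra_lung$mask
  idx <- which(both, arr.ind = TRUE)
  xs <- roi$origin[1] + (range(idx[, 1]) - 1) * roi$spacing[1]
  midplane <- mean(xs)
  mirrored <- cen
  mirrored[1] <- 2 * midplane - cen[1]
  cidx <- which(contra_lung$mask, arr.ind = TRUE)
  cphys <- sweep(sweep(cidx - 1, 2, roi$spacing, "*"), 2, roi$origin, "+")
  d2 <- rowSums(sweep(cphys, 2, mirrored, "-")^2)
  nearest <- which.min(d2)
  dist <- sqrt(d2[nearest])
  if (dist > 30)
    warning(sprintf(
      "placement warning: mirrored centroid lands %.1f mm from the contralateral lung",
      dist), call. = FALSE)
  snapped <- cphys[nearest, ]
  vol_mm3 <- sum(roi$mask) * prod(roi$spacing)
  radius <- (3 * vol_mm3 / (4 * pi))^(1 / 3)
  ref <- image_volume(array(0, dim(roi$mask)), roi$spacing, roi$origin)
  sphere_roi(ref, snapped, radius, within = contra_lung$mask,
             label = label, tissue = roi$tissue)
}

# sum of an array over a spherical neighbourhood, by shift accumulation
sphere_sum <- function(a, spacing, radius_mm) {
  r <- floor(radius_mm / spacing)
  acc <- array(0, dim(a))
  for (di in -r[1]:r[1]) for (dj in -r[2]:r[2]) for (dk in -r[3]:r[3]) {
    if (sum((c(di, dj, dk) * spacing)^2) > radius_mm^2) next
    acc <- acc + shift_array(shift_array(shift_array(a, di, 1L), dj, 2L),
                             dk, 3L)
  }
  acc
}

#' Select the three ventilation-based points of interest
#'
#' HHV is a spherical region High both pre- and post-treatment, LLV is
#' Low at both time points, and HLV is High pre but Low post.  Candidate
#' centres are lung voxels satisfying the class pair whose surrounding
#' sphere has at least `purity` of its in-sphere lung voxels in the same
#' pair (the requirement that each point sit within a region of similar
#' ventilation values).  The centre maximising that purity wins; ties are
#' broken deterministically by the most superior (largest z index), then
#' most anterior (smallest y index), then most right (smallest x index)
#' voxel.  A class pair with no qualifying candidate is reported
#' unavailable rather than failing, since availability is
#' subject-dependent.
#'
#' @param pre,post congruent ventilation maps.
#' @param ipsi_lung `roi_mask` of the ipsilateral lung.
#' @param radius_mm sphere radius in mm (default 10, standing in for the
#'   roughly one-inch histology sections).
#' @param purity minimum in-sphere class purity (default 0.9).
#' @param high_min,low_max level thresholds, see [classify_ventilation()].
#' @return named list with elements `HHV`, `HLV`, `LLV`; each is either a
#'   `roi_mask` (with attribute `purity`) or `NULL` when unavailable.
#' @export
select_ventilation_points <- function(pre, post, ipsi_lung, radius_mm = 10,
                                      purity = 0.9, high_min = 1.2,
                                      low_max = 1.1) {
  stop_if_incongruent(pre, post, "ventilation maps")
  if (!any(ipsi_lung$mask))
    stop("mask error: empty lung mask", call. = FALSE)
  d <- dim(pre$data)
  hi_pre <- pre$data >= high_min; lo_pre <- pre$data <= low_max
  hi_post <- post$data >= high_min; lo_post <- post$data <= low_max
  pairs <- list(HHV = hi_pre & hi_post, LLV = lo_pre & lo_post,
                HLV = hi_pre & lo_post)
  L <- ipsi_lung$mask
  lung_count <- sphere_sum(L * 1, pre$spacing, radius_mm)
  ref <- image_volume(array(0, d), pre$spacing, pre$origin)
  out <- list()
  for (nm in names(pairs)) {
    P <- pairs[[nm]] & L
    if (!any(P)) { out[[nm]] <- NULL; next }
    pur <- sphere_sum(P * 1, pre$spacing, radius_mm) / pmax(lung_count, 1)
    pur[!P] <- -1
    best <- max(pur)
    if (best < purity) {
      lfx_log("roi_dose", sprintf(
        "no candidate reaches purity %.2f for %s (best %.2f); unavailable",
        purity, nm, best))
      out[nm] <- list(NULL)
      next
    }
    cand <- which(pur >= best - 1e-12, arr.ind = TRUE)
    ord <- order(-cand[, 3], cand[, 2], cand[, 1])
    centre_idx <- cand[ord[1], ]
    centre <- pre$origin + (centre_idx - 1) * pre$spacing
    roi <- sphere_roi(ref, centre, radius_mm, within = L, label = nm,
                      tissue = "parenchyma")
    attr(roi, "purity") <- best
    out[[nm]] <- roi
  }
  # keep stable HHV/HLV/LLV naming with NULLs preserved
  structure(list(HHV = out[["HHV"]], HLV = out[["HLV"]], LLV = out[["LLV"]]))
}

#' Serialize / deserialize a vessel tree as JSON
#' @param tree a [vessel_tree()].
#' @param path JSON file path.
#' @export
write_vessel_tree <- function(tree, path) {
  jsonlite::write_json(list(root = tree$root, nodes = tree$nodes), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_vessel_tree
#' @export
read_vessel_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- obj$nodes
  if (!"parent" %in% names(nodes)) nodes$parent <- NA_character_
  nodes$parent[vapply(nodes$parent, is.null, logical(1))] <- NA
  nodes$parent <- as.character(nodes$parent)
  nodes$parent[nodes$parent == "NULL"] <- NA_character_
  vessel_tree(nodes)
}
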