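# End-to-end synthetic study: phantom -> dose -> contours -> ventilation
# and perfusion biomarkers -> pathology -> concordance, for a cohort of
# simulated subjects with seeded reproducibility.

#' Build the standard analysis contours on a phantom
#'
#' Selects, from the phantom's vessel tree and a dose grid, the five
#' vessel contours (MD; low/no dose crossed with fed/not-fed, with dose
#' level verified through [classify_dose_level()] and topology through
#' [fed_status()]), mirrors the MD contour into the contralateral lung
#' for CON, and optionally adds the three ventilation-selected points.
#'
#' @param phantom output of [make_lung_phantom()].
#' @param dose output of [make_dose()].
#' @param pre_map,post_map ventilation maps for HHV/HLV/LLV selection;
#'   omit to build vessel contours only.
#' @param vessel_roi_radius radius (mm) of the vessel-centred spheres.
#' @param vent_radius radius (mm) of the ventilation-point spheres.
#' @param avoid data frame of centres (columns x, y, z) that vessel
#'   contours must keep clear of (e.g. planted ventilation regions).
#' @return list with `rois` (named list of `roi_mask`), `assignments`
#'   (data frame: contour, node, dose_level, fed_status) and `ptv`.
#' @export
build_standard_contours <- function(phantom, dose, pre_map = NULL,
                                    post_map = NULL,
                                    vessel_roi_radius = 6,
                                    vent_radius = 8, avoid = NULL) {
  tree <- attr(dose, "tree")
  nodes <- tree$nodes
  md_pos <- as.numeric(nodes[match(phantom$md_node, nodes$id),
                             c("x", "y", "z")])
  ptv <- sphere_roi(phantom$ct, md_pos, 10, label = "PTV")
  fed <- tree_descendants(tree, phantom$md_node)
  ipsi_ids <- c(phantom$md_node, fed,
                tree_descendants(tree, "N-mid"), "N-mid",
                tree_descendants(tree, "I-inf"), "I-inf")
  clear_of_avoid <- function(id) {
    if (is.null(avoid) || nrow(avoid) == 0L) return(TRUE)
    p <- as.numeric(nodes[match(id, nodes$id), c("x", "y", "z")])
    all(sqrt((avoid$x - p[1])^2 + (avoid$y - p[2])^2 +
               (avoid$z - p[3])^2) > avoid$radius + vessel_roi_radius + 2)
  }
  node_roi <- function(id, label) {
    p <- as.numeric(nodes[match(id, nodes$id), c("x", "y", "z")])
    sphere_roi(phantom$ct, p, vessel_roi_radius, label = label,
               tissue = "vessel")
  }
  pick <- function(label, candidates, want_level, want_fed) {
    for (id in candidates) {
      if (!clear_of_avoid(id)) next
      roi <- node_roi(id, label)
      lvl <- classify_dose_level(roi, dose, ptv)
      fs <- fed_status(tree, id, phantom$md_node)
      if (identical(lvl, want_level) && identical(fs, want_fed))
        return(list(id = id, roi = roi, level = lvl, fed = fs))
    }
    stop("contour construction: no ", label, " candidate (", want_level,
         "/", want_fed, ") on this phantom", call. = FALSE)
  }
  # order candidates by |dose - centre of the wanted band| for stability
  cand_by_dose <- function(ids, centre) {
    d <- nodes$dose[match(ids, nodes$id)]
    ids[order(abs(d - centre))]
  }
  not_fed_ids <- setdiff(ipsi_ids, c(phantom$md_node, fed))
  sel <- list(
    MD = list(id = phantom$md_node, roi = node_roi(phantom$md_node, "MD"),
              level = "MaxDose", fed = "NotFed"),
    LDF = pick("LDF", cand_by_dose(fed, 12.5), "LowDose", "Fed"),
    NDF = pick("NDF", cand_by_dose(fed, 2.5), "NoDose", "Fed"),
    LDNF = pick("LDNF", cand_by_dose(not_fed_ids, 12.5), "LowDose",
                "NotFed"),
    NDNF = pick("NDNF", cand_by_dose(not_fed_ids, 2.5), "NoDose",
                "NotFed"))
  con <- mirror_contralateral(sel$MD$roi, phantom$lung_ipsi,
                              phantom$lung_contra, label = "CON")
  rois <- lapply(sel, `[[`, "roi")
  rois$CON <- con
  assignments <- data.frame(
    contour = c(names(sel), "CON"),
    node = c(vapply(sel, `[[`, character(1), "id"), "C-MD"),
    dose_level = c(vapply(sel, `[[`, character(1), "level"), "NoDose"),
    fed_status = c(vapply(sel, `[[`, character(1), "fed"), "NotFed"))
  if (!is.null(pre_map) && !is.null(post_map)) {
    vp <- select_ventilation_points(pre_map, post_map, phantom$lung_ipsi,
                                    radius_mm = vent_radius)
    for (nm in c("HHV", "HLV", "LLV")) {
      if (is.null(vp[[nm]])) {
        lfx_log("contours", nm, " point unavailable on this subject")
        next
      }
      rois[[nm]] <- vp[[nm]]
      assignments <- rbind(assignments, data.frame(
        contour = nm, node = NA_character_, dose_level = "NoDose",
        fed_status = NA_character_))
    }
  }
  list(rois = rois, assignments = assignments, ptv = ptv)
}

#' Matched vessel/parenchyma ROI pairs for dose-binned measurements
#'
#' For each vessel node, a sphere at the node position is split into its
#' vessel voxels and the surrounding lung parenchyma.  Using the same
#' sphere for both tissues keeps their dose sampling aligned, so the
#' vessel-versus-parenchyma change relationship is not distorted by
#' geometry.  Nodes without vessel or parenchyma voxels in reach (e.g.
#' mediastinal trunk segments) are skipped.
#'
#' @param phantom output of [make_lung_phantom()].
#' @param dose output of [make_dose()].
#' @param radius_mm sphere radius in mm.
#' @return list with `vessel` and `parenchyma` lists of `roi_mask`.
#' @export
dose_bin_rois <- function(phantom, dose, radius_mm = 9) {
  tree <- attr(dose, "tree")
  vrois <- list(); prois <- list()
  parench <- phantom$lung_both$mask & !(phantom$vessel_label > 0L)
  for (i in seq_len(nrow(tree$nodes))) {
    p <- as.numeric(tree$nodes[i, c("x", "y", "z")])
    v <- tryCatch(sphere_roi(phantom$ct, p, radius_mm,
                             within = phantom$vessel_label > 0L,
                             label = "vessel-bin", tissue = "vessel"),
                  error = function(e) NULL)
    q <- tryCatch(sphere_roi(phantom$ct, p, radius_mm, within = parench),
                  error = function(e) NULL)
    # keep only complete vessel/parenchyma pairs so both tissues sample
    # the same dose neighbourhoods
    if (!is.null(v) && !is.null(q)) {
      vrois[[length(vrois) + 1L]] <- v
      prois[[length(prois) + 1L]] <- q
    }
  }
  list(vessel = vrois, parenchyma = prois)
}

#' Run the full synthetic study
#'
#' Simulates a cohort of subjects end to end: phantom and dose, pre- and
#' post-treatment breathing series (ventilation maps via registration or
#' the true bypass fields), dynamic contrast studies, the nine analysis
#' contours, per-contour ventilation change ratios and classes,
#' per-contour perfusion AUC changes, dose-binned vessel/parenchyma
#' deltas, coupled pathology sampling, and the resulting concordance
#' table.  All randomness derives from `seed`.
#'
#' @param n_subjects simulated cohort size (default 5).
#' @param seed master seed.
#' @param spec_template [phantom_spec()] whose seed is re-derived per
#'   subject.
#' @param n_phases breathing phases per 4DCT.
#' @param registration `"bypass"` (true fields) or `"demons"`.
#' @param times contrast frame times (s).
#' @param kinetics a [kinetic_model()].
#' @param out_dir if non-NULL, tables are written there as CSV
#'   (ventilation.csv, perfusion.csv, contours.csv, dose_bins.csv,
#'   concordance.csv, collagen.csv, diagnoses.csv).
#' @return list with `ventilation`, `perfusion`, `contours`, `dose_bins`
#'   data frames, `auc_tests` (per-contour paired t-tests of AUC),
#'   `correlation` (vessel/parenchyma fit), `pathology`, `concordance`.
#' @export
run_synthetic_study <- function(n_subjects = 5, seed = 1L,
                                spec_template = phantom_spec(),
                                n_phases = 10,
                                registration = c("bypass", "demons"),
                                times = seq(0, 40, by = 2),
                                kinetics = kinetic_model(),
                                out_dir = NULL) {
  registration <- match.arg(registration)
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
  subjects <- paste0("S", seq_len(n_subjects))
  vent_rows <- list(); perf_rows <- list(); cont_rows <- list()
  bin_rows <- list()
  for (s in seq_len(n_subjects)) {
    lfx_log("study", "simulating subject ", subjects[s])
    spec <- spec_template
    spec$seed <- subject_seeds[s]
    phantom <- make_lung_phantom(spec)
    dose <- make_dose(phantom)
    model <- make_expansion_model(phantom, dose, seed = subject_seeds[s])
    maps <- list()
    for (tp in c("pre", "post")) {
      target <- model[[tp]]
      bs <- make_breathing_series(phantom, target, n_phases = n_phases)
      flds <- if (registration == "bypass") {
        register_to_exhale(bs$series, fields = bs$fields)
      } else {
        register_to_exhale(bs$series)
      }
      jmaps <- lapply(flds, jacobian_map,
                      smooth_sigma = if (registration == "demons") 1 else 0)
      m <- ler_n(jmaps, tidal_volume = bs$series$tidal_volume)
      maps[[tp]] <- effort_correct(m, phantom$lung_both,
                                   measured_tv = bs$series$tidal_volume,
                                   reference_tv = 1.0)
    }
    avoid <- model$regions[, c("x", "y", "z", "radius")]
    contours <- build_standard_contours(phantom, dose, maps$pre,
                                        maps$post, avoid = avoid)
    for (nm in names(contours$rois)) {
      rc <- roi_change(maps$pre, maps$post, contours$rois[[nm]])
      rc$subject <- subjects[s]
      vent_rows[[length(vent_rows) + 1L]] <- rc
    }
    a <- contours$assignments
    a$subject <- subjects[s]
    cont_rows[[length(cont_rows) + 1L]] <- a
    # ---- perfusion ----------------------------------------------------
    tree0 <- attr(dose, "tree")
    pre_cs <- make_contrast_study(phantom, kinetics, times, post = FALSE,
                                  seed = subject_seeds[s])
    post_cs <- make_contrast_study(phantom, kinetics, times, post = TRUE,
                                   dose = dose, seed = subject_seeds[s])
    vessel_contours <- c("MD", "LDF", "LDNF", "NDF", "NDNF", "CON")
    for (nm in vessel_contours) {
      node <- a$node[a$contour == nm]
      # sample the vessel at the node itself (a node's full capsule can
      # reach into the higher-dose proximal segment)
      pos <- as.numeric(tree0$nodes[match(node, tree0$nodes$id),
                                    c("x", "y", "z")])
      vroi <- tryCatch(
        sphere_roi(phantom$ct, pos, 6, within = phantom$vessel_label > 0L,
                   label = nm, tissue = "vessel"),
        error = function(e) vessel_node_roi(phantom, node, label = nm))
      cpre <- extract_curve(pre_cs, vroi, n_precontrast = 3L)
      cpost <- extract_curve(post_cs, vroi, n_precontrast = 3L)
      mpre <- perfusion_metrics(cpre); mpost <- perfusion_metrics(cpost)
      perf_rows[[length(perf_rows) + 1L]] <- data.frame(
        subject = subjects[s], contour = nm,
        auc_pre = mpre$auc, auc_post = mpost$auc,
        auc_ratio = mpost$auc / mpre$auc,
        peak_pre = mpre$peak_enhancement,
        peak_post = mpost$peak_enhancement)
    }
    br <- dose_bin_rois(phantom, dose)
    bins <- dose_binned_deltas(pre_cs, post_cs, br$vessel, br$parenchyma,
                               dose, n_precontrast = 3L,
                               pair_by_vessel = TRUE)
    bins$subject <- subjects[s]
    bin_rows[[length(bin_rows) + 1L]] <- bins
  }
  ventilation <- do.call(rbind, vent_rows)
  ventilation <- ventilation[, c("subject", "contour", "mean_pre",
                                 "mean_post", "ratio", "change_class")]
  perfusion <- do.call(rbind, perf_rows)
  contours_tab <- do.call(rbind, cont_rows)
  dose_bins <- do.call(rbind, bin_rows)
  # paired AUC t-tests per contour across subjects
  auc_tests <- if (n_subjects >= 2) {
    lapply(split(perfusion, perfusion$contour), function(df) {
      paired_t_test(df$auc_pre, df$auc_post)
    })
  } else NULL
  # cohort vessel/parenchyma correlation: average each bin over subjects
  pooled <- stats::aggregate(delta_metric ~ bin_lo + bin_hi + tissue,
                             data = dose_bins, FUN = mean)
  corr <- tryCatch(vessel_parenchyma_correlation(pooled, min_dose = 25),
                   error = function(e) NULL)
  # ---- pathology + concordance ---------------------------------------
  pa <- merge(contours_tab,
              ventilation[, c("subject", "contour", "change_class")],
              by = c("subject", "contour"))
  pathology <- make_pathology(pa, seed = seed)
  conc <- build_concordance(
    ventilation[, c("subject", "contour", "change_class")],
    pathology$collagen, pathology$diagnoses)
  out <- list(ventilation = ventilation, perfusion = perfusion,
              contours = contours_tab, dose_bins = dose_bins,
              auc_tests = auc_tests, correlation = corr,
              pathology = pathology, concordance = conc)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(ventilation, file.path(out_dir, "ventilation.csv"))
    write_table_csv(perfusion, file.path(out_dir, "perfusion.csv"))
    write_table_csv(contours_tab, file.path(out_dir, "contours.csv"))
    write_table_csv(dose_bins, file.path(out_dir, "dose_bins.csv"))
    write_table_csv(conc$table, file.path(out_dir, "concordance.csv"))
    write_table_csv(pathology$collagen, file.path(out_dir, "collagen.csv"))
    write_table_csv(pathology$diagnoses,
                    file.path(out_dir, "diagnoses.csv"))
  }
  out
}
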