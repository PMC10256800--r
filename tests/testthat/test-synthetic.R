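test_that("the phantom has disjoint lungs, embedded vessels and HU modes", {
  ph <- small_phantom()
  expect_false(any(ph$lung_ipsi$mask & ph$lung_contra$mask))
  # vessel voxels sit inside the thorax near the lungs
  v <- ph$vessel_label > 0
  idx <- which(ph$lung_both$mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min) - 4; hi <- apply(idx, 2, max) + 4
  vidx <- which(v, arr.ind = TRUE)
  expect_true(all(sweep(vidx, 2, lo, ">=") & sweep(vidx, 2, hi, "<=")))
  hu <- ph$ct$data
  expect_lt(abs(mean(hu[!ph$lung_both$mask & hu < -500]) + 1000), 30)
  parench <- ph$lung_both$mask & !v & !ph$airway
  expect_lt(abs(mean(hu[parench]) + 750), 20)
  expect_lt(abs(mean(hu[v & ph$lung_both$mask & !ph$airway]) - 50), 10)
  expect_lt(abs(mean(hu[abs(hu) < 200 & !ph$lung_both$mask])), 20)
})

test_that("overlapping lungs are a spec error", {
  expect_error(make_lung_phantom(phantom_spec(lung_center_x = 20)),
               "spec error")
})

test_that("generators are pure functions of their seed", {
  s <- small_spec(seed = 21)
  a <- make_lung_phantom(s); b <- make_lung_phantom(s)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$tree$nodes, b$tree$nodes)
  d1 <- make_dose(a); d2 <- make_dose(b)
  expect_identical(d1$data, d2$data)
  k <- kinetic_model(noise_sd = 3)
  c1 <- make_contrast_study(a, k, seed = 5)
  c2 <- make_contrast_study(b, k, seed = 5)
  expect_identical(c1$frames[[4]]$data, c2$frames[[4]]$data)
})

test_that("the dose model honours its closed form and lung constraints", {
  ph <- small_phantom()
  dose <- small_dose()
  tree <- attr(dose, "tree")
  centre <- as.numeric(tree$nodes[match("MD", tree$nodes$id),
                                  c("x", "y", "z")])
  # Gaussian closed form at an ipsilateral grid voxel
  probe <- which(ph$lung_ipsi$mask, arr.ind = TRUE)[50, ]
  p <- ph$ct$origin + (probe - 1) * ph$ct$spacing
  expected <- 60 * exp(-sum((p - centre)^2) / (2 * 18^2))
  expect_equal(dose$data[probe[1], probe[2], probe[3]], expected,
               tolerance = 1e-6)
  expect_gt(max(dose$data), 59)
  expect_lt(max(dose$data[ph$lung_contra$mask]), 5)
  expect_error(make_dose(ph, sigma_mm = 500), "spec error")
})

test_that("breathing construction carries exact analytic Jacobians", {
  ph <- small_phantom()
  flat <- image_volume(array(1, dim(ph$ct$data)), ph$ct$spacing,
                       ph$ct$origin)
  bs0 <- make_breathing_series(ph, flat, n_phases = 3)
  expect_equal(max(abs(bs0$fields[[1]]$uz)), 0)
  expect_equal(max(abs(bs0$series$phases[[2]]$data - ph$ct$data)), 0)

  uni <- image_volume(array(1.331, dim(ph$ct$data)), ph$ct$spacing,
                      ph$ct$origin)
  expect_warning(bs1 <- make_breathing_series(ph, uni, n_phases = 2),
                 NA)
  expect_equal(max(abs(bs1$analytic_jacobians[[1]]$data - 1.331)), 0,
               tolerance = 0.02 * 1.331)
  # the finite-difference Jacobian of the sampled field agrees interiorly
  J <- jacobian_map(bs1$fields[[1]])$data
  inner <- J[5:44, 5:44, 5:44]
  expect_lt(max(abs(inner - 1.331)), 0.02 * 1.331)

  # the pipeline on the true fields recovers the target field
  ph2 <- small_phantom()
  dose <- small_dose()
  model <- make_expansion_model(ph2, dose, seed = 3)
  bs <- make_breathing_series(ph2, model$pre, n_phases = 4)
  m <- ler_n(lapply(bs$fields, jacobian_map))
  lung <- ph2$lung_both$mask
  expect_lt(mean(abs(m$data[lung] - model$pre$data[lung]) /
                   model$pre$data[lung]), 0.02)
})

test_that("a target outside the small-deformation regime warns", {
  ph <- small_phantom()
  big <- image_volume(array(1.7, dim(ph$ct$data)), ph$ct$spacing,
                      ph$ct$origin)
  expect_warning(make_breathing_series(ph, big, n_phases = 2),
                 "construction warning")
})

test_that("contrast timelines are validated", {
  ph <- small_phantom()
  expect_error(make_contrast_study(ph, kinetic_model(t0 = -1)),
               "timeline error")
  expect_error(
    make_contrast_study(ph, kinetic_model(t0 = 2), times = seq(0, 40, 2)),
    "pre-injection")
})

test_that("the expansion model stays within the designed value ranges", {
  ph <- small_phantom()
  dose <- small_dose()
  model <- make_expansion_model(ph, dose, seed = 5)
  reg <- model$regions
  expect_true(reg$target_pre[reg$region == "HHV"] >= 1.25 &&
                reg$target_pre[reg$region == "HHV"] <= 1.48)
  expect_true(reg$target_pre[reg$region == "LLV"] >= 1.02 &&
                reg$target_pre[reg$region == "LLV"] <= 1.1)
  expect_true(reg$target_pre[reg$region == "HLV"] >= 1.2 &&
                reg$target_pre[reg$region == "HLV"] <= 1.27)
  expect_true(reg$target_post[reg$region == "HLV"] >= 1.03 &&
                reg$target_post[reg$region == "HLV"] <= 1.1)
})

test_that("pathology sampling is monotone in dose and has a null model", {
  asg <- data.frame(subject = rep(sprintf("S%03d", 1:400), each = 2),
                    contour = rep(c("MD", "CON"), 400),
                    dose_level = rep(c("MaxDose", "NoDose"), 400),
                    fed_status = NA_character_,
                    change_class = rep(c("Decline", "Stable"), 400))
  pa <- make_pathology(asg, seed = 2)
  g <- parse_collagen_grade(pa$collagen$grade_label)
  expect_gt(mean(g[pa$collagen$contour == "MD"]),
            mean(g[pa$collagen$contour == "CON"]))
  null <- make_pathology(asg, pathology_effect_model(effect_scale = 0),
                         seed = 2)
  expect_true(all(null$collagen$grade_label == "no significant"))
  expect_equal(nrow(null$diagnoses), 0L)
  again <- make_pathology(asg, seed = 2)
  expect_identical(pa$collagen, again$collagen)
})

test_that("packaged study tables load with verified checksums", {
  fb <- load_study_fixture("groupB")
  expect_equal(nrow(fb$ventilation), 45L)
  expect_equal(sort(unique(fb$ventilation$contour)),
               sort(c("MD", "LDF", "LDNF", "NDF", "NDNF", "CON", "HHV",
                      "HLV", "LLV")))
  con <- fb$collagen[fb$collagen$contour == "CON", ]
  expect_true(all(parse_collagen_grade(con$grade_label) == 0))
  fa <- load_study_fixture("groupA")
  tal <- diagnosis_tally(fa$diagnoses)
  expect_equal(tally_count(tal, "MD", "red_blood_cell_proliferation"), 4L)
})
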