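flat_series <- function(value = 50, n = 6) {
  frames <- lapply(1:n, function(i)
    toy_volume(array(value, c(4, 4, 4))))
  contrast_series(frames, seq_len(n))
}

test_that("curve extraction averages the ROI per frame", {
  s <- flat_series(50)
  roi <- full_mask(s$frames[[1]], label = "vessel-bin")
  cu <- extract_curve(s, roi, n_precontrast = 2)
  expect_equal(cu$values, rep(50, 6))
  # single-voxel ROI follows that voxel exactly
  frames <- lapply(1:5, function(i) {
    a <- array(0, c(4, 4, 4)); a[2, 2, 2] <- i * 10; toy_volume(a)
  })
  s2 <- contrast_series(frames, 1:5)
  sel <- array(FALSE, c(4, 4, 4)); sel[2, 2, 2] <- TRUE
  roi1 <- roi_mask(sel, frames[[1]], label = "vessel-bin")
  expect_equal(extract_curve(s2, roi1, 1)$values, (1:5) * 10)
  expect_error(extract_curve(s, roi, n_precontrast = 6), "n_precontrast")
})

test_that("automatic pre-contrast detection finds the onset frame", {
  vals <- c(-800, -801, -799, -800, -500, -300, -400)
  cu <- contrast_curve(1:7, vals, n_precontrast = 4)
  frames <- lapply(vals, function(v) toy_volume(array(v, c(4, 4, 4))))
  s <- contrast_series(frames, 1:7)
  auto <- extract_curve(s, full_mask(frames[[1]], "vessel-bin"))
  expect_equal(auto$n_precontrast, 4L)
})

test_that("baseline, peak enhancement and AUC match hand values", {
  cu <- contrast_curve(c(0, 10), c(-800, -800), n_precontrast = 1)
  expect_equal(baseline_hu(cu), -800)
  cu2 <- contrast_curve(1:3, c(-810, -790, -500), n_precontrast = 2)
  expect_equal(baseline_hu(cu2), -800)
  expect_equal(peak_enhancement(cu2), 300)
  flat <- contrast_curve(1:4, rep(5, 4), n_precontrast = 1)
  expect_equal(peak_enhancement(flat), 0)
  expect_equal(curve_auc(flat), 0)
  tri <- contrast_curve(c(-5, 0, 10, 20), c(0, 0, 100, 0),
                        n_precontrast = 1)
  expect_equal(curve_auc(tri), 1000)
})

test_that("AUC reproduces the gamma-variate closed-form integral", {
  A <- 5; alpha <- 2; beta <- 3
  t <- seq(0, 60, by = 0.05)
  y <- A * t^alpha * exp(-t / beta)
  cu <- contrast_curve(c(-1, t), c(0, y), n_precontrast = 1)
  expect_equal(curve_auc(cu), A * beta^(alpha + 1) * gamma(alpha + 1),
               tolerance = 0.01)
})

test_that("AUC is linear in the curve and invariant to time shifts", {
  set.seed(3)
  t <- seq(0, 30, by = 1)
  y <- c(rep(0, 3), abs(rnorm(28, 50, 20)))
  cu <- contrast_curve(t, y, n_precontrast = 3)
  cu3 <- contrast_curve(t, 3 * y, n_precontrast = 3)
  expect_equal(curve_auc(cu3), 3 * curve_auc(cu))
  shifted <- contrast_curve(t + 17, y, n_precontrast = 3)
  expect_equal(curve_auc(shifted), curve_auc(cu))
})

test_that("peak enhancement is non-negative exactly when warranted", {
  dec <- contrast_curve(1:5, c(10, 10, 8, 6, 5), n_precontrast = 2)
  expect_equal(peak_enhancement(dec), 0)
  up <- contrast_curve(1:5, c(10, 10, 30, 6, 5), n_precontrast = 2)
  expect_gt(peak_enhancement(up), 0)
})

test_that("pre/post deltas subtract metrics and check ROI pairing", {
  m1 <- list(baseline = -800, peak_enhancement = 300, auc = 1000,
             roi_label = "MD")
  expect_equal(delta_pre_post(m1, m1, "auc"), 0)
  m2 <- m1; m2$peak_enhancement <- 200
  expect_equal(delta_pre_post(m1, m2, "peak_enhancement"), -100)
  m3 <- m2; m3$roi_label <- "CON"
  expect_error(delta_pre_post(m1, m3, "auc"), "pairing error")
})

test_that("noiseless generator recovers peak A and AUC effect multipliers", {
  ph <- small_phantom()
  dose <- small_dose()
  kin <- kinetic_model(noise_sd = 0)
  pre <- make_contrast_study(ph, kin, post = FALSE, seed = 1)
  post <- make_contrast_study(ph, kin, post = TRUE, dose = dose, seed = 1)
  tree <- attr(dose, "tree")
  fed <- tree_descendants(tree, ph$md_node)
  low_fed <- fed[tree$nodes$dose[match(fed, tree$nodes$id)] < 25][1]
  roi <- vessel_node_roi(ph, low_fed)
  cpre <- extract_curve(pre, roi, 3)
  expect_equal(peak_enhancement(cpre), kin$A, tolerance = 1e-8)
  cpost <- extract_curve(post, roi, 3)
  ratio <- curve_auc(cpost) / curve_auc(cpre)
  expect_equal(ratio, kin$fed_mult, tolerance = 0.02)
  # and an unirradiated, not-fed vessel is unchanged
  roi_con <- vessel_node_roi(ph, "C-MD")
  r_con <- curve_auc(extract_curve(post, roi_con, 3)) /
    curve_auc(extract_curve(pre, roi_con, 3))
  expect_equal(r_con, 1, tolerance = 0.02)
})

test_that("dose-binned deltas vanish for identical series and drop empty bins", {
  ph <- small_phantom()
  dose <- small_dose()
  kin <- kinetic_model(noise_sd = 0)
  pre <- make_contrast_study(ph, kin, post = FALSE, seed = 1)
  ids <- attr(dose, "tree")$nodes$id
  vrois <- lapply(ids[c(4, 6, 10)], function(id) vessel_node_roi(ph, id))
  prois <- lapply(vrois, function(r)
    sphere_roi(ph$ct, roi_centroid(r), 10,
               within = ph$lung_both$mask & !(ph$vessel_label > 0L)))
  msgs <- capture.output(
    tab <- dose_binned_deltas(pre, pre, vrois, prois, dose, 3),
    type = "message")
  expect_true(all(tab$delta_metric == 0))
  expect_true(any(grepl("row omitted", msgs)))
  expect_lt(nrow(tab), 12)
})

test_that("vessel/parenchyma correlation recovers slope and flags degeneracy", {
  tab <- data.frame(bin_lo = rep(c(30, 40, 50), 2),
                    bin_hi = rep(c(40, 50, 60), 2),
                    tissue = rep(c("vessel", "parenchyma"), each = 3),
                    delta_metric = c(-10, -20, -30, 10, 20, 30))
  fit <- vessel_parenchyma_correlation(tab, min_dose = 25)
  expect_equal(fit$slope, -1)
  expect_equal(fit$pearson_r, -1)
  tab$delta_metric[4:6] <- 5
  fit2 <- vessel_parenchyma_correlation(tab, min_dose = 25)
  expect_true(fit2$degenerate)
  expect_equal(fit2$slope, 0)
  expect_error(vessel_parenchyma_correlation(tab[c(1, 4), ], min_dose = 35),
               "insufficient-data")
})

test_that("the generator's leakage slope is recovered from the dose bins", {
  ph <- small_phantom()
  dose <- small_dose()
  kin <- kinetic_model(noise_sd = 1, fed_mult = 1, par_slope = 0.6)
  pre <- make_contrast_study(ph, kin, post = FALSE, seed = 2)
  post <- make_contrast_study(ph, kin, post = TRUE, dose = dose, seed = 2)
  br <- dose_bin_rois(ph, dose)
  tab <- suppressMessages(
    dose_binned_deltas(pre, post, br$vessel, br$parenchyma, dose, 3,
                       pair_by_vessel = TRUE))
  fit <- vessel_parenchyma_correlation(tab, min_dose = 25)
  expect_equal(fit$slope, -0.6, tolerance = 0.1)
  expect_lt(fit$pearson_r, -0.9)
})
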