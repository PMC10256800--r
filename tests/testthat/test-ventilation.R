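make_field <- function(fun, n = 12, spacing = 2) {
  ref <- toy_volume(array(0, c(n, n, n)), spacing = rep(spacing, 3))
  g <- grid_coords(ref)
  d <- dim(ref$data)
  X <- array(rep(g$x, times = d[2] * d[3]), d)
  Y <- array(rep(rep(g$y, each = d[1]), times = d[3]), d)
  Z <- array(rep(g$z, each = d[1] * d[2]), d)
  u <- fun(X, Y, Z)
  displacement_field(u$x, u$y, u$z, ref)
}

interior <- function(d, margin = 2) {
  m <- array(FALSE, d)
  m[(1 + margin):(d[1] - margin), (1 + margin):(d[2] - margin),
    (1 + margin):(d[3] - margin)] <- TRUE
  m
}

test_that("jacobian_map matches analytic determinants of affine fields", {
  zero <- make_field(function(x, y, z)
    list(x = 0 * x, y = 0 * y, z = 0 * z))
  expect_equal(max(abs(jacobian_map(zero)$data - 1)), 0)

  iso <- make_field(function(x, y, z)
    list(x = 0.1 * x, y = 0.1 * y, z = 0.1 * z))
  J <- jacobian_map(iso)$data
  expect_equal(max(abs(J[interior(dim(J))] - 1.1^3)), 0, tolerance = 1e-6)

  diag2 <- make_field(function(x, y, z)
    list(x = 0.05 * x, y = 0.02 * y, z = 0 * z))
  J2 <- jacobian_map(diag2)$data
  expect_equal(max(abs(J2[interior(dim(J2))] - 1.05 * 1.02)), 0,
               tolerance = 1e-6)
})

test_that("jacobian_map is within 1% on smooth sinusoidal fields at 2 mm", {
  n <- 24; L <- 48; A <- 1.5
  f <- make_field(function(x, y, z)
    list(x = A * sin(2 * pi * x / L), y = 0 * y,
         z = A * cos(2 * pi * z / L)), n = n, spacing = 2)
  J <- jacobian_map(f)$data
  ref <- toy_volume(array(0, c(n, n, n)), spacing = c(2, 2, 2))
  g <- grid_coords(ref)
  Jx <- 1 + A * 2 * pi / L * cos(2 * pi * g$x / L)
  Jz <- 1 - A * 2 * pi / L * sin(2 * pi * g$z / L)
  Jtrue <- outer(outer(Jx, rep(1, n)), Jz)
  idx <- interior(dim(J))
  expect_lt(max(abs(J[idx] - Jtrue[idx]) / Jtrue[idx]), 0.01)
})

test_that("jacobian_map refuses axes that cannot take a gradient", {
  ref <- toy_volume(array(0, c(2, 5, 5)))
  f <- displacement_field(array(0, c(2, 5, 5)), array(0, c(2, 5, 5)),
                          array(0, c(2, 5, 5)), ref)
  expect_error(jacobian_map(f), "gradient error")
})

jmap <- function(vals, spacing = c(2, 2, 2)) {
  toy_volume(array(vals, c(4, 4, 4)), spacing = spacing)
}

test_that("ler_n is the max/min ratio over phases plus the exhale state", {
  expect_equal(ler_n(list(jmap(1.331)))$data[1], 1.331)
  m <- ler_n(list(jmap(1.2), jmap(0.95), jmap(1.05)))
  expect_equal(m$data[1], 1.2 / 0.95)
  expect_equal(ler_n(list(jmap(1), jmap(1)))$data[1], 1)
})

test_that("ler_n properties: >= 1, order-invariant, monotone in phases", {
  set.seed(42)
  for (rep in 1:5) {
    js <- lapply(1:4, function(i) jmap(runif(64, 0.8, 1.5)))
    m <- ler_n(js)
    expect_true(all(m$data >= 1))
    m_perm <- ler_n(js[c(3, 1, 4, 2)])
    expect_equal(m$data, m_perm$data)
    m_fewer <- ler_n(js[1:3])
    expect_true(all(m$data - m_fewer$data >= -1e-12))
  }
})

test_that("non-positive Jacobians invalidate voxels and are excluded", {
  bad <- jmap(1.2); bad$data[1, 1, 1] <- -0.1
  m <- ler_n(list(bad))
  expect_true(is.na(m$data[1, 1, 1]))
  roi <- roi_mask(array(TRUE, c(4, 4, 4)), bad, label = "lung")
  s <- roi_ventilation(m, roi)
  expect_equal(s$n_valid, 63)
  expect_equal(s$mean, 1.2)
})

test_that("effort correction scales excess expansion by the TV ratio", {
  m <- jmap(1.10)
  lung <- full_mask(m)
  expect_equal(effort_correct(m, lung, 1, 1)$data, m$data)
  corr <- effort_correct(m, lung, measured_tv = 0.5, reference_tv = 1)
  expect_equal(corr$data[1], 1.20)
  m1 <- jmap(1)
  expect_equal(effort_correct(m1, full_mask(m1), 0.3, 1)$data[1], 1)
  # downscaling can never push a map below 1
  low <- jmap(1.05)
  expect_true(all(effort_correct(low, full_mask(low), 2, 1)$data >= 1))
  expect_error(effort_correct(m, lung, 0, 1), "tidal volumes")
})

test_that("ventilation level thresholds behave exactly as printed", {
  expect_equal(as.character(classify_ventilation(
    c(1.25, 1.02, 1.15, 1.2, 1.1))),
    c("High", "Low", "Moderate", "High", "Low"))
  expect_error(classify_ventilation(NaN), "value error")
})

test_that("change classification uses strict ratio thresholds", {
  r <- classify_change(1.0, c(0.88, 0.95, 1.0, 0.94, 1.06, 1.0601))
  expect_equal(as.character(r$class),
               c("Decline", "Stable", "Stable", "Stable", "Stable",
                 "Increase"))
  expect_equal(r$ratio[1], 0.88)
  expect_equal(classify_change(1.3, 1.3)$ratio, 1)
  expect_error(classify_change(0, 1), "value error")
})

test_that("ROI summaries and contour change ratios are correct", {
  m <- jmap(1.2)
  roi <- full_mask(m)
  s <- roi_ventilation(m, roi)
  expect_equal(s$mean, 1.2); expect_equal(s$sd, 0)
  two <- jmap(1.0); two$data[1, 1, 1] <- 1.2
  sel <- array(FALSE, c(4, 4, 4)); sel[1:2, 1, 1] <- TRUE
  roi2 <- roi_mask(sel, two, label = "HHV")
  expect_equal(roi_ventilation(two, roi2)$mean, 1.1)
  pre <- jmap(1.2); post <- jmap(1.08)
  rc <- roi_change(pre, post, roi)
  expect_equal(rc$ratio, 1.08 / 1.2)
  expect_equal(rc$change_class, "Decline")
  rc2 <- roi_change(pre, post, roi, method = "mean_of_ratios")
  expect_equal(rc2$ratio, 1.08 / 1.2)
})

test_that("declining voxels localise the true declining region (Dice)", {
  ph <- small_phantom()
  lung <- ph$lung_both$mask
  base <- array(1, dim(lung)); base[lung] <- 1.2
  pre <- image_volume(base, ph$ct$spacing, ph$ct$origin)
  region <- sphere_roi(ph$ct, c(-40, 0, -10), 16, within = lung)$mask
  postd <- base; postd[region] <- 1.2 * 0.88
  post <- image_volume(postd, ph$ct$spacing, ph$ct$origin)
  bs_pre <- make_breathing_series(ph, pre, n_phases = 2)
  bs_post <- make_breathing_series(ph, post, n_phases = 2)
  m_pre <- ler_n(lapply(bs_pre$fields, jacobian_map))
  m_post <- ler_n(lapply(bs_post$fields, jacobian_map))
  ratio <- m_post$data / m_pre$data
  declined <- lung & !is.na(ratio) & ratio < 0.94
  dice <- 2 * sum(declined & region) / (sum(declined) + sum(region))
  expect_gte(dice, 0.95)
})
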