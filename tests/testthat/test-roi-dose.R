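toy_dose <- function(value, n = 8) {
  dose_grid(toy_volume(array(value, c(n, n, n)), spacing = c(2, 2, 2)))
}

corner_roi <- function(ref, label = "vessel-bin") {
  m <- array(FALSE, dim(ref$data)); m[1:2, 1:2, 1:2] <- TRUE
  roi_mask(m, ref, label = label, tissue = "vessel")
}

test_that("dose levels follow the 5/20 Gy rules with PTV precedence", {
  d3 <- toy_dose(3); d12 <- toy_dose(12); d30 <- toy_dose(30)
  roi <- corner_roi(d3)
  far <- array(FALSE, c(8, 8, 8)); far[7:8, 7:8, 7:8] <- TRUE
  ptv_far <- roi_mask(far, d3, label = "PTV")
  expect_equal(classify_dose_level(roi, d3, ptv_far), "NoDose")
  expect_equal(classify_dose_level(roi, d12, ptv_far), "LowDose")
  # boundary values are inclusive for the low-dose band
  expect_equal(classify_dose_level(roi, toy_dose(5), ptv_far), "LowDose")
  expect_equal(classify_dose_level(roi, toy_dose(20), ptv_far), "LowDose")
  expect_equal(classify_dose_level(roi, toy_dose(4.99), ptv_far), "NoDose")
  # intersecting the PTV wins regardless of dose
  ptv_here <- roi_mask(roi$mask, d3, label = "PTV")
  expect_equal(classify_dose_level(roi, d3, ptv_here), "MaxDose")
  expect_equal(
    suppressMessages(classify_dose_level(roi, d30, ptv_far)),
    "Unclassified")
})

test_that("fed status agrees with an exhaustive path oracle on random trees", {
  # brute-force oracle: enumerate the root-to-node path
  oracle <- function(nodes, vessel_id, md_id) {
    path <- character(0); cur <- vessel_id
    while (!is.na(cur)) {
      path <- c(path, cur)
      cur <- nodes$parent[match(cur, nodes$id)]
    }
    if (md_id %in% path[-1]) "Fed" else "NotFed"
  }
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    parent <- c(NA, vapply(2:n, function(i)
      as.character(sample(i - 1, 1)), character(1)))
    nodes <- data.frame(id = as.character(1:n), x = rnorm(n), y = rnorm(n),
                        z = rnorm(n), radius = 10 * 0.99^(1:n),
                        parent = parent)
    # make radii consistent with the tree ordering
    nodes$radius <- 10 - as.numeric(nodes$id) * 0.01
    tree <- vessel_tree(nodes)
    md <- as.character(sample(n, 1))
    for (v in as.character(sample(n, 12)))
      expect_equal(fed_status(tree, v, md), oracle(nodes, v, md),
                   label = paste("node", v, "md", md))
  }
})

test_that("direct children are Fed, siblings are not, the MD node itself is not", {
  nodes <- data.frame(id = c("r", "a", "b", "a1", "a1x"),
                      x = 0, y = 0, z = 0:4 * 10,
                      radius = c(5, 4, 4, 3, 2),
                      parent = c(NA, "r", "r", "a", "a1"))
  tree <- vessel_tree(nodes)
  expect_equal(fed_status(tree, "a1", "a"), "Fed")
  expect_equal(fed_status(tree, "a1x", "a"), "Fed")   # deep grandchild
  expect_equal(fed_status(tree, "b", "a"), "NotFed")
  expect_equal(fed_status(tree, "a", "a"), "NotFed")
  expect_error(fed_status(tree, "zz", "a"), "lookup error")
})

test_that("vessel trees validate structure and survive JSON round trips", {
  nodes <- data.frame(id = c("r", "a"), x = 0:1, y = 0, z = 0,
                      radius = c(2, 1), parent = c(NA, "r"))
  tree <- vessel_tree(nodes)
  path <- file.path(tempdir(), "tree.json")
  write_vessel_tree(tree, path)
  back <- read_vessel_tree(path)
  expect_equal(back$nodes$id, tree$nodes$id)
  expect_equal(back$root, "r")
  bad <- nodes; bad$parent <- c("a", "r")
  expect_error(vessel_tree(bad), "root")
  fat <- nodes; fat$radius <- c(1, 2)
  expect_error(vessel_tree(fat), "radius")
})

test_that("contralateral mirroring reflects across the mid-sagittal plane", {
  ph <- small_phantom()
  md <- sphere_roi(ph$ct, c(-40, 0, 25), 6, within = ph$lung_ipsi$mask,
                   label = "MD", tissue = "vessel")
  con <- mirror_contralateral(md, ph$lung_ipsi, ph$lung_contra)
  c_md <- roi_centroid(md); c_con <- roi_centroid(con)
  # symmetric phantom: mirrored centroid is equidistant from the midplane
  expect_lt(abs(abs(c_md[1]) - abs(c_con[1])), max(ph$ct$spacing))
  expect_lt(abs(c_md[3] - c_con[3]), 2 * max(ph$ct$spacing))
  expect_true(all(con$mask[!ph$lung_contra$mask] == FALSE))
  # a distant target raises a placement warning
  tiny <- array(FALSE, dim(ph$ct$data)); tiny[24, 24, 46] <- TRUE
  contra_far <- roi_mask(tiny, ph$ct, label = "lung-contra")
  expect_warning(
    mirror_contralateral(md, ph$lung_ipsi, contra_far),
    "placement warning")
})

test_that("ventilation point selection lands inside the designed regions", {
  ph <- small_phantom()
  lung <- ph$lung_ipsi$mask
  base <- array(1.15, dim(lung))
  centres <- list(HHV = c(-40, -20, -10), LLV = c(-40, 22, -25),
                  HLV = c(-44, 0, 25))
  pre <- base; post <- base
  paint <- function(a, c, v) {
    a[sphere_roi(ph$ct, c, 14)$mask] <- v; a
  }
  pre <- paint(pre, centres$HHV, 1.3); post <- paint(post, centres$HHV, 1.3)
  pre <- paint(pre, centres$LLV, 1.05); post <- paint(post, centres$LLV, 1.05)
  pre <- paint(pre, centres$HLV, 1.25); post <- paint(post, centres$HLV, 1.05)
  mpre <- image_volume(pre, ph$ct$spacing, ph$ct$origin)
  mpost <- image_volume(post, ph$ct$spacing, ph$ct$origin)
  vp <- select_ventilation_points(mpre, mpost, ph$lung_ipsi, radius_mm = 8)
  for (nm in c("HHV", "HLV", "LLV")) {
    expect_false(is.null(vp[[nm]]), label = nm)
    d <- sqrt(sum((roi_centroid(vp[[nm]]) - centres[[nm]])^2))
    expect_lt(d, 14)
  }
  # noiseless phantom: purity 1.0 gives the same centres as 0.9
  vp2 <- select_ventilation_points(mpre, mpost, ph$lung_ipsi,
                                   radius_mm = 8, purity = 1.0)
  for (nm in c("HHV", "HLV", "LLV"))
    expect_equal(roi_centroid(vp2[[nm]]), roi_centroid(vp[[nm]]))
})

test_that("a single-class lung yields only the matching point", {
  ph <- small_phantom()
  hi <- image_volume(array(1.3, dim(ph$ct$data)), ph$ct$spacing,
                     ph$ct$origin)
  vp <- suppressMessages(
    select_ventilation_points(hi, hi, ph$lung_ipsi, radius_mm = 8))
  expect_false(is.null(vp$HHV))
  expect_null(vp$HLV)
  expect_null(vp$LLV)
})
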