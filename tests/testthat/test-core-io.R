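test_that("volume read/write round-trips data, spacing and origin", {
  v <- toy_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                  spacing = c(1, 1, 3), origin = c(10, -5, 2))
  for (ext in c(".nii.gz", ".nii", ".mha", ".mhd")) {
    path <- file.path(tempdir(), paste0("rt", ext))
    write_volume(v, path)
    b <- read_volume(path)
    expect_equal(b$data, v$data, tolerance = 1e-12, ignore_attr = TRUE,
                 label = ext)
    expect_equal(b$spacing, v$spacing, tolerance = 1e-9)
    expect_equal(b$origin, v$origin, tolerance = 1e-9)
  }
})

test_that("a generated phantom survives a write/read round trip exactly", {
  ph <- small_phantom()
  path <- file.path(tempdir(), "phantom.mha")
  write_volume(ph$ct, path)
  b <- read_volume(path)
  expect_equal(max(abs(b$data - ph$ct$data)), 0)
  expect_equal(b$spacing, ph$ct$spacing)
})

test_that("unreadable or unsupported inputs raise format errors", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  bad <- file.path(tempdir(), "bad.txt")
  writeLines("hello", bad)
  expect_error(read_volume(bad), "format error")
  badmhd <- file.path(tempdir(), "bad.mhd")
  writeLines(c("ObjectType = Image", "NDims = 2", "DimSize = 4 4",
               "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL"),
             badmhd)
  expect_error(read_volume(badmhd), "dimensionality error")
})

test_that("image_volume enforces its invariants", {
  expect_error(image_volume(matrix(0, 3, 3)), "3D")
  expect_error(image_volume(array(0, c(1, 4, 4))), "at least 2")
  expect_error(image_volume(array(0, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "spacing")
})

test_that("resampling onto the same grid is the identity", {
  v <- toy_volume(array(rnorm(5^3), c(5, 5, 5)), spacing = c(2, 2, 2))
  for (interp in c("linear", "nearest")) {
    r <- resample_like(v, v, interp)
    expect_equal(r$data, v$data, tolerance = 1e-12)
  }
})

test_that("constants are interpolation-invariant inside the domain", {
  v <- toy_volume(array(7, c(6, 6, 6)), spacing = c(2, 2, 2))
  ref <- toy_volume(array(0, c(4, 4, 4)), spacing = c(1.7, 1.7, 1.7),
                    origin = c(1, 1, 1))
  r <- resample_like(v, ref, "linear")
  expect_true(all(r$data == 7))
})

test_that("a linear ramp resampled at half-spacing matches the analytic ramp", {
  d <- c(9, 5, 5)
  x <- array(rep((0:8) * 2, times = 25), d)   # f(x) = x, spacing 2 mm
  v <- toy_volume(x, spacing = c(2, 1, 1))
  ref <- toy_volume(array(0, c(15, 5, 5)), spacing = c(1, 1, 1))
  r <- resample_like(v, ref, "linear")
  g <- grid_coords(ref)
  expect_equal(r$data[, 3, 3], g$x, tolerance = 1e-6)
})

test_that("nearest-neighbour resampling of a mask stays binary", {
  m <- array(0, c(8, 8, 8)); m[3:5, 3:5, 3:5] <- 1
  v <- toy_volume(m, spacing = c(2, 2, 2))
  ref <- toy_volume(array(0, c(11, 11, 11)), spacing = c(1.4, 1.4, 1.4))
  r <- resample_like(v, ref, "nearest", fill = 0)
  expect_true(all(r$data %in% c(0, 1)))
})

test_that("ROI masks validate shape, occupancy and vocabulary", {
  v <- toy_volume()
  expect_error(roi_mask(array(FALSE, c(4, 4, 4)), v), "empty-ROI")
  expect_error(roi_mask(array(TRUE, c(3, 4, 4)), v), "shape")
  expect_error(roi_mask(array(TRUE, c(4, 4, 4)), v, label = "XYZ"),
               "unknown label")
  m <- roi_mask(array(TRUE, c(4, 4, 4)), v, label = "MD",
                tissue = "vessel")
  expect_s3_class(m, "roi_mask")
})

test_that("dose grids reject negatives and hot spots over the cap", {
  v <- toy_volume(array(10, c(4, 4, 4)))
  expect_s3_class(dose_grid(v, prescription = 60), "dose_grid")
  v$data[1] <- -1
  expect_error(dose_grid(v), ">= 0")
  v$data[1] <- 80
  expect_error(dose_grid(v, prescription = 60), "cap")
})

test_that("subject records encode the group contour sets", {
  a <- subject_record("p1", "A"); b <- subject_record("p2", "B")
  expect_true(all(a$contours %in% b$contours))
  expect_length(b$contours, 9L)
})

test_that("YAML configuration round-trips and fills defaults", {
  cfg_path <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("high_min: 1.25", "seed: 99"), cfg_path)
  cfg <- load_config(cfg_path)
  expect_equal(cfg$high_min, 1.25)
  expect_equal(cfg$seed, 99)
  expect_equal(cfg$decline_max, 0.94)
})
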