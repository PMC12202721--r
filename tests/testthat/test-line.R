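# build a small aTSC map directly for sampler tests; 3-mm slices so the
# 9-mm band depth spans one slice either side
mini_atsc <- function(data, spacing = c(1, 1, 3), valid = NULL) {
  v <- scalar_volume(data, spacing, units = "mM", valid = valid)
  class(v) <- c("atsc_map", class(v))
  v
}

test_that("a constant field samples to the constant everywhere in the band", {
  vol <- mini_atsc(array(42, c(12, 12, 5)))
  ln <- line_roi(c(5, 2), c(5, 9), slice_selection(3, 3))
  g <- sample_line_band(vol, ln)
  expect_true(all(g$values == 42, na.rm = TRUE))
  expect_false(anyNA(g$values))   # whole band inside the volume
  prof <- band_profile(g)
  expect_true(all(prof$value == 42))
  expect_equal(prof$n, rep(9L, length(prof$n)))
})

test_that("a field varying only along the line gives nine equal transverse
           samples per step", {
  arr <- array(0, c(12, 12, 5))
  for (j in 1:12) arr[, j, ] <- 10 * j
  vol <- mini_atsc(arr)
  ln <- line_roi(c(5, 2), c(5, 9), slice_selection(3, 3))  # along axis 2
  g <- sample_line_band(vol, ln)
  expect_true(all(apply(g$values, 1, function(r) length(unique(r)) == 1)))
  expect_equal(g$values[, 5], 10 * (3:10))
})

test_that("oblique line sampling matches an exhaustive nearest-voxel oracle", {
  set.seed(61)
  arr <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  vol <- mini_atsc(arr, spacing = c(1, 1, 3))
  start <- c(1.2, 0.7); end <- c(6.3, 5.9)
  ln <- line_roi(start, end, slice_selection(3, 3))
  g <- sample_line_band(vol, ln, band_mm = 9)
  u <- (end - start) / sqrt(sum((end - start)^2))
  v <- c(-u[2], u[1])
  offs <- expand.grid(lat = c(-1, 0, 1), thr = c(-1, 0, 1))
  n_steps <- floor(sqrt(sum((end - start)^2))) + 1
  for (s in seq_len(n_steps)) for (o in seq_len(9)) {
    pos <- start + (s - 1) * u + offs$lat[o] * 3 * v   # 3 px = 9mm/3 / 1mm
    k <- 3 + offs$thr[o] * 1                           # 9mm/3 / 3mm = 1 slice
    ij <- ceiling(pos - 0.5) + 1
    expected <- if (all(ij >= 1) && ij[1] <= 8 && ij[2] <= 8 &&
                    k >= 1 && k <= 5)
      arr[ij[1], ij[2], k] else NA_real_
    expect_identical(g$values[s, o], expected)
  }
})

test_that("invalid voxels and out-of-ROI samples become missing; profile
           averages the valid remainder", {
  arr <- array(1, c(12, 12, 5))
  valid <- array(TRUE, c(12, 12, 5))
  valid[5, , ] <- FALSE                 # kills the lat = -1 sample row
  vol <- mini_atsc(arr, valid = valid)
  ln <- line_roi(c(7, 2), c(7, 9), slice_selection(3, 3))
  g <- sample_line_band(vol, ln)        # lateral rows (0-based): 4, 7, 10
  expect_true(all(is.na(g$values[, c(3, 6, 9)])))  # lat = +1 offsets row 4
  prof <- band_profile(g)
  expect_equal(prof$n, rep(6L, length(prof$n)))
  expect_true(all(prof$value == 1))

  roi <- binary_mask(matrix(rep(c(FALSE, TRUE), c(5, 7)), 12, 12,
                            byrow = FALSE))  # rows 1:5 excluded
  g2 <- sample_line_band(vol, ln, roi = roi)
  expect_true(all(is.na(g2$values[, c(3, 6, 9)])))
  expect_false(anyNA(g2$values[, c(5, 8)]))  # lat 0 rows survive the ROI
})

test_that("profile distances are step positions in mm and translation leaves
           the profile unchanged", {
  set.seed(62)
  base <- array(0, c(20, 20, 5))
  patt <- matrix(rnorm(20 * 8), 20, 8)
  a1 <- base; a1[, 3:10, ] <- array(rep(patt, 5), c(20, 8, 5))
  a2 <- base; a2[, 9:16, ] <- array(rep(patt, 5), c(20, 8, 5))
  l1 <- line_roi(c(10, 2), c(10, 9), slice_selection(3, 3))
  l2 <- line_roi(c(10, 8), c(10, 15), slice_selection(3, 3))
  p1 <- band_profile(sample_line_band(mini_atsc(a1), l1))
  p2 <- band_profile(sample_line_band(mini_atsc(a2), l2))
  expect_equal(p1$value, p2$value)
  expect_equal(p1$distance, p2$distance)
  expect_equal(p1$distance, 0:7)
})

test_that("degenerate lines are rejected", {
  vol <- mini_atsc(array(1, c(6, 6, 3)))
  expect_error(line_roi(c(2, 2), c(2, 2), slice_selection(3, 2)), "coincide")
  short <- line_roi(c(2, 2), c(2, 3.2), slice_selection(3, 2))
  expect_error(sample_line_band(vol, short), "3 sampling steps")
  out <- line_roi(c(-30, -30), c(-30, -20), slice_selection(3, 2))
  expect_error(sample_line_band(vol, out), "outside")
})

test_that("line ROI JSON round-trips, including world coordinates", {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(list(slice_axis = 3, slice_index = 16,
                            start = c(47, 33), end = c(47, 49),
                            coordinate_space = "voxel"),
                       f, auto_unbox = TRUE, digits = NA)
  ln <- read_line_roi(f)
  expect_equal(ln$start, c(47, 33))
  expect_equal(ln$slice$index, 16L)
  expect_error(read_line_roi(tempfile()), "not found")

  # a world-coordinate line on a scaled grid equals its voxel twin
  arr <- array(rnorm(10 * 10 * 4), c(10, 10, 4))
  vol <- mini_atsc(arr, spacing = c(2, 2, 3))
  lv <- line_roi(c(4, 1), c(4, 8), slice_selection(3, 2))
  lw <- line_roi(c(8, 2), c(8, 16), slice_selection(3, 2), space = "world")
  gv <- sample_line_band(vol, lv, offsets_in_pixels = TRUE)
  gw <- sample_line_band(vol, lw, offsets_in_pixels = TRUE)
  expect_identical(gv$values, gw$values)
})

test_that("radial profile on the noiseless phantom recovers the gradient
           within discretization tolerance", {
  st <- make_phantom(noiseless_spec(), seed = 2)
  res <- run_quantify(run_config(study = st))
  expect_lt(abs(res$line$slope - st$truth$cmsg) / st$truth$cmsg, 0.10)
})
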