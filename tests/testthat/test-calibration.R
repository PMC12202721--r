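vol3 <- function(data, ...) scalar_volume(data, ...)

test_that("sensitivity profile normalization scales the maximum to one", {
  arr <- array(runif(27, 0.5, 2), c(3, 3, 3)); arr[2, 2, 2] <- 4
  p <- normalize_profile(vol3(arr))
  expect_equal(max(p$data), 1)
  expect_equal(p$data, arr / 4)
  expect_equal(normalize_profile(p)$data, p$data)   # idempotent
  expect_true(all(normalize_profile(vol3(array(3, c(2, 2, 2))))$data == 1))
  expect_error(normalize_profile(vol3(array(0, c(2, 2, 2)))), "positive")
})

test_that("sensitivity correction divides pixel-wise and guards zeros", {
  set.seed(41)
  sig <- vol3(array(runif(8^3, 1, 5), c(8, 8, 8)))
  prof <- vol3(array(runif(8^3, 0.2, 1), c(8, 8, 8)))
  out <- sensitivity_correct(sig, prof)
  expect_equal(out$data, sig$data / prof$data, tolerance = 1e-15)

  unif <- vol3(array(1, c(8, 8, 8)))
  expect_equal(sensitivity_correct(sig, unif)$data, sig$data)

  k <- 3.7
  expect_equal(sensitivity_correct(vol3(k * prof$data), prof)$data,
               array(k, c(8, 8, 8)))

  prof$data[1, 1, 1] <- 0
  guarded <- sensitivity_correct(sig, prof)
  expect_false(guarded$valid[1, 1, 1])
  expect_equal(guarded$data[1, 1, 1], 0)

  expect_error(sensitivity_correct(sig, vol3(array(1, c(4, 4, 4)))), "grid")
})

test_that("relative intensity threshold keeps exactly the pixels at or above
           the cut and is monotone in the fraction", {
  vol <- vol3(array(as.numeric(1:100), c(10, 5, 2)))
  m10 <- threshold_mask(vol, 0.10)
  expect_identical(which(m10$data), which(vol$data >= 10))
  expect_true(all(threshold_mask(vol, 0)$data))
  expect_true(all(threshold_mask(vol3(array(5, c(2, 2, 2))))$data))
  for (f in c(0.05, 0.3, 0.6)) {
    lo <- threshold_mask(vol, f)$data
    hi <- threshold_mask(vol, f + 0.2)$data
    expect_true(all(lo[hi]))   # larger fraction => subset
  }
  expect_error(threshold_mask(vol, 1), "\\[0, 1\\)")
})

test_that("SNR equals mean signal over noise sd (n-1), matching an
           independent computation", {
  set.seed(42)
  arr <- array(rnorm(1000, 50, 4), c(10, 10, 10))
  sroi <- binary_mask(array(rep(c(TRUE, FALSE), c(200, 800)), c(10, 10, 10)))
  nroi <- binary_mask(array(rep(c(FALSE, TRUE), c(700, 300)), c(10, 10, 10)))
  vol <- vol3(arr)
  got <- compute_snr(vol, sroi, nroi)
  x <- arr[sroi$data]; y <- arr[nroi$data]
  expect_equal(got,
               (sum(x) / length(x)) /
                 sqrt(sum((y - sum(y) / length(y))^2) / (length(y) - 1)),
               tolerance = 1e-12)
  # forced value: signal mean 12 over a noise ROI of known sd
  arr2 <- array(0, c(4, 4, 4)); arr2[1:8] <- 12
  arr2[33:64] <- c(rep(1, 16), rep(3, 16))
  s2 <- binary_mask(array(seq_len(64) <= 8, c(4, 4, 4)))
  n2 <- binary_mask(array(seq_len(64) > 32, c(4, 4, 4)))
  vol2 <- vol3(arr2)
  expect_equal(compute_snr(vol2, s2, n2), 12 / sd(arr2[33:64]))
  expect_error(compute_snr(vol2, s2, binary_mask(array(FALSE, c(4, 4, 4)))),
               "empty|2 voxels")
})

test_that("phantom regression recovers exact proportionality and flags
           degenerate input", {
  shp <- c(8, 8, 4)
  mk_roi <- function(i) {
    a <- array(FALSE, shp); a[i, 1:2, 1] <- TRUE
    binary_mask(a)
  }
  rois <- lapply(1:4, mk_roi)
  conc <- c(50, 75, 100, 125)
  arr <- array(0, shp)
  for (i in 1:4) arr[i, 1:2, 1] <- 2 * conc[i]
  ph <- reference_phantoms(conc, rois)
  fit <- fit_phantom_calibration(ph, vol3(arr), model = "origin")
  expect_equal(fit$m, 2.0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-12)
  expect_true(fit$physical)

  # equal signals: with-intercept slope is exactly 0, non-physical
  arr2 <- array(0, shp); for (i in 1:4) arr2[i, 1:2, 1] <- 80
  fit2 <- fit_phantom_calibration(ph, vol3(arr2), model = "intercept")
  expect_equal(fit2$m, 0)
  expect_false(fit2$physical)

  expect_error(reference_phantoms(c(100, 100), rois[1:2]), "distinct")
  expect_error(reference_phantoms(conc[1:2], rois[1:2][c(1, 1)]), "overlap")
})

test_that("noisy phantom regression matches the normal-equations oracle", {
  set.seed(43)
  shp <- c(8, 8, 4)
  rois <- lapply(1:4, function(i) {
    a <- array(FALSE, shp); a[i, 1:3, 2] <- TRUE; binary_mask(a)
  })
  conc <- c(50, 75, 100, 125)
  arr <- array(0, shp)
  for (i in 1:4) arr[i, 1:3, 2] <- 1.8 * conc[i] + rnorm(3, sd = 5)
  ph <- reference_phantoms(conc, rois)
  fit <- fit_phantom_calibration(ph, vol3(arr), model = "intercept")
  ms <- vapply(rois, function(r) mean(arr[r$data]), numeric(1))
  o <- oracle_ols(conc, ms)
  expect_equal(fit$m, o$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(fit$r_squared, o$r2, tolerance = 1e-10)
})

test_that("relaxation correction component matches an independently coded
           formula and its analytic reductions", {
  sq <- sequence_params(TR = 60, TE = 0.3, f = 0.6)
  indep <- function(T1, T2s, T2l, TR, TE, f)
    (1 - exp(-TR / T1)) * (f * exp(-TE / T2s) + (1 - f) * exp(-TE / T2l))
  for (med in c("kidney", "agarose")) {
    rp <- relaxation_params(med)
    expect_equal(correction_component(rp, sq),
                 indep(rp$T1, rp$T2s, rp$T2l, 60, 0.3, 0.6),
                 tolerance = 1e-12)
  }
  # TE = 0 and TR >> T1 saturate both factors to exactly 1
  rp <- relaxation_params("kidney")
  expect_identical(correction_component(rp, sequence_params(TR = 1e9 * rp$T1,
                                                            TE = 0)), 1)
  # f = 1 reduces to the mono-exponential closed form
  sq1 <- sequence_params(TR = 45, TE = 1.2, f = 1)
  expect_equal(correction_component(rp, sq1),
               (1 - exp(-45 / rp$T1)) * exp(-1.2 / rp$T2s),
               tolerance = 1e-12)
  sq0 <- sequence_params(TR = 45, TE = 1.2, f = 0)
  expect_equal(correction_component(rp, sq0),
               (1 - exp(-45 / rp$T1)) * exp(-1.2 / rp$T2l),
               tolerance = 1e-12)
})

test_that("correction component is within (0,1], increasing in TR and
           decreasing in TE", {
  rp <- relaxation_params("agarose")
  trs <- c(5, 10, 30, 60, 120, 500)
  vals_tr <- vapply(trs, function(tr)
    correction_component(rp, sequence_params(TR = tr, TE = 0.5)), numeric(1))
  expect_true(all(vals_tr > 0 & vals_tr <= 1))
  expect_true(all(diff(vals_tr) > 0))
  tes <- c(0, 0.15, 0.3, 1, 3, 10)
  vals_te <- vapply(tes, function(te)
    correction_component(rp, sequence_params(TR = 60, TE = te)), numeric(1))
  expect_true(all(diff(vals_te) < 0))
})

test_that("correction factor is the agarose/kidney component ratio", {
  sq <- sequence_params()
  k <- relaxation_params("kidney")
  a <- relaxation_params("agarose")
  expect_equal(correction_factor(a, k, sq),
               correction_component(a, sq) / correction_component(k, sq),
               tolerance = 1e-15)
  # identical media cancel exactly
  expect_equal(correction_factor(k, k, sq), 1)
  # TE = 0 reduces to the saturation-recovery ratio
  sq0 <- sequence_params(TR = 42, TE = 0)
  expect_equal(correction_factor(a, k, sq0),
               (1 - exp(-42 / a$T1)) / (1 - exp(-42 / k$T1)),
               tolerance = 1e-12)
})

test_that("aTSC map is c*S/m on valid voxels and inverts a known field", {
  set.seed(44)
  shp <- c(6, 6, 3)
  rois <- lapply(1:2, function(i) {
    a <- array(FALSE, shp); a[i, 1, 1] <- TRUE; binary_mask(a)
  })
  arr <- array(0, shp); arr[1, 1, 1] <- 100; arr[2, 1, 1] <- 200
  ph <- reference_phantoms(c(50, 100), rois)
  fit <- fit_phantom_calibration(ph, vol3(arr))   # m = 2 exactly

  conc <- array(runif(prod(shp), 50, 250), shp)
  cfac <- 0.93
  sig <- vol3(fit$m * conc / cfac)
  atsc <- compute_atsc(sig, fit, cfac)
  expect_equal(atsc$data, conc, tolerance = 1e-12)
  expect_equal(atsc$units, "mM")

  # per-voxel oracle on random input with a mask
  sig2 <- vol3(array(runif(prod(shp), 0, 10), shp))
  msk <- binary_mask(array(runif(prod(shp)) > 0.3, shp))
  out <- compute_atsc(sig2, fit, cfac, msk)
  expect_equal(out$data[msk$data], cfac * sig2$data[msk$data] / fit$m,
               tolerance = 1e-12)
  expect_true(all(out$data[!msk$data] == 0))
  expect_identical(out$valid, msk$data)

  fit$m <- -1
  expect_error(compute_atsc(sig2, fit, cfac), "positive")
})
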