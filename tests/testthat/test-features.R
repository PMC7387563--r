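test_that("FWHM of analytic Lorentzian and Gaussian surfaces is exact", {
  lor <- lorentz_surface(gamma_mm = 1)
  fw <- measure_fwhm(lor)
  expect_equal(fw$fwhm_x, 2.0, tolerance = 1e-3)
  expect_equal(fw$fwhm_y, 2.0, tolerance = 1e-3)
  gau <- gauss_surface(sigma_mm = 1)
  fg <- measure_fwhm(gau)
  expect_equal(fg$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-3)
  expect_equal(fg$fwhm, 2.3548, tolerance = 1e-3)
})

test_that("FWHM is invariant to whole-pixel translation of the peak", {
  a <- lorentz_surface(n = 81, gamma_mm = 0.8)
  b <- lorentz_surface(n = 81, gamma_mm = 0.8, center = c(35, 47))
  expect_equal(measure_fwhm(a)$fwhm, measure_fwhm(b)$fwhm, tolerance = 1e-9)
})

test_that("FWHM errors when the ROI does not reach half maximum", {
  wide <- lorentz_surface(n = 21, pitch_mm = 0.05, gamma_mm = 5)
  expect_error(measure_fwhm(wide), "ROI too small")
})

test_that("peak metrics recover analytic area and volume", {
  z <- lorentz_surface(n = 201, pitch_mm = 0.05, A = 2, gamma_mm = 1)
  pm <- peak_metrics(z, raw_max = 302)
  expect_equal(pm$amplitude, 2, tolerance = 1e-6)
  expect_equal(pm$area, pi, tolerance = 0.02)      # half-max disc, r = gamma
  g <- gauss_surface(n = 201, pitch_mm = 0.05, A = 1.5, sigma_mm = 0.6)
  pg <- peak_metrics(g)
  expect_equal(pg$volume, 2 * pi * 1.5 * 0.6^2, tolerance = 0.01)
  z0 <- matrix(0, 10, 10); attr(z0, "pitch_mm") <- 0.1
  p0 <- peak_metrics(z0)
  expect_equal(c(p0$amplitude, p0$area, p0$volume), c(0, 0, 0))
})

test_that("surface fits recover their own noiseless parameters", {
  lor <- lorentz_surface(n = 61, A = 1.7, gamma_mm = 1.2)
  fl <- fit_surface(lor, "lorentzian")
  expect_true(fl$converged)
  expect_equal(unname(fl$pars["A"]), 1.7, tolerance = 1e-3)
  expect_equal(unname(fl$pars["gx"]), 1.2, tolerance = 1e-3)
  expect_lt(fl$sse, 1e-3)
  gau <- gauss_surface(n = 61, A = 0.8, sigma_mm = 0.9)
  fg <- fit_surface(gau, "gaussian")
  expect_true(fg$converged)
  expect_equal(unname(fg$pars["sx"]), 0.9, tolerance = 1e-3)
  expect_lt(fg$sse, 1e-3)
})

test_that("model mismatch raises the SSE above the matched model", {
  gau <- gauss_surface(n = 61, A = 1, sigma_mm = 1)
  sse_match <- fit_surface(gau, "gaussian")$sse
  sse_mismatch <- fit_surface(gau, "lorentzian")$sse
  expect_gt(sse_mismatch, sse_match)
  expect_gt(sse_mismatch, 1e-4)
})

test_that("fit residuals reproduce the injected noise variance", {
  set.seed(31)
  sigma <- 0.05
  z <- lorentz_surface(n = 61, A = 2, gamma_mm = 1) +
    matrix(rnorm(61^2, sd = sigma), 61, 61)
  attr(z, "pitch_mm") <- 0.1
  f <- fit_surface(z, "lorentzian")
  expect_equal(f$mse, sigma^2, tolerance = 0.1)
})

test_that("ROI snaps to the local maximum and clips at frame edges", {
  shape <- lorentz_surface(n = 61, A = 1, gamma_mm = 0.7, center = c(31, 31))
  v <- synthetic_video(shape, pre = 1, on = 3, post = 1)
  roi_exact <- make_roi(v, c(31, 31))
  roi_off <- make_roi(v, c(28, 34))   # within the snap neighbourhood
  expect_equal(roi_exact$seed, c(31, 31))
  expect_equal(roi_off$rows, roi_exact$rows)
  expect_equal(roi_off$cols, roi_exact$cols)
  edge <- make_roi(v, c(2, 2))
  expect_gte(edge$rows[1], 1)
  expect_gte(edge$cols[1], 1)
  expect_error(make_roi(v, c(500, 1)), "outside")
})

test_that("excess frames subtract background and ignore constant offsets", {
  shape <- lorentz_surface(n = 41, A = 1, gamma_mm = 0.8)
  v <- synthetic_video(shape, pre = 1, on = 3, post = 1)
  roi <- make_roi(v)
  ex_pre <- excess_frame(v, roi, t = 0.5)
  expect_equal(max(abs(ex_pre)), 0, tolerance = 1e-12)
  v2 <- v
  v2$frames <- v$frames + 7.3
  ex1 <- excess_frame(v, roi)
  ex2 <- excess_frame(v2, roi)
  expect_equal(as.numeric(ex1), as.numeric(ex2), tolerance = 1e-10)
  # heating grows during exposure
  e_first <- excess_frame(v, roi, t = 1.2)
  expect_gt(max(ex1), max(e_first))
})

test_that("steady-state dispersion is zero for smoothly scaled flat scenes and tracks noise", {
  flat <- matrix(1, 31, 31)
  v <- synthetic_video(flat, pre = 1, on = 3, post = 1)
  roi <- structure(list(rows = c(5, 25), cols = c(5, 25), seed = c(16, 16),
                        background_frames = which(v$timestamps < 1)),
                   class = "fdti_roi")
  ss <- steady_state_std(v, roi)
  expect_lt(ss$spatial, 1e-10)
  # pure camera noise on a flat scene: averaging over the plateau window
  # leaves sigma / sqrt(n_frames)
  vn <- synthetic_video(flat * 0, pre = 1, on = 3, post = 1, noise_sd = 0.02,
                        seed = 12)
  nwin <- sum(vn$timestamps >= 3 & vn$timestamps <= 4)
  ssn <- steady_state_std(vn, roi)
  expect_equal(ssn$spatial, 0.02 / sqrt(nwin), tolerance = 0.25)
})

test_that("kinetic fits recover exact exponential constants", {
  shape <- gauss_surface(n = 31, A = 1, sigma_mm = 1)
  v <- synthetic_video(shape, tau_rise = 2, tau_decay = 3, pre = 1, on = 10,
                       post = 10)
  roi <- make_roi(v)
  kin <- fit_kinetics(v, roi)
  expect_false(kin$flagged)
  expect_equal(kin$tau_rise, 2, tolerance = 1e-3)
  expect_equal(kin$tau_decay, 3, tolerance = 1e-3)
  expect_gt(kin$r2_rise, 0.999)
  expect_gt(kin$r2_decay, 0.999)
})

test_that("feature extraction is deterministic and offset-invariant", {
  shape <- lorentz_surface(n = 41, A = 1.2, gamma_mm = 0.9)
  v <- synthetic_video(shape, noise_sd = 0.01, seed = 77)
  f1 <- extract_features(v)
  f2 <- extract_features(v)
  expect_identical(f1, f2)
  v2 <- v; v2$frames <- v$frames + 4.2
  f3 <- extract_features(v2)
  off_invariant <- setdiff(names(f1), c("t_max"))
  expect_equal(f1[, off_invariant], f3[, off_invariant], tolerance = 1e-6)
  expect_equal(f3$t_max - f1$t_max, 4.2, tolerance = 1e-9)
})

test_that("physical features scale with pixel pitch, not pixel count", {
  shape <- lorentz_surface(n = 61, pitch_mm = 0.1, A = 1, gamma_mm = 1)
  v1 <- synthetic_video(shape, pitch = 1e-4)
  f1 <- extract_features(v1)
  # same physical scene sampled twice as finely
  shape2 <- lorentz_surface(n = 121, pitch_mm = 0.05, A = 1, gamma_mm = 1)
  v2 <- synthetic_video(shape2, pitch = 5e-5)
  f2 <- extract_features(v2)
  expect_equal(f1$fwhm, f2$fwhm, tolerance = 0.01)
  expect_equal(f1$area, f2$area, tolerance = 0.03)
  expect_equal(f1$volume, f2$volume, tolerance = 0.03)
})
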