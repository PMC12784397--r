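# Detection, fitting, precision, drift, filtering, statistics, FRC.

test_that("wavelet detection finds isolated spots and nothing in blank frames", {
  expect_equal(nrow(detect_candidates(matrix(0, 32, 32))), 0)
  cam <- camera_model()
  one <- render_psf(0, psf_model("gaussian2d"), 2000, cam, 31)
  cand <- detect_candidates(one)
  expect_equal(nrow(cand), 1)
  expect_equal(unname(c(cand$row, cand$col)), c(16, 16))
  # two emitters 10 sigma apart
  two <- one
  two[, ] <- 0
  sep <- ceiling(10 * 1.05)
  p <- render_psf(0, psf_model("gaussian2d"), 2000, cam, 15)
  two[5:19, 3:17] <- two[5:19, 3:17] + p
  two[5:19, 3:17 + sep] <- two[5:19, 3:17 + sep] + p
  expect_equal(nrow(detect_candidates(two)), 2)
})

test_that("weighted least-squares fitting recovers noiseless spots exactly", {
  cam <- camera_model()
  psf <- psf_model("gaussian2d")
  roi <- render_psf(0, psf, 1000, cam, 15) + 10
  f <- fit_gaussian2d_wls(roi, cam, units = "photons")
  expect_true(f$ok)
  expect_equal(f$N, 1000, tolerance = 1e-4)
  expect_equal(f$b, 10, tolerance = 1e-4)
  expect_equal(f$sigma_px, 1.05, tolerance = 1e-4)
  expect_equal(f$x_px, 7.5, tolerance = 1e-4)
  # translation equivariance: shift by 0.3 px
  roi2 <- render_psf(0, psf, 1000, cam, 15,
                     offset_um = c(0.3 * cam$pixel_size_x_um, 0)) + 10
  f2 <- fit_gaussian2d_wls(roi2, cam, units = "photons")
  expect_equal(f2$x_px - f$x_px, 0.3, tolerance = 1e-3)
  expect_equal(f2$y_px, f$y_px, tolerance = 1e-3)
  # rejection path
  flat <- matrix(10, 15, 15)
  expect_false(fit_gaussian2d_wls(flat, cam, units = "photons")$ok)
})

test_that("the EMCCD precision formula behaves like a Cramer-Rao style bound", {
  expect_error(precision_emccd(0, 1), "positive")
  # monotone: decreasing in N, increasing in b
  ns <- c(500, 1000, 4000, 16000)
  expect_true(all(diff(precision_emccd(ns, 10)) < 0))
  bs <- c(0, 5, 20, 80)
  expect_true(all(diff(precision_emccd(2000, bs)) > 0))
  # b -> 0 equals the background-free expression
  s2 <- (1.05 * 0.158)^2 + 0.158^2 / 12
  expect_equal(precision_emccd(2000, 0),
               sqrt(s2 / 2000 * 2 * 16 / 9) * 1000, tolerance = 1e-12)
  # shot-limited: quadrupling N halves the uncertainty
  expect_equal(precision_emccd(4 * 2000, 0.01) / precision_emccd(2000, 0.01), 0.5,
               tolerance = 0.05)
})

test_that("Monte-Carlo fitting scatter matches the precision formula", {
  set.seed(123)
  cam <- camera_model()
  n_rep <- 120
  xs <- replicate(n_rep, {
    f <- fit_gaussian2d_wls(noisy_spot_photons(4320, 16.1), cam, units = "photons")
    if (f$ok) f$x_um else NA
  })
  emp_nm <- sd(xs, na.rm = TRUE) * 1000
  pred_nm <- precision_emccd(4320, 16.1, 1.05 * sqrt(0.157 * 0.159),
                             sqrt(0.157 * 0.159))
  expect_lt(abs(emp_nm - pred_nm) / pred_nm, 0.25)
})

test_that("double-helix fits invert the angle model over the full range", {
  cam <- camera_model()
  psf <- psf_model("double_helix")
  zs <- seq(-0.9, 0.9, by = 0.15)
  zf <- vapply(zs, function(z) {
    roi <- render_psf(z, psf, 5000, cam, 17, offset_um = c(0.02, -0.03)) + 2
    f <- fit_dh_double_gaussian(roi, psf, cam, units = "photons")
    if (f$ok) f$z_um else NA_real_
  }, numeric(1))
  fit <- lm(zf ~ zs)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-3)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_lt(abs(zf[which.min(abs(zs))]) * 1000, 1)  # |z(0)| below 1 nm
  # lobe exchange (180 degree rotation of the patch) leaves the fit unchanged
  roi <- render_psf(0.4, psf, 5000, cam, 17) + 2
  f1 <- fit_dh_double_gaussian(roi, psf, cam, units = "photons")
  f2 <- fit_dh_double_gaussian(roi[17:1, 17:1], psf, cam, units = "photons")
  expect_equal(f2$z_um, f1$z_um, tolerance = 1e-6)
  # single-lobe patch is rejected
  lone <- render_psf(0, psf_model("gaussian2d"), 3000, cam, 9) + 2
  expect_false(fit_dh_double_gaussian(lone, psf, cam, units = "photons")$ok)
})

test_that("fiducial drift correction removes injected drift and respects noise", {
  set.seed(31)
  nfr <- 1000
  drift_x <- seq(0, 0.05, length.out = nfr)  # 50 nm linear drift
  fid <- data.frame(frame = 1:nfr, id = 1,
                    x_um = 5 + drift_x + rnorm(nfr, sd = 0.002),
                    y_um = -3 + rnorm(nfr, sd = 0.002))
  locs <- data.frame(frame = 1:nfr, x_um = rnorm(nfr), y_um = rnorm(nfr))
  out <- drift_correct(locs, fid)
  sds <- attr(out, "fiducial_sd")
  expect_true(all(sds["post", ] <= sds["pre", ]))
  est <- attr(out, "drift")$x_um
  expect_lt(max(abs(est - (drift_x - mean(drift_x)))) * 1000, 5)
  # zero drift: correction stays below the localization noise
  fid0 <- data.frame(frame = 1:200, id = 1,
                     x_um = rnorm(200, sd = 0.002), y_um = rnorm(200, sd = 0.002))
  out0 <- drift_correct(data.frame(frame = 1:200, x_um = 0, y_um = 0), fid0)
  expect_lt(max(abs(attr(out0, "drift")$x_um)), 0.002)
  expect_error(drift_correct(locs, fid[0, ]), "fiducial")
})

test_that("threshold filtering removes exactly the offending records", {
  toy <- data.frame(frame = 1:5,
                    uncertainty_xy_nm = c(20, 150, 30, 40, 50),
                    photons = c(1e3, 1e4, 2e6, 5e3, 1e5))
  out <- suppressMessages(
    filter_localizations(toy, list(max_uncertainty_xy_nm = 100, max_photons = 1e6)))
  expect_equal(out$frame, c(1, 4, 5))
  expect_equal(unname(attr(out, "removed")), c(1, 1))
  # empty in, empty out; all-pass preserves order
  expect_equal(nrow(filter_localizations(toy[0, ], list(max_photons = 1e6))), 0)
  expect_identical(filter_localizations(toy, list(max_photons = 1e7))$frame, toy$frame)
  expect_error(filter_localizations(toy, list(max_uncertainty_z_nm = 50)), "missing column")
  expect_error(filter_localizations(toy, list(bogus = 1)), "unknown rule")
})

test_that("axial rescaling multiplies z by the index-mismatch factor only", {
  toy <- data.frame(frame = 1, x_um = 1.234, y_um = -0.567, z_um = 0.100)
  out <- rescale_axial(toy)
  expect_equal(out$z_um, 0.075)  # 100 nm -> 75 nm
  expect_identical(out$x_um, toy$x_um)
  expect_identical(out$y_um, toy$y_um)
  expect_identical(rescale_axial(toy, 1), toy)
  expect_error(rescale_axial(toy[c("frame", "x_um")], ), "z column")
})

test_that("region binning matches brute-force assignment and normalizes to region 1", {
  constructed <- data.frame(
    x_um = c(rep(0.5, 10), rep(1.5, 8), rep(2.5, 6), rep(3.5, 4), rep(4.5, 2)),
    y_um = 0)
  rs <- bin_regions(constructed, 5, axis = "x", bounds = c(0, 5))
  expect_equal(rs$count, c(10, 8, 6, 4, 2))
  expect_equal(rs$norm_count, c(1, 0.8, 0.6, 0.4, 0.2))
  # brute force oracle on random data
  set.seed(77)
  rand <- data.frame(x_um = runif(500, -3, 7), y_um = 0)
  rs2 <- bin_regions(rand, 5, bounds = c(-3, 7))
  edges <- seq(-3, 7, length.out = 6)
  brute <- vapply(1:5, function(r)
    sum(rand$x_um >= edges[r] &
          (rand$x_um < edges[r + 1] | (r == 5 & rand$x_um <= edges[6]))), numeric(1))
  expect_equal(rs2$count, brute)
  expect_equal(sum(rs2$count), nrow(rand))
  # uniform data: normalized counts within 3 sigma of multinomial sampling
  expect_true(all(abs(rs2$count - 100) < 3 * sqrt(500 * 0.2 * 0.8)))
  expect_warning(bin_regions(data.frame(x_um = c(4.9, 4.95), y_um = 0), 5,
                             bounds = c(0, 5)), "region 1")
})

test_that("signal-to-background ratios follow their definition and invariances", {
  locs <- data.frame(photons = 100 * 2 * pi * 0.165^2 / (0.157 * 0.159),
                     background = 10, sigma_um = 0.165)
  out <- compute_sbr(locs)
  expect_equal(out$sbr, 10)  # peak 100 photons/px over background 10
  double <- locs; double$photons <- double$photons * 2; double$background <- 20
  expect_equal(compute_sbr(double)$sbr, out$sbr)
  zero <- locs; zero$background <- 0
  expect_true(is.infinite(compute_sbr(zero)$sbr))
  # line-scan mode
  x <- seq(0, 5, by = 0.05)
  prof <- 100 * exp(-2 * (x - 2.5)^2 / 0.2^2) + 10
  expect_equal(compute_sbr_linescan(prof, 0.05, 1.6), 110 / 10, tolerance = 0.01)
})

test_that("FRC resolution is bounded, translation invariant and noise monotone", {
  set.seed(55)
  n <- 4000
  struct <- data.frame(x_um = runif(n, 0, 2), y_um = runif(n, 0, 0.02))
  with_noise <- function(s, sd_um)
    data.frame(x_um = s$x_um + rnorm(n, sd = sd_um),
               y_um = s$y_um + rnorm(n, sd = sd_um))
  r10 <- frc_resolution(with_noise(struct, 0.010), seed = 2)
  r30 <- frc_resolution(with_noise(struct, 0.030), seed = 2)
  expect_gt(r30, r10)
  # forced identical halves: perfect correlation, bounded by the render Nyquist
  locs <- with_noise(struct, 0.01)
  expect_equal(as.numeric(frc_resolution(locs, halves = list(1:n, 1:n))), 16)
  # translation invariance
  shifted <- locs
  shifted$x_um <- shifted$x_um + 5.3
  shifted$y_um <- shifted$y_um - 2.1
  expect_equal(as.numeric(frc_resolution(shifted, seed = 2)),
               as.numeric(frc_resolution(locs, seed = 2)), tolerance = 1e-9)
  expect_error(frc_resolution(locs[1:10, ]), "too few")
})

test_that("localizing a simulated movie recovers ground truth within prediction", {
  em <- emitter_set(data.frame(x_um = c(-2, 0.013, 1.5), y_um = c(-1, 0.5, 2.07),
                               z_um = 0), photon_rate = 4320, on_probability = 1)
  mv <- simulate_frames(em, "epi", psf_model("gaussian2d"), camera_model(),
                        n_frames = 20, seed = 3, fov_px = c(64, 64),
                        bg_photons_per_px = 16.1)
  locs <- localize_movie(mv)
  expect_equal(nrow(locs), 60)  # 3 emitters x 20 frames
  tr <- mv$truth
  errs <- vapply(seq_len(nrow(locs)), function(i) {
    d <- sqrt((tr$x_um - locs$x_um[i])^2 + (tr$y_um - locs$y_um[i])^2)
    min(d[tr$frame == locs$frame[i]])
  }, numeric(1))
  pred_nm <- median(locs$uncertainty_xy_nm)
  expect_lt(abs(median(errs) * 1000 / 1.18 - pred_nm) / pred_nm, 0.5)
  expect_equal(median(locs$photons), 4320, tolerance = 0.05)
  expect_equal(median(locs$background), 16.1, tolerance = 0.1)
})
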