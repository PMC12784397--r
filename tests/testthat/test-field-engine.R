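# Angular-spectrum propagation, ideal-lens Fourier mapping, volume synthesis.

test_that("zero-distance propagation is the exact identity", {
  f <- gaussian_field()
  g <- propagate_angular_spectrum(f, 0)
  expect_identical(g$amplitude, f$amplitude)
})

test_that("a uniform plane wave acquires only the phase exp(i 2 pi n d / lambda)", {
  n <- 64; d <- 0.5; lam <- 0.56; medium <- 1.33
  f <- scalar_field(matrix(1 + 0i, n, n), d, d, lam, medium)
  dist <- 7.3
  g <- propagate_angular_spectrum(f, dist, pad = 1)
  expected <- exp(1i * 2 * pi * medium * dist / lam)
  expect_lt(max(Mod(g$amplitude - expected)), 1e-12)
})

test_that("a Gaussian beam spreads by the closed-form w(z) law", {
  w0 <- 2; lam <- 0.56; medium <- 1.33
  f <- gaussian_field(w0 = w0, n = 256, d = 0.25, medium = medium)
  zr <- pi * medium * w0^2 / lam
  for (dist in c(15, 30, 60)) {
    g <- propagate_angular_spectrum(f, dist)
    prof <- Mod(g$amplitude[, 129])^2
    w_fit <- as.numeric(one_over_e2_radius(prof, 0.25))
    expect_equal(w_fit, w0 * sqrt(1 + (dist / zr)^2), tolerance = 0.01)
  }
})

test_that("power is conserved over 100 chained propagation steps", {
  f <- gaussian_field(w0 = 3, n = 128, d = 0.25)
  p0 <- field_power(f)
  g <- f
  for (i in 1:100) g <- propagate_angular_spectrum(g, 0.2)
  expect_lt(abs(field_power(g) - p0) / p0, 1e-6)
})

test_that("propagation composes additively in distance", {
  f <- gaussian_field(w0 = 2.5, n = 128, d = 0.25)
  g1 <- propagate_angular_spectrum(propagate_angular_spectrum(f, 8), 5)
  g2 <- propagate_angular_spectrum(f, 13)
  expect_lt(max(Mod(g1$amplitude - g2$amplitude)) / max(Mod(g2$amplitude)), 1e-8)
})

test_that("propagation rejects bad distances and aliased fields", {
  f <- gaussian_field()
  expect_error(propagate_angular_spectrum(f, NA), "finite")
  expect_error(propagate_angular_spectrum(f, Inf), "finite")
  # a checkerboard oscillates at the grid Nyquist frequency: severe aliasing
  n <- 64
  cb <- outer(1:n, 1:n, function(i, j) (-1)^(i + j)) + 0i
  bad <- scalar_field(cb, 0.5, 0.5, 0.56, 1)
  expect_error(propagate_angular_spectrum(bad, 5, pad = 1), "aliasing")
})

test_that("lens mapping sends a point source to a flat spectrum and conserves power", {
  n <- 128
  amp <- matrix(0i, n, n)
  amp[n / 2 + 1, n / 2 + 1] <- 1
  f <- scalar_field(amp, 1, 1, 0.56, 1)
  g <- lens_fourier(f, 1800)
  mags <- Mod(g$amplitude)
  expect_lt((max(mags) - min(mags)) / max(mags), 1e-12)
  expect_lt(abs(field_power(g) - field_power(f)) / field_power(f), 1e-9)
  expect_error(lens_fourier(f, -1), "positive")
})

test_that("applying the lens mapping twice returns the input spatially inverted", {
  n <- 128
  zc <- grid_coords(n, 0.25)
  amp <- outer(exp(-((zc - 3) / 2)^2), exp(-((zc + 1.5) / 2)^2)) + 0i
  f <- scalar_field(amp, 0.25, 0.25, 0.56, 1)
  h2 <- lens_fourier(lens_fourier(f, 900), 900)
  inverted <- amp[c(1, n:2), c(1, n:2)]  # periodic reflection about the center
  expect_lt(max(Mod(h2$amplitude - inverted)) / max(Mod(amp)), 1e-8)
})

test_that("two pupil slits 2.4 mm apart produce 0.42 um focal fringes", {
  train <- optical_train(sample_index = 1)
  mask <- mask_spec(slit_centers_mm = c(-1.2, 1.2), slit_width_mm = 0.08,
                    slit_length_mm = 1, optical_density = 12)
  n1 <- 2048; d1 <- 3
  bfp <- mask_transmission(mask, list(n1 = n1, n2 = 16, d1 = d1, d2 = 50), train)
  focal <- lens_fourier(bfp, train$focal_length_um)
  prof <- Mod(focal$amplitude[, 9])^2
  # fringe period from the mean spacing of the local maxima near the center
  ctr <- (n1 / 2 + 1) + (-60:60)
  p <- prof[ctr]
  peaks <- which(diff(sign(diff(p))) == -2) + 1
  period <- mean(diff(peaks)) * focal$dx
  expected <- 0.560 * 1800 / 2400  # lambda * f / d
  expect_lt(abs(period - expected), focal$dx)
})

test_that("volume synthesis validates its range and reproduces the focal plane", {
  f <- gaussian_field(w0 = 2, n = 128, d = 0.25)
  expect_error(synthesize_volume(f, 0, 0, 2), "x_min < x_max")
  expect_error(synthesize_volume(f, -5, 5, 1), ">= 2")
  vol <- synthesize_volume(f, -10, 10, 21)
  # plane at x = 0 equals |focal|^2 exactly
  j0 <- which(volume_x(vol) == 0)
  expect_identical(vol$intensity[, , j0], Mod(f$amplitude)^2)
  # free-space symmetry about the focus of an ideal (real) focal field
  rel <- max(abs(vol$intensity[, , 1] - vol$intensity[, , 21])) / max(vol$intensity)
  expect_lt(rel, 1e-6)
})
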