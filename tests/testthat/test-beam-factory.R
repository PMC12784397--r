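# Mask transmission, sheet construction, dithering, steering, mirror.

test_that("mask transmittance follows the optical density", {
  train <- optical_train()
  grid <- list(n1 = 512, n2 = 16, d1 = 10, d2 = 100)
  m <- mask_transmission(mask_spec(optical_density = 5.2), grid, train)
  amp <- Re(m$amplitude)
  expect_equal(min(amp), 10^(-2.6), tolerance = 1e-12)
  expect_equal(max(amp), 1)
  m0 <- mask_transmission(mask_spec(optical_density = 0), grid, train)
  expect_true(all(Re(m0$amplitude) == 1))
  expect_error(
    mask_transmission(mask_spec(slit_centers_mm = c(-5, 0, 5)), grid, train),
    "pupil")
})

test_that("open-area power fraction matches the direct slit-area integral", {
  train <- optical_train()
  grid <- list(n1 = 4096, n2 = 64, d1 = 1.5, d2 = 40)
  mask <- mask_spec(optical_density = Inf)
  m <- mask_transmission(mask, grid, train)
  open_power <- sum(Re(m$amplitude)^2) * grid$d1 * grid$d2
  slit_area <- 3 * (mask$slit_width_mm * 1000) * (mask$slit_length_mm * 1000)
  expect_equal(open_power, slit_area, tolerance = 0.01)
})

test_that("the gaussian sheet hits its waist, width flatness and closed-form range", {
  vol <- default_gaussian_sheet()
  expect_equal(vol$meta$focal_thickness_um, 1.8, tolerance = 0.01)
  # y-profile flat within 1% across the central half-width
  iy <- volume_y(vol)
  iz <- which.min(abs(volume_z(vol)))
  j0 <- which.min(abs(volume_x(vol)))
  sel <- abs(iy) <= 0.5 * 32.9
  prof <- vol$intensity[iz, sel, j0]
  expect_lt((max(prof) - min(prof)) / max(prof), 0.01)
  # effective range equals the confocal parameter 2 pi n w0^2 / lambda
  m <- ls_metrics(vol, restrict_central_lobe = FALSE)
  expect_equal(m$effective_range, 2 * pi * 1.33 * 1.8^2 / 0.56, tolerance = 0.05)
  # waist below the diffraction limit is rejected
  expect_error(
    make_gaussian_sheet(sheet_spec("gaussian", target_waist_w0 = 0.05), optical_train()),
    "diffraction limit")
})

test_that("the lattice sheet is symmetric in z and matches the target thickness", {
  vol <- default_lattice_sheet()
  expect_equal(vol$meta$focal_thickness_um, 1.8, tolerance = 0.05)
  j0 <- which.min(abs(volume_x(vol)))
  iy <- which.min(abs(volume_y(vol)))
  prof <- vol$intensity[, iy, j0]
  zc <- volume_z(vol)
  # symmetric slit pattern -> z-profile symmetric about z = 0
  n <- length(prof)
  ctr <- which.min(abs(zc))
  k <- min(ctr - 1, n - ctr)
  asym <- max(abs(prof[(ctr - k):(ctr + k)] - rev(prof[(ctr - k):(ctr + k)]))) / max(prof)
  expect_lt(asym, 1e-6)
})

test_that("matched-waist lattice outranges the gaussian sheet at least 1.5-fold", {
  ml <- ls_metrics(default_lattice_sheet())
  mg <- ls_metrics(default_gaussian_sheet())
  expect_gte(ml$effective_range / mg$effective_range, 1.5)
})

test_that("dither conserves per-plane energy and is the identity at amplitude zero", {
  vol <- default_gaussian_sheet()
  expect_identical(apply_dither(vol, 0)$intensity, vol$intensity)
  expect_error(apply_dither(vol, -1), "non-negative")
  dith <- apply_dither(vol, 3.5)
  sums0 <- apply(vol$intensity, 3, sum)
  sums1 <- apply(dith$intensity, 3, sum)
  expect_lt(max(abs(sums1 - sums0) / sums0), 1e-6)
})

test_that("dither attenuates a periodic y-structure by the sine-dwell (Bessel) factor", {
  # I(y) = 1 + cos(2 pi y / p): the time average over x -> y + A sin(phase)
  # attenuates the ripple by |J0(2 pi A / p)| (independent dense-quadrature
  # oracle below)
  ny <- 256; dy <- 0.1; p <- 1.6
  yc <- (seq_len(ny) - 1) * dy
  plane <- matrix(rep(1 + cos(2 * pi * yc / p), each = 4), 4, ny)
  vol <- beam_volume(array(rep(plane, 2), c(4, ny, 2)), dx = 1, dy = dy, dz = 1)
  oracle_ripple <- function(A) {
    th <- seq(0, 2 * pi, length.out = 20001)[-1]
    prof <- rowMeans(outer(yc, A * sin(th), function(y, s) 1 + cos(2 * pi * (y + s) / p)))
    (max(prof) - min(prof)) / 2 / mean(prof)
  }
  for (A in c(0.3827 * p, p)) {
    dith <- apply_dither(vol, A, n_phases = 256)
    prof <- dith$intensity[1, , 1]
    ripple <- (max(prof) - min(prof)) / 2 / mean(prof)
    expect_equal(ripple, oracle_ripple(A), tolerance = 0.02)
    expect_equal(ripple, abs(besselJ(2 * pi * A / p, 0)), tolerance = 0.02)
  }
})

test_that("steering follows the calibrated linear maps and composes additively", {
  expect_equal(steering_shift_um(steering_state(galvo_z_volts = 0.01))[["dz"]], 0.64)
  expect_equal(steering_shift_um(steering_state(galvo_z_volts = 0.05))[["dz"]], 3.20)
  expect_equal(steering_shift_um(steering_state(tunable_lens_mA = 10))[["dx"]], 2.41)
  expect_equal(steering_shift_um(steering_state(galvo_y_volts = 0.01))[["dy"]], 0.35)
  # 2x galvo response on the gaussian path
  expect_equal(steering_shift_um(steering_state(galvo_z_volts = 0.01), "gaussian")[["dz"]], 1.28)

  vol <- default_gaussian_sheet()
  # integer-voxel shifts compose exactly
  s1 <- steering_state(galvo_z_volts = 0.02)   # 1.28 um = 16 voxels
  s2 <- steering_state(galvo_z_volts = 0.03)   # 1.92 um = 24 voxels
  s12 <- steering_state(galvo_z_volts = 0.05)
  v_a <- steer_sheet(steer_sheet(vol, s1), s2)
  v_b <- steer_sheet(vol, s12)
  expect_equal(v_a$intensity, v_b$intensity)
  # fractional shifts compose up to the interpolation error
  f1 <- steering_state(galvo_y_volts = 0.04)
  f2 <- steering_state(galvo_y_volts = -0.01)
  f12 <- steering_state(galvo_y_volts = 0.03)
  v_c <- steer_sheet(steer_sheet(vol, f1), f2)
  v_d <- steer_sheet(vol, f12)
  expect_lt(max(abs(v_c$intensity - v_d$intensity)) / max(vol$intensity), 0.02)
  expect_error(steer_sheet(vol, steering_state(galvo_z_volts = 10)), "extent")
})

test_that("the micromirror reflects by 2*(45 - wall angle) and conserves intensity", {
  expect_error(mirror_spec(0), "between")
  expect_error(mirror_spec(95), "between")
  vol <- default_gaussian_sheet()
  # 45 degrees: horizontal propagation, exact identity
  r45 <- reflect_at_mirror(vol, mirror_spec(45))
  expect_identical(r45$intensity, vol$intensity)
  expect_equal(r45$meta$tilt_deg, 0)
  r39 <- reflect_at_mirror(vol, mirror_spec(39))
  expect_equal(r39$meta$tilt_deg, 12)
  expect_lt(abs(sum(r39$intensity) - sum(vol$intensity)) / sum(vol$intensity), 1e-6)
  # measured axis tilt: slope of the z-centroid along x
  centroid <- function(v) {
    zc <- volume_z(v)
    apply(v$intensity[, which.min(abs(volume_y(v))), ], 2, function(p) sum(p * zc) / sum(p))
  }
  xs <- volume_x(vol)
  sel <- abs(xs) < 30  # stay clear of shear wrap-around at the x-borders
  slope <- coef(lm(centroid(r39)[sel] ~ xs[sel]))[2]
  expect_equal(as.numeric(atan(slope) * 180 / pi), -12, tolerance = 0.05)
})
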