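# Phantoms, PSF rendering, EMCCD camera chain.

test_that("phantoms are deterministic and respect their geometry", {
  shell <- make_cell_phantom("nuclear_shell",
                             list(semi_axes_um = c(4, 3, 2),
                                  shell_thickness_um = 0.1), seed = 5)
  # all emitters close to the ellipsoid surface
  r <- sqrt((shell$x_um / 4)^2 + (shell$y_um / 3)^2 + (shell$z_um / 2)^2)
  expect_true(all(abs(r - 1) < 0.1 / 2 + 1e-9))
  expect_identical(shell,
                   make_cell_phantom("nuclear_shell",
                                     list(semi_axes_um = c(4, 3, 2),
                                          shell_thickness_um = 0.1), seed = 5))
  expect_equal(nrow(make_cell_phantom("two_plane", list(n_emitters = 0), seed = 1)), 0)
})

test_that("two-plane phantom counts follow Poisson sampling statistics", {
  lam <- 2 * (2 * 5)^2  # density * area per plane
  counts <- vapply(1:20, function(s)
    nrow(make_cell_phantom("two_plane", list(density_per_um2 = 2, fov_um = 5),
                           seed = s)), numeric(1))
  expect_true(all(abs(counts - 2 * lam) < 3 * sqrt(2 * lam) + 3 * sqrt(2 * lam) * 0.5))
  expect_lt(abs(mean(counts) - 2 * lam) / (2 * lam), 0.1)
})

test_that("rendered patches integrate to the photon count with centered centroids", {
  cam <- camera_model()
  for (psf in list(psf_model("gaussian2d"), psf_model("double_helix"))) {
    p <- render_psf(0.3, psf, 1000, cam, 17)
    expect_equal(sum(p), 1000, tolerance = 0.005)
    xs <- (1:17) - 0.5
    cx <- sum(colSums(p) * xs) / sum(p)
    cy <- sum(rowSums(p) * xs) / sum(p)
    # lobe midpoint / spot center at the patch center, within 1 nm
    expect_lt(abs(cx - 8.5) * cam$pixel_size_x_um * 1000, 1)
    expect_lt(abs(cy - 8.5) * cam$pixel_size_y_um * 1000, 1)
  }
})

test_that("double-helix lobes rotate linearly and mirror in z", {
  psf <- psf_model("double_helix")
  angle_of <- function(z) {
    p <- render_psf(z, psf, 1000, camera_model(), 17)
    hits <- which(p == max(p), arr.ind = TRUE)[1, ]
    atan2(hits[1] - 9, hits[2] - 9) * 180 / pi
  }
  expect_equal(unname(angle_of(0)) %% 180, 0)  # lobe axis along theta0 = 0
  a_plus <- render_psf(0.4, psf, 1e3, camera_model(), 17)
  a_minus <- render_psf(-0.4, psf, 1e3, camera_model(), 17)
  # theta(z) - theta0 = -(theta(-z) - theta0): -z patch is the y-mirror image
  expect_equal(a_plus, a_minus[17:1, ], tolerance = 1e-3)
  expect_error(render_psf(1.5, psf, 1e3), "range")
})

test_that("a camera-only movie sits at the dark level", {
  mv <- simulate_frames(emitter_set(data.frame(x_um = numeric(0), y_um = numeric(0),
                                               z_um = numeric(0))),
                        "epi", psf_model("gaussian2d"), camera_model(),
                        n_frames = 4, seed = 1, fov_px = c(32, 32),
                        bg_photons_per_px = 0)
  m <- mean(unlist(mv$frames))
  # mean read noise in ADU is ~read_noise/conversion/sqrt(n) ~ 0.1
  expect_equal(m, 500, tolerance = 1e-3)
})

test_that("the EM gain chain reproduces mean and excess-noise variance", {
  cam <- camera_model()
  em <- emitter_set(data.frame(x_um = 0, y_um = 0, z_um = 0),
                    photon_rate = 2000, on_probability = 1)
  mv <- simulate_frames(em, "epi", psf_model("gaussian2d"), cam,
                        n_frames = 500, seed = 2, fov_px = c(21, 21),
                        bg_photons_per_px = 0)
  ints <- vapply(mv$frames, function(f) sum(f - cam$dark_level), numeric(1))
  expected_mean <- 2000 * cam$em_gain / cam$conversion_gain
  expect_equal(mean(ints), expected_mean, tolerance = 0.02)
  # Var(sum ADU) = N (2 g^2 - g) / c^2 + n_px (read / c)^2
  expected_var <- 2000 * (2 * cam$em_gain^2 - cam$em_gain) / cam$conversion_gain^2 +
    21^2 * (cam$read_noise / cam$conversion_gain)^2
  expect_equal(var(ints), expected_var, tolerance = 0.10)
})

test_that("sheet illumination extinguishes emitters far above the plane", {
  beam <- make_gaussian_sheet(sheet_spec("gaussian"), optical_train(),
                              x_range_um = c(-10, 10), n_planes = 5,
                              grid = list(n1 = 256, d1 = 0.08, n2 = 32, d2 = 2))
  em <- emitter_set(data.frame(x_um = c(0, 0), y_um = c(-2, 2),
                               z_um = c(0, 5 * 1.8)),
                    photon_rate = 5000, on_probability = 1)
  mv <- simulate_frames(em, beam, psf_model("gaussian2d"), camera_model(),
                        n_frames = 20, seed = 3, fov_px = c(48, 48),
                        bg_photons_per_px = 0)
  tr <- mv$truth
  sig_in <- sum(tr$photons[tr$z_um == 0])
  sig_out <- sum(tr$photons[tr$z_um > 0])
  expect_lt(sig_out, 0.01 * sig_in)
})

test_that("movies are fully deterministic under a fixed seed", {
  em <- make_cell_phantom("two_plane", list(fov_um = 3, density_per_um2 = 0.3), seed = 4)
  mv1 <- simulate_frames(em, "epi", psf_model("gaussian2d"), camera_model(),
                         n_frames = 5, seed = 9, fov_px = c(32, 32))
  mv2 <- simulate_frames(em, "epi", psf_model("gaussian2d"), camera_model(),
                         n_frames = 5, seed = 9, fov_px = c(32, 32))
  expect_identical(mv1$frames, mv2$frames)
  expect_identical(mv1$truth, mv2$truth)
})
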