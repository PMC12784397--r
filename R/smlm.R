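#' EMCCD camera model
#'
#' Gain chain and pixel geometry of the electron-multiplying CCD used for
#' acquisition. Signal photoelectrons pass through the electron-multiplying
#' register (mean gain `em_gain`, modeled as a Gamma cascade with excess
#' noise factor 2), read noise is added in electrons, and the result is
#' digitized at `conversion_gain` photoelectrons per A/D count on top of a
#' constant dark level.
#'
#' @param em_gain calibrated electron-multiplying gain (default 182).
#' @param conversion_gain photoelectrons per A/D count (default 4.41).
#' @param dark_level A/D counts offset (default 500).
#' @param read_noise read noise, electrons RMS (default 50).
#' @param pixel_size_x_um,pixel_size_y_um calibrated pixel pitch in the
#'   sample plane: 0.157 um horizontally, 0.159 um vertically.
#' @param excess_noise_factor EM excess noise factor (default 2).
#' @return Object of class `camera_model`.
#' @export
camera_model <- function(em_gain = 182, conversion_gain = 4.41, dark_level = 500,
                         read_noise = 50, pixel_size_x_um = 0.157,
                         pixel_size_y_um = 0.159, excess_noise_factor = 2) {
  if (em_gain <= 0 || conversion_gain <= 0) stop("gains must be positive")
  if (pixel_size_x_um <= 0 || pixel_size_y_um <= 0) stop("pixel sizes must be positive")
  structure(list(em_gain = em_gain, conversion_gain = conversion_gain,
                 dark_level = dark_level, read_noise = read_noise,
                 pixel_size_x_um = pixel_size_x_um, pixel_size_y_um = pixel_size_y_um,
                 excess_noise_factor = excess_noise_factor),
            class = "camera_model")
}

#' Point-spread-function model
#'
#' Either a symmetric 2D Gaussian whose width grows with defocus, or a
#' double-helix PSF: two Gaussian lobes on opposite sides of the emitter
#' whose axis rotates linearly with emitter depth, `theta(z) = theta0 +
#' rate * z`. The commercial phase-mask parameters are not public; the
#' defaults (short range: 90 deg/um over +/-1 um; long range: 30 deg/um over
#' +/-3 um) are configurable placeholders.
#'
#' @param family `"gaussian2d"` or `"double_helix"`.
#' @param sigma0_px in-focus Gaussian sigma in pixels (default 1.05).
#' @param defocus_range_um depth over which the gaussian2d sigma grows by
#'   sqrt(2) (default 0.4).
#' @param lobe_sep_um double-helix lobe separation (default 1.0).
#' @param rot_rate_deg_per_um rotation rate (non-zero for double_helix).
#' @param z_range_um full usable axial range (default 2 for the short-range
#'   variant; use 6 with rate 30 for the long-range variant).
#' @param theta0_deg lobe-axis angle at z = 0.
#' @return Object of class `psf_model`.
#' @export
psf_model <- function(family = c("gaussian2d", "double_helix"), sigma0_px = 1.05,
                      defocus_range_um = 0.4, lobe_sep_um = 1.0,
                      rot_rate_deg_per_um = 90, z_range_um = 2, theta0_deg = 0) {
  family <- match.arg(family)
  if (family == "double_helix" && rot_rate_deg_per_um == 0)
    stop("double-helix rotation rate must be non-zero")
  structure(list(family = family, sigma0_px = sigma0_px,
                 defocus_range_um = defocus_range_um, lobe_sep_um = lobe_sep_um,
                 rot_rate_deg_per_um = rot_rate_deg_per_um,
                 z_range_um = z_range_um, theta0_deg = theta0_deg),
            class = "psf_model")
}

#' Long-range double-helix preset (fiducial channel)
#' @return A [psf_model()].
#' @export
psf_double_helix_long <- function() {
  psf_model("double_helix", rot_rate_deg_per_um = 30, z_range_um = 6)
}

#' Set of blinking emitters
#'
#' @param positions data frame or matrix with columns `x_um`, `y_um`, `z_um`.
#' @param photon_rate expected signal photons per frame under full
#'   illumination (recycled).
#' @param on_probability per-frame on probability (PAINT-like independent
#'   blinking; recycled).
#' @param fiducial logical flag per emitter (always on, bright).
#' @return Object of class `emitter_set` (a data frame).
#' @export
emitter_set <- function(positions, photon_rate = 4320, on_probability = 0.02,
                        fiducial = FALSE) {
  pos <- as.data.frame(positions)
  if (nrow(pos) == 0) {
    df <- data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                     photon_rate = numeric(0), on_probability = numeric(0),
                     fiducial = logical(0))
    return(structure(df, class = c("emitter_set", "data.frame")))
  }
  stopifnot(all(c("x_um", "y_um", "z_um") %in% names(pos)))
  if (any(photon_rate < 0)) stop("`photon_rate` must be >= 0")
  if (any(on_probability < 0 | on_probability > 1))
    stop("`on_probability` must lie in [0, 1]")
  pos$photon_rate <- rep_len(photon_rate, nrow(pos))
  pos$on_probability <- rep_len(on_probability, nrow(pos))
  pos$fiducial <- rep_len(fiducial, nrow(pos))
  structure(pos, class = c("emitter_set", "data.frame"))
}

#' Synthetic cell-like emitter phantoms
#'
#' Deterministic (seeded) emitter layouts standing in for labeled cellular
#' structures: `nuclear_shell` places emitters on an ellipsoidal shell (a
#' nuclear-envelope-like target), `mito_network` on random 3D tubular
#' segments, and `two_plane` on two parallel x-y planes separated in z (the
#' configuration used to probe optical sectioning and signal-to-background).
#'
#' @param kind phantom kind.
#' @param params named list of overrides: `n_emitters`, `fov_um`
#'   (half-extent in x and y), `semi_axes_um`, `shell_thickness_um`
#'   (nuclear_shell), `n_segments`, `tube_radius_um` (mito_network),
#'   `z_sep_um` (two_plane), `density_per_um2` or `density_per_um3`,
#'   `photon_rate`, `on_probability`.
#' @param seed RNG seed.
#' @return An [emitter_set()].
#' @export
make_cell_phantom <- function(kind = c("nuclear_shell", "mito_network", "two_plane"),
                              params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- utils::modifyList(list(
    fov_um = 5, photon_rate = 4320, on_probability = 0.02,
    semi_axes_um = c(4, 3, 2), shell_thickness_um = 0.1,
    n_segments = 12, tube_radius_um = 0.15, segment_length_um = 3,
    z_sep_um = 4, density_per_um2 = 2, density_per_um3 = NULL,
    n_emitters = NULL), params)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  pos <- switch(kind,
    nuclear_shell = {
      n <- if (!is.null(p$n_emitters)) p$n_emitters else
        stats::rpois(1, p$density_per_um2 * 4 * pi * (prod(p$semi_axes_um))^(2 / 3))
      u <- matrix(stats::rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- 1 + stats::runif(n, -p$shell_thickness_um, p$shell_thickness_um) /
        mean(p$semi_axes_um)
      data.frame(x_um = u[, 1] * p$semi_axes_um[1] * r,
                 y_um = u[, 2] * p$semi_axes_um[2] * r,
                 z_um = u[, 3] * p$semi_axes_um[3] * r)
    },
    mito_network = {
      segs <- lapply(seq_len(p$n_segments), function(i) {
        a <- stats::runif(3, -p$fov_um, p$fov_um) * c(1, 1, 0.3)
        dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
        len <- stats::runif(1, 0.5, 1) * p$segment_length_um
        n_i <- stats::rpois(1, p$density_per_um2 * len)
        t_i <- stats::runif(n_i, 0, len)
        jit <- matrix(stats::rnorm(3 * n_i, sd = p$tube_radius_um), ncol = 3)
        sweep(outer(t_i, dir), 2, a, "+") + jit
      })
      m <- do.call(rbind, segs)
      data.frame(x_um = m[, 1], y_um = m[, 2], z_um = m[, 3])
    },
    two_plane = {
      area <- (2 * p$fov_um)^2
      n_per <- if (!is.null(p$n_emitters)) p$n_emitters else
        stats::rpois(2, p$density_per_um2 * area)
      n_per <- rep_len(n_per, 2)
      zs <- c(0, p$z_sep_um)
      do.call(rbind, lapply(1:2, function(k)
        data.frame(x_um = stats::runif(n_per[k], -p$fov_um, p$fov_um),
                   y_um = stats::runif(n_per[k], -p$fov_um, p$fov_um),
                   z_um = rep(zs[k], n_per[k]))))
    })
  emitter_set(pos, photon_rate = p$photon_rate, on_probability = p$on_probability)
}

## Pixel-integrated Gaussian: expected photons per pixel for a lobe centered
## at (cx, cy) in pixel units, sigma in pixels, over a (nx x ny) patch.
## Pixel i covers [i - 1, i) in 0-based pixel coordinates.
pixel_gauss <- function(nx, ny, cx, cy, sigma, photons) {
  ex <- diff(stats::pnorm(0:nx, mean = cx, sd = sigma))
  ey <- diff(stats::pnorm(0:ny, mean = cy, sd = sigma))
  photons * outer(ey, ex)  # [row = y, col = x]
}

#' Expected-photon image patch of a single emitter
#'
#' Renders the noise-free expected photon counts of one emitter at depth `z`
#' into a square patch, using pixel-integrated Gaussians. For the
#' double-helix family two equal lobes are placed at `+/- lobe_sep/2` around
#' the emitter along the axis `theta0 + rate * z`; their midpoint is the
#' emitter's lateral position.
#'
#' @param z_um emitter depth (um). Must lie within `+/- z_range/2` for the
#'   double helix.
#' @param psf a [psf_model()].
#' @param photons expected total signal photons in the patch.
#' @param camera a [camera_model()] (pixel geometry).
#' @param patch_px patch side length in pixels (odd).
#' @param offset_um lateral offset `c(x, y)` of the emitter from the patch
#'   center (um).
#' @return Matrix `[y, x]` of expected photons, summing to `photons` up to
#'   the tail mass outside the finite window.
#' @export
render_psf <- function(z_um, psf, photons, camera = camera_model(),
                       patch_px = 15, offset_um = c(0, 0)) {
  stopifnot(inherits(psf, "psf_model"))
  n <- patch_px
  c0 <- n / 2  # patch center in 0-based pixel coordinates
  cx <- c0 + offset_um[1] / camera$pixel_size_x_um
  cy <- c0 + offset_um[2] / camera$pixel_size_y_um
  px <- sqrt(camera$pixel_size_x_um * camera$pixel_size_y_um)
  if (psf$family == "gaussian2d") {
    sig <- psf$sigma0_px * sqrt(1 + (z_um / psf$defocus_range_um)^2)
    return(pixel_gauss(n, n, cx, cy, sig, photons))
  }
  if (abs(z_um) > psf$z_range_um / 2)
    stop("z outside the usable double-helix range")
  theta <- (psf$theta0_deg + psf$rot_rate_deg_per_um * z_um) * pi / 180
  half <- psf$lobe_sep_um / 2
  dx <- half * cos(theta) / camera$pixel_size_x_um
  dy <- half * sin(theta) / camera$pixel_size_y_um
  sig <- psf$sigma0_px
  pixel_gauss(n, n, cx + dx, cy + dy, sig, photons / 2) +
    pixel_gauss(n, n, cx - dx, cy - dy, sig, photons / 2)
}

## Illumination weight (normalized intensity) of a beam volume at sample
## positions; nearest-plane in x (clamped), bilinear in y/z, 0 outside y/z.
illumination_weight <- function(volume, x, y, z) {
  d <- dim(volume$intensity)
  jx <- pmin(pmax(round((x - volume$origin[1]) / volume$dx) + 1, 1), d[3])
  fy <- (y - volume$origin[2]) / volume$dy + 1
  fz <- (z - volume$origin[3]) / volume$dz + 1
  peak <- max(volume$intensity)
  w <- numeric(length(x))
  ok <- fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[1]
  if (any(ok)) {
    iy0 <- floor(fy[ok]); iz0 <- floor(fz[ok])
    ay <- fy[ok] - iy0; az <- fz[ok] - iz0
    iy1 <- pmin(iy0 + 1, d[2]); iz1 <- pmin(iz0 + 1, d[1])
    v <- volume$intensity
    idx <- cbind(iz0, iy0, jx[ok])
    w[ok] <- (1 - az) * (1 - ay) * v[cbind(iz0, iy0, jx[ok])] +
      (1 - az) * ay * v[cbind(iz0, iy1, jx[ok])] +
      az * (1 - ay) * v[cbind(iz1, iy0, jx[ok])] +
      az * ay * v[cbind(iz1, iy1, jx[ok])]
  }
  w / peak
}

#' Simulate a single-molecule movie with EMCCD noise
#'
#' Per frame, each emitter switches on independently with its
#' `on_probability` (fiducials are always on); the expected signal equals
#' `photon_rate` times the normalized illumination intensity at the
#' emitter's 3D position (1 everywhere for epi-illumination). Expected
#' photons (plus background) then pass through the full camera chain:
#' Poisson shot noise, Gamma electron multiplication (mean `em_gain`, excess
#' noise factor 2), Gaussian read noise, and digitization to A/D counts on
#' top of the dark level.
#'
#' @param emitters an [emitter_set()].
#' @param illumination a [beam_volume()] or the string `"epi"` (uniform).
#' @param psf a [psf_model()].
#' @param camera a [camera_model()].
#' @param n_frames number of frames.
#' @param seed RNG seed (full determinism).
#' @param fov_px frame size `c(nx, ny)` in pixels; the field of view is
#'   centered on (0, 0) in the sample frame.
#' @param bg_photons_per_px dye/out-of-focus background under epi
#'   illumination (photons per pixel per frame). Under sheet illumination
#'   it is attenuated by the sheet's z-confinement ratio
#'   (sheet z-integral / epi depth).
#' @param bg_depth_um depth over which epi illumination excites dye.
#' @param patch_px rendering patch size per emitter.
#' @return List of class `smlm_movie`: `frames` (list of integer matrices
#'   `[y, x]` in A/D counts), `truth` (ground-truth data frame: frame, id,
#'   x_um, y_um, z_um, photons), `camera`, `psf`, `fov_px`, `bg_photons_per_px`.
#' @export
simulate_frames <- function(emitters, illumination, psf, camera = camera_model(),
                            n_frames = 10, seed = 1, fov_px = c(64, 64),
                            bg_photons_per_px = 2, bg_depth_um = 10,
                            patch_px = 15) {
  stopifnot(inherits(emitters, "emitter_set"), inherits(psf, "psf_model"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  nx <- fov_px[1]; ny <- fov_px[2]
  epi <- identical(illumination, "epi")
  ne <- nrow(emitters)
  weights <- if (ne == 0) numeric(0) else if (epi) rep(1, ne) else
    illumination_weight(illumination, emitters$x_um, emitters$y_um, emitters$z_um)
  # dye background: proportional to the z-integrated illumination
  if (epi) {
    bg <- bg_photons_per_px
  } else {
    iy <- which.min(abs(volume_y(illumination)))
    jx <- which.min(abs(volume_x(illumination)))
    zint <- sum(illumination$intensity[, iy, jx] / max(illumination$intensity)) *
      illumination$dz
    bg <- bg_photons_per_px * min(1, zint / bg_depth_um)
  }
  # pixel centers: pixel (ix, iy) covers [ix-1, ix) etc. in 0-based pixel
  # coordinates; sample-frame origin at the FOV center
  half <- patch_px %/% 2
  truth <- vector("list", n_frames)
  frames <- vector("list", n_frames)
  g <- camera$em_gain
  for (fr in seq_len(n_frames)) {
    expected <- matrix(bg, ny, nx)
    if (ne > 0) {
      on <- stats::runif(ne) < emitters$on_probability | emitters$fiducial
      rows <- which(on & weights > 0)
    } else rows <- integer(0)
    rec <- list()
    for (i in rows) {
      if (psf$family == "double_helix" &&
          abs(emitters$z_um[i]) > psf$z_range_um / 2) next
      # emitter position in 0-based pixel coordinates of the full frame
      px_x <- emitters$x_um[i] / camera$pixel_size_x_um + nx / 2
      px_y <- emitters$y_um[i] / camera$pixel_size_y_um + ny / 2
      ix0 <- round(px_x); iy0 <- round(px_y)
      if (ix0 < -half || ix0 > nx + half || iy0 < -half || iy0 > ny + half) next
      nph <- emitters$photon_rate[i] * weights[i]
      # patch center (corner convention) maps to frame coordinate ix0 + 0.5
      patch <- render_psf(emitters$z_um[i], psf, nph, camera, patch_px,
                          offset_um = c((px_x - ix0 - 0.5) * camera$pixel_size_x_um,
                                        (px_y - iy0 - 0.5) * camera$pixel_size_y_um))
      xs <- (ix0 - half):(ix0 + half)
      ys <- (iy0 - half):(iy0 + half)
      okx <- xs >= 0 & xs < nx; oky <- ys >= 0 & ys < ny
      if (any(okx) && any(oky))
        expected[ys[oky] + 1, xs[okx] + 1] <-
          expected[ys[oky] + 1, xs[okx] + 1] + patch[oky, okx, drop = FALSE]
      rec[[length(rec) + 1]] <- data.frame(
        frame = fr, id = i, x_um = emitters$x_um[i], y_um = emitters$y_um[i],
        z_um = emitters$z_um[i], photons = nph, fiducial = emitters$fiducial[i])
    }
    nphot <- matrix(stats::rpois(length(expected), expected), ny, nx)
    electrons <- matrix(0, ny, nx)
    nz <- nphot > 0
    electrons[nz] <- stats::rgamma(sum(nz), shape = nphot[nz], scale = g)
    electrons <- electrons + stats::rnorm(length(electrons), sd = camera$read_noise)
    adu <- round(electrons / camera$conversion_gain + camera$dark_level)
    frames[[fr]] <- matrix(as.integer(pmin(pmax(adu, 0), 65535)), ny, nx)
    truth[[fr]] <- if (length(rec)) do.call(rbind, rec) else NULL
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(frame = integer(0), id = integer(0), x_um = numeric(0),
                        y_um = numeric(0), z_um = numeric(0), photons = numeric(0),
                        fiducial = logical(0))
  structure(list(frames = frames, truth = truth, camera = camera, psf = psf,
                 fov_px = fov_px, bg_photons_per_px = bg,
                 seed = seed),
            class = "smlm_movie")
}

#' @export
print.smlm_movie <- function(x, ...) {
  cat(sprintf("<smlm_movie> %d frames of %d x %d px, %d ground-truth records\n",
              length(x$frames), x$fov_px[1], x$fov_px[2], nrow(x$truth)))
  invisible(x)
}
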