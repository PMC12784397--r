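#' Optical train of the single-objective platform
#'
#' High-NA oil-immersion objective used both to launch the sheet (through a
#' back-focal-plane photomask) and to detect fluorescence.
#'
#' @param na numerical aperture (default 1.45).
#' @param focal_length_um objective focal length in micrometres. Default
#'   1800 (180 mm tube standard divided by 100x magnification).
#' @param immersion_index immersion oil index (default 1.518).
#' @param sample_index refractive index of the sample medium (default 1.33).
#' @param wavelength_um vacuum excitation wavelength (default 0.560).
#' @return Object of class `optical_train`.
#' @export
optical_train <- function(na = 1.45, focal_length_um = 1800,
                          immersion_index = 1.518, sample_index = 1.33,
                          wavelength_um = 0.560) {
  if (na <= 0 || na > immersion_index) stop("need 0 < NA <= immersion_index")
  if (focal_length_um <= 0) stop("`focal_length_um` must be positive")
  structure(list(na = na, focal_length_um = focal_length_um,
                 immersion_index = immersion_index, sample_index = sample_index,
                 wavelength_um = wavelength_um),
            class = "optical_train")
}

pupil_radius_um <- function(train) train$na * train$focal_length_um

#' Binary slit photomask at the back focal plane
#'
#' The mask is a set of parallel transmissive slits in an otherwise opaque
#' (finite optical density) substrate. Slits are long along the pupil y-axis
#' and narrow along the pupil z-axis; their z-positions set the lattice
#' structure of the sheet. Defaults: three equally spaced slits with the
#' outer pair 2.4 mm apart, slit width 0.08 mm, optical density 5.2.
#'
#' @param slit_centers_mm slit center positions along the pupil z-axis (mm),
#'   symmetric about 0 when there is more than one slit.
#' @param slit_width_mm slit width (mm, > 0).
#' @param slit_length_mm slit length along the pupil y-axis (mm).
#' @param optical_density decadic optical density of the opaque area;
#'   amplitude transmittance outside the slits is `10^(-OD/2)`.
#' @return Object of class `mask_spec`.
#' @export
mask_spec <- function(slit_centers_mm = c(-1.2, 0, 1.2), slit_width_mm = 0.08,
                      slit_length_mm = 1.0, optical_density = 5.2) {
  if (slit_width_mm <= 0) stop("`slit_width_mm` must be positive")
  if (optical_density < 0) stop("`optical_density` must be >= 0")
  if (length(slit_centers_mm) > 1 &&
      max(abs(slit_centers_mm + rev(slit_centers_mm))) > 1e-9)
    stop("slit centers must be symmetric about 0")
  structure(list(slit_centers_mm = sort(slit_centers_mm),
                 slit_width_mm = slit_width_mm,
                 slit_length_mm = slit_length_mm,
                 optical_density = optical_density),
            class = "mask_spec")
}

#' @export
print.mask_spec <- function(x, ...) {
  cat(sprintf("<mask_spec> %d slit(s) at [%s] mm, width %.3g mm, length %.3g mm, OD %.2f\n",
              length(x$slit_centers_mm), paste(signif(x$slit_centers_mm, 3), collapse = ", "),
              x$slit_width_mm, x$slit_length_mm, x$optical_density))
  invisible(x)
}

## Anti-aliased 1D coverage of interval [a, b] by pixels centered at x, pitch d.
interval_coverage <- function(x, d, a, b) {
  pmax(0, (pmin(x + d / 2, b) - pmax(x - d / 2, a)) / d)
}

#' Amplitude transmittance of a slit photomask on a field grid
#'
#' Samples the mask on the grid of a template [scalar_field()] geometry:
#' amplitude 1 inside the slits, `10^(-OD/2)` outside, with sub-pixel edge
#' coverage blended linearly so that slit positions vary smoothly with the
#' mask scale. Axis 1 of the grid is the pupil z-axis, axis 2 the pupil
#' y-axis. Mask coordinates are given in mm and converted to micrometres.
#'
#' @param mask a [mask_spec()].
#' @param grid list with `n1`, `n2`, `d1`, `d2` (samples and pitches, um) or
#'   a [scalar_field()] whose geometry is reused.
#' @param train an [optical_train()]; slits must lie inside the pupil radius
#'   `NA * f`.
#' @param scale dimensionless factor applied to all mask coordinates
#'   (centers and widths); used by the auto-scaling of
#'   [make_lattice_sheet()].
#' @return A real-amplitude [scalar_field()] (values in (0, 1]).
#' @export
mask_transmission <- function(mask, grid, train, scale = 1) {
  stopifnot(inherits(mask, "mask_spec"), inherits(train, "optical_train"))
  if (inherits(grid, "scalar_field"))
    grid <- list(n1 = nrow(grid$amplitude), n2 = ncol(grid$amplitude),
                 d1 = grid$dx, d2 = grid$dy)
  centers <- mask$slit_centers_mm * 1000 * scale
  width <- mask$slit_width_mm * 1000 * scale
  len <- mask$slit_length_mm * 1000 * scale
  rp <- pupil_radius_um(train)
  if (any(abs(centers) + width / 2 > rp))
    stop("slit extends outside the pupil radius NA*f")
  zc <- grid_coords(grid$n1, grid$d1)
  yc <- grid_coords(grid$n2, grid$d2)
  cov_z <- rep(0, grid$n1)
  for (c0 in centers)
    cov_z <- pmax(cov_z, interval_coverage(zc, grid$d1, c0 - width / 2, c0 + width / 2))
  cov_y <- interval_coverage(yc, grid$d2, -len / 2, len / 2)
  t_out <- 10^(-mask$optical_density / 2)
  amp <- t_out + (1 - t_out) * outer(cov_z, cov_y)
  scalar_field(amp, grid$d1, grid$d2, train$wavelength_um, 1)
}

#' Target geometry of a light sheet
#'
#' @param family `"lattice"` or `"gaussian"`.
#' @param target_waist_w0 desired 1/e^2 intensity radius of the sheet
#'   thickness at focus (um, default 1.8).
#' @param width_um desired 1/e^2 half-width of the sheet along y (um,
#'   default 32.9).
#' @param dither_amplitude_um lateral (y) dither amplitude of the
#'   time-averaged sheet (um). Default 3.5, i.e. a 0.1 V sine on a galvo with
#'   a 35 um/V in-plane calibration.
#' @return Object of class `sheet_spec`.
#' @export
sheet_spec <- function(family = c("lattice", "gaussian"), target_waist_w0 = 1.8,
                       width_um = 32.9, dither_amplitude_um = 3.5) {
  family <- match.arg(family)
  if (target_waist_w0 <= 0) stop("`target_waist_w0` must be positive")
  structure(list(family = family, target_waist_w0 = target_waist_w0,
                 width_um = width_um, dither_amplitude_um = dither_amplitude_um),
            class = "sheet_spec")
}

## Focal field of the lattice sheet for a given mask scale, on a
## (z: n1 x y: n2) back-focal-plane grid. Returns the focal-plane field.
## The illuminating laser spot is modeled as a Gaussian sized to the slit
## pattern (it scales with the mask), so that the finite-OD leakage outside
## the pattern stays proportionate to the open slit area.
lattice_focal_field <- function(mask, train, spec, scale,
                                n1 = 4096, d1 = 2, n2 = 64) {
  f <- train$focal_length_um
  lam <- train$wavelength_um
  # y-envelope at the pupil: Gaussian whose Fourier transform has the target
  # focal 1/e^2 half-width
  w_bfp <- lam * f / (pi * spec$width_um)
  ext_y_focal <- 4 * spec$width_um
  d2 <- lam * f / ext_y_focal
  bfp <- mask_transmission(mask, list(n1 = n1, n2 = n2, d1 = d1, d2 = d2),
                           train, scale = scale)
  yc <- grid_coords(n2, d2)
  zc <- grid_coords(n1, d1)
  pattern_extent <- (max(abs(mask$slit_centers_mm)) + mask$slit_width_mm / 2) * 1000 * scale
  r_illum <- 2 * max(pattern_extent, mask$slit_width_mm * 1000 * scale)
  env_z <- exp(-(zc / r_illum)^2)
  env_y <- exp(-(yc / w_bfp)^2)
  bfp$amplitude <- bfp$amplitude * outer(env_z, env_y)
  bfp$medium_index <- train$sample_index
  lens_fourier(bfp, f)
}

## 1D z-only version used for the fast auto-scaling root search.
lattice_focal_thickness <- function(mask, train, spec, scale, n1 = 4096, d1 = 2) {
  f <- lattice_focal_field(mask, train, spec, scale, n1 = n1, d1 = d1, n2 = 8)
  prof <- Mod(f$amplitude[, ncol(f$amplitude) / 2 + 1])^2
  as.numeric(one_over_e2_radius(prof, f$dx, restrict_central_lobe = TRUE))
}

#' Construct a dithered lattice light sheet from a slit photomask
#'
#' Pipeline: illuminate the mask at the back focal plane, Fourier-map it to
#' the sample focal plane through the objective, synthesize the intensity
#' volume by angular-spectrum propagation, and time-average the lateral
#' dither. Because the relay-telescope magnification between the physical
#' mask and the pupil is a free design parameter, the mask coordinates are
#' auto-scaled by a single factor so that the fitted 1/e^2 focal thickness of
#' the central lobe matches `spec$target_waist_w0`.
#'
#' @param mask a [mask_spec()].
#' @param train an [optical_train()].
#' @param spec a [sheet_spec()] (family `"lattice"`).
#' @param x_range_um propagation range `c(x_min, x_max)` in um.
#' @param n_planes number of x-planes.
#' @param autoscale auto-scale the mask to hit the target waist (default
#'   TRUE). With `autoscale = FALSE` the mask is used as given.
#' @param dither apply the y-dither time average (default TRUE).
#' @param grid list overriding the back-focal-plane grid (`n1`, `d1`, `n2`).
#' @param z_keep stored z half-range of the volume (um).
#' @return A [beam_volume()] with `family = "lattice"`; the applied mask
#'   scale and the fitted focal thickness are stored in `meta`.
#' @export
make_lattice_sheet <- function(mask, train, spec = sheet_spec("lattice"),
                               x_range_um = c(-60, 60), n_planes = 121,
                               autoscale = TRUE, dither = TRUE,
                               grid = list(n1 = 4096, d1 = 2, n2 = 64),
                               z_keep = 20) {
  stopifnot(inherits(spec, "sheet_spec"))
  w0 <- spec$target_waist_w0
  dl <- train$wavelength_um * train$sample_index / (pi * train$na)
  if (w0 < dl) stop("requested waist is below the diffraction limit for this NA")
  scale <- 1
  if (autoscale) {
    fthick <- function(s) lattice_focal_thickness(mask, train, spec, s,
                                                  n1 = grid$n1, d1 = grid$d1) - w0
    # thickness decreases with scale (wider slit separation -> finer fringes)
    lo <- 0.02; hi <- 1
    scale <- tryCatch(stats::uniroot(fthick, c(lo, hi), tol = 1e-4)$root,
                      error = function(e)
                        stop("auto-scaling failed: requested waist unattainable for this mask/NA"))
  }
  focal <- lattice_focal_field(mask, train, spec, scale,
                               n1 = grid$n1, d1 = grid$d1, n2 = grid$n2)
  vol <- synthesize_volume(focal, x_range_um[1], x_range_um[2], n_planes,
                           z_keep = z_keep)
  if (dither && spec$dither_amplitude_um > 0)
    vol <- apply_dither(vol, amplitude_um = spec$dither_amplitude_um)
  prof0 <- vol$intensity[, which.min(abs(volume_y(vol))), which.min(abs(volume_x(vol)))]
  w_fit <- as.numeric(one_over_e2_radius(prof0, vol$dz, restrict_central_lobe = TRUE))
  if (autoscale && abs(w_fit - w0) / w0 > 0.05)
    stop(sprintf("synthesized focal thickness %.3f um misses target %.3f um by > 5%%",
                 w_fit, w0))
  vol$family <- "lattice"
  vol$meta$mask_scale <- scale
  vol$meta$focal_thickness_um <- w_fit
  vol
}

#' Construct a single-objective Gaussian light sheet
#'
#' Models a cylindrical-lens sheet: Gaussian in the thickness direction (z)
#' with the requested 1/e^2 waist at focus, and a collimated flat-top
#' (super-Gaussian) envelope along the width (y). The volume is synthesized
#' by angular-spectrum propagation of the focal field.
#'
#' @param spec a [sheet_spec()] (family `"gaussian"`).
#' @param train an [optical_train()].
#' @param x_range_um,n_planes propagation sampling, as in
#'   [make_lattice_sheet()].
#' @param grid list with `n1`, `d1` (z samples/pitch, um) and `n2`, `d2`
#'   (y samples/pitch, um).
#' @return A [beam_volume()] with `family = "gaussian"`.
#' @export
make_gaussian_sheet <- function(spec = sheet_spec("gaussian"), train = optical_train(),
                                x_range_um = c(-60, 60), n_planes = 121,
                                grid = list(n1 = 512, d1 = 0.08, n2 = 64, d2 = 2)) {
  stopifnot(inherits(spec, "sheet_spec"))
  w0 <- spec$target_waist_w0
  dl <- train$wavelength_um * train$sample_index / (pi * train$na)
  if (w0 < dl) stop("requested waist is below the diffraction limit for this NA")
  zc <- grid_coords(grid$n1, grid$d1)
  yc <- grid_coords(grid$n2, grid$d2)
  # amplitude: 1/e^2 *intensity* radius w0 in z; order-8 super-Gaussian flat
  # top in y with 1/e^2 intensity half-width spec$width_um
  amp <- outer(exp(-zc^2 / w0^2), exp(-(yc / spec$width_um)^8))
  focal <- scalar_field(amp, grid$d1, grid$d2, train$wavelength_um, train$sample_index)
  vol <- synthesize_volume(focal, x_range_um[1], x_range_um[2], n_planes)
  prof0 <- vol$intensity[, which.min(abs(volume_y(vol))), which.min(abs(volume_x(vol)))]
  w_fit <- as.numeric(one_over_e2_radius(prof0, vol$dz))
  if (abs(w_fit - w0) / w0 > 0.01)
    stop(sprintf("focal waist %.4f um deviates from requested %.4f um by > 1%%", w_fit, w0))
  vol$family <- "gaussian"
  vol$meta$focal_thickness_um <- w_fit
  vol
}

## Periodic fractional shift of a matrix along columns (axis 2) by s voxels.
shift_periodic_cols <- function(m, s) {
  n <- ncol(m)
  s <- s %% n
  i0 <- floor(s); f <- s - i0
  idx1 <- ((seq_len(n) - 1 - i0) %% n) + 1
  idx2 <- ((seq_len(n) - 2 - i0) %% n) + 1
  (1 - f) * m[, idx1, drop = FALSE] + f * m[, idx2, drop = FALSE]
}

shift_periodic_rows <- function(m, s) t(shift_periodic_cols(t(m), s))

#' Time-averaged lateral dither of a beam volume
#'
#' Emulates sinusoidal scanning of the sheet along its width: the intensity
#' is averaged over one full period of the displacement `A * sin(2*pi*t)`
#' sampled at `n_phases` uniform time points (sine-distributed dwell).
#' Shifts use periodic linear interpolation, so the summed intensity of every
#' plane is conserved exactly.
#'
#' @param volume a [beam_volume()].
#' @param amplitude_um dither amplitude A in micrometres (>= 0).
#' @param axis dither axis; only `"y"` is meaningful for a sheet.
#' @param n_phases number of time samples over one period (>= 32 recommended).
#' @return The dithered [beam_volume()].
#' @export
apply_dither <- function(volume, amplitude_um, axis = "y", n_phases = 32) {
  stopifnot(inherits(volume, "beam_volume"))
  if (!identical(axis, "y")) stop("dither is only supported along y")
  if (!is.finite(amplitude_um) || amplitude_um < 0)
    stop("`amplitude_um` must be non-negative")
  if (amplitude_um == 0) return(volume)
  shifts <- amplitude_um * sin(2 * pi * (seq_len(n_phases) - 0.5) / n_phases) / volume$dy
  d <- dim(volume$intensity)
  out <- array(0, d)
  for (j in seq_len(d[3])) {
    plane <- volume$intensity[, , j]
    acc <- matrix(0, d[1], d[2])
    for (s in shifts) acc <- acc + shift_periodic_cols(plane, s)
    out[, , j] <- acc / n_phases
  }
  volume$intensity <- out
  volume$meta$dither_amplitude_um <- amplitude_um
  volume
}

#' Calibrated beam-steering state
#'
#' Linear calibrations of the steering units: two galvanometric mirrors
#' translate the sheet axially (z) and in-plane (y), and a tunable lens
#' shifts the focus along the propagation axis (x). Defaults are the
#' measured slopes: 0.64 um per 0.01 V axially, 0.35 um per 0.01 V
#' in-plane, and 2.41 um per 10 mA of focus shift. The Gaussian-sheet path
#' lacks the beam-shrinking relay of the lattice path, which doubles its
#' galvo response; this is modeled by a per-family multiplier.
#'
#' @param galvo_z_volts,galvo_y_volts galvo signals (V).
#' @param tunable_lens_mA tunable-lens signal (mA).
#' @param slope_z_um_per_V,slope_y_um_per_V,slope_x_um_per_10mA calibration
#'   slopes.
#' @param family_multiplier named multipliers applied to the galvo slopes per
#'   sheet family.
#' @return Object of class `steering_state`.
#' @export
steering_state <- function(galvo_z_volts = 0, galvo_y_volts = 0, tunable_lens_mA = 0,
                           slope_z_um_per_V = 64, slope_y_um_per_V = 35,
                           slope_x_um_per_10mA = 2.41,
                           family_multiplier = c(lattice = 1, gaussian = 2)) {
  sl <- c(slope_z_um_per_V, slope_y_um_per_V, slope_x_um_per_10mA)
  if (any(!is.finite(sl))) stop("calibration slopes must be finite")
  structure(list(galvo_z_volts = galvo_z_volts, galvo_y_volts = galvo_y_volts,
                 tunable_lens_mA = tunable_lens_mA,
                 slope_z_um_per_V = slope_z_um_per_V,
                 slope_y_um_per_V = slope_y_um_per_V,
                 slope_x_um_per_10mA = slope_x_um_per_10mA,
                 family_multiplier = family_multiplier),
            class = "steering_state")
}

#' Displacement implied by a steering state
#'
#' @param state a [steering_state()].
#' @param family sheet family for the galvo multiplier (default `"lattice"`).
#' @return Named vector `c(dx, dy, dz)` in micrometres.
#' @export
steering_shift_um <- function(state, family = "lattice") {
  m <- state$family_multiplier[[family]]
  if (is.null(m) || is.na(m)) m <- 1
  c(dx = state$slope_x_um_per_10mA * state$tunable_lens_mA / 10,
    dy = state$slope_y_um_per_V * state$galvo_y_volts * m,
    dz = state$slope_z_um_per_V * state$galvo_z_volts * m)
}

## Non-periodic fractional shift of a vector by s samples (zero fill).
shift_vec <- function(v, s) {
  n <- length(v)
  i0 <- floor(s); f <- s - i0
  out <- rep(0, n)
  src <- seq_len(n) - i0
  ok <- src >= 1 & src <= n
  out[ok] <- (1 - f) * v[src[ok]]
  src2 <- src - 1
  ok2 <- src2 >= 1 & src2 <= n
  out[ok2] <- out[ok2] + f * v[src2[ok2]]
  out
}

#' Translate a beam volume by the calibrated steering response
#'
#' Applies the strictly linear volt/current-to-displacement maps of
#' [steering_state()] as a rigid translation of the volume (separable linear
#' interpolation, zero fill at the borders). Composing two steering
#' operations is equivalent to one with the summed signals.
#'
#' @param volume a [beam_volume()].
#' @param state a [steering_state()].
#' @return The translated [beam_volume()].
#' @export
steer_sheet <- function(volume, state) {
  stopifnot(inherits(volume, "beam_volume"), inherits(state, "steering_state"))
  fam <- if (is.null(volume$family)) "lattice" else volume$family
  sh <- steering_shift_um(state, fam)
  d <- dim(volume$intensity)
  ext <- c(d[3] * volume$dx, d[2] * volume$dy, d[1] * volume$dz)
  if (any(abs(sh) > ext))
    stop("requested shift exceeds the volume extent")
  v <- volume$intensity
  sz <- sh[["dz"]] / volume$dz
  sy <- sh[["dy"]] / volume$dy
  sx <- sh[["dx"]] / volume$dx
  if (sz != 0) for (j in seq_len(d[3])) for (iy in seq_len(d[2]))
    v[, iy, j] <- shift_vec(v[, iy, j], sz)
  if (sy != 0) for (j in seq_len(d[3])) for (iz in seq_len(d[1]))
    v[iz, , j] <- shift_vec(v[iz, , j], sy)
  if (sx != 0) for (iz in seq_len(d[1])) for (iy in seq_len(d[2]))
    v[iz, iy, ] <- shift_vec(v[iz, iy, ], sx)
  volume$intensity <- v
  volume
}

#' Reflective micromirror insert
#'
#' Angled side wall of the microfluidic insert that redirects the vertically
#' launched sheet into the sample. A wall at 45 degrees to the coverslip
#' reflects the sheet into a horizontal path; the measured optimum of 39
#' degrees tilts the reflected propagation axis downward by
#' `2 * (45 - angle)` degrees.
#'
#' @param wall_angle_deg wall angle relative to the coverslip plane,
#'   0 < angle < 90 (default 39).
#' @return Object of class `mirror_spec`.
#' @export
mirror_spec <- function(wall_angle_deg = 39) {
  if (!is.finite(wall_angle_deg) || wall_angle_deg <= 0 || wall_angle_deg >= 90)
    stop("`wall_angle_deg` must lie strictly between 0 and 90")
  structure(list(wall_angle_deg = wall_angle_deg), class = "mirror_spec")
}

#' Reflect a beam volume at the micromirror
#'
#' Specular reflection of the vertically propagating sheet into the sample
#' frame, implemented as a rigid rotation of the volume in the x-z plane by
#' the downward tilt `2 * (45 - wall_angle)` degrees. The rotation uses the
#' three-shear decomposition with periodic fractional shifts, which conserves
#' the total intensity exactly; no re-diffraction is modeled (the mirror is
#' flat and large compared to the beam).
#'
#' @param volume a [beam_volume()] whose x-axis is the incoming propagation
#'   direction.
#' @param mirror a [mirror_spec()].
#' @return The reflected [beam_volume()]; the applied tilt (degrees, positive
#'   = downward) is stored in `meta$tilt_deg`.
#' @export
reflect_at_mirror <- function(volume, mirror) {
  stopifnot(inherits(volume, "beam_volume"), inherits(mirror, "mirror_spec"))
  tilt_deg <- 2 * (45 - mirror$wall_angle_deg)
  tau <- -tilt_deg * pi / 180  # positive tilt dips the axis toward -z
  volume$meta$tilt_deg <- tilt_deg
  if (tau == 0) return(volume)
  a <- -tan(tau / 2)   # x-shear (physical units): x' = x + a * z
  b <- sin(tau)        # z-shear: z' = z + b * x
  d <- dim(volume$intensity)
  zc <- volume_z(volume) - mean(volume_z(volume))
  xc <- volume_x(volume) - mean(volume_x(volume))
  v <- volume$intensity
  shear_x <- function(v) {
    for (iz in seq_len(d[1])) {
      s <- a * zc[iz] / volume$dx
      if (s != 0) for (iy in seq_len(d[2])) {
        vv <- v[iz, iy, ]
        n <- length(vv); sm <- s %% n; i0 <- floor(sm); f <- sm - i0
        idx1 <- ((seq_len(n) - 1 - i0) %% n) + 1
        idx2 <- ((seq_len(n) - 2 - i0) %% n) + 1
        v[iz, iy, ] <- (1 - f) * vv[idx1] + f * vv[idx2]
      }
    }
    v
  }
  shear_z <- function(v) {
    for (j in seq_len(d[3])) {
      s <- b * xc[j] / volume$dz
      if (s != 0) v[, , j] <- shift_periodic_rows(v[, , j], s)
    }
    v
  }
  v <- shear_x(v); v <- shear_z(v); v <- shear_x(v)
  volume$intensity <- v
  volume
}
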