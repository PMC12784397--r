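#' Random scattering medium for split-step beam propagation
#'
#' Statistical stand-in for a turbid sample (dye plus beads in an agarose
#' gel): thin random phase screens with Gaussian autocorrelation placed at
#' regular spacings along the propagation axis, optionally with absorbing
#' spherical scatterers (applied as opaque disks at the nearest screen) and a
#' uniform background fluorophore density. The model is a qualitative
#' emulation parameterized by per-screen RMS phase and correlation length,
#' not a calibration to any particular gel recipe.
#'
#' @param screen_spacing_um spacing between phase screens (um, > 0).
#' @param rms_phase RMS phase per screen in radians (>= 0).
#' @param correlation_length_um Gaussian autocorrelation 1/e half-width of
#'   each screen (um, > 0).
#' @param scatterer_density absorbing scatterers per um^3 (>= 0).
#' @param scatterer_radius_um scatterer radius (um).
#' @param background_fluorophore_density dye emission per unit illumination
#'   intensity (arbitrary units); used when the medium feeds the
#'   single-molecule simulator.
#' @param obstacles optional list of deterministic absorbing obstacles, each
#'   `list(x_um =, z_center_um =, z_halfwidth_um =)` (a strip across y) or
#'   with `y_center_um`/`radius_um` for a disk.
#' @param seed integer RNG seed; identical seed and parameters yield an
#'   identical medium realization.
#' @return Object of class `scatter_medium`.
#' @export
scatter_medium <- function(screen_spacing_um = 5, rms_phase = 0.6,
                           correlation_length_um = 2, scatterer_density = 0,
                           scatterer_radius_um = 1,
                           background_fluorophore_density = 0,
                           obstacles = list(), seed = 1) {
  if (screen_spacing_um <= 0) stop("`screen_spacing_um` must be positive")
  if (rms_phase < 0) stop("`rms_phase` must be >= 0")
  if (correlation_length_um <= 0) stop("`correlation_length_um` must be positive")
  if (scatterer_density < 0) stop("`scatterer_density` must be >= 0")
  structure(list(screen_spacing_um = screen_spacing_um, rms_phase = rms_phase,
                 correlation_length_um = correlation_length_um,
                 scatterer_density = scatterer_density,
                 scatterer_radius_um = scatterer_radius_um,
                 background_fluorophore_density = background_fluorophore_density,
                 obstacles = obstacles, seed = as.integer(seed)),
            class = "scatter_medium")
}

#' Alias constructor matching the medium-then-seed call pattern
#' @param params named list of [scatter_medium()] arguments.
#' @param seed RNG seed.
#' @return A `scatter_medium`.
#' @export
make_medium <- function(params = list(), seed = 1) {
  do.call(scatter_medium, c(params, list(seed = seed)))
}

#' Realize the phase screens of a medium on a field grid
#'
#' Screens are generated by spectral filtering of white Gaussian noise with
#' the square root of a Gaussian power spectrum (autocorrelation
#' `exp(-r^2 / l^2)`), normalized by the theoretical filter gain so the
#' ensemble RMS equals `rms_phase`. Generation is deterministic in
#' `medium$seed`.
#'
#' @param medium a [scatter_medium()].
#' @param field_template a [scalar_field()] defining the grid.
#' @param n_screens number of screens.
#' @return List of `n_screens` real matrices of phases (radians).
#' @export
realize_screens <- function(medium, field_template, n_screens) {
  n1 <- nrow(field_template$amplitude); n2 <- ncol(field_template$amplitude)
  l <- medium$correlation_length_um
  kx <- k_freqs(n1, field_template$dx)
  ky <- k_freqs(n2, field_template$dy)
  h <- exp(-outer(kx^2, ky^2, "+") * l^2 / 8)  # sqrt of Gaussian PSD
  gain <- sqrt(mean(h^2))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(medium$seed)
  lapply(seq_len(n_screens), function(k) {
    white <- matrix(stats::rnorm(n1 * n2), n1, n2)
    filt <- Re(stats::fft(stats::fft(white) * h, inverse = TRUE)) / (n1 * n2)
    filt / gain * medium$rms_phase
  })
}

#' Split-step propagation of a field through a scattering medium
#'
#' Alternates free-space angular-spectrum propagation with multiplication by
#' the medium's random phase screens (and absorbing scatterer/obstacle
#' masks), recording the transverse intensity at `n_planes` uniformly spaced
#' positions between 0 and `distance`. With a fully transparent medium the
#' result coincides with free-space [synthesize_volume()].
#'
#' @param field input [scalar_field()] at x = 0.
#' @param medium a [scatter_medium()].
#' @param distance propagation distance (um, > 0).
#' @param n_planes number of recorded planes (default: one per screen
#'   spacing, at least 2).
#' @param z_keep,y_keep stored crop half-widths, as in
#'   [synthesize_volume()].
#' @return A [beam_volume()] covering x in `[0, distance]`.
#' @export
propagate_through_medium <- function(field, medium, distance,
                                     n_planes = NULL, z_keep = NULL, y_keep = NULL) {
  stopifnot(inherits(field, "scalar_field"), inherits(medium, "scatter_medium"))
  if (!is.finite(distance) || distance <= 0) stop("`distance` must be positive")
  sp <- medium$screen_spacing_um
  if (sp > distance) {
    warning("screen spacing exceeds the distance; using a single mid-path screen")
    screen_x <- distance / 2
  } else {
    screen_x <- seq(sp, distance, by = sp)
  }
  if (is.null(n_planes)) n_planes <- max(2, length(screen_x) + 1)
  transparent <- medium$rms_phase == 0 && medium$scatterer_density == 0 &&
    length(medium$obstacles) == 0
  screens <- if (transparent) NULL else realize_screens(medium, field, length(screen_x))

  n1 <- nrow(field$amplitude); n2 <- ncol(field$amplitude)
  zc <- grid_coords(n1, field$dx)
  yc <- grid_coords(n2, field$dy)

  scat <- NULL
  if (medium$scatterer_density > 0) {
    vol_um3 <- distance * (n1 * field$dx) * (n2 * field$dy)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(medium$seed + 1L)
    n_scat <- stats::rpois(1, medium$scatterer_density * vol_um3)
    scat <- data.frame(x = stats::runif(n_scat, 0, distance),
                       y = stats::runif(n_scat, min(yc), max(yc)),
                       z = stats::runif(n_scat, min(zc), max(zc)))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }

  screen_mask <- function(k) {
    mask <- matrix(1, n1, n2)
    x0 <- screen_x[k]
    if (!is.null(scat) && nrow(scat) > 0) {
      sel <- abs(scat$x - x0) <= sp / 2
      for (i in which(sel)) {
        inside <- outer((zc - scat$z[i])^2, (yc - scat$y[i])^2, "+") <=
          medium$scatterer_radius_um^2
        mask[inside] <- 0
      }
    }
    for (ob in medium$obstacles) {
      if (abs(ob$x_um - x0) <= sp / 2) {
        if (!is.null(ob$z_halfwidth_um)) {
          rows <- abs(zc - ob$z_center_um) <= ob$z_halfwidth_um
          mask[rows, ] <- 0
        } else {
          inside <- outer((zc - ob$z_center_um)^2, (yc - ob$y_center_um)^2, "+") <=
            ob$radius_um^2
          mask[inside] <- 0
        }
      }
    }
    mask
  }

  x_out <- seq(0, distance, length.out = n_planes)
  keep_z <- if (is.null(z_keep)) rep(TRUE, n1) else abs(zc) <= z_keep
  keep_y <- if (is.null(y_keep)) rep(TRUE, n2) else abs(yc) <= y_keep
  out <- array(0, c(sum(keep_z), sum(keep_y), n_planes))

  events <- rbind(data.frame(x = screen_x, type = "screen", idx = seq_along(screen_x)),
                  data.frame(x = x_out, type = "out", idx = seq_along(x_out)))
  events <- events[order(events$x, events$type == "out"), ]
  cur <- field
  x_cur <- 0
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    if (ev$x > x_cur) {
      cur <- propagate_angular_spectrum(cur, ev$x - x_cur, pad = 1,
                                        check_sampling = FALSE)
      x_cur <- ev$x
    }
    if (ev$type == "screen") {
      if (!transparent) {
        phase <- screens[[ev$idx]]
        cur$amplitude <- cur$amplitude * exp(1i * phase) * screen_mask(ev$idx)
      }
    } else {
      out[, , ev$idx] <- Mod(cur$amplitude[keep_z, keep_y, drop = FALSE])^2
    }
  }
  beam_volume(out, dx = if (n_planes > 1) diff(x_out[1:2]) else 1,
              dy = field$dy, dz = field$dx,
              origin = c(0, min(yc[keep_y]), min(zc[keep_z])),
              meta = list(medium_seed = medium$seed,
                          n_screens = length(screen_x)))
}

#' Self-healing comparison of lattice and Gaussian sheets behind an obstacle
#'
#' Runs a matched-waist lattice and Gaussian sheet through the identical
#' medium realization with a single absorbing strip blocking the beam core
#' at the focus, and measures the Pearson correlation between the obstructed
#' and unobstructed z-profiles (at the y-center) a fixed distance past the
#' obstacle. A beam that redistributes energy around the obstruction keeps a
#' higher correlation with its unperturbed self.
#'
#' @param seed medium realization seed.
#' @param waist_um matched 1/e^2 focal thickness of both sheets.
#' @param obstacle_halfwidth_um half-width (in z) of the absorbing strip.
#' @param recovery_um distance past the obstacle at which profiles are
#'   compared.
#' @param medium_params named list of [scatter_medium()] overrides.
#' @param train an [optical_train()].
#' @return List with correlations `lattice` and `gaussian` and the margin
#'   `lattice - gaussian`.
#' @export
self_healing_comparison <- function(seed, waist_um = 1.8,
                                    obstacle_halfwidth_um = 1.8,
                                    recovery_um = 10,
                                    medium_params = list(rms_phase = 0.3,
                                                         screen_spacing_um = 2.5,
                                                         correlation_length_um = 2),
                                    train = optical_train()) {
  sp_lat <- sheet_spec("lattice", target_waist_w0 = waist_um)
  sp_gau <- sheet_spec("gaussian", target_waist_w0 = waist_um)
  grid1 <- list(n1 = 2048, d1 = 2, n2 = 16)
  scale <- stats::uniroot(function(s)
    lattice_focal_thickness(mask_spec(), train, sp_lat, s, n1 = grid1$n1, d1 = grid1$d1) -
      waist_um, c(0.02, 1), tol = 1e-4)$root
  lat_field <- lattice_focal_field(mask_spec(), train, sp_lat, scale,
                                   n1 = grid1$n1, d1 = grid1$d1, n2 = grid1$n2)
  zc <- grid_coords(512, lat_field$dx)
  yc <- grid_coords(grid1$n2, lat_field$dy)
  gau_amp <- outer(exp(-grid_coords(2048, lat_field$dx)^2 / waist_um^2),
                   exp(-(grid_coords(grid1$n2, lat_field$dy) / sp_gau$width_um)^2))
  gau_field <- scalar_field(gau_amp, lat_field$dx, lat_field$dy,
                            train$wavelength_um, train$sample_index)

  distance <- recovery_um + 2.5
  run <- function(field, med) {
    vol <- propagate_through_medium(field, med, distance,
                                    n_planes = 2, z_keep = 20)
    iy <- which.min(abs(volume_y(vol)))
    vol$intensity[, iy, 2]
  }
  med_free <- do.call(scatter_medium, c(medium_params, list(seed = seed)))
  med_obs <- do.call(scatter_medium, c(
    medium_params,
    list(seed = seed,
         obstacles = list(list(x_um = 2.5, z_center_um = 0,
                               z_halfwidth_um = obstacle_halfwidth_um)))))
  cors <- vapply(list(lat_field, gau_field), function(fld) {
    stats::cor(run(fld, med_free), run(fld, med_obs))
  }, numeric(1))
  list(lattice = cors[1], gaussian = cors[2], margin = cors[1] - cors[2])
}
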