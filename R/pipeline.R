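#' Default run configuration
#'
#' Fully resolved configuration for an end-to-end run: beam construction,
#' optional scattering, phantom, movie simulation, localization and
#' statistics. Every field can be overridden via `overrides` (a nested named
#' list, e.g. from a YAML file); the resolved configuration is written next
#' to the outputs of [run_pipeline()] so each run is reproducible.
#'
#' @param overrides nested named list of overrides.
#' @return Nested list of class `run_config`.
#' @export
default_run_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1,
    train = list(na = 1.45, focal_length_um = 1800, immersion_index = 1.518,
                 sample_index = 1.33, wavelength_um = 0.560),
    sheet = list(family = "lattice", target_waist_w0 = 1.8, width_um = 32.9,
                 dither_amplitude_um = 3.5),
    mask = list(slit_centers_mm = c(-1.2, 0, 1.2), slit_width_mm = 0.08,
                slit_length_mm = 1.0, optical_density = 5.2),
    mirror = list(wall_angle_deg = 39, apply = FALSE),
    beam = list(x_range_um = c(-30, 30), n_planes = 41),
    medium = NULL,
    phantom = list(kind = "two_plane", z_sep_um = 4, fov_um = 4,
                   density_per_um2 = 0.15, photon_rate = 4320,
                   on_probability = 0.05),
    psf = list(family = "gaussian2d"),
    camera = list(),
    movie = list(n_frames = 20, fov_px = c(64, 64), bg_photons_per_px = 5),
    localize = list(threshold_coeff = 2),
    filter = list(max_uncertainty_xy_nm = 100, max_photons = 1e6),
    axial_scale = 0.75,
    frc = list(sr_pixel_nm = 8, min_locs = 100))
  cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = c("run_config", "list"))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file of overrides on [default_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  default_run_config(yaml::read_yaml(path))
}

#' Run the full simulation and analysis pipeline
#'
#' Stages: simulate the configured light sheet (optionally through a
#' scattering medium and/or reflected at the micromirror), generate an
#' emitter phantom, simulate a single-molecule movie under that
#' illumination, localize it, filter, rescale axially (3D data), and compute
#' summary statistics (region counts, SBR, FRC when enough localizations
#' survive). All intermediates are written into `out_dir` together with the
#' fully resolved configuration and a log.
#'
#' @param config a `run_config` (see [default_run_config()]).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the main artifacts (`beam`, `movie`,
#'   `locs`, `report`) and their file paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("solls_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run.log")
  log <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  log("pipeline start (solls %s, seed %d)",
      as.character(utils::packageVersion("solls")), config$seed)

  train <- do.call(optical_train, config$train)
  spec <- do.call(sheet_spec, config$sheet)
  beam <- stage("simulate-beam", {
    if (spec$family == "lattice") {
      make_lattice_sheet(do.call(mask_spec, config$mask), train, spec,
                         x_range_um = unlist(config$beam$x_range_um),
                         n_planes = config$beam$n_planes)
    } else {
      make_gaussian_sheet(spec, train,
                          x_range_um = unlist(config$beam$x_range_um),
                          n_planes = config$beam$n_planes)
    }
  })
  log("beam: %s, focal thickness %.3f um", spec$family, beam$meta$focal_thickness_um)
  if (isTRUE(config$mirror$apply)) {
    beam <- stage("reflect", reflect_at_mirror(beam, mirror_spec(config$mirror$wall_angle_deg)))
    log("mirror: tilt %.1f deg", beam$meta$tilt_deg)
  }
  beam_path <- file.path(out_dir, "beam.tif")
  write_beam_volume(beam, beam_path)

  phantom_params <- config$phantom[setdiff(names(config$phantom), "kind")]
  emitters <- stage("phantom",
    make_cell_phantom(config$phantom$kind, phantom_params, seed = config$seed))
  log("phantom: %s with %d emitters", config$phantom$kind, nrow(emitters))

  cam <- do.call(camera_model, config$camera)
  psf <- do.call(psf_model, config$psf)
  movie <- stage("simulate-smlm",
    simulate_frames(emitters, beam, psf, cam,
                    n_frames = config$movie$n_frames, seed = config$seed + 1,
                    fov_px = unlist(config$movie$fov_px),
                    bg_photons_per_px = config$movie$bg_photons_per_px))
  write_movie(movie, file.path(out_dir, "movie.tif"))
  write_localizations(movie$truth, file.path(out_dir, "ground_truth.csv"))
  log("movie: %d frames, %d ground-truth records",
      length(movie$frames), nrow(movie$truth))

  locs <- stage("localize",
    localize_movie(movie, threshold_coeff = config$localize$threshold_coeff))
  log("localized: %d records", nrow(locs))
  locs <- stage("filter",
    suppressMessages(filter_localizations(locs, config$filter)))
  if (nrow(locs) == 0) log("warning: all localizations rejected by the filter rules")
  if ("z_um" %in% names(locs) && nrow(locs) > 0)
    locs <- stage("rescale", rescale_axial(locs, config$axial_scale))
  locs <- if (nrow(locs) > 0) compute_sbr(locs, cam$pixel_size_x_um * cam$pixel_size_y_um) else locs
  locs_path <- file.path(out_dir, "locs.csv")
  write_localizations(locs, locs_path)

  report <- list(n_localizations = nrow(locs),
                 seed = config$seed,
                 focal_thickness_um = beam$meta$focal_thickness_um)
  if (nrow(locs) > 0) {
    report$median_photons <- stats::median(locs$photons)
    report$median_background <- stats::median(locs$background)
    report$median_uncertainty_xy_nm <- stats::median(locs$uncertainty_xy_nm)
    report$mean_sbr <- mean(locs$sbr[is.finite(locs$sbr)])
    rs <- bin_regions(locs, 5, axis = "x")
    report$region_counts <- rs$count
  }
  if (nrow(locs) >= config$frc$min_locs) {
    report$frc_resolution_nm <- as.numeric(stage("frc",
      frc_resolution(locs, config$frc$sr_pixel_nm, seed = config$seed,
                     min_locs = config$frc$min_locs)))
    log("FRC resolution: %.1f nm", report$frc_resolution_nm)
  }
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  log("pipeline done")
  invisible(list(beam = beam, movie = movie, locs = locs, report = report,
                 out_dir = out_dir))
}

#' Sheet versus epi-illumination signal-to-background comparison
#'
#' Full simulation round trip on the two-plane phantom: emitters on a focal
#' plane and on a second plane `z_sep_um` above it are imaged under sheet
#' illumination (only the focal plane excited) and under uniform epi
#' illumination (both planes excited, the out-of-focus plane contributing
#' diffuse background), localized, and compared by their mean fitted
#' signal-to-background ratio.
#'
#' @param seed RNG seed for the phantom and the movies.
#' @param z_sep_um separation of the two emitter planes (default 4).
#' @param waist_um sheet 1/e^2 focal thickness (default 1.8).
#' @param n_frames frames per condition.
#' @param density_per_um2 emitter density per plane.
#' @return List with `sbr_sheet`, `sbr_epi` and their `ratio`.
#' @export
sbr_sheet_vs_epi <- function(seed = 1, z_sep_um = 4, waist_um = 1.8,
                             n_frames = 15, density_per_um2 = 0.6) {
  train <- optical_train()
  beam <- make_gaussian_sheet(sheet_spec("gaussian", target_waist_w0 = waist_um),
                              train, x_range_um = c(-10, 10), n_planes = 5,
                              grid = list(n1 = 256, d1 = 0.08, n2 = 32, d2 = 2))
  em <- make_cell_phantom("two_plane",
                          list(z_sep_um = z_sep_um, fov_um = 4,
                               density_per_um2 = density_per_um2,
                               on_probability = 0.15, photon_rate = 4320),
                          seed = seed)
  run <- function(illum) {
    mv <- simulate_frames(em, illum, psf_model("gaussian2d"), camera_model(),
                          n_frames = n_frames, seed = seed + 100,
                          fov_px = c(56, 56), bg_photons_per_px = 2)
    locs <- compute_sbr(localize_movie(mv))
    mean(locs$sbr[is.finite(locs$sbr)])
  }
  s <- run(beam); e <- run("epi")
  list(sbr_sheet = s, sbr_epi = e, ratio = s / e)
}

#' Generate the small deterministic fixture bundle
#'
#' Writes a 16-plane Gaussian-sheet beam volume, a 50-frame single-molecule
#' movie and a 100-row localization table, all generated from `seed`, into
#' `dir`. Used by the test suite; regenerates bit-identically for a given
#' seed.
#'
#' @param seed RNG seed.
#' @param dir output directory.
#' @return Named list of file paths.
#' @export
make_fixtures <- function(seed = 1, dir = tempfile("solls_fixtures_")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  train <- optical_train()
  beam <- make_gaussian_sheet(sheet_spec("gaussian"), train,
                              x_range_um = c(-15, 15), n_planes = 16,
                              grid = list(n1 = 256, d1 = 0.08, n2 = 32, d2 = 2))
  beam_path <- file.path(dir, "beam.tif")
  write_beam_volume(beam, beam_path)
  em <- make_cell_phantom("two_plane",
                          list(z_sep_um = 4, fov_um = 3, density_per_um2 = 0.2,
                               on_probability = 0.1),
                          seed = seed)
  movie <- simulate_frames(em, beam, psf_model("gaussian2d"), camera_model(),
                           n_frames = 50, seed = seed, fov_px = c(48, 48),
                           bg_photons_per_px = 2)
  movie_path <- file.path(dir, "movie.tif")
  write_movie(movie, movie_path)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed + 2L)
  n <- 100
  locs <- data.frame(frame = sample(1:50, n, replace = TRUE),
                     x_um = stats::runif(n, -3, 3),
                     y_um = stats::runif(n, -3, 3),
                     z_um = stats::rnorm(n, sd = 0.3),
                     photons = stats::rlnorm(n, log(4000), 0.4),
                     background = stats::rlnorm(n, log(15), 0.3),
                     sigma_um = stats::rnorm(n, 0.165, 0.01))
  locs$uncertainty_xy_nm <- precision_emccd(locs$photons, locs$background,
                                            locs$sigma_um, 0.158)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  locs_path <- file.path(dir, "locs.csv")
  write_localizations(locs, locs_path)
  list(beam = beam_path, movie = movie_path, locs = locs_path, dir = dir)
}
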