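# Shared builders with per-session caching of the more expensive objects.

.solls_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .solls_cache)) assign(name, builder(), envir = .solls_cache)
  get(name, envir = .solls_cache)
}

# Circular Gaussian test beam (well-sampled, compact on the grid).
gaussian_field <- function(w0 = 2, n = 128, d = 0.25, lam = 0.56, medium = 1.33) {
  zc <- grid_coords(n, d)
  scalar_field(outer(exp(-(zc / w0)^2), exp(-(zc / w0)^2)), d, d, lam, medium)
}

# Full-scale default sheets shared by metric and acceptance tests.
default_lattice_sheet <- function() cached("lattice_sheet", function()
  make_lattice_sheet(mask_spec(), optical_train()))

default_gaussian_sheet <- function() cached("gaussian_sheet", function()
  make_gaussian_sheet(sheet_spec("gaussian"), optical_train()))

# One noisy camera frame of a single emitter through the full EMCCD chain,
# returned in photons (dark-corrected).
noisy_spot_photons <- function(n_photons, bg, patch_px = 15, cam = camera_model(),
                               psf = psf_model("gaussian2d"), offset_um = c(0, 0)) {
  mu <- render_psf(0, psf, n_photons, cam, patch_px, offset_um) + bg
  nph <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
  el <- matrix(0, nrow(mu), ncol(mu))
  nz <- nph > 0
  el[nz] <- rgamma(sum(nz), shape = nph[nz], scale = cam$em_gain)
  el <- el + rnorm(length(el), sd = cam$read_noise)
  adu <- round(el / cam$conversion_gain + cam$dark_level)
  adu_to_photons(adu, cam)
}
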