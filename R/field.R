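#' Complex scalar optical field on one transverse plane
#'
#' A `scalar_field` holds a complex amplitude sampled on a regular 2D grid in
#' a single plane transverse to the propagation axis. Axis 1 (matrix rows) has
#' pitch `dx`, axis 2 (columns) pitch `dy`; the grid is centered so that the
#' coordinate origin sits at index `floor(n/2) + 1` along each axis. When a
#' field is used to build a light sheet, axis 1 is the sheet-thickness (z)
#' direction and axis 2 the sheet-width (y) direction.
#'
#' @param amplitude complex (or numeric) matrix of field amplitudes.
#' @param dx,dy grid pitch along axis 1 / axis 2 (micrometres, > 0).
#' @param wavelength_vac vacuum wavelength in micrometres (> 0).
#' @param medium_index refractive index of the propagation medium (>= 1).
#' @return An object of class `scalar_field`.
#' @export
scalar_field <- function(amplitude, dx, dy = dx, wavelength_vac, medium_index = 1) {
  if (!is.matrix(amplitude)) stop("`amplitude` must be a matrix")
  if (!is.complex(amplitude)) amplitude <- amplitude + 0i
  if (!is.finite(dx) || dx <= 0 || !is.finite(dy) || dy <= 0)
    stop("grid pitches must be positive and finite")
  if (!is.finite(wavelength_vac) || wavelength_vac <= 0)
    stop("`wavelength_vac` must be positive")
  if (!is.finite(medium_index) || medium_index < 1)
    stop("`medium_index` must be >= 1")
  if (!all(is.finite(Mod(amplitude)))) stop("amplitude contains non-finite values")
  structure(
    list(amplitude = amplitude, dx = dx, dy = dy,
         wavelength_vac = wavelength_vac, medium_index = medium_index),
    class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("<scalar_field> %d x %d, pitch %.4g x %.4g um, lambda %.4g um (n = %.3g)\n",
              nrow(x$amplitude), ncol(x$amplitude), x$dx, x$dy,
              x$wavelength_vac, x$medium_index))
  cat(sprintf("  power: %.6g\n", field_power(x)))
  invisible(x)
}

#' Total optical power carried by a field
#'
#' Discrete approximation `sum(|A|^2) * dx * dy`.
#' @param field a [scalar_field()].
#' @return Numeric scalar.
#' @export
field_power <- function(field) {
  sum(Mod(field$amplitude)^2) * field$dx * field$dy
}

#' Centered grid coordinates for one axis
#'
#' Coordinates in physical units for `n` samples of pitch `d`, with the origin
#' at index `floor(n/2) + 1`.
#' @param n number of samples.
#' @param d pitch.
#' @return Numeric vector of length `n`.
#' @export
grid_coords <- function(n, d) (seq_len(n) - 1 - floor(n / 2)) * d

## Unshifted angular frequencies (rad / unit) matching R's fft ordering.
k_freqs <- function(n, d) {
  i <- seq_len(n) - 1
  i[i >= ceiling(n / 2)] <- i[i >= ceiling(n / 2)] - n
  2 * pi * i / (n * d)
}

fftshift_mat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((floor(nr / 2) + 1):nr, seq_len(floor(nr / 2)))
  ci <- c((floor(nc / 2) + 1):nc, seq_len(floor(nc / 2)))
  m[ri, ci, drop = FALSE]
}

ifftshift_mat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((ceiling(nr / 2) + 1):nr, seq_len(ceiling(nr / 2)))
  ci <- c((ceiling(nc / 2) + 1):nc, seq_len(ceiling(nc / 2)))
  m[ri, ci, drop = FALSE]
}

pad_matrix <- function(m, factor) {
  if (factor <= 1) return(m)
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0i, nr * factor, nc * factor)
  r0 <- floor((nr * factor - nr) / 2)
  c0 <- floor((nc * factor - nc) / 2)
  out[r0 + seq_len(nr), c0 + seq_len(nc)] <- m
  out
}

crop_matrix <- function(m, nr, nc) {
  r0 <- floor((nrow(m) - nr) / 2)
  c0 <- floor((ncol(m) - nc) / 2)
  m[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
}

## Fraction of spectral power in the outer band of the grid's Nyquist range.
spectral_edge_fraction <- function(spec_pow, kx, ky, edge = 0.9) {
  kx_max <- max(abs(kx)); ky_max <- max(abs(ky))
  mask_r <- abs(kx) > edge * kx_max
  mask_c <- abs(ky) > edge * ky_max
  tot <- sum(spec_pow)
  if (tot == 0) return(0)
  (sum(spec_pow[mask_r, ]) + sum(spec_pow[!mask_r, mask_c])) / tot
}

#' Free-space propagation by the angular-spectrum method
#'
#' Propagates a scalar field over `distance` by multiplying its 2D spectrum by
#' the exact non-paraxial kernel `exp(i * d * sqrt(k^2 n^2 - kx^2 - ky^2))`.
#' Evanescent components (`kx^2 + ky^2 > k^2 n^2`) are set to zero, which is
#' appropriate for propagation distances much larger than a wavelength. The
#' kernel is unitary on propagating components, so total power is conserved.
#'
#' @param field a [scalar_field()]. The grid must sample the field finely
#'   enough that its band limit stays inside the grid Nyquist range.
#' @param distance propagation distance in micrometres (may be negative).
#' @param pad integer zero-padding factor applied before the spectral
#'   multiplication to suppress periodic wrap-around (default 2). Use
#'   `pad = 1` for strictly periodic fields such as plane waves.
#' @param check_sampling if `TRUE` (default), error when more than 0.1% of the
#'   spectral power lies in the outer 10% of the Nyquist band (severe
#'   aliasing).
#' @return A [scalar_field()] at the displaced plane, same grid.
#' @export
propagate_angular_spectrum <- function(field, distance, pad = 2, check_sampling = TRUE) {
  stopifnot(inherits(field, "scalar_field"))
  if (!is.numeric(distance) || length(distance) != 1 || !is.finite(distance))
    stop("`distance` must be a finite scalar")
  if (distance == 0) return(field)
  amp <- pad_matrix(field$amplitude, pad)
  spec <- stats::fft(amp)
  kx <- k_freqs(nrow(amp), field$dx)
  ky <- k_freqs(ncol(amp), field$dy)
  if (check_sampling) {
    frac <- spectral_edge_fraction(Mod(spec)^2, kx, ky)
    if (frac > 1e-3)
      stop(sprintf(
        "severe aliasing: %.3g of spectral power in the outer Nyquist band; refine the grid",
        frac))
  }
  kn <- 2 * pi * field$medium_index / field$wavelength_vac
  arg <- outer(kx^2, ky^2, "+")
  kz <- sqrt(pmax(kn^2 - arg, 0))
  kernel <- exp(1i * distance * kz)
  kernel[arg > kn^2] <- 0
  out <- stats::fft(spec * kernel, inverse = TRUE) / length(spec)
  out <- crop_matrix(out, nrow(field$amplitude), ncol(field$amplitude))
  scalar_field(out, field$dx, field$dy, field$wavelength_vac, field$medium_index)
}

#' Ideal-lens Fourier mapping between conjugate planes
#'
#' Maps a field in the front focal plane of an ideal lens to the back focal
#' plane via a scaled Fourier transform with coordinate mapping
#' `u = x / (lambda * f)`. The discrete transform is normalized so that
#' Parseval power equality holds exactly; applying the mapping twice
#' reproduces the input field spatially inverted.
#'
#' @param field a [scalar_field()] in the front focal plane.
#' @param focal_length lens focal length in micrometres (> 0).
#' @return A [scalar_field()] in the back focal plane; the output pitch is
#'   `lambda * f / (n_samples * input_pitch)` per axis.
#' @export
lens_fourier <- function(field, focal_length) {
  stopifnot(inherits(field, "scalar_field"))
  if (!is.numeric(focal_length) || length(focal_length) != 1 ||
      !is.finite(focal_length) || focal_length <= 0)
    stop("`focal_length` must be a positive scalar")
  lam <- field$wavelength_vac
  amp <- field$amplitude
  n1 <- nrow(amp); n2 <- ncol(amp)
  out <- fftshift_mat(stats::fft(ifftshift_mat(amp))) * field$dx * field$dy / (lam * focal_length)
  du <- lam * focal_length / (n1 * field$dx)
  dv <- lam * focal_length / (n2 * field$dy)
  scalar_field(out, du, dv, lam, field$medium_index)
}

#' 3D intensity volume of a light beam
#'
#' Axis convention: x is the propagation direction, y the sheet width, z the
#' sheet thickness. The intensity array is stored as `[z, y, x]`, i.e.
#' `intensity[ , , j]` is the transverse image of plane `j`, with voxel
#' centers at `origin + index * pitch` (0-based indices).
#'
#' @param intensity non-negative 3D array `[z, y, x]`.
#' @param dx plane spacing along the propagation axis (micrometres).
#' @param dy,dz transverse pitches (micrometres).
#' @param origin coordinates `c(x0, y0, z0)` of voxel (0, 0, 0) in the sample
#'   frame (micrometres).
#' @param family optional label, e.g. `"lattice"` or `"gaussian"`.
#' @param meta optional metadata list.
#' @return Object of class `beam_volume`.
#' @export
beam_volume <- function(intensity, dx, dy, dz, origin = c(0, 0, 0),
                        family = NULL, meta = list()) {
  if (length(dim(intensity)) != 3) stop("`intensity` must be a 3D array")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (any(!is.finite(c(dx, dy, dz))) || any(c(dx, dy, dz) <= 0))
    stop("voxel pitches must be positive")
  structure(
    list(intensity = intensity, dx = dx, dy = dy, dz = dz,
         origin = as.numeric(origin), family = family, meta = meta),
    class = "beam_volume")
}

#' @export
print.beam_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<beam_volume%s> %d z x %d y x %d planes, pitch (dx, dy, dz) = (%.3g, %.3g, %.3g) um\n",
              if (!is.null(x$family)) paste0(": ", x$family) else "",
              d[1], d[2], d[3], x$dx, x$dy, x$dz))
  cat(sprintf("  x range [%.4g, %.4g] um, peak intensity %.4g\n",
              x$origin[1], x$origin[1] + (d[3] - 1) * x$dx, max(x$intensity)))
  invisible(x)
}

#' @export
plot.beam_volume <- function(x, view = c("side", "top"), ...) {
  view <- match.arg(view)
  img <- max_intensity_projection(x, axis = if (view == "side") "y" else "z")
  graphics::image(volume_x(x), if (view == "side") volume_z(x) else volume_y(x),
                  t(img), xlab = "x (um)",
                  ylab = if (view == "side") "z (um)" else "y (um)",
                  col = grDevices::hcl.colors(64, "inferno"), useRaster = TRUE, ...)
  invisible(x)
}

#' @rdname beam_volume
#' @param volume a `beam_volume`.
#' @export
volume_x <- function(volume) volume$origin[1] + (seq_len(dim(volume$intensity)[3]) - 1) * volume$dx

#' @rdname beam_volume
#' @export
volume_y <- function(volume) volume$origin[2] + (seq_len(dim(volume$intensity)[2]) - 1) * volume$dy

#' @rdname beam_volume
#' @export
volume_z <- function(volume) volume$origin[3] + (seq_len(dim(volume$intensity)[1]) - 1) * volume$dz

#' Synthesize a beam volume by repeated propagation of a focal field
#'
#' Plane `j` of the result is `|propagate(focal_field, x_j)|^2` for `n_planes`
#' uniformly spaced positions between `x_min` and `x_max`. The spectrum of the
#' focal field is computed once and each plane needs only one inverse FFT.
#'
#' @param focal_field the [scalar_field()] at `x = 0` (the focal plane);
#'   axis 1 is z (thickness), axis 2 is y (width).
#' @param x_min,x_max propagation range in micrometres (`x_min < x_max`).
#' @param n_planes number of planes (>= 2).
#' @param pad zero-padding factor for the spectral step (default 1; the
#'   focal fields used here are compact on a wide grid).
#' @param z_keep,y_keep optional half-widths (micrometres): the stored volume
#'   is cropped to `|z| <= z_keep`, `|y| <= y_keep` to bound memory.
#' @return A [beam_volume()].
#' @export
synthesize_volume <- function(focal_field, x_min, x_max, n_planes,
                              pad = 1, z_keep = NULL, y_keep = NULL) {
  stopifnot(inherits(focal_field, "scalar_field"))
  if (!is.numeric(n_planes) || n_planes < 2) stop("`n_planes` must be >= 2")
  if (!is.finite(x_min) || !is.finite(x_max) || x_min >= x_max)
    stop("need a non-degenerate range with x_min < x_max")
  amp <- pad_matrix(focal_field$amplitude, pad)
  spec <- stats::fft(amp)
  kx <- k_freqs(nrow(amp), focal_field$dx)
  ky <- k_freqs(ncol(amp), focal_field$dy)
  kn <- 2 * pi * focal_field$medium_index / focal_field$wavelength_vac
  arg <- outer(kx^2, ky^2, "+")
  kz <- sqrt(pmax(kn^2 - arg, 0))
  prop_mask <- arg <= kn^2

  nz <- nrow(focal_field$amplitude); ny <- ncol(focal_field$amplitude)
  zc <- grid_coords(nz, focal_field$dx)
  yc <- grid_coords(ny, focal_field$dy)
  keep_z <- if (is.null(z_keep)) rep(TRUE, nz) else abs(zc) <= z_keep
  keep_y <- if (is.null(y_keep)) rep(TRUE, ny) else abs(yc) <= y_keep
  if (!any(keep_z) || !any(keep_y)) stop("crop window excludes the whole grid")

  x_pos <- seq(x_min, x_max, length.out = n_planes)
  out <- array(0, c(sum(keep_z), sum(keep_y), n_planes))
  for (j in seq_len(n_planes)) {
    if (x_pos[j] == 0) {
      plane <- focal_field$amplitude
    } else {
      kernel <- exp(1i * x_pos[j] * kz)
      kernel[!prop_mask] <- 0
      plane <- stats::fft(spec * kernel, inverse = TRUE) / length(spec)
      plane <- crop_matrix(plane, nz, ny)
    }
    out[, , j] <- Mod(plane[keep_z, keep_y, drop = FALSE])^2
  }
  beam_volume(out, dx = diff(x_pos[1:2]), dy = focal_field$dy, dz = focal_field$dx,
              origin = c(x_min, min(yc[keep_y]), min(zc[keep_z])),
              meta = list(wavelength_vac = focal_field$wavelength_vac,
                          medium_index = focal_field$medium_index))
}
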