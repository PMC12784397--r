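#' Fit the 1/e^2 intensity radius of a single-peak profile
#'
#' Least-squares fit of `I(r) = I0 * exp(-2 (r - r0)^2 / w^2) + offset` to a
#' 1D intensity profile. Multi-lobe profiles (e.g. a lattice cross-section)
#' can be restricted to the central lobe, defined as the region between the
#' first local minima flanking the dominant peak, so that side lobes do not
#' bias the fit.
#'
#' @param profile numeric vector of intensity samples with a single dominant
#'   peak (after central-lobe restriction).
#' @param spacing sample spacing in micrometres.
#' @param restrict_central_lobe if `TRUE`, fit only between the first local
#'   minima flanking the peak.
#' @return Fitted 1/e^2 radius `w` in micrometres, with attributes `center`
#'   (peak position relative to the first sample) and `I0`, `offset`.
#' @export
one_over_e2_radius <- function(profile, spacing, restrict_central_lobe = FALSE) {
  if (!is.numeric(profile) || length(profile) < 5) stop("profile too short to fit")
  if (!is.finite(spacing) || spacing <= 0) stop("`spacing` must be positive")
  x <- (seq_along(profile) - 1) * spacing
  y <- as.numeric(profile)
  ipk <- which.max(y)
  if (restrict_central_lobe) {
    lo <- ipk; hi <- ipk
    while (lo > 1 && y[lo - 1] <= y[lo]) lo <- lo - 1
    while (hi < length(y) && y[hi + 1] <= y[hi]) hi <- hi + 1
    if (hi - lo + 1 >= 5) { x <- x[lo:hi]; y <- y[lo:hi]; ipk <- which.max(y) }
  }
  off0 <- min(y)
  i0 <- max(y) - off0
  if (i0 <= 0) stop("profile has no peak above its baseline")
  # moment-based width start
  w <- y - off0
  mu <- sum(x * w) / sum(w)
  sd0 <- sqrt(sum((x - mu)^2 * w) / sum(w))
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- spacing
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-2 * (x - r0)^2 / w2) + off, data = dat,
                      start = list(I0 = i0, r0 = x[ipk], w2 = (2 * sd0)^2, off = off0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf(
      "1/e^2 radius fit failed (%s); peak index %d, %d samples",
      conditionMessage(e), ipk, length(y))))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["w2"]]) || cf[["w2"]] <= 0) stop("1/e^2 radius fit returned non-positive width")
  structure(sqrt(cf[["w2"]]),
            center = cf[["r0"]], I0 = cf[["I0"]], offset = cf[["off"]])
}

#' Direct 1/e^2 half-width of a profile by threshold crossing
#'
#' Model-free alternative to the Gaussian fit, appropriate for flat-top
#' profiles (e.g. the sheet width): locates the outermost crossings of
#' `peak / e^2` by linear interpolation and returns half the distance
#' between them.
#'
#' @inheritParams one_over_e2_radius
#' @return 1/e^2 half-width in micrometres.
#' @export
one_over_e2_crossing_radius <- function(profile, spacing) {
  y <- as.numeric(profile)
  thr <- max(y) / exp(2)
  above <- which(y >= thr)
  if (length(above) < 1) stop("profile never exceeds its 1/e^2 threshold")
  lo <- min(above); hi <- max(above)
  x_lo <- if (lo > 1) (lo - 1) - (y[lo] - thr) / (y[lo] - y[lo - 1]) else lo - 1
  x_hi <- if (hi < length(y)) (hi - 1) + (y[hi] - thr) / (y[hi] - y[hi + 1]) else hi - 1
  (x_hi - x_lo) / 2 * spacing
}

#' Thickness-versus-propagation curve of a light-sheet volume
#'
#' Fits the 1/e^2 thickness radius of the z-profile at the beam's y-center
#' for every x-plane of a [beam_volume()]. Planes whose fit fails are flagged
#' and excluded with a warning.
#'
#' @param volume a [beam_volume()] containing the focus.
#' @param restrict_central_lobe restrict each fit to the central lobe
#'   (recommended for lattice sheets; harmless for Gaussian sheets).
#' @param y_average number of y-columns around the y-center to average before
#'   fitting (odd, default 1).
#' @return Object of class `thickness_profile`: a data frame with columns
#'   `x_um` and `w_um` plus attributes `waist_w0` and `waist_position`.
#' @export
thickness_curve <- function(volume, restrict_central_lobe = TRUE, y_average = 1) {
  stopifnot(inherits(volume, "beam_volume"))
  d <- dim(volume$intensity)
  yc <- volume_y(volume)
  iy <- which.min(abs(yc))
  half <- (y_average - 1) %/% 2
  iys <- max(1, iy - half):min(d[2], iy + half)
  xs <- volume_x(volume)
  ws <- rep(NA_real_, d[3])
  for (j in seq_len(d[3])) {
    prof <- rowMeans(volume$intensity[, iys, j, drop = FALSE])
    ws[j] <- tryCatch(
      as.numeric(one_over_e2_radius(prof, volume$dz,
                                    restrict_central_lobe = restrict_central_lobe)),
      error = function(e) NA_real_)
  }
  bad <- is.na(ws)
  if (any(bad))
    warning(sprintf("%d of %d plane fits failed and were excluded", sum(bad), d[3]))
  if (all(bad)) stop("all plane fits failed")
  out <- data.frame(x_um = xs[!bad], w_um = ws[!bad])
  i0 <- which.min(out$w_um)
  structure(out, class = c("thickness_profile", "data.frame"),
            waist_w0 = out$w_um[i0], waist_position = out$x_um[i0])
}

#' @export
print.thickness_profile <- function(x, ...) {
  cat(sprintf("<thickness_profile> %d planes, waist %.3f um at x = %.2f um\n",
              nrow(x), attr(x, "waist_w0"), attr(x, "waist_position")))
  invisible(x)
}

#' @export
plot.thickness_profile <- function(x, ...) {
  graphics::plot(x$x_um, x$w_um, type = "l", xlab = "x (um)",
                 ylab = "1/e^2 thickness w (um)", ...)
  graphics::abline(h = sqrt(2) * attr(x, "waist_w0"), lty = 2)
  invisible(x)
}

#' Effective propagation range of a light sheet
#'
#' The effective range is the length of the longest contiguous x-interval
#' containing the waist over which the fitted 1/e^2 thickness stays within a
#' factor of sqrt(2) of the waist value (the light-sheet analogue of the
#' Gaussian confocal parameter). Sub-sample threshold crossings are located
#' by linear interpolation between planes. In `post_focus` mode the range is
#' measured from the waist forward only, mirroring measurements where the
#' pre-focus region is not accessible.
#'
#' @param profile a [thickness_curve()] result (or data frame with `x_um`,
#'   `w_um`).
#' @param mode `"symmetric"` (both sides of the waist) or `"post_focus"`.
#' @return Effective range in micrometres.
#' @export
effective_range <- function(profile, mode = c("symmetric", "post_focus")) {
  mode <- match.arg(mode)
  x <- profile$x_um; w <- profile$w_um
  if (is.unsorted(x)) { o <- order(x); x <- x[o]; w <- w[o] }
  w0 <- attr(profile, "waist_w0")
  if (is.null(w0)) w0 <- min(w)
  thr <- sqrt(2) * w0
  i0 <- which.min(w)
  n <- length(x)
  # expand right
  hi <- i0
  while (hi < n && w[hi + 1] <= thr) hi <- hi + 1
  x_hi <- if (hi < n) {
    # interpolate crossing between hi and hi+1
    x[hi] + (thr - w[hi]) / (w[hi + 1] - w[hi]) * (x[hi + 1] - x[hi])
  } else x[n]
  lo <- i0
  while (lo > 1 && w[lo - 1] <= thr) lo <- lo - 1
  x_lo <- if (lo > 1) {
    x[lo] - (thr - w[lo]) / (w[lo - 1] - w[lo]) * (x[lo] - x[lo - 1])
  } else x[1]
  if (mode == "post_focus") return(x_hi - x[i0])
  if (i0 == 1 || i0 == n)
    warning("waist lies on the domain boundary; returning the one-sided span")
  x_hi - x_lo
}

#' Maximum-intensity projection of a beam volume
#'
#' @param volume a [beam_volume()].
#' @param axis projection axis: `"x"` (propagation), `"y"` (width) or `"z"`
#'   (thickness).
#' @return A matrix: `[z, y]` for axis x, `[z, x]` for axis y, `[y, x]` for
#'   axis z.
#' @export
max_intensity_projection <- function(volume, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  v <- volume$intensity
  switch(axis,
         x = apply(v, c(1, 2), max),
         y = apply(v, c(1, 3), max),
         z = apply(v, c(2, 3), max))
}

#' Summary metrics of a light-sheet volume
#'
#' Computes the waist thickness, the 1/e^2 width of the y-profile at the
#' waist plane, and the effective range.
#'
#' @param volume a [beam_volume()].
#' @param mode effective-range mode, see [effective_range()].
#' @param restrict_central_lobe passed to [thickness_curve()].
#' @return A list of class `ls_metrics` with elements `thickness_w0`,
#'   `width_1e2`, `effective_range`, `mode` and the `thickness_profile`.
#' @export
ls_metrics <- function(volume, mode = "symmetric", restrict_central_lobe = TRUE) {
  tp <- thickness_curve(volume, restrict_central_lobe = restrict_central_lobe)
  xs <- volume_x(volume)
  j0 <- which.min(abs(xs - attr(tp, "waist_position")))
  zc <- volume_z(volume)
  iz <- which.min(abs(zc))
  yprof <- volume$intensity[iz, , j0]
  width <- tryCatch(one_over_e2_crossing_radius(yprof, volume$dy),
                    error = function(e) NA_real_)
  structure(list(thickness_w0 = attr(tp, "waist_w0"),
                 waist_position = attr(tp, "waist_position"),
                 width_1e2 = width,
                 effective_range = effective_range(tp, mode = mode),
                 mode = mode, profile = tp),
            class = "ls_metrics")
}

#' @export
print.ls_metrics <- function(x, ...) {
  cat(sprintf("<ls_metrics> waist %.3f um at x = %.2f um, width %.2f um, effective range %.2f um (%s)\n",
              x$thickness_w0, x$waist_position, x$width_1e2, x$effective_range, x$mode))
  invisible(x)
}
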