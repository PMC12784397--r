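#' Convert raw A/D counts to photons
#'
#' Inverts the EMCCD gain chain: `(adu - dark_level) * conversion_gain /
#' em_gain`.
#' @param img numeric matrix (A/D counts).
#' @param camera a [camera_model()].
#' @return Matrix of estimated photons per pixel.
#' @export
adu_to_photons <- function(img, camera) {
  (img - camera$dark_level) * camera$conversion_gain / camera$em_gain
}

## Separable convolution with replicate padding.
conv_sep <- function(img, k) {
  hw <- (length(k) - 1) %/% 2
  pad_idx <- function(n) c(rep(1, hw), seq_len(n), rep(n, hw))
  a <- img[pad_idx(nrow(img)), , drop = FALSE]
  a <- apply(a, 2, function(col) stats::filter(col, k, sides = 2))[hw + seq_len(nrow(img)), , drop = FALSE]
  b <- a[, pad_idx(ncol(img)), drop = FALSE]
  t(apply(b, 1, function(row) stats::filter(row, k, sides = 2))[hw + seq_len(ncol(img)), , drop = FALSE])
}

#' Wavelet spot detection (a trous B-spline filtering)
#'
#' Detects candidate emitters as 8-connected local maxima of the second
#' wavelet level of an undecimated B-spline (order 3) wavelet transform,
#' thresholded at `threshold_coeff` times the standard deviation of the
#' first wavelet level (the noise band). This mirrors the common
#' wavelet-filter / peak-intensity-threshold detection used in localization
#' software (B-spline order 3, scale 2).
#'
#' @param frame numeric matrix, dark-level corrected (photons or counts;
#'   the detection is scale-invariant).
#' @param threshold_coeff peak intensity threshold coefficient (default 2).
#' @return Data frame with 1-based pixel coordinates `row` (y) and `col`
#'   (x) and the wavelet response `value`, deduplicated.
#' @export
detect_candidates <- function(frame, threshold_coeff = 2) {
  k1 <- c(1, 4, 6, 4, 1) / 16
  k2 <- c(1, 0, 4, 0, 6, 0, 4, 0, 1) / 16
  v1 <- conv_sep(frame, k1)
  v2 <- conv_sep(v1, k2)
  w1 <- frame - v1
  w2 <- v1 - v2
  thr <- threshold_coeff * stats::sd(w1)
  if (!is.finite(thr) || thr <= 0) return(data.frame(row = integer(0), col = integer(0), value = numeric(0)))
  nr <- nrow(w2); nc <- ncol(w2)
  # 8-connected local maxima (strictly greater than the neighborhood max
  # with ties broken by first occurrence via >= on shifted copies)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- w2
  nb_max <- matrix(-Inf, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb_max <- pmax(nb_max, pad[2:(nr + 1) + dr, 2:(nc + 1) + dc])
  }
  hits <- which(w2 > nb_max & w2 > thr, arr.ind = TRUE)
  data.frame(row = hits[, 1], col = hits[, 2], value = w2[hits])
}

## Expected-photon model for a symmetric pixel-integrated 2D Gaussian.
gauss2d_model <- function(par, nr, nc) {
  ex <- diff(stats::pnorm(0:nc, mean = par[["x"]], sd = par[["sigma"]]))
  ey <- diff(stats::pnorm(0:nr, mean = par[["y"]], sd = par[["sigma"]]))
  par[["N"]] * outer(ey, ex) + par[["b"]]
}

#' Weighted least-squares fit of a symmetric 2D Gaussian spot
#'
#' Fits `N * G(x, y; sigma) + b` (pixel-integrated Gaussian plus constant
#' background, in photons) to a region of interest by weighted least
#' squares, with per-pixel weights equal to the inverse of the expected
#' EMCCD variance (`excess_noise_factor * model + (read_noise / em_gain)^2`
#' photons^2), iteratively re-weighted once. Non-convergence or a
#' non-positive photon count rejects the record with a reason.
#'
#' @param roi numeric matrix containing one candidate spot, in A/D counts
#'   (default) or photons.
#' @param camera a [camera_model()].
#' @param units `"adu"` or `"photons"`.
#' @param sigma_start starting sigma in pixels.
#' @return List with `ok`; on success `x_px`, `y_px` (0-based pixel
#'   coordinates), `x_um`, `y_um`, `sigma_px`, `sigma_um`, `N` (photons),
#'   `b` (photons/pixel); on rejection `reason`.
#' @export
fit_gaussian2d_wls <- function(roi, camera = camera_model(),
                               units = c("adu", "photons"), sigma_start = 1.05) {
  units <- match.arg(units)
  img <- if (units == "adu") adu_to_photons(roi, camera) else roi
  nr <- nrow(img); nc <- ncol(img)
  b0 <- max(stats::quantile(img, 0.25), 1e-3)
  pos <- pmax(img - b0, 0)
  tot <- sum(pos)
  if (tot <= 0) return(list(ok = FALSE, reason = "no signal above background"))
  xs <- (seq_len(nc) - 0.5); ys <- (seq_len(nr) - 0.5)
  x0 <- sum(colSums(pos) * xs) / tot
  y0 <- sum(rowSums(pos) * ys) / tot
  par <- c(x = x0, y = y0, sigma = sigma_start, N = tot, b = b0)
  var_floor <- (camera$read_noise / camera$em_gain * camera$conversion_gain /
                  camera$conversion_gain)^2  # photons^2
  w <- NULL
  for (pass in 1:2) {
    mu <- gauss2d_model(par, nr, nc)
    w <- 1 / pmax(camera$excess_noise_factor * mu + var_floor, 1e-6)
    res_fn <- function(p) {
      p <- stats::setNames(p, names(par))
      if (p[["sigma"]] <= 0.1 || p[["N"]] < 0) return(rep(1e6, length(img)))
      as.vector((gauss2d_model(p, nr, nc) - img) * sqrt(w))
    }
    fit <- tryCatch(minpack.lm::nls.lm(par, fn = res_fn,
                                       control = minpack.lm::nls.lm.control(maxiter = 100)),
                    error = function(e) NULL)
    if (is.null(fit)) return(list(ok = FALSE, reason = "fit error"))
    par <- stats::setNames(stats::coef(fit), names(par))
  }
  if (fit$info %in% c(0, 9)) return(list(ok = FALSE, reason = "non-convergence"))
  if (par[["N"]] <= 0) return(list(ok = FALSE, reason = "negative photon count"))
  px <- camera$pixel_size_x_um; py <- camera$pixel_size_y_um
  list(ok = TRUE,
       x_px = unname(par[["x"]]), y_px = unname(par[["y"]]),
       x_um = unname(par[["x"]]) * px, y_um = unname(par[["y"]]) * py,
       sigma_px = unname(par[["sigma"]]),
       sigma_um = unname(par[["sigma"]]) * sqrt(px * py),
       N = unname(par[["N"]]), b = unname(par[["b"]]))
}

#' EMCCD localization precision from fitted spot parameters
#'
#' Least-squares precision of a pixel-integrated Gaussian fit with the
#' shot-noise and background terms inflated by the EM excess noise factor:
#'
#' `sigma_loc^2 = (sa^2 / N) * (F * 16/9 + 8 * pi * sa^2 * F * b / (N * a^2))`
#'
#' with `sa^2 = sigma^2 + a^2 / 12` the pixelation-corrected PSF variance,
#' `N` signal photons, `b` background photons per pixel, `a` the pixel size
#' and `F = 2` the excess noise factor. The expression is validated against
#' the Monte-Carlo fitting ensemble, which is the authoritative contract.
#'
#' @param N signal photons (> 0; vectorized).
#' @param b background photons per pixel (>= 0).
#' @param sigma_um fitted PSF sigma in micrometres.
#' @param pixel_um pixel size in micrometres.
#' @param excess_noise_factor EM excess noise factor (default 2).
#' @return Localization precision in nanometres.
#' @export
precision_emccd <- function(N, b, sigma_um = 1.05 * 0.158, pixel_um = 0.158,
                            excess_noise_factor = 2) {
  if (any(N <= 0)) stop("`N` must be positive")
  if (any(b < 0)) stop("`b` must be non-negative")
  sa2 <- sigma_um^2 + pixel_um^2 / 12
  f <- excess_noise_factor
  var_um2 <- (sa2 / N) * (f * 16 / 9 + 8 * pi * sa2 * f * b / (N * pixel_um^2))
  sqrt(var_um2) * 1000
}

## Two-lobe expected-photon model (shared sigma, equal lobes).
dh_model <- function(par, nr, nc, sep_px_x, sep_px_y) {
  th <- par[["theta"]]
  dx <- sep_px_x * cos(th) / 2
  dy <- sep_px_y * sin(th) / 2
  half <- function(cx, cy) {
    ex <- diff(stats::pnorm(0:nc, mean = cx, sd = par[["sigma"]]))
    ey <- diff(stats::pnorm(0:nr, mean = cy, sd = par[["sigma"]]))
    outer(ey, ex)
  }
  par[["N"]] / 2 * (half(par[["x"]] + dx, par[["y"]] + dy) +
                    half(par[["x"]] - dx, par[["y"]] - dy)) + par[["b"]]
}

wrap_half_deg <- function(a) {
  a <- (a + 90) %% 180
  a[a == 0] <- 180
  a - 90
}

#' Double-Gaussian fit of a double-helix spot with z from the lobe angle
#'
#' Fits two equal Gaussian lobes with fixed separation and shared width to a
#' region of interest; the lateral position is the lobe midpoint, the depth
#' follows from inverting the linear angle model `theta(z) = theta0 +
#' rate * z` after wrapping the fitted angle into (-90, 90] degrees (which
#' resolves the lobe-exchange degeneracy).
#'
#' @param roi numeric matrix containing both lobes (A/D counts or photons).
#' @param psf a [psf_model()] with family `"double_helix"`.
#' @param camera a [camera_model()].
#' @param units `"adu"` or `"photons"`.
#' @return List with `ok`; on success `x_um`, `y_um`, `z_um`, `N`, `b`,
#'   `theta_deg`, `sigma_px`; on rejection `reason`.
#' @export
fit_dh_double_gaussian <- function(roi, psf, camera = camera_model(),
                                   units = c("adu", "photons")) {
  stopifnot(inherits(psf, "psf_model"))
  if (psf$family != "double_helix") stop("`psf` must be a double-helix model")
  units <- match.arg(units)
  img <- if (units == "adu") adu_to_photons(roi, camera) else roi
  nr <- nrow(img); nc <- ncol(img)
  sep_px_x <- psf$lobe_sep_um / camera$pixel_size_x_um
  sep_px_y <- psf$lobe_sep_um / camera$pixel_size_y_um
  if (sep_px_x + 4 > nc || sep_px_y + 4 > nr)
    return(list(ok = FALSE, reason = "patch too small for both lobes"))
  b0 <- max(stats::quantile(img, 0.25), 1e-3)
  pos <- pmax(img - b0, 0)
  tot <- sum(pos)
  if (tot <= 0) return(list(ok = FALSE, reason = "no signal above background"))
  xs <- seq_len(nc) - 0.5; ys <- seq_len(nr) - 0.5
  x0 <- sum(colSums(pos) * xs) / tot
  y0 <- sum(rowSums(pos) * ys) / tot
  # orientation from the principal axis of the second moments
  xx <- outer(rep(1, nr), xs) - x0
  yy <- outer(ys, rep(1, nc)) - y0
  mxx <- sum(pos * xx^2) / tot; myy <- sum(pos * yy^2) / tot
  mxy <- sum(pos * xx * yy) / tot
  th0 <- 0.5 * atan2(2 * mxy, mxx - myy)
  par <- c(x = x0, y = y0, theta = th0, sigma = psf$sigma0_px, N = tot, b = b0)
  res_fn <- function(p) {
    p <- stats::setNames(p, names(par))
    if (p[["sigma"]] <= 0.1 || p[["N"]] < 0) return(rep(1e6, length(img)))
    mu <- dh_model(p, nr, nc, sep_px_x, sep_px_y)
    w <- 1 / pmax(2 * mu, 1e-6)
    as.vector((mu - img) * sqrt(w))
  }
  fit <- tryCatch(minpack.lm::nls.lm(par, fn = res_fn,
                                     control = minpack.lm::nls.lm.control(maxiter = 200)),
                  error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0, 9))
    return(list(ok = FALSE, reason = "non-convergence"))
  par <- stats::setNames(stats::coef(fit), names(par))
  if (par[["N"]] <= 0) return(list(ok = FALSE, reason = "negative photon count"))
  theta_deg <- wrap_half_deg(par[["theta"]] * 180 / pi - psf$theta0_deg)
  z_um <- theta_deg / psf$rot_rate_deg_per_um
  if (abs(z_um) > psf$z_range_um / 2 * 1.05)
    return(list(ok = FALSE, reason = "z outside usable range"))
  px <- camera$pixel_size_x_um; py <- camera$pixel_size_y_um
  list(ok = TRUE,
       x_um = unname(par[["x"]]) * px, y_um = unname(par[["y"]]) * py,
       z_um = unname(z_um), N = unname(par[["N"]]), b = unname(par[["b"]]),
       theta_deg = unname(theta_deg) + psf$theta0_deg,
       sigma_px = unname(par[["sigma"]]))
}

#' Localize an entire simulated movie
#'
#' Runs wavelet detection and spot fitting on every frame and assembles a
#' localization table. With a Gaussian PSF each spot is fit by
#' [fit_gaussian2d_wls()]; with a double-helix PSF, lobe pairs are fit by
#' [fit_dh_double_gaussian()] on a larger window. Lateral uncertainties come
#' from [precision_emccd()]; the axial uncertainty of double-helix fits uses
#' the lobe-angle error propagated through the rotation rate.
#'
#' @param movie an `smlm_movie` from [simulate_frames()], or a list of
#'   matrices in A/D counts (then `camera`, `psf` must be given).
#' @param camera,psf override the movie's own camera/PSF models.
#' @param threshold_coeff detection threshold coefficient.
#' @param roi_px fitting window size (odd; default 11 for Gaussian, grown to
#'   cover both lobes for the double helix).
#' @param min_photons drop fits below this photon count (default 0).
#' @return A `localization_table` data frame: `frame`, `x_um`, `y_um`
#'   (`z_um` for double helix), `photons`, `background`, `sigma_um`,
#'   `uncertainty_xy_nm` (`uncertainty_z_nm`), with attribute `rejected`
#'   counting rejections by reason.
#' @export
localize_movie <- function(movie, camera = NULL, psf = NULL,
                           threshold_coeff = 2, roi_px = NULL, min_photons = 0) {
  center_off <- c(0, 0)  # origin offset: movie objects use a centered frame
  if (inherits(movie, "smlm_movie")) {
    frames <- movie$frames
    camera <- camera %||% movie$camera
    psf <- psf %||% movie$psf
    center_off <- c(movie$fov_px[1] / 2, movie$fov_px[2] / 2)
  } else frames <- movie
  if (is.null(camera) || is.null(psf)) stop("`camera` and `psf` are required")
  dh <- psf$family == "double_helix"
  if (is.null(roi_px))
    roi_px <- if (dh) {
      2 * ceiling((psf$lobe_sep_um / min(camera$pixel_size_x_um, camera$pixel_size_y_um) +
                     4 * psf$sigma0_px) / 2) + 1
    } else 11
  half <- roi_px %/% 2
  px <- camera$pixel_size_x_um; py <- camera$pixel_size_y_um
  rows <- list()
  rejected <- c()
  for (fr in seq_along(frames)) {
    img <- adu_to_photons(frames[[fr]], camera)
    cand <- detect_candidates(img, threshold_coeff)
    if (dh && nrow(cand) > 1) {
      # merge candidate pairs closer than the lobe separation (two lobes of
      # one emitter) into their midpoint
      keep <- rep(TRUE, nrow(cand))
      sep_px <- psf$lobe_sep_um / sqrt(px * py)
      for (i in seq_len(nrow(cand) - 1)) for (j in (i + 1):nrow(cand)) {
        if (keep[i] && keep[j] &&
            (cand$row[i] - cand$row[j])^2 + (cand$col[i] - cand$col[j])^2 <=
              (1.2 * sep_px)^2) {
          cand$row[i] <- (cand$row[i] + cand$row[j]) / 2
          cand$col[i] <- (cand$col[i] + cand$col[j]) / 2
          keep[j] <- FALSE
        }
      }
      cand <- cand[keep, , drop = FALSE]
    }
    for (k in seq_len(nrow(cand))) {
      r0 <- round(cand$row[k]); c0 <- round(cand$col[k])
      if (r0 - half < 1 || r0 + half > nrow(img) ||
          c0 - half < 1 || c0 + half > ncol(img)) {
        rejected["border"] <- (rejected["border"] %||% 0) + 1; next
      }
      roi <- img[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
      fit <- if (dh) fit_dh_double_gaussian(roi, psf, camera, units = "photons")
             else fit_gaussian2d_wls(roi, camera, units = "photons")
      if (!fit$ok) { rejected[fit$reason] <- (rejected[fit$reason] %||% 0) + 1; next }
      if (fit$N < min_photons) { rejected["min_photons"] <- (rejected["min_photons"] %||% 0) + 1; next }
      sig_um <- if (dh) fit$sigma_px * sqrt(px * py) else fit$sigma_um
      unc <- precision_emccd(fit$N, max(fit$b, 0), sig_um, sqrt(px * py),
                             camera$excess_noise_factor)
      row <- data.frame(
        frame = fr,
        x_um = (c0 - 1 - half - center_off[1]) * px + fit$x_um,
        y_um = (r0 - 1 - half - center_off[2]) * py + fit$y_um,
        photons = fit$N, background = fit$b, sigma_um = sig_um,
        uncertainty_xy_nm = unc)
      if (dh) {
        row$z_um <- fit$z_um
        # angle error from the per-lobe lateral error across the half
        # separation, through the rotation rate
        lobe_prec_nm <- precision_emccd(fit$N / 2, max(fit$b, 0), sig_um,
                                        sqrt(px * py), camera$excess_noise_factor)
        dtheta <- lobe_prec_nm / 1000 / (psf$lobe_sep_um / 2)  # radians
        row$uncertainty_z_nm <- dtheta * 180 / pi / psf$rot_rate_deg_per_um * 1000
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(frame = integer(0), x_um = numeric(0), y_um = numeric(0),
               photons = numeric(0), background = numeric(0),
               sigma_um = numeric(0), uncertainty_xy_nm = numeric(0))
  structure(out, class = c("localization_table", "data.frame"),
            rejected = rejected)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Fiducial-based drift correction
#'
#' Estimates per-frame stage drift as the mean displacement of the fiducial
#' localizations from their per-fiducial mean positions, fills frames
#' without fiducial coverage by linear interpolation, smooths the trajectory
#' with a centered moving average, and subtracts it from all localizations.
#'
#' @param locs a localization table (columns `frame`, `x_um`, `y_um`,
#'   optionally `z_um`).
#' @param fiducials localization table of the fiducial beads (same columns,
#'   optionally an `id` column when several beads are present).
#' @param smoothing_window moving-average window in frames (default 50).
#' @return The corrected table, with the estimated drift per frame in
#'   attribute `drift` and the per-axis fiducial standard deviations before
#'   and after correction in attribute `fiducial_sd`.
#' @export
drift_correct <- function(locs, fiducials, smoothing_window = 50) {
  if (is.null(fiducials) || nrow(fiducials) == 0) stop("no fiducials provided")
  axes <- intersect(c("x_um", "y_um", "z_um"), names(locs))
  axes <- intersect(axes, names(fiducials))
  if (!"id" %in% names(fiducials)) fiducials$id <- 1L
  frames <- seq(min(locs$frame, fiducials$frame), max(locs$frame, fiducials$frame))
  drift <- matrix(NA_real_, length(frames), length(axes),
                  dimnames = list(NULL, axes))
  disp <- fiducials
  for (ax in axes)
    disp[[ax]] <- disp[[ax]] - stats::ave(disp[[ax]], disp$id, FUN = mean)
  agg <- stats::aggregate(disp[axes], by = list(frame = disp$frame), FUN = mean)
  drift[match(agg$frame, frames), ] <- as.matrix(agg[axes])
  smooth_ma <- function(v) {
    if (all(is.na(v))) stop("fiducials cover no frames")
    v <- stats::approx(frames[!is.na(v)], v[!is.na(v)], xout = frames, rule = 2)$y
    w <- min(smoothing_window, length(v))
    kern <- rep(1, w)
    num <- stats::filter(v, kern, sides = 2)
    den <- stats::filter(rep(1, length(v)), kern, sides = 2)
    sm <- as.numeric(num / den)
    # partial windows at the edges
    na <- is.na(sm)
    if (any(na)) {
      cs <- cumsum(v); n <- length(v); hw <- w %/% 2
      for (i in which(na)) {
        lo <- max(1, i - hw); hi <- min(n, i + hw)
        sm[i] <- (cs[hi] - if (lo > 1) cs[lo - 1] else 0) / (hi - lo + 1)
      }
    }
    sm
  }
  for (ax in axes) drift[, ax] <- smooth_ma(drift[, ax])
  pre_sd <- vapply(axes, function(ax) stats::sd(disp[[ax]]), numeric(1))
  correct <- function(tab) {
    idx <- match(tab$frame, frames)
    for (ax in axes) tab[[ax]] <- tab[[ax]] - drift[idx, ax]
    tab
  }
  out <- correct(locs)
  fid_c <- correct(fiducials)
  for (ax in axes)
    fid_c[[ax]] <- fid_c[[ax]] - stats::ave(fid_c[[ax]], fid_c$id, FUN = mean)
  post_sd <- vapply(axes, function(ax) stats::sd(fid_c[[ax]]), numeric(1))
  structure(out, drift = as.data.frame(cbind(frame = frames, drift)),
            fiducial_sd = rbind(pre = pre_sd, post = post_sd))
}

#' Threshold filtering of localization tables
#'
#' Removes records failing any rule; removal counts per rule are attached as
#' attribute `removed` and reported via a message. Rule names map to
#' columns: `max_uncertainty_xy_nm` / `max_uncertainty_z_nm` (upper bounds),
#' `min_photons` / `max_photons`. A rule whose column is absent from the
#' table is an error.
#'
#' @param locs localization table.
#' @param rules named list of thresholds, e.g.
#'   `list(max_uncertainty_xy_nm = 100, max_photons = 1e6)` (the outlier
#'   rules of the scattering comparison) or
#'   `list(max_uncertainty_xy_nm = 42, max_uncertainty_z_nm = 50,
#'   min_photons = 3000)` (a two-target rendering rule set).
#' @return Filtered table (row order preserved).
#' @export
filter_localizations <- function(locs, rules) {
  colmap <- c(max_uncertainty_xy_nm = "uncertainty_xy_nm",
              max_uncertainty_z_nm = "uncertainty_z_nm",
              min_photons = "photons", max_photons = "photons")
  unknown <- setdiff(names(rules), names(colmap))
  if (length(unknown)) stop("unknown rule(s): ", paste(unknown, collapse = ", "))
  keep <- rep(TRUE, nrow(locs))
  removed <- integer(0)
  for (rn in names(rules)) {
    col <- colmap[[rn]]
    if (!col %in% names(locs))
      stop(sprintf("rule `%s` references missing column `%s`", rn, col))
    bad <- if (startsWith(rn, "min")) locs[[col]] < rules[[rn]]
           else locs[[col]] > rules[[rn]]
    bad[is.na(bad)] <- FALSE
    removed[rn] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (nrow(locs) > 0 && sum(removed) > 0)
    message(sprintf("filtered %d of %d localizations (%s)",
                    sum(!keep), nrow(locs),
                    paste(sprintf("%s: %d", names(removed), removed), collapse = ", ")))
  structure(locs[keep, , drop = FALSE], removed = removed)
}

#' Rescale axial coordinates for refractive-index mismatch
#'
#' Multiplies every z coordinate by `factor` (default 0.75, the correction
#' for focusing from glass into an aqueous sample); all other columns are
#' untouched.
#'
#' @param locs localization table with a `z_um` (or `z_nm`) column.
#' @param factor axial scaling factor.
#' @return The rescaled table.
#' @export
rescale_axial <- function(locs, factor = 0.75) {
  zcol <- intersect(c("z_um", "z_nm"), names(locs))
  if (length(zcol) == 0) stop("no z column present")
  for (cn in zcol) locs[[cn]] <- locs[[cn]] * factor
  locs
}

#' Per-localization signal-to-background ratio
#'
#' SBR of each localization as the fitted peak per-pixel signal over the
#' fitted background: `photons * pixel_area / (2 * pi * sigma^2) /
#' background`. Zero-background records are flagged infinite and excluded
#' from summary means.
#'
#' @param locs localization table with `photons`, `background`, `sigma_um`.
#' @param pixel_area_um2 camera pixel area (default 0.157 x 0.159).
#' @return The table with an `sbr` column appended.
#' @export
compute_sbr <- function(locs, pixel_area_um2 = 0.157 * 0.159) {
  need <- c("photons", "background", "sigma_um")
  if (!all(need %in% names(locs))) stop("columns required: ", paste(need, collapse = ", "))
  peak <- locs$photons * pixel_area_um2 / (2 * pi * locs$sigma_um^2)
  locs$sbr <- ifelse(locs$background > 0, peak / locs$background, Inf)
  locs
}

#' Signal-to-background ratio from an intensity line scan
#'
#' Diffraction-limited SBR estimate: the peak of the line scan over the mean
#' background measured in a window of `background_window_um` (the window
#' with the lowest mean is used).
#'
#' @param profile numeric intensity line scan.
#' @param spacing_um sample spacing.
#' @param background_window_um background window length (default 1.6).
#' @return SBR (peak / mean background).
#' @export
compute_sbr_linescan <- function(profile, spacing_um, background_window_um = 1.6) {
  wlen <- max(1, round(background_window_um / spacing_um))
  if (wlen >= length(profile)) stop("background window longer than the profile")
  means <- stats::filter(profile, rep(1 / wlen, wlen), sides = 2)
  bg <- min(means, na.rm = TRUE)
  if (bg <= 0) return(Inf)
  max(profile) / bg
}

#' Region statistics of a localization table
#'
#' Bins localizations into `n_regions` rectangular regions of equal area
#' along one axis (region 1 nearest the lower/reference edge, e.g. the
#' mirror side) and reports per-region counts, counts normalized to region
#' 1, and mean +/- sd of the SBR and lateral uncertainty where available.
#'
#' @param locs localization table.
#' @param n_regions number of regions (default 5).
#' @param axis binning axis, `"x"` or `"y"`.
#' @param bounds FOV bounds `c(min, max)` along the axis; defaults to the
#'   data range.
#' @return Data frame of class `region_stats` with one row per region.
#' @export
bin_regions <- function(locs, n_regions = 5, axis = c("x", "y"), bounds = NULL) {
  axis <- match.arg(axis)
  col <- paste0(axis, "_um")
  if (!col %in% names(locs)) stop("missing column ", col)
  if (is.null(bounds)) bounds <- range(locs[[col]])
  edges <- seq(bounds[1], bounds[2], length.out = n_regions + 1)
  idx <- findInterval(locs[[col]], edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > n_regions] <- NA
  stat <- function(v) {
    vapply(seq_len(n_regions), function(r) {
      vv <- v[!is.na(idx) & idx == r]
      vv <- vv[is.finite(vv)]
      if (length(vv)) c(mean(vv), stats::sd(vv)) else c(NA_real_, NA_real_)
    }, numeric(2))
  }
  counts <- vapply(seq_len(n_regions), function(r) sum(!is.na(idx) & idx == r), numeric(1))
  out <- data.frame(region = seq_len(n_regions), count = counts)
  if (counts[1] == 0) {
    warning("region 1 is empty; normalized counts undefined")
    out$norm_count <- NA_real_
  } else out$norm_count <- counts / counts[1]
  if ("sbr" %in% names(locs)) {
    s <- stat(locs$sbr); out$sbr_mean <- s[1, ]; out$sbr_sd <- s[2, ]
  }
  if ("uncertainty_xy_nm" %in% names(locs)) {
    s <- stat(locs$uncertainty_xy_nm)
    out$uncertainty_mean_nm <- s[1, ]; out$uncertainty_sd_nm <- s[2, ]
  }
  structure(out, class = c("region_stats", "data.frame"), edges = edges)
}

#' Fourier ring correlation resolution of a localization data set
#'
#' Randomly splits the localizations in half, renders each half as a 2D
#' histogram with super-resolution pixels of `sr_pixel_nm`, computes the
#' ring-averaged correlation of their Fourier transforms, and returns the
#' inverse of the spatial frequency at which the curve first drops below
#' the fixed 1/7 threshold. If the curve never drops below 1/7 the result is
#' bounded by twice the super-resolution pixel (the render Nyquist limit).
#'
#' @param locs localization table (`x_um`, `y_um`).
#' @param sr_pixel_nm super-resolution pixel size (default 8).
#' @param seed RNG seed of the random split.
#' @param n_splits number of random splits averaged (default 1).
#' @param min_locs minimum number of localizations (default 100; >= 1000
#'   recommended for a stable estimate).
#' @param halves optional list of two index vectors forcing the split.
#' @return FRC resolution in nanometres, with the FRC curve of the last
#'   split in attribute `frc`.
#' @export
frc_resolution <- function(locs, sr_pixel_nm = 8, seed = 1, n_splits = 1,
                           min_locs = 100, halves = NULL) {
  n <- nrow(locs)
  if (n < min_locs) stop(sprintf("too few localizations (%d < %d)", n, min_locs))
  x <- locs$x_um * 1000; y <- locs$y_um * 1000
  x <- x - min(x); y <- y - min(y)
  npix <- 2 * ceiling((max(max(x), max(y)) / sr_pixel_nm + 8) / 2)
  hist2 <- function(sel) {
    ix <- pmin(floor(x[sel] / sr_pixel_nm), npix - 1)
    iy <- pmin(floor(y[sel] / sr_pixel_nm), npix - 1)
    m <- matrix(0, npix, npix)
    tab <- table(iy * npix + ix)
    m[as.integer(names(tab)) + 1] <- as.integer(tab)
    m
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  kx <- c(0:(npix / 2), (npix / 2 - 1):1)
  ring <- outer(kx^2, kx^2, "+")
  ring <- round(sqrt(ring))
  ring_f <- factor(ring, levels = 0:(npix / 2))
  res <- numeric(n_splits)
  frc_curve <- NULL
  for (s in seq_len(n_splits)) {
    if (!is.null(halves)) { i1 <- halves[[1]]; i2 <- halves[[2]] }
    else { i1 <- sample(n, n %/% 2); i2 <- setdiff(seq_len(n), i1) }
    f1 <- stats::fft(hist2(i1)); f2 <- stats::fft(hist2(i2))
    num <- Re(f1 * Conj(f2))
    d1 <- Mod(f1)^2; d2 <- Mod(f2)^2
    rnum <- tapply(num, ring_f, sum)
    rd1 <- tapply(d1, ring_f, sum); rd2 <- tapply(d2, ring_f, sum)
    frc <- as.numeric(rnum / sqrt(rd1 * rd2))
    frc[is.na(frc)] <- 0
    q <- (0:(npix / 2)) / (npix * sr_pixel_nm)  # 1/nm
    usable <- seq(2, floor(npix / 2 * 0.9))
    below <- which(frc[usable] < 1 / 7)
    if (length(below) == 0) {
      res[s] <- 2 * sr_pixel_nm
    } else {
      i <- usable[below[1]]
      # linear interpolation of the crossing between i-1 and i
      f_hi <- frc[i - 1]; f_lo <- frc[i]
      t <- (f_hi - 1 / 7) / (f_hi - f_lo)
      qc <- q[i - 1] + t * (q[i] - q[i - 1])
      res[s] <- max(1 / qc, 2 * sr_pixel_nm)
    }
    frc_curve <- data.frame(q_per_nm = q, frc = frc)
  }
  structure(mean(res), frc = frc_curve)
}
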