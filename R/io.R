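#' Write a beam volume as a multi-page 32-bit float TIFF with YAML sidecar
#'
#' One TIFF page per x-plane. Intensities are stored normalized to [0, 1];
#' the normalization factor, voxel pitches, origin and family are recorded
#' in a YAML sidecar (`<path>.yaml`) so the volume round-trips losslessly up
#' to float precision.
#'
#' @param volume a [beam_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_beam_volume <- function(volume, path) {
  stopifnot(inherits(volume, "beam_volume"))
  peak <- max(volume$intensity)
  scale <- if (peak > 0) peak else 1
  d <- dim(volume$intensity)
  pages <- lapply(seq_len(d[3]), function(j) volume$intensity[, , j] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  side <- list(dx_um = volume$dx, dy_um = volume$dy, dz_um = volume$dz,
               origin_um = as.numeric(volume$origin),
               intensity_scale = scale,
               family = volume$family %||% "unknown",
               n_planes = d[3])
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a beam volume written by [write_beam_volume()]
#'
#' @param path TIFF path (expects `<path>.yaml` sidecar).
#' @return A [beam_volume()].
#' @export
read_beam_volume <- function(path) {
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (j in seq_along(pages)) arr[, , j] <- pages[[j]] * side$intensity_scale
  fam <- side$family
  beam_volume(arr, side$dx_um, side$dy_um, side$dz_um,
              origin = unlist(side$origin_um),
              family = if (identical(fam, "unknown")) NULL else fam)
}

#' Write a single-molecule movie as a multi-page 16-bit TIFF
#'
#' @param movie an `smlm_movie` (see [simulate_frames()]) or list of
#'   integer matrices in A/D counts.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  frames <- if (inherits(movie, "smlm_movie")) movie$frames else movie
  pages <- lapply(frames, function(f) pmin(pmax(f, 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path.
#' @return List of integer matrices (A/D counts).
#' @export
read_movie <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages
}

#' Write a localization table as CSV
#'
#' Plain comma-separated table with a header row; units are carried in the
#' column names (`x_um`, `uncertainty_xy_nm`, ...).
#'
#' @param locs localization table (data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  utils::write.csv(as.data.frame(locs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization table CSV
#'
#' @param path CSV path.
#' @return A `localization_table` data frame.
#' @export
read_localizations <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE)
  structure(df, class = c("localization_table", "data.frame"))
}
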