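# The in-memory MSI dataset model.
#
# Continuous mode: one shared ascending m/z axis (`mz` numeric vector) and an
# n_pixels x n_mz intensity matrix (`intensity`). Processed mode: per-pixel
# axes (`mz` and `intensity` are lists of equal-length vectors). Coordinates
# are 0-based (x, y) grid positions; the original 1-based imzML offset is
# recorded so files round-trip exactly. Missing grid positions are simply
# absent rows, never zero-filled.

#' Construct an MSI dataset
#'
#' @param coords Integer matrix (n x 2) of 0-based (x, y) pixel coordinates.
#' @param mz Shared ascending m/z axis (continuous mode) or list of per-pixel
#'   axes (processed mode).
#' @param intensity Intensity matrix n_pixels x n_mz (continuous) or list of
#'   per-pixel vectors (processed); all values must be finite and >= 0.
#' @param centroided `TRUE` for centroid (stick) spectra, `FALSE` for profile.
#' @param pixel_size_um Pixel pitch in micrometres (default 10).
#' @param normalization `"raw"` or `"tic"`.
#' @param source Provenance string (file path or generator description).
#' @param coord_offset 1-based (x, y) offset of the original grid.
#' @return An object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensity, centroided = FALSE,
                        pixel_size_um = 10, normalization = "raw",
                        source = "in-memory", coord_offset = c(1L, 1L)) {
  coords <- matrix(as.integer(coords), ncol = 2L,
                   dimnames = list(NULL, c("x", "y")))
  n <- nrow(coords)
  if (n == 0L) stop("empty dataset: no pixels", call. = FALSE)
  if (anyDuplicated(coords)) stop("duplicate pixel coordinates", call. = FALSE)
  continuous <- !is.list(mz)
  if (continuous) {
    mz <- as.numeric(mz)
    if (is.unsorted(mz, strictly = TRUE)) {
      stop("m/z axis must be strictly ascending", call. = FALSE)
    }
    intensity <- as.matrix(intensity)
    stopifnot(nrow(intensity) == n, ncol(intensity) == length(mz))
    if (any(!is.finite(intensity)) || any(intensity < 0)) {
      stop("intensities must be finite and non-negative", call. = FALSE)
    }
  } else {
    stopifnot(is.list(intensity), length(mz) == n, length(intensity) == n)
    for (i in seq_len(n)) {
      if (length(mz[[i]]) != length(intensity[[i]])) {
        stop("pixel ", i, ": m/z and intensity lengths differ", call. = FALSE)
      }
      if (is.unsorted(mz[[i]], strictly = TRUE)) {
        stop("pixel ", i, ": m/z axis must be strictly ascending", call. = FALSE)
      }
      if (any(!is.finite(intensity[[i]])) || any(intensity[[i]] < 0)) {
        stop("pixel ", i, ": intensities must be finite and non-negative",
             call. = FALSE)
      }
    }
  }
  structure(list(coords = coords, mz = mz, intensity = intensity,
                 continuous = continuous, centroided = centroided,
                 pixel_size_um = pixel_size_um, normalization = normalization,
                 source = source, coord_offset = as.integer(coord_offset)),
            class = "msi_dataset")
}

n_pixels <- function(d) nrow(d$coords)

# Per-pixel spectrum accessor (list with mz, intensity).
get_spectrum <- function(d, i) {
  if (d$continuous) list(mz = d$mz, intensity = d$intensity[i, ])
  else list(mz = d$mz[[i]], intensity = d$intensity[[i]])
}

#' Per-pixel total ion current
#'
#' Profile spectra are integrated by the trapezoid rule over the m/z axis;
#' centroid spectra are summed.
#'
#' @param dataset An `msi_dataset`.
#' @return Numeric vector, one TIC per pixel.
#' @export
pixel_tic <- function(dataset) {
  d <- dataset
  if (d$continuous) {
    if (d$centroided || length(d$mz) < 2L) return(rowSums(d$intensity))
    as.numeric(d$intensity %*% tic_weights(d$mz))
  } else {
    vapply(seq_len(n_pixels(d)), function(i) {
      s <- get_spectrum(d, i)
      if (d$centroided || length(s$mz) < 2L) sum(s$intensity)
      else sum(tic_weights(s$mz) * s$intensity)
    }, numeric(1))
  }
}

# Trapezoid quadrature weights over the axis; segments much wider than the
# native spacing (gaps of a windowed acquisition axis) carry no signal and
# are excluded so the TIC reflects sampled regions only.
tic_weights <- function(mz, gap_factor = 10) {
  dx <- diff(mz)
  dx[dx > gap_factor * stats::median(dx)] <- 0
  n <- length(mz)
  c(dx[1] / 2, (dx[-(n - 1L)] + dx[-1]) / 2, dx[n - 1L] / 2)
}

#' Grid dimensions of a dataset
#'
#' @param dataset An `msi_dataset`.
#' @return c(nx, ny): extent of the 0-based coordinate grid.
#' @export
grid_dims <- function(dataset) {
  c(nx = max(dataset$coords[, 1]) + 1L, ny = max(dataset$coords[, 2]) + 1L)
}

#' @export
print.msi_dataset <- function(x, ...) {
  dims <- grid_dims(x)
  cat(sprintf(paste0("<msi_dataset> %d pixels on a %dx%d grid (%g um), %s %s, ",
                     "%s-normalized\n  source: %s\n"),
              n_pixels(x), dims[1], dims[2], x$pixel_size_um,
              if (x$continuous) "continuous" else "processed",
              if (x$centroided) "centroid" else "profile",
              x$normalization, x$source))
  invisible(x)
}

# Keep a subset of pixels (used when dropping zero-TIC pixels).
subset_pixels <- function(d, keep) {
  out <- d
  out$coords <- d$coords[keep, , drop = FALSE]
  if (d$continuous) out$intensity <- d$intensity[keep, , drop = FALSE]
  else { out$mz <- d$mz[keep]; out$intensity <- d$intensity[keep] }
  out
}
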