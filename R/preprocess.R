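# Spectral preprocessing: TIC normalization, mean spectra, peak/peak-width
# detection on mean spectra, and per-pixel area-under-curve integration of
# peak bins into a feature matrix.

#' Total-ion-current normalization
#'
#' Scales every pixel's spectrum so that its TIC equals the dataset's mean raw
#' TIC. Relative intensities within a pixel are unchanged, so any per-pixel
#' multiplicative gain cancels; the mean-TIC target (rather than 1) keeps the
#' intensity scale comparable to the raw data for plotting. Zero-TIC pixels
#' are dropped with a logged warning.
#'
#' @param dataset An `msi_dataset` with `normalization == "raw"`.
#' @return TIC-normalized `msi_dataset` (normalization tag `"tic"`, target
#'   stored in attribute `tic_target`).
#' @export
tic_normalize <- function(dataset) {
  d <- dataset
  stopifnot(inherits(d, "msi_dataset"))
  if (identical(d$normalization, "tic")) return(d)
  tic <- pixel_tic(d)
  zero <- tic <= 0
  if (any(zero)) {
    pm_log("drop_zero_tic", "dropping %d zero-TIC pixel(s)", sum(zero))
    d <- subset_pixels(d, !zero)
    tic <- tic[!zero]
  }
  target <- mean(tic)
  scale <- target / tic
  if (d$continuous) {
    d$intensity <- d$intensity * scale
  } else {
    d$intensity <- lapply(seq_along(d$intensity),
                          function(i) d$intensity[[i]] * scale[i])
  }
  d$normalization <- "tic"
  d$tic_target <- target
  d
}

#' Mean spectrum over a dataset or pixel subset
#'
#' Pointwise arithmetic mean of the per-pixel spectra. Processed-mode data are
#' first resampled by linear interpolation onto a common axis spanning the
#' union of the per-pixel axes at the median native spacing.
#'
#' @param dataset An `msi_dataset`.
#' @param pixels Optional integer vector of pixel indices (default: all).
#' @return List with ascending `mz` and `intensity`.
#' @export
mean_spectrum <- function(dataset, pixels = NULL) {
  d <- dataset
  stopifnot(inherits(d, "msi_dataset"))
  pixels <- pixels %||% seq_len(n_pixels(d))
  if (!length(pixels)) stop("empty pixel subset", call. = FALSE)
  if (d$continuous) {
    y <- if (length(pixels) == 1L) d$intensity[pixels, ]
         else colMeans(d$intensity[pixels, , drop = FALSE])
    return(list(mz = d$mz, intensity = as.numeric(y)))
  }
  axes <- d$mz[pixels]
  spacing <- stats::median(unlist(lapply(axes, function(m)
    if (length(m) > 1L) diff(m) else numeric(0))))
  rng <- range(unlist(axes))
  grid <- seq(rng[1], rng[2], by = spacing)
  acc <- numeric(length(grid))
  for (i in seq_along(pixels)) {
    s <- get_spectrum(d, pixels[i])
    acc <- acc + stats::approx(s$mz, s$intensity, xout = grid, rule = 2)$y
  }
  list(mz = grid, intensity = acc / length(pixels))
}

#' Construct a set of peak bins
#'
#' @param center,left,right Numeric vectors: peak apex m/z and integration
#'   borders (`left < center < right`, centers strictly ascending).
#' @param prominence,fwhm Optional per-peak prominence and full width at half
#'   maximum.
#' @return A `peak_bins` data.frame.
#' @export
peak_bins <- function(center, left, right, prominence = NA_real_,
                      fwhm = NA_real_) {
  df <- data.frame(center = center, left = left, right = right,
                   prominence = rep_len(prominence, length(center)),
                   fwhm = rep_len(fwhm, length(center)))
  df <- df[order(df$center), , drop = FALSE]
  if (any(df$left >= df$center) || any(df$center >= df$right)) {
    stop("peak bins must satisfy left < center < right", call. = FALSE)
  }
  if (anyDuplicated(df$center)) stop("duplicate peak centers", call. = FALSE)
  overlaps <- which(df$right[-nrow(df)] > df$left[-1])
  if (length(overlaps)) {
    pm_log("overlapping_bins", "%d pair(s) of overlapping bins", length(overlaps))
  }
  rownames(df) <- NULL
  structure(df, class = c("peak_bins", "data.frame"))
}

#' @export
print.peak_bins <- function(x, ...) {
  cat(sprintf("<peak_bins> %d bins, m/z %.4f - %.4f\n", nrow(x),
              if (nrow(x)) min(x$center) else NA, if (nrow(x)) max(x$center) else NA))
  invisible(x)
}

#' Detect peaks and peak widths on a profile spectrum
#'
#' Local maxima are kept when their topographic prominence exceeds
#' `snr_threshold` times the noise level, estimated robustly as
#' 1.4826 x MAD of the first difference of the spectrum divided by sqrt(2).
#' The peak width is the full width at half maximum found by linear
#' interpolation; integration borders are placed at the nearest flanking
#' local minima, clipped to center +/- 3 FWHM, and overlapping borders of
#' adjacent peaks are truncated at the midpoint between their centers so the
#' bins partition the axis.
#'
#' @param spectrum List with `mz` and `intensity` (profile mode, >= 32 points).
#' @param snr_threshold Prominence threshold in noise units (default 5).
#' @param min_fwhm_points Minimum number of samples above half height
#'   (default 3).
#' @return A `peak_bins` object (possibly with zero rows for a flat spectrum).
#' @export
detect_peaks <- function(spectrum, snr_threshold = 5, min_fwhm_points = 3) {
  mz <- spectrum$mz
  y <- spectrum$intensity
  n <- length(y)
  if (n < 32L) stop("profile spectrum must have at least 32 points", call. = FALSE)
  empty <- peak_bins(numeric(0), numeric(0), numeric(0))
  if (max(y) <= min(y)) return(empty)

  noise <- 1.4826 * stats::mad(diff(y), constant = 1) / sqrt(2)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE)
  apex <- which(is_max)
  if (!length(apex)) return(empty)

  # topographic prominence: drop to the higher of the two key saddles
  prominence <- numeric(length(apex))
  left_min_idx <- right_min_idx <- integer(length(apex))
  for (k in seq_along(apex)) {
    i <- apex[k]
    # walk left until a point higher than the apex (or the edge)
    j <- i
    lmin <- i
    while (j > 1L && y[j] <= y[i]) {
      j <- j - 1L
      if (y[j] < y[lmin]) lmin <- j
    }
    j <- i
    rmin <- i
    while (j < n && y[j] <= y[i]) {
      j <- j + 1L
      if (y[j] < y[rmin]) rmin <- j
    }
    prominence[k] <- y[i] - max(y[lmin], y[rmin])
    left_min_idx[k] <- lmin
    right_min_idx[k] <- rmin
  }

  keep <- prominence > 0 & (noise == 0 | prominence >= snr_threshold * noise)
  apex <- apex[keep]
  prominence <- prominence[keep]
  left_min_idx <- left_min_idx[keep]
  right_min_idx <- right_min_idx[keep]
  if (!length(apex)) return(empty)

  # FWHM by linear interpolation at half the apex height above the local base
  fwhm <- numeric(length(apex))
  npts_above <- integer(length(apex))
  for (k in seq_along(apex)) {
    i <- apex[k]
    base <- max(min(y[left_min_idx[k]:i]), min(y[i:right_min_idx[k]]))
    half <- base + (y[i] - base) / 2
    jl <- i
    while (jl > left_min_idx[k] && y[jl - 1L] > half) jl <- jl - 1L
    xl <- if (jl == 1L || y[jl - 1L] > half) mz[jl] else {
      stats::approx(y[(jl - 1L):jl], mz[(jl - 1L):jl], xout = half)$y
    }
    jr <- i
    while (jr < right_min_idx[k] && y[jr + 1L] > half) jr <- jr + 1L
    xr <- if (jr == n || y[jr + 1L] > half) mz[jr] else {
      stats::approx(y[jr:(jr + 1L)], mz[jr:(jr + 1L)], xout = half)$y
    }
    fwhm[k] <- xr - xl
    npts_above[k] <- jr - jl + 1L
  }
  keep <- npts_above >= min_fwhm_points & fwhm > 0
  apex <- apex[keep]; prominence <- prominence[keep]; fwhm <- fwhm[keep]
  left_min_idx <- left_min_idx[keep]; right_min_idx <- right_min_idx[keep]
  if (!length(apex)) return(empty)

  center <- mz[apex]
  left <- pmax(mz[left_min_idx], center - 3 * fwhm)
  right <- pmin(mz[right_min_idx], center + 3 * fwhm)
  # partition: truncate overlapping neighbours at the midpoint of the centers
  if (length(center) > 1L) {
    mid <- (center[-length(center)] + center[-1]) / 2
    right[-length(center)] <- pmin(right[-length(center)], mid)
    left[-1] <- pmax(left[-1], mid)
  }
  ok <- left < center & center < right
  peak_bins(center[ok], left[ok], right[ok], prominence[ok], fwhm[ok])
}

# Trapezoid-integration weights of the piecewise-linear interpolant of a
# spectrum over [l, r]: returns a weight vector w with integral = sum(w * y).
# Exact additivity over adjacent bins follows because the underlying
# interpolant is shared.
bin_weights <- function(mz, l, r) {
  n <- length(mz)
  w <- numeric(n)
  a <- max(l, mz[1]); b <- min(r, mz[n])
  if (a >= b) return(w)
  for (i in seq_len(n - 1L)) {
    x0 <- mz[i]; x1 <- mz[i + 1L]
    if (x1 <= a) next
    if (x0 >= b) break
    s0 <- max(x0, a); s1 <- min(x1, b)
    h <- s1 - s0
    if (h <= 0) next
    dx <- x1 - x0
    # endpoints of the clipped segment expressed in y_i, y_{i+1}
    t0 <- (s0 - x0) / dx; t1 <- (s1 - x0) / dx
    # integral = h/2 * (y(s0) + y(s1)); y(s) = (1-t) y_i + t y_{i+1}
    w[i] <- w[i] + h / 2 * ((1 - t0) + (1 - t1))
    w[i + 1L] <- w[i + 1L] + h / 2 * (t0 + t1)
  }
  w
}

#' Integrate peak bins into a pixels-by-bins feature matrix
#'
#' Profile spectra are integrated by the trapezoid rule over the piecewise
#' linear interpolant within each bin's `[left, right]` interval (so adjacent
#' bins add exactly); centroid spectra sum the stick intensities falling in
#' the bin. Bins lying entirely outside the m/z axis yield a zero column with
#' a logged warning.
#'
#' @param dataset A TIC-normalized `msi_dataset`.
#' @param bins A `peak_bins` object.
#' @param require_normalized Refuse raw data (default `TRUE`); the enrichment
#'   statistics downstream assume gain-corrected intensities.
#' @return A `feature_matrix`: list with `values` (pixels x bins), `coords`,
#'   `bins`, `normalization`.
#' @export
integrate_bins <- function(dataset, bins, require_normalized = TRUE) {
  d <- dataset
  stopifnot(inherits(d, "msi_dataset"), inherits(bins, "peak_bins"))
  if (require_normalized && !identical(d$normalization, "tic")) {
    stop("dataset is not TIC-normalized; run tic_normalize() first ",
         "(or set require_normalized = FALSE)", call. = FALSE)
  }
  nb <- nrow(bins)
  n <- n_pixels(d)
  vals <- matrix(0, n, nb)
  colnames(vals) <- sprintf("mz_%.4f", bins$center)
  if (nb) {
    if (d$continuous) {
      W <- matrix(0, length(d$mz), nb)
      for (j in seq_len(nb)) {
        if (bins$right[j] < d$mz[1] || bins$left[j] > d$mz[length(d$mz)]) {
          pm_log("bin_outside_axis", "bin %.4f outside m/z axis", bins$center[j])
          next
        }
        W[, j] <- if (d$centroided) {
          as.numeric(d$mz >= bins$left[j] & d$mz <= bins$right[j])
        } else {
          bin_weights(d$mz, bins$left[j], bins$right[j])
        }
      }
      vals <- d$intensity %*% W
      colnames(vals) <- sprintf("mz_%.4f", bins$center)
    } else {
      for (i in seq_len(n)) {
        s <- get_spectrum(d, i)
        for (j in seq_len(nb)) {
          vals[i, j] <- if (d$centroided) {
            sum(s$intensity[s$mz >= bins$left[j] & s$mz <= bins$right[j]])
          } else {
            sum(bin_weights(s$mz, bins$left[j], bins$right[j]) * s$intensity)
          }
        }
      }
    }
  }
  structure(list(values = vals, coords = d$coords, bins = bins,
                 normalization = d$normalization,
                 pixel_size_um = d$pixel_size_um),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d pixels x %d bins (%s-normalized AUC)\n",
              nrow(x$values), ncol(x$values), x$normalization))
  invisible(x)
}

#' Export / read a feature matrix as CSV
#'
#' Coordinates occupy the first two columns (`x`, `y`), one column per bin.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (writer); data.frame (reader).
#' @export
write_feature_csv <- function(fm, path) {
  df <- data.frame(x = fm$coords[, 1], y = fm$coords[, 2], fm$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
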