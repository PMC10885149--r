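# Shared fixture builders: small in-code datasets used across test files.

# tiny continuous profile dataset with known content
tiny_dataset <- function(n_pixels = 4, n_points = 100, seed = 1) {
  set.seed(seed)
  mz <- seq(400, 401, length.out = n_points)
  intensity <- matrix(stats::runif(n_pixels * n_points, 0, 10),
                      n_pixels, n_points)
  coords <- cbind(x = (seq_len(n_pixels) - 1L) %% 2L,
                  y = (seq_len(n_pixels) - 1L) %/% 2L)
  msi_dataset(coords, mz, intensity)
}

# processed-mode dataset with per-pixel axes
tiny_processed <- function(n_pixels = 3, seed = 2) {
  set.seed(seed)
  mz <- lapply(seq_len(n_pixels), function(i) sort(stats::runif(50 + i, 400, 900)))
  intensity <- lapply(mz, function(m) stats::runif(length(m), 0, 5))
  coords <- cbind(x = seq_len(n_pixels) - 1L, y = rep(0L, n_pixels))
  msi_dataset(coords, mz, intensity)
}

# single analytic Gaussian peak on a uniform axis
gaussian_spectrum <- function(area = 10, center = 500, fwhm = 0.05,
                              spacing = fwhm / 10, span = 30 * fwhm,
                              baseline = 0) {
  mz <- seq(center - span / 2, center + span / 2, by = spacing)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  list(mz = mz, intensity = area * stats::dnorm(mz, center, sigma) + baseline)
}

# small, fast synthetic study: few species, small grid
small_panel <- function(folds = c("GM1(d18:1/18:0)" = 3,
                                  "CerP(d18:1/18:0)" = 2,
                                  "ST(d18:1/24:0)" = 0.5)) {
  nm <- c(names(folds), "PE(18:0/22:6)", "PI(18:0/20:4)", "PA(16:0/16:0)")
  fold_map <- stats::setNames(rep(1, length(nm)), nm)
  fold_map[names(folds)] <- folds
  make_panel(names = nm, fold_map = fold_map, n_decoys = 4)
}

small_sim <- function(seed = 1, grid = c(32, 32), n_plaques = 4, ...) {
  simulate_msi(grid = grid, n_plaques = n_plaques, radius_px = c(2.5, 4),
               panel = small_panel(), seed = seed, ...)
}
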