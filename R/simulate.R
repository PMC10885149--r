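# Synthetic MALDI-MSI data with known plaque geometry, planted fold changes
# and noise, emulating negative-ion-mode lipid imaging of brain tissue at
# 10 um pixels: focal circular plaque hotspots in which sphingolipid species
# are fold-enriched and sulfatides fold-depleted against a spatially smooth
# background, with per-pixel multiplicative gain (exercising TIC
# normalization) and counting-like noise on peak areas.

# default planted fold change per lipid class: gangliosides, ceramide
# phosphates/phosphoethanolamines, hexosylceramides and the phospholipid
# classes are plaque-enriched, sulfatides depleted
DEFAULT_CLASS_FOLDS <- c(
  GM1 = 3, GM2 = 3, GM3 = 3, CerP = 2.5, "PE-Cer" = 2.5, HexCer = 2,
  PI = 2, LPI = 2, PE = 2, LPE = 2, "PE-P" = 2, PA = 2, LPA = 2, CPA = 2,
  ST = 0.5, Cer = 2
)

# base (background) peak areas per class, in arbitrary counts; phospholipids
# are the abundant structural background, gangliosides minor components
DEFAULT_CLASS_BASE <- c(
  GM1 = 80, GM2 = 80, GM3 = 90, CerP = 60, "PE-Cer" = 60, HexCer = 70,
  PI = 150, LPI = 120, PE = 300, LPE = 200, "PE-P" = 250, PA = 100,
  LPA = 90, CPA = 90, ST = 200, Cer = 100
)

# fixed decoy background peak positions (m/z), all > 0.2 Da from any panel
# species so annotation at 2 ppm never confuses them
DECOY_MZ <- c(433.1101, 465.9873, 512.3456, 555.0012, 610.8765,
              701.2345, 808.7654, 955.4321, 1050.1111, 1302.5678)

#' Build a species panel for the synthetic generator
#'
#' Default panel: every species of the built-in brain lipid panel (including
#' the internally inconsistent reference row, with its parser-computed mass)
#' plus `n_decoys` decoy background peaks at fold 1. Fold defaults are
#' class-based: GM 3, CerP / PE-Cer 2.5, HexCer 2, PI / PE / PA families 2,
#' ST 0.5 (depleted), decoys 1.
#'
#' @param names Character vector of shorthand lipid names (default: the full
#'   built-in panel).
#' @param fold_map Optional named numeric vector of per-species fold
#'   overrides (names matched against canonical species names).
#' @param n_decoys Number of decoy background peaks (default 10).
#' @param base_map Optional named numeric vector of per-species base-area
#'   overrides.
#' @return data.frame with `name`, `lipid_class`, `mz` (`[M-H]-`), `fold`,
#'   `base`, `depleted`.
#' @export
make_panel <- function(names = NULL, fold_map = NULL, n_decoys = 10,
                       base_map = NULL) {
  names <- names %||% brain_lipid_panel(include_excluded = TRUE)$name
  species <- lapply(names, parse_lipid_name)
  df <- data.frame(
    name = vapply(species, `[[`, character(1), "name"),
    lipid_class = vapply(species, `[[`, character(1), "lipid_class"),
    mz = vapply(species, function(s) adduct_mz(s$neutral_mass), numeric(1)),
    stringsAsFactors = FALSE)
  df$fold <- unname(DEFAULT_CLASS_FOLDS[df$lipid_class])
  df$base <- unname(DEFAULT_CLASS_BASE[df$lipid_class])
  if (n_decoys > 0) {
    if (n_decoys > length(DECOY_MZ)) {
      stop("at most ", length(DECOY_MZ), " decoys available", call. = FALSE)
    }
    df <- rbind(df, data.frame(
      name = sprintf("decoy_%.4f", DECOY_MZ[seq_len(n_decoys)]),
      lipid_class = "decoy", mz = DECOY_MZ[seq_len(n_decoys)],
      fold = 1, base = 120, stringsAsFactors = FALSE))
  }
  if (!is.null(fold_map)) {
    hit <- match(names(fold_map), df$name)
    if (anyNA(hit)) {
      stop("unknown species in fold_map: ",
           paste(names(fold_map)[is.na(hit)], collapse = ", "), call. = FALSE)
    }
    df$fold[hit] <- unname(fold_map)
  }
  if (!is.null(base_map)) {
    hit <- match(names(base_map), df$name)
    df$base[hit[!is.na(hit)]] <- unname(base_map[!is.na(hit)])
  }
  if (any(df$fold <= 0)) stop("fold changes must be > 0", call. = FALSE)
  df$depleted <- df$fold < 1
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# separable Gaussian blur of a matrix (zero-padded borders)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    padded <- c(numeric(r), v, numeric(r))
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(padded[i:(i + 2 * r)] * k)
    out
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

place_plaques <- function(nx, ny, n_plaques, radius_px, max_tries = 2000L) {
  if (2 * radius_px[2] + 4 > min(nx, ny)) {
    stop("grid ", nx, "x", ny, " is too small for plaques of radius ",
         radius_px[2], " px", call. = FALSE)
  }
  centers <- matrix(numeric(0), 0, 3)  # cx, cy, r
  tries <- 0L
  while (nrow(centers) < n_plaques) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not place ", n_plaques, " non-overlapping plaques in ",
           max_tries, " tries; reduce n_plaques or the radius range",
           call. = FALSE)
    }
    r <- stats::runif(1, radius_px[1], radius_px[2])
    cx <- stats::runif(1, r + 1, nx - r - 2)
    cy <- stats::runif(1, r + 1, ny - r - 2)
    if (nrow(centers)) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (any(d < centers[, 3] + r + 2)) next
    }
    centers <- rbind(centers, c(cx, cy, r))
  }
  centers
}

#' Generate a synthetic MSI dataset with known ground truth
#'
#' Per pixel, the expected peak area of species s is
#' `base_s * fold_s^strength(pixel) * gain(pixel)`, where `strength` is 1
#' inside a plaque disc and 0 outside (optionally softened by a Gaussian rim
#' blur), `gain` is log-normal with standard deviation `gain_sigma` on the
#' log scale, and per-plaque strength multipliers (log-normal,
#' `plaque_jitter_sigma`) emulate plaque-to-plaque heterogeneity. Observed
#' areas are Gamma-perturbed with shape `snr^2` (coefficient of variation
#' 1/snr); `snr = Inf` switches noise off. In profile mode each peak is laid
#' down as a Gaussian of FWHM = m/z / resolution on a uniform-spacing axis
#' windowed around the panel peaks (spacing FWHM/6 at the panel's median
#' m/z); centroid mode emits one stick per species.
#'
#' @param grid c(nx, ny) pixel grid (default 128 x 128).
#' @param pixel_size_um Pixel pitch (default 10 um).
#' @param n_plaques Number of non-overlapping circular plaques (default 20).
#' @param radius_px Plaque radius range in pixels (default c(3, 6)).
#' @param panel Species panel from [make_panel()].
#' @param resolution Mass resolving power defining peak FWHM (default 120000).
#' @param gain_sigma SD of the log-normal per-pixel gain (default 0.3).
#' @param snr Area signal-to-noise ratio; Gamma shape is `snr^2`
#'   (default 10). `Inf` disables area noise.
#' @param rim_sigma Gaussian rim blur of the plaque strength field in pixels
#'   (default 0 = hard discs; 1 emulates diffuse halos).
#' @param plaque_jitter_sigma SD (log scale) of per-plaque strength
#'   multipliers (default 0.4, matching the wide per-plaque enrichment spread
#'   seen in real single-plaque bar plots; 0 disables).
#' @param noise_floor SD of additive baseline noise on profile points
#'   (default 0.02 in units of the median peak apex; 0 disables).
#' @param mode `"profile"` or `"centroid"`.
#' @param seed RNG seed; with fixed seed and parameters the output is
#'   bit-identical.
#' @return List with `dataset` (`msi_dataset`) and `truth`
#'   (`msi_ground_truth`: `plaque_labels` matrix, `panel`, `gain`,
#'   `strength`, `background` template spectrum, `seed`, `params`).
#' @export
simulate_msi <- function(grid = c(128, 128), pixel_size_um = 10,
                         n_plaques = 20, radius_px = c(3, 6),
                         panel = make_panel(), resolution = 120000,
                         gain_sigma = 0.3, snr = 10, rim_sigma = 0,
                         plaque_jitter_sigma = 0.4, noise_floor = 0.02,
                         mode = c("profile", "centroid"), seed = 1) {
  mode <- match.arg(mode)
  nx <- grid[1]; ny <- grid[2]
  set.seed(derive_seed(seed, 1L))

  plaque_labels <- matrix(0L, ny, nx)
  strength <- matrix(0, ny, nx)
  if (n_plaques > 0) {
    centers <- place_plaques(nx, ny, n_plaques, radius_px)
    xs <- matrix(rep(seq_len(nx), each = ny), ny, nx)
    ys <- matrix(rep(seq_len(ny), nx), ny, nx)
    jitter <- if (plaque_jitter_sigma > 0) {
      exp(stats::rnorm(n_plaques, 0, plaque_jitter_sigma))
    } else rep(1, n_plaques)
    for (p in seq_len(n_plaques)) {
      disc <- (xs - centers[p, 1])^2 + (ys - centers[p, 2])^2 <= centers[p, 3]^2
      plaque_labels[disc] <- p
      strength[disc] <- jitter[p]
    }
    strength <- gaussian_blur(strength, rim_sigma)
  }

  # pixel order: x fastest (row-major image rows)
  coords <- cbind(x = rep(0:(nx - 1), times = ny), y = rep(0:(ny - 1), each = nx))
  npx <- nrow(coords)
  s_vec <- strength[cbind(coords[, 2] + 1L, coords[, 1] + 1L)]
  gain <- if (gain_sigma > 0) exp(stats::rnorm(npx, 0, gain_sigma)) else rep(1, npx)

  ns <- nrow(panel)
  # expected areas: npx x ns
  A <- exp(outer(s_vec, log(panel$fold)))
  A <- sweep(A, 2, panel$base, "*") * gain
  if (is.finite(snr)) {
    shape <- snr^2
    A[] <- stats::rgamma(length(A), shape = shape, rate = shape / A)
  }

  fwhm <- panel$mz / resolution
  if (mode == "centroid") {
    dataset <- msi_dataset(coords, panel$mz, A, centroided = TRUE,
                           pixel_size_um = pixel_size_um,
                           source = sprintf("simulate_msi(seed=%s)", seed))
    background <- list(mz = panel$mz, intensity = panel$base)
  } else {
    spacing <- (stats::median(panel$mz) / resolution) / 6
    lo <- panel$mz - 4 * fwhm
    hi <- panel$mz + 4 * fwhm
    # merge overlapping windows into disjoint intervals
    ord <- order(lo)
    iv_lo <- lo[ord][1]; iv_hi <- hi[ord][1]
    intervals <- list()
    for (i in seq_along(ord)[-1]) {
      if (lo[ord][i] <= iv_hi + spacing) iv_hi <- max(iv_hi, hi[ord][i])
      else { intervals[[length(intervals) + 1L]] <- c(iv_lo, iv_hi)
             iv_lo <- lo[ord][i]; iv_hi <- hi[ord][i] }
    }
    intervals[[length(intervals) + 1L]] <- c(iv_lo, iv_hi)
    axis <- unlist(lapply(intervals, function(iv) seq(iv[1], iv[2], by = spacing)))

    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    B <- matrix(0, ns, length(axis))
    for (s in seq_len(ns)) {
      j <- which(axis >= panel$mz[s] - 5 * fwhm[s] &
                 axis <= panel$mz[s] + 5 * fwhm[s])
      B[s, j] <- stats::dnorm(axis[j], panel$mz[s], sigma[s])
    }
    intensity <- A %*% B
    if (noise_floor > 0) {
      apex_scale <- stats::median(panel$base / (sigma * sqrt(2 * pi)))
      intensity <- intensity +
        matrix(stats::rnorm(length(intensity), 0, noise_floor * apex_scale),
               nrow(intensity))
      intensity[intensity < 0] <- 0
    }
    dataset <- msi_dataset(coords, axis, intensity, centroided = FALSE,
                           pixel_size_um = pixel_size_um,
                           source = sprintf("simulate_msi(seed=%s)", seed))
    background <- list(mz = axis, intensity = as.numeric(panel$base %*% B))
  }

  truth <- structure(list(
    plaque_labels = plaque_labels, strength = strength, panel = panel,
    gain = gain, coords = coords, background = background, seed = seed,
    params = list(grid = grid, pixel_size_um = pixel_size_um,
                  n_plaques = n_plaques, radius_px = radius_px,
                  resolution = resolution, gain_sigma = gain_sigma, snr = snr,
                  rim_sigma = rim_sigma,
                  plaque_jitter_sigma = plaque_jitter_sigma,
                  noise_floor = noise_floor, mode = mode)),
    class = "msi_ground_truth")
  list(dataset = dataset, truth = truth)
}

#' @export
print.msi_ground_truth <- function(x, ...) {
  cat(sprintf("<msi_ground_truth> %dx%d grid, %d plaques, %d species (seed %s)\n",
              x$params$grid[1], x$params$grid[2], max(x$plaque_labels),
              nrow(x$panel), format(x$seed)))
  invisible(x)
}

dice_coefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Score pipeline outputs against the generator's ground truth
#'
#' @param truth An `msi_ground_truth`.
#' @param rois Optional recovered `roi_set` -> Dice/Jaccard of the plaque
#'   union, recovered and true plaque counts.
#' @param enrichment_table Optional `enrichment_table` whose `bin` column
#'   carries species names -> per-species fold bias (log2) and RMSE.
#' @param annotation Optional `best_hits()`-style table for the detected bins
#'   -> annotation precision/recall at the matching tolerance.
#' @param spsc_matrix Optional `spsc_matrix` with species-named columns ->
#'   enriched-block / enriched-vs-depleted mean correlations.
#' @return List of metric blocks (only those with inputs supplied).
#' @export
score_recovery <- function(truth, rois = NULL, enrichment_table = NULL,
                           annotation = NULL, spsc_matrix = NULL) {
  stopifnot(inherits(truth, "msi_ground_truth"))
  out <- list()
  if (!is.null(rois)) {
    if (!all(dim(rois$plaque) == dim(truth$plaque_labels))) {
      stop("ROI mask grid does not match the ground-truth grid", call. = FALSE)
    }
    out$segmentation <- list(
      dice = dice_coefficient(rois$plaque > 0, truth$plaque_labels > 0),
      jaccard = {
        a <- rois$plaque > 0; b <- truth$plaque_labels > 0
        u <- sum(a | b); if (u == 0) 1 else sum(a & b) / u
      },
      n_recovered = max(rois$plaque),
      n_true = max(truth$plaque_labels))
  }
  if (!is.null(enrichment_table) && nrow(enrichment_table)) {
    per <- split(enrichment_table, enrichment_table$bin)
    fold <- truth$panel$fold[match(names(per), truth$panel$name)]
    keep <- !is.na(fold)
    est <- vapply(per[keep], function(g) stats::median(g$log2_ratio), numeric(1))
    bias <- est - log2(fold[keep])
    out$quantification <- list(
      species = names(per)[keep],
      planted_log2 = log2(fold[keep]),
      estimated_log2 = unname(est),
      bias = unname(bias),
      mean_abs_bias = mean(abs(bias)),
      rmse = sqrt(mean(bias^2)))
  }
  if (!is.null(annotation)) {
    planted <- truth$panel$name[truth$panel$lipid_class != "decoy"]
    hit_col <- if ("name" %in% names(annotation)) "name" else "species"
    hits <- annotation[[hit_col]]
    hits <- hits[!is.na(hits) & hits != "unknown"]
    tp <- sum(hits %in% planted)
    out$annotation <- list(
      precision = if (length(hits)) tp / length(hits) else NA_real_,
      recall = length(intersect(hits, planted)) / length(planted))
  }
  if (!is.null(spsc_matrix)) {
    # co-enriched sphingolipid block vs the depleted block
    sphingo <- truth$panel$lipid_class %in% c("GM1", "GM2", "GM3", "CerP", "PE-Cer")
    enr <- intersect(colnames(spsc_matrix),
                     truth$panel$name[truth$panel$fold > 1 & sphingo])
    if (length(enr) < 2) {
      enr <- intersect(colnames(spsc_matrix),
                       truth$panel$name[truth$panel$fold > 1])
    }
    dep <- intersect(colnames(spsc_matrix),
                     truth$panel$name[truth$panel$depleted])
    within <- unclass(spsc_matrix)[enr, enr, drop = FALSE]
    cross <- unclass(spsc_matrix)[enr, dep, drop = FALSE]
    out$spsc <- list(
      mean_within_enriched = mean(within[upper.tri(within)]),
      mean_enriched_vs_depleted = mean(cross))
  }
  out
}
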