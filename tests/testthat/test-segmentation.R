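# Bisecting k-means and ROI derivation.

# feature matrix directly from a value matrix (bypasses spectra)
fm_from_values <- function(values, coords) {
  structure(list(values = values, coords = coords,
                 bins = peak_bins(seq_len(ncol(values)) + 400,
                                  seq_len(ncol(values)) + 399.9,
                                  seq_len(ncol(values)) + 400.1),
                 normalization = "tic", pixel_size_um = 10),
            class = "feature_matrix")
}

two_clouds <- function(n = 60, sep = 20, seed = 4) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n, 0, 1), n / 2, 2),
             matrix(stats::rnorm(n, sep, 1), n / 2, 2))
  coords <- cbind(x = 0:(n - 1), y = rep(0L, n))
  list(fm = fm_from_values(X, coords), truth = rep(1:2, each = n / 2))
}

test_that("k = 1 puts all pixels in one cluster; k > n errors", {
  tc <- two_clouds()
  seg <- bisecting_kmeans(tc$fm, k = 1, seed = 1)
  expect_equal(unique(seg$labels), 1L)
  expect_error(bisecting_kmeans(tc$fm, k = 1000, seed = 1), "exceeds")
})

test_that("two well-separated clouds are recovered exactly at k = 2", {
  tc <- two_clouds(sep = 20)
  seg <- bisecting_kmeans(tc$fm, k = 2, seed = 1)
  # label-permutation-invariant comparison
  agree <- max(mean(seg$labels == tc$truth), mean(seg$labels == 3 - tc$truth))
  expect_equal(agree, 1)
})

test_that("total within-cluster SSE is non-increasing in k", {
  sim <- small_sim(seed = 21, grid = c(24, 24), n_plaques = 2)
  d <- suppressMessages(tic_normalize(sim$dataset))
  fm <- integrate_bins(d, detect_peaks(mean_spectrum(d)))
  sse <- vapply(1:6, function(k)
    bisecting_kmeans(fm, k = k, seed = 1)$total_wcss, numeric(1))
  expect_true(all(diff(sse) <= 1e-8))
})

test_that("segmentation is invariant to pixel order and bin relabeling", {
  tc <- two_clouds(sep = 15)
  seg <- bisecting_kmeans(tc$fm, k = 2, seed = 1)
  perm <- sample(seq_len(nrow(tc$fm$values)))
  fm_p <- fm_from_values(tc$fm$values[perm, ], tc$fm$coords[perm, ])
  seg_p <- bisecting_kmeans(fm_p, k = 2, seed = 1)
  lab1 <- seg$labels[perm]; lab2 <- seg_p$labels
  expect_equal(max(mean(lab1 == lab2), mean(lab1 == 3 - lab2)), 1)
  # reversing the bin order must not change the partition
  fm_r <- fm_from_values(tc$fm$values[, 2:1], tc$fm$coords)
  seg_r <- bisecting_kmeans(fm_r, k = 2, seed = 1)
  expect_equal(max(mean(seg$labels == seg_r$labels),
                   mean(seg$labels == 3 - seg_r$labels)), 1)
})

test_that("the bisection tree records non-increasing within-SS per split", {
  tc <- two_clouds()
  seg <- bisecting_kmeans(tc$fm, k = 4, seed = 2)
  expect_equal(nrow(seg$tree), 3L)
  expect_true(all(seg$tree$wcss_after <= seg$tree$wcss_before + 1e-8))
  expect_equal(seg$k, length(unique(seg$labels)))
})

test_that("marker rule selects the plaque cluster; featureless data finds none", {
  sim <- small_sim(seed = 23)
  d <- suppressMessages(tic_normalize(sim$dataset))
  fm <- integrate_bins(d, detect_peaks(mean_spectrum(d)))
  seg <- bisecting_kmeans(fm, k = 6, seed = 1)
  gm1_col <- which.min(abs(fm$bins$center - adduct_mz(
    parse_lipid_name("GM1(d18:1/18:0)")$neutral_mass)))
  sel_marker <- select_plaque_clusters(seg, fm, rule = "marker",
                                       marker_bins = gm1_col)
  expect_gt(length(sel_marker), 0)
  truth_vec <- sim$truth$plaque_labels[
    cbind(fm$coords[, 2] + 1L, fm$coords[, 1] + 1L)] > 0
  expect_gt(mean(truth_vec[seg$labels %in% sel_marker]), 0.8)
  # punctate rule agrees on the same data
  sel_punct <- select_plaque_clusters(seg, fm, rule = "punctate",
                                      area_bounds = c(5, 100))
  expect_true(all(sel_punct %in% sel_marker) || all(sel_marker %in% sel_punct))

  # spatially featureless data: no plaque-like cluster
  set.seed(9)
  flat <- fm_from_values(matrix(stats::rnorm(400 * 3, 100, 1), 400, 3),
                         cbind(x = rep(0:19, 20), y = rep(0:19, each = 20)))
  seg_f <- bisecting_kmeans(flat, k = 4, seed = 1)
  sel_f <- suppressMessages(
    select_plaque_clusters(seg_f, flat, rule = "marker", marker_bins = 1,
                           marker_min_ratio = 1.2))
  expect_equal(length(sel_f), 0L)
  expect_true(isTRUE(attr(sel_f, "none_found")))
})

test_that("connected components use 8-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[cbind(c(2, 3), c(2, 3))] <- TRUE  # diagonal touch -> one component
  comp <- plaquemap:::connected_components(m)
  expect_equal(max(comp), 1L)
  m[5, 5] <- TRUE
  expect_equal(max(plaquemap:::connected_components(m)), 2L)
})

test_that("derive_rois filters by area and orders ids by centroid", {
  # one disc of radius 4 (~49 px) plus two 2-px specks
  lab <- matrix(0L, 30, 30)
  for (y in 1:30) for (x in 1:30) {
    if ((x - 10)^2 + (y - 10)^2 <= 16) lab[y, x] <- 1L
  }
  lab[cbind(c(25, 25), c(3, 4))] <- 1L
  lab[cbind(c(28, 28), c(20, 21))] <- 1L
  coords <- cbind(x = rep(0:29, times = 30), y = rep(0:29, each = 30))
  seg <- structure(list(labels = as.integer(lab[cbind(coords[, 2] + 1,
                                                      coords[, 1] + 1)]),
                        k = 2L, coords = coords, seed = 1),
                   class = "segmentation_result")
  rois <- derive_rois(seg, clusters = 1L, min_area = 5, max_area = 200)
  expect_equal(max(rois$plaque), 1L)
  expect_equal(rois$table$area_px, 49L)
  expect_equal(rois$table$centroid_x, 9, tolerance = 0.01)
  # with min_area 1 the specks appear, ordered by centroid (y, x)
  rois3 <- derive_rois(seg, clusters = 1L, min_area = 1, max_area = 200)
  expect_equal(max(rois3$plaque), 3L)
  expect_true(all(diff(rois3$table$centroid_y[rois3$table$type == "plaque"]) >= 0))
  # everything filtered -> empty ROI set allowed
  rois0 <- derive_rois(seg, clusters = 1L, min_area = 100, max_area = 200)
  expect_equal(max(rois0$plaque), 0L)
})

test_that("annulus controls ring each plaque and respect the tissue mask", {
  lab <- matrix(0L, 40, 40)
  for (y in 1:40) for (x in 1:40) {
    if ((x - 20)^2 + (y - 20)^2 <= 9) lab[y, x] <- 1L
  }
  rois <- roi_set_from_mask(lab)
  rois <- control_rois(rois, inner_margin_px = 2, outer_margin_px = 5)
  ring <- which(rois$control == 1L, arr.ind = TRUE)
  d <- sqrt((ring[, 2] - 20)^2 + (ring[, 1] - 20)^2)
  expect_true(all(d >= 3 + 1))          # outside the disc plus margin
  expect_true(all(d <= 3 + 5 + 1))      # inside the outer margin
  # expected ring area ~ pi((r+5)^2 - (r+2)^2); discretization slack 20%
  expected <- pi * ((3 + 5)^2 - (3 + 2)^2)
  expect_lt(abs(nrow(ring) - expected) / expected, 0.25)
  expect_error(control_rois(rois, 3, 2), "outer_margin")
})

test_that("overlapping annuli assign pixels to the nearer plaque", {
  lab <- matrix(0L, 30, 30)
  lab[15, 10] <- 1L
  lab[15, 16] <- 2L
  rois <- roi_set_from_mask(lab)
  rois <- control_rois(rois, inner_margin_px = 1, outer_margin_px = 4)
  mid_owner <- rois$control[15, 12]  # closer to plaque 1 (at x = 10)
  expect_equal(mid_owner, 1L)
  expect_equal(rois$control[15, 14], 2L)
})

test_that("a plaque with an empty annulus gets a fallback control patch", {
  lab <- matrix(0L, 20, 20)
  lab[1:2, 1:2] <- 1L   # corner plaque
  tissue <- matrix(FALSE, 20, 20)
  tissue[1:2, 1:2] <- TRUE          # no free tissue anywhere near
  tissue[15:20, 15:20] <- TRUE      # distant patch available
  rois <- roi_set_from_mask(lab)
  expect_message(rois <- control_rois(rois, 2, 4, tissue_mask = tissue),
                 "fallback")
  expect_gt(sum(rois$control == 1L), 0)
  expect_true(all(which(rois$control == 1L) %in% which(tissue & lab == 0L)))
})

test_that("plaque recovery on synthetic data meets the Dice target", {
  res <- suppressMessages(run_pipeline(
    plaque_config(seed = 31, simulate = list(grid = c(48, 48), n_plaques = 5)),
    out_dir = withr::local_tempdir()))
  m <- res$metrics[[1]]$segmentation
  expect_gte(m$dice, 0.8)
  expect_gte(m$n_recovered, 4)
})
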