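# Enrichment ratios, group tests, and single-pixel signal correlation.

# hand-built feature matrix + ROI set on a 10x10 grid: plaque ROI 1 is the
# central 3x3 block, its control ring is everything at distance 2-4
stat_fixture <- function(plaque_value = 2, control_value = 1, n_bins = 2,
                         noise_sd = 0, seed = 1) {
  set.seed(seed)
  lab <- matrix(0L, 10, 10)
  lab[5:7, 5:7] <- 1L
  coords <- cbind(x = rep(0:9, times = 10), y = rep(0:9, each = 10))
  inplaque <- lab[cbind(coords[, 2] + 1, coords[, 1] + 1)] > 0
  values <- sapply(seq_len(n_bins), function(j)
    ifelse(inplaque, plaque_value, control_value) +
      stats::rnorm(100, 0, noise_sd))
  colnames(values) <- paste0("bin", seq_len(n_bins))
  fm <- structure(list(values = values, coords = coords,
                       normalization = "tic", pixel_size_um = 10),
                  class = "feature_matrix")
  rois <- control_rois(roi_set_from_mask(lab), 2, 4)
  list(fm = fm, rois = rois)
}

test_that("enrichment ratio is plaque mean over matched control mean", {
  fx <- stat_fixture(plaque_value = 2, control_value = 1)
  et <- enrichment(fx$fm, fx$rois)
  expect_equal(nrow(et), 2L)
  expect_equal(et$ratio, c(2, 2))
  expect_equal(et$log2_ratio, c(1, 1))
  # identical plaque and control distributions -> ratio near 1
  fx0 <- stat_fixture(plaque_value = 1, control_value = 1, noise_sd = 0.05)
  et0 <- enrichment(fx0$fm, fx0$rois)
  expect_lt(max(abs(et0$log2_ratio)), 0.15)
  # grand-mean reference mode
  etg <- enrichment(fx$fm, fx$rois, reference = "grand_mean")
  expect_equal(etg$control_mean, rep(mean(fx$fm$values[, 1]), 2))
})

test_that("zero control means drop the row with a message", {
  fx <- stat_fixture(plaque_value = 2, control_value = 0)
  expect_message(et <- enrichment(fx$fm, fx$rois), "zero_control")
  expect_equal(nrow(et), 0L)
})

test_that("enrichment is invariant to global rescaling of intensities", {
  fx <- stat_fixture(plaque_value = 3, control_value = 1.5, noise_sd = 0.1)
  et1 <- enrichment(fx$fm, fx$rois)
  fm2 <- fx$fm; fm2$values <- fm2$values * 1e3
  et2 <- enrichment(fm2, fx$rois)
  expect_equal(et1$ratio, et2$ratio)
})

test_that("exact Wilcoxon group test matches the sign-pattern enumeration oracle", {
  # oracle: for n = 5 distinct magnitudes, enumerate all 2^5 sign patterns of
  # the signed-rank statistic; two-sided exact p = P(V >= v_obs or <= sym)
  magnitudes <- c(0.2, 0.35, 0.5, 0.65, 0.8)
  ranks <- rank(magnitudes)
  all_v <- vapply(0:31, function(mask) {
    sum(ranks[which(bitwAnd(mask, 2^(0:4)) > 0)])
  }, numeric(1))
  v_obs <- sum(ranks)  # all positive
  p_oracle <- mean(all_v >= v_obs) + mean(all_v <= (15 - v_obs))

  tab <- data.frame(subject = paste0("s", 1:5), roi_id = 1L, bin = "sp1",
                    plaque_mean = 1, control_mean = 1, ratio = 1,
                    log2_ratio = magnitudes)
  gt <- group_test(tab)
  expect_equal(gt$p_value, p_oracle)
  expect_equal(gt$p_value, 0.0625)
  expect_gt(gt$statistic, 0)
})

test_that("degenerate and insufficient group inputs are handled", {
  zero <- data.frame(subject = paste0("s", 1:5), roi_id = 1L, bin = "sp1",
                     plaque_mean = 1, control_mean = 1, ratio = 1,
                     log2_ratio = 0)
  gt <- group_test(zero)
  expect_equal(gt$p_value, 1)
  expect_equal(gt$statistic, 0)
  two <- zero[1:2, ]
  expect_error(group_test(two), "3 subjects")
})

test_that("group statistic sign tracks the effect direction and BH is reported", {
  tab <- rbind(
    data.frame(subject = paste0("s", 1:5), roi_id = 1L, bin = "up",
               plaque_mean = 2, control_mean = 1, ratio = 2,
               log2_ratio = c(0.8, 0.9, 1.0, 1.1, 1.2)),
    data.frame(subject = paste0("s", 1:5), roi_id = 1L, bin = "down",
               plaque_mean = 0.5, control_mean = 1, ratio = 0.5,
               log2_ratio = -c(0.8, 0.9, 1.0, 1.1, 1.2)))
  gt <- group_test(tab)
  expect_equal(sign(gt$statistic), sign(gt$mean_log2))
  expect_true(all(gt$p_adj >= gt$p_value))
  expect_true(all(gt$p_adj <= 1))
  tt <- group_test(tab, test = "t")
  expect_equal(sign(tt$statistic), sign(tt$mean_log2))
})

test_that("type-I error of the group test is nominal under the null", {
  # 200 null studies of 5 subjects; subject-level mean log2 ratios simulated
  # from the sampling distribution of a null enrichment contrast
  set.seed(99)
  alpha <- 0.0625   # smallest attainable exact two-sided level at n = 5
  rejections <- vapply(1:200, function(i) {
    tab <- data.frame(subject = paste0("s", 1:5), roi_id = 1L, bin = "sp",
                      plaque_mean = 1, control_mean = 1, ratio = 1,
                      log2_ratio = stats::rnorm(5, 0, 0.2))
    group_test(tab)$p_value <= alpha
  }, logical(1))
  # binomial 95% CI around 200 * 0.0625 = 12.5 rejections
  expect_gte(sum(rejections), stats::qbinom(0.025, 200, alpha))
  expect_lte(sum(rejections), stats::qbinom(0.975, 200, alpha))
})

test_that("SPSC has unit diagonal, symmetry, and handles exact dependences", {
  fx <- stat_fixture(n_bins = 3, noise_sd = 0.2, seed = 5)
  fm <- fx$fm
  fm$values[, 2] <- 3 * fm$values[, 1]                  # exact scalar multiple
  fm$values[, 3] <- 2 * mean(fm$values[, 1]) - fm$values[, 1]  # exact negative
  R <- spsc(fm, fx$rois)
  expect_equal(diag(R), c(bin1 = 1, bin2 = 1, bin3 = 1))
  expect_equal(unclass(R), t(unclass(R)))
  expect_equal(R[1, 2], 1)
  expect_equal(R[1, 3], -1)
  expect_true(all(R >= -1 & R <= 1))
})

test_that("constant species vectors are flagged and set to zero", {
  fx <- stat_fixture(n_bins = 2, noise_sd = 0.2, seed = 6)
  fm <- fx$fm
  fm$values[, 2] <- 5
  expect_message(R <- spsc(fm, fx$rois), "constant")
  expect_equal(R[1, 2], 0)
  expect_equal(attr(R, "flagged"), "bin2")
})

test_that("SPSC is invariant to positive affine transforms per species", {
  fx <- stat_fixture(n_bins = 2, noise_sd = 0.3, seed = 7)
  R1 <- spsc(fx$fm, fx$rois)
  fm2 <- fx$fm
  fm2$values[, 1] <- 4 + 2.5 * fm2$values[, 1]
  R2 <- spsc(fm2, fx$rois)
  expect_equal(unclass(R1), unclass(R2))
})

test_that("per-ROI-mean scope needs at least 3 plaques", {
  fx <- stat_fixture()
  expect_error(spsc(fx$fm, fx$rois, mask_scope = "per_roi_mean"),
               "at least 3")
})

test_that("SPSC CSV round-trips the matrix exactly", {
  fx <- stat_fixture(n_bins = 3, noise_sd = 0.4, seed = 8)
  R <- spsc(fx$fm, fx$rois)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spsc_csv(R, path)
  back <- read_spsc_csv(path)
  expected <- unclass(R)
  attributes(expected) <- list(dim = dim(R))
  expect_identical(unname(back), expected)
})

test_that("co-enriched species correlate positively, depleted negatively", {
  sim <- small_sim(seed = 41, grid = c(48, 48), n_plaques = 6)
  d <- suppressMessages(tic_normalize(sim$dataset))
  bins <- detect_peaks(mean_spectrum(d))
  fm <- integrate_bins(d, bins)
  anno <- annotate_features(bins, build_mass_library(brain_lipid_panel()))
  ac <- which(anno$species != "unknown")
  colnames(fm$values)[ac] <- anno$species[ac]
  rois <- suppressMessages(control_rois(roi_set_from_mask(sim$truth$plaque_labels)))
  R <- spsc(fm, rois, bins = ac)
  sc <- score_recovery(sim$truth, spsc_matrix = R)$spsc
  expect_gt(sc$mean_within_enriched, 0)
  expect_lt(sc$mean_enriched_vs_depleted, 0)
})
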