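# Per-plaque enrichment quantification, group-level tests across subjects,
# and single-pixel signal correlation (SPSC).

fm_pixel_index <- function(fm) {
  # map grid (y+1, x+1) -> row of the feature matrix
  dims <- c(max(fm$coords[, 1]) + 1L, max(fm$coords[, 2]) + 1L)
  m <- matrix(NA_integer_, dims[2], dims[1])
  m[cbind(fm$coords[, 2] + 1L, fm$coords[, 1] + 1L)] <- seq_len(nrow(fm$coords))
  m
}

#' Per-plaque enrichment table
#'
#' For every plaque ROI and feature bin: the mean AUC over plaque pixels, the
#' mean over that plaque's matched control pixels, their ratio and its log2.
#' Rows with a zero control mean are dropped with a log note. An alternative
#' reference (`"grand_mean"`) normalizes each plaque mean to the subject's
#' tissue-wide mean instead of the local annulus.
#'
#' @param features A TIC-normalized `feature_matrix`.
#' @param rois An `roi_set` with control ROIs filled in.
#' @param bins Optional column subset (indices or names); default all bins.
#' @param reference `"control"` (matched annulus, default) or `"grand_mean"`.
#' @param subject Optional subject identifier stored in the table.
#' @return An `enrichment_table` data.frame: `subject`, `roi_id`, `bin`,
#'   `plaque_mean`, `control_mean`, `ratio`, `log2_ratio`.
#' @export
enrichment <- function(features, rois, bins = NULL,
                       reference = c("control", "grand_mean"),
                       subject = NA_character_) {
  fm <- features
  stopifnot(inherits(fm, "feature_matrix"), inherits(rois, "roi_set"))
  reference <- match.arg(reference)
  if (!identical(fm$normalization, "tic")) {
    stop("enrichment expects a TIC-normalized feature matrix", call. = FALSE)
  }
  cols <- bins %||% seq_len(ncol(fm$values))
  V <- fm$values[, cols, drop = FALSE]
  bin_names <- colnames(V) %||% as.character(cols)
  pix <- fm_pixel_index(fm)
  np <- max(rois$plaque)
  grand <- colMeans(V)
  out <- vector("list", np)
  for (p in seq_len(np)) {
    prows <- pix[rois$plaque == p]
    crows <- pix[rois$control == p]
    prows <- prows[!is.na(prows)]
    crows <- crows[!is.na(crows)]
    if (!length(prows) || (reference == "control" && !length(crows))) {
      pm_log("roi_unmatched", "plaque ROI %d has no usable pixels, skipped", p)
      next
    }
    pmean <- colMeans(V[prows, , drop = FALSE])
    cmean <- if (reference == "control") colMeans(V[crows, , drop = FALSE]) else grand
    ok <- cmean > 0
    if (any(!ok)) {
      pm_log("zero_control", "plaque ROI %d: %d bin(s) with zero control mean dropped",
             p, sum(!ok))
    }
    if (!any(ok)) next
    out[[p]] <- data.frame(subject = subject, roi_id = p, bin = bin_names[ok],
                           plaque_mean = pmean[ok], control_mean = cmean[ok],
                           ratio = pmean[ok] / cmean[ok],
                           log2_ratio = log2(pmean[ok] / cmean[ok]),
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(subject = character(0), roi_id = integer(0),
                      bin = character(0), plaque_mean = numeric(0),
                      control_mean = numeric(0), ratio = numeric(0),
                      log2_ratio = numeric(0))
  }
  structure(res, class = c("enrichment_table", "data.frame"))
}

#' Group-level test of plaque enrichment across subjects
#'
#' Per species/bin, the subject-level mean log2 ratio is computed and tested
#' against zero with a two-sided one-sample test: exact Wilcoxon signed-rank
#' by default (n is small and normality unverifiable) or Student's t.
#' Raw p-values are reported with Benjamini-Hochberg adjusted values
#' alongside.
#'
#' @param table An `enrichment_table` with a filled `subject` column covering
#'   >= 3 subjects.
#' @param test `"wilcoxon"` (exact signed-rank) or `"t"`.
#' @return A `group_stat_table` data.frame: `bin`, `n_subjects`, `mean_log2`,
#'   `statistic` (centered so its sign matches the effect direction),
#'   `p_value`, `p_adj`, `test`.
#' @export
group_test <- function(table, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  subj <- unique(table$subject)
  if (length(subj) < 3L) {
    stop("group_test needs >= 3 subjects; with fewer, report the descriptive ",
         "per-plaque enrichment table only", call. = FALSE)
  }
  agg <- stats::aggregate(log2_ratio ~ subject + bin, data = table, FUN = mean)
  res <- do.call(rbind, lapply(split(agg, agg$bin), function(g) {
    x <- g$log2_ratio
    n <- length(x)
    if (test == "wilcoxon") {
      nz <- x[x != 0]
      if (!length(nz)) {
        stat <- 0; p <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(nz, mu = 0, exact = TRUE))
        # center V so the sign tracks the effect direction
        stat <- unname(wt$statistic) - length(nz) * (length(nz) + 1) / 4
        p <- wt$p.value
      }
    } else {
      if (stats::sd(x) == 0) {
        stat <- if (mean(x) == 0) 0 else sign(mean(x)) * Inf
        p <- if (mean(x) == 0) 1 else 0
      } else {
        tt <- stats::t.test(x, mu = 0)
        stat <- unname(tt$statistic)
        p <- tt$p.value
      }
    }
    data.frame(bin = g$bin[1], n_subjects = n, mean_log2 = mean(x),
               statistic = stat, p_value = p, test = test,
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  structure(res[, c("bin", "n_subjects", "mean_log2", "statistic",
                    "p_value", "p_adj", "test")],
            class = c("group_stat_table", "data.frame"))
}

#' Single-pixel signal correlation (SPSC)
#'
#' Pearson correlation between the AUC vectors of each species pair over the
#' pixels of the plaque mask. The default scope is the union of all plaque
#' ROI pixels; `"per_roi_mean"` instead correlates per-ROI mean intensities
#' (one observation per plaque). Constant species vectors yield undefined
#' correlations; those entries are set to 0 and flagged.
#'
#' @param features A `feature_matrix`.
#' @param rois An `roi_set`.
#' @param bins Optional column subset; default all bins.
#' @param mask_scope `"plaque_union"` (default) or `"per_roi_mean"`.
#' @return An `spsc_matrix`: symmetric species x species correlation matrix
#'   with unit diagonal; attributes `n_pixels` and `flagged` (constant
#'   species).
#' @export
spsc <- function(features, rois, bins = NULL,
                 mask_scope = c("plaque_union", "per_roi_mean")) {
  fm <- features
  mask_scope <- match.arg(mask_scope)
  stopifnot(inherits(fm, "feature_matrix"), inherits(rois, "roi_set"))
  cols <- bins %||% seq_len(ncol(fm$values))
  V <- fm$values[, cols, drop = FALSE]
  pix <- fm_pixel_index(fm)
  if (mask_scope == "plaque_union") {
    rows <- pix[rois$plaque > 0]
    rows <- rows[!is.na(rows)]
    X <- V[rows, , drop = FALSE]
  } else {
    np <- max(rois$plaque)
    X <- do.call(rbind, lapply(seq_len(np), function(p) {
      rws <- pix[rois$plaque == p]
      rws <- rws[!is.na(rws)]
      if (!length(rws)) return(NULL)
      colMeans(V[rws, , drop = FALSE])
    }))
  }
  if (is.null(X) || nrow(X) < 3L) {
    stop("SPSC needs at least 3 observations in the plaque mask", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  flagged <- colnames(X)[sds == 0] %||% character(0)
  if (length(flagged)) {
    pm_log("spsc_constant", "%d constant species set to correlation 0",
           length(flagged))
  }
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  structure(R, class = c("spsc_matrix", class(R)),
            n_pixels = nrow(X), flagged = flagged)
}

#' @export
print.spsc_matrix <- function(x, ...) {
  cat(sprintf("<spsc_matrix> %d species over %d observations\n",
              ncol(x), attr(x, "n_pixels")))
  invisible(x)
}

#' Write / read an SPSC matrix as CSV (exact round trip)
#'
#' @param mat An `spsc_matrix`.
#' @param path CSV path.
#' @return `path` invisibly (writer); matrix (reader).
#' @export
write_spsc_csv <- function(mat, path) {
  vals <- apply(unclass(mat), 2, function(col) sprintf("%.17g", col))
  df <- data.frame(species = colnames(mat) %||% as.character(seq_len(ncol(mat))),
                   vals, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("species", colnames(mat) %||% as.character(seq_len(ncol(mat))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spsc_csv
#' @export
read_spsc_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
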