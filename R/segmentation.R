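# Bisecting k-means spatial segmentation and plaque / control ROI derivation.

cluster_wcss <- function(X, idx) {
  if (length(idx) < 2L) return(0)
  sum(scale(X[idx, , drop = FALSE], scale = FALSE)^2)
}

#' Bisecting k-means segmentation of a feature matrix
#'
#' Starts from a single cluster and repeatedly splits the cluster with the
#' largest within-cluster sum of squares using 2-means (best of `n_restarts`
#' random initializations, lowest within-SS kept) until `k` leaves exist.
#' Features are scaled per bin before clustering (`"zscore"` by default, so
#' high-abundance background lipids do not dominate the Euclidean distance).
#' Deterministic for a fixed `seed`.
#'
#' @param features A `feature_matrix`.
#' @param k Number of clusters (default 8).
#' @param seed RNG seed for the 2-means initializations.
#' @param n_restarts Random restarts per split (default 10).
#' @param scaling `"zscore"` or `"none"`.
#' @return A `segmentation_result`: per-pixel `labels` (1..k), the bisection
#'   `tree` (split step, parent, within-SS before/after), `k`, `seed`,
#'   `coords`.
#' @export
bisecting_kmeans <- function(features, k = 8, seed = 1, n_restarts = 10,
                             scaling = c("zscore", "none")) {
  fm <- features
  stopifnot(inherits(fm, "feature_matrix"))
  scaling <- match.arg(scaling)
  X <- fm$values
  n <- nrow(X)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of pixels (", n, ")",
                  call. = FALSE)
  if (scaling == "zscore") {
    mu <- colMeans(X)
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  }

  labels <- rep(1L, n)
  wcss <- c(cluster_wcss(X, seq_len(n)))
  tree <- data.frame(step = integer(0), parent = integer(0),
                     wcss_before = numeric(0), wcss_after = numeric(0))
  next_label <- 2L
  step <- 0L
  while (length(unique(labels)) < k) {
    step <- step + 1L
    # split the splittable cluster with the largest within-SS
    cand <- order(wcss, decreasing = TRUE)
    target <- NA_integer_
    for (cl in cand) {
      idx <- which(labels == cl)
      if (length(idx) >= 2L && wcss[cl] > 0 &&
          nrow(unique(X[idx, , drop = FALSE])) >= 2L) { target <- cl; break }
    }
    if (is.na(target)) {
      stop("cannot reach k = ", k, " clusters: no splittable cluster left",
           call. = FALSE)
    }
    idx <- which(labels == target)
    set.seed(derive_seed(seed, step))
    km <- suppressWarnings(stats::kmeans(X[idx, , drop = FALSE], centers = 2L,
                                         nstart = n_restarts, iter.max = 100L))
    child <- next_label
    next_label <- next_label + 1L
    labels[idx[km$cluster == 2L]] <- child
    tree <- rbind(tree, data.frame(step = step, parent = target,
                                   wcss_before = wcss[target],
                                   wcss_after = sum(km$withinss)))
    wcss[target] <- km$withinss[1]
    wcss[child] <- km$withinss[2]
  }
  # relabel 1..k in order of first appearance for stability
  labels <- match(labels, unique(sort(labels)))
  structure(list(labels = as.integer(labels), k = as.integer(k), tree = tree,
                 seed = seed, coords = fm$coords,
                 total_wcss = sum(wcss[unique(labels)], na.rm = TRUE)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d pixels in %d clusters (seed %s), total within-SS %.3g\n",
              length(x$labels), x$k, format(x$seed), x$total_wcss))
  invisible(x)
}

# label matrix (ny x nx indexed [y+1, x+1]) from per-pixel labels
label_matrix <- function(coords, labels, dims = NULL) {
  dims <- dims %||% c(max(coords[, 1]) + 1L, max(coords[, 2]) + 1L)
  m <- matrix(0L, dims[2], dims[1])
  m[cbind(coords[, 2] + 1L, coords[, 1] + 1L)] <- labels
  m
}

# 8-connected component labelling of a logical matrix (rows = y, cols = x).
connected_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      py <- (p - 1L) %% ny + 1L
      px <- (p - 1L) %/% ny + 1L
      for (dy in -1:1) for (dx in -1:1) {
        qy <- py + dy; qx <- px + dx
        if (qy < 1L || qy > ny || qx < 1L || qx > nx) next
        q <- (qx - 1L) * ny + qy
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

#' Select plaque-like clusters
#'
#' Two selection rules mirror how focal pathology stands out from smooth
#' tissue background: `"marker"` picks clusters whose mean intensity in
#' designated marker bins exceeds the grand mean by `marker_min_ratio`;
#' `"punctate"` picks clusters whose 8-connected components have a median
#' area within plaque-scale bounds (a smooth background cluster forms one
#' huge component and is rejected).
#'
#' @param seg A `segmentation_result`.
#' @param features The `feature_matrix` that was segmented.
#' @param rule `"marker"` or `"punctate"`.
#' @param marker_bins Column indices (or names) of the marker bins.
#' @param marker_min_ratio Minimum cluster-mean / grand-mean ratio (default 1.2).
#' @param area_bounds c(min, max) component area in pixels for the punctate
#'   rule (default c(5, 200)).
#' @return Integer vector of selected cluster ids (length 0 when none found,
#'   with attribute `none_found = TRUE`).
#' @export
select_plaque_clusters <- function(seg, features, rule = c("marker", "punctate"),
                                   marker_bins = NULL, marker_min_ratio = 1.2,
                                   area_bounds = c(5, 200)) {
  rule <- match.arg(rule)
  labels <- seg$labels
  sel <- integer(0)
  if (rule == "marker") {
    if (is.null(marker_bins)) stop("marker rule needs `marker_bins`", call. = FALSE)
    V <- features$values[, marker_bins, drop = FALSE]
    marker <- rowMeans(V)
    grand <- mean(marker)
    cl_means <- tapply(marker, labels, mean)
    if (grand > 0) {
      sel <- as.integer(names(cl_means)[cl_means >= marker_min_ratio * grand])
    }
  } else {
    for (cl in sort(unique(labels))) {
      comp <- connected_components(label_matrix(seg$coords, labels == cl) > 0)
      if (!any(comp > 0)) next
      areas <- tabulate(comp[comp > 0])
      med <- stats::median(areas)
      if (med >= area_bounds[1] && med <= area_bounds[2]) sel <- c(sel, cl)
    }
  }
  if (!length(sel)) {
    pm_log("no_plaque_cluster", "no plaque-like cluster found (rule %s)", rule)
    attr(sel, "none_found") <- TRUE
  }
  sel
}

#' Derive individual plaque ROIs from selected clusters
#'
#' 8-connected components of the selected-cluster pixels become individual
#' plaque ROIs, filtered by area bounds and assigned stable ids ordered by
#' component centroid (y, then x).
#'
#' @param seg A `segmentation_result`.
#' @param clusters Integer vector of selected cluster ids.
#' @param min_area,max_area Component area bounds in pixels (defaults 5, 200).
#' @return An `roi_set`: `plaque` label matrix (ny x nx, 0 = none), `table`
#'   with per-ROI id/centroid/area, `control` label matrix (filled by
#'   [control_rois()]), `provenance`.
#' @export
derive_rois <- function(seg, clusters, min_area = 5, max_area = 200) {
  stopifnot(inherits(seg, "segmentation_result"))
  dims <- c(max(seg$coords[, 1]) + 1L, max(seg$coords[, 2]) + 1L)
  mask <- label_matrix(seg$coords, as.integer(seg$labels %in% clusters), dims) > 0
  comp <- connected_components(mask)
  ncomp <- max(comp)
  keep <- integer(0)
  stats_list <- list()
  for (cid in seq_len(ncomp)) {
    px <- which(comp == cid, arr.ind = TRUE)  # rows = y index, cols = x index
    area <- nrow(px)
    if (area < min_area || area > max_area) next
    keep <- c(keep, cid)
    stats_list[[length(keep)]] <- c(cy = mean(px[, 1]) - 1, cx = mean(px[, 2]) - 1,
                                    area = area)
  }
  plaque <- matrix(0L, dims[2], dims[1])
  tab <- data.frame(roi_id = integer(0), type = character(0),
                    centroid_x = numeric(0), centroid_y = numeric(0),
                    area_px = integer(0))
  if (length(keep)) {
    st <- do.call(rbind, stats_list)
    ord <- order(st[, "cy"], st[, "cx"])
    for (i in seq_along(ord)) {
      cid <- keep[ord[i]]
      plaque[comp == cid] <- i
    }
    tab <- data.frame(roi_id = seq_along(ord), type = "plaque",
                      centroid_x = st[ord, "cx"], centroid_y = st[ord, "cy"],
                      area_px = as.integer(st[ord, "area"]))
  }
  structure(list(plaque = plaque, control = matrix(0L, dims[2], dims[1]),
                 table = tab, dims = dims,
                 provenance = "cluster-derived"),
            class = "roi_set")
}

#' Build an ROI set directly from a labelled plaque mask
#'
#' Used for ground-truth masks from the synthetic generator or user-supplied
#' masks (replacing registration to microscopy).
#'
#' @param plaque_labels Integer matrix (ny x nx), 0 = background.
#' @param provenance Provenance string.
#' @return An `roi_set`.
#' @export
roi_set_from_mask <- function(plaque_labels, provenance = "user-supplied") {
  ids <- setdiff(sort(unique(as.integer(plaque_labels))), 0L)
  tab <- do.call(rbind, lapply(seq_along(ids), function(i) {
    px <- which(plaque_labels == ids[i], arr.ind = TRUE)
    data.frame(roi_id = i, type = "plaque", centroid_x = mean(px[, 2]) - 1,
               centroid_y = mean(px[, 1]) - 1, area_px = nrow(px))
  }))
  relab <- plaque_labels
  for (i in seq_along(ids)) relab[plaque_labels == ids[i]] <- i
  structure(list(plaque = relab,
                 control = matrix(0L, nrow(plaque_labels), ncol(plaque_labels)),
                 table = tab %||% data.frame(),
                 dims = c(ncol(plaque_labels), nrow(plaque_labels)),
                 provenance = provenance),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  np <- max(x$plaque)
  cat(sprintf("<roi_set> %d plaque ROI(s), %s control pixels, provenance: %s\n",
              np, sum(x$control > 0), x$provenance))
  invisible(x)
}

#' Derive per-plaque annulus control ROIs
#'
#' Each plaque gets a ring of pixels whose Euclidean distance to the plaque
#' lies in `[inner_margin_px, outer_margin_px]`, excluding all plaque pixels
#' and off-tissue pixels. Where two annuli overlap, pixels go to the nearer
#' plaque. A plaque whose annulus is empty (e.g. at the tissue edge) receives
#' a control patch of matched area sampled from free tissue, with a log note.
#'
#' @param rois An `roi_set` with plaque ROIs.
#' @param inner_margin_px,outer_margin_px Ring margins in pixels
#'   (default 2 and 6; at 10 um pixels a 20-60 um ring).
#' @param tissue_mask Optional logical matrix of on-tissue pixels (default:
#'   everything).
#' @param seed Seed for the fallback patch sampling.
#' @return The `roi_set` with its `control` label matrix filled in (control
#'   label i belongs to plaque ROI i).
#' @export
control_rois <- function(rois, inner_margin_px = 2, outer_margin_px = 6,
                         tissue_mask = NULL, seed = 1) {
  stopifnot(inherits(rois, "roi_set"))
  if (!(outer_margin_px > inner_margin_px && inner_margin_px >= 1)) {
    stop("need outer_margin > inner_margin >= 1", call. = FALSE)
  }
  plaque <- rois$plaque
  ny <- nrow(plaque); nx <- ncol(plaque)
  tissue <- tissue_mask %||% matrix(TRUE, ny, nx)
  np <- max(plaque)
  best_dist <- matrix(Inf, ny, nx)
  owner <- matrix(0L, ny, nx)
  r <- ceiling(outer_margin_px)
  for (p in seq_len(np)) {
    px <- which(plaque == p, arr.ind = TRUE)
    y1 <- max(1L, min(px[, 1]) - r); y2 <- min(ny, max(px[, 1]) + r)
    x1 <- max(1L, min(px[, 2]) - r); x2 <- min(nx, max(px[, 2]) + r)
    for (yy in y1:y2) for (xx in x1:x2) {
      d2 <- min((yy - px[, 1])^2 + (xx - px[, 2])^2)
      d <- sqrt(d2)
      if (d >= inner_margin_px && d <= outer_margin_px &&
          d < best_dist[yy, xx]) {
        best_dist[yy, xx] <- d
        owner[yy, xx] <- p
      }
    }
  }
  owner[plaque > 0 | !tissue] <- 0L

  # fallback: matched random free-tissue patches for plaques with empty rings
  free <- which(plaque == 0L & owner == 0L & tissue)
  set.seed(derive_seed(seed, 777L))
  for (p in seq_len(np)) {
    if (any(owner == p)) next
    area <- sum(plaque == p)
    take <- sample(free, min(length(free), max(area, 1L)))
    owner[take] <- p
    free <- setdiff(free, take)
    pm_log("control_fallback",
           "plaque ROI %d: empty annulus, matched random tissue patch used", p)
  }
  rois$control <- owner
  if (nrow(rois$table)) {
    ctl <- data.frame(roi_id = seq_len(np), type = "control",
                      centroid_x = NA_real_, centroid_y = NA_real_,
                      area_px = as.integer(tabulate(owner[owner > 0], np)))
    rois$table <- rbind(rois$table[rois$table$type == "plaque", ], ctl)
  }
  rois
}

#' Export an ROI set as CSV (and the label masks as PNG)
#'
#' @param rois An `roi_set`.
#' @param path CSV path for the ROI table; when `png_prefix` is given,
#'   `<png_prefix>_plaque.png` and `<png_prefix>_control.png` label masks are
#'   written as well.
#' @param png_prefix Optional path prefix for mask PNGs.
#' @return `path` invisibly.
#' @export
export_roi_set <- function(rois, path, png_prefix = NULL) {
  utils::write.csv(rois$table, path, row.names = FALSE)
  if (!is.null(png_prefix)) {
    write_label_png(rois$plaque, paste0(png_prefix, "_plaque.png"))
    write_label_png(rois$control, paste0(png_prefix, "_control.png"))
  }
  invisible(path)
}
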