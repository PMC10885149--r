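# Figure and map rendering: single-ion images, segmentation maps, SPSC
# heatmaps and the tabular outputs that accompany them.

# categorical palette for label maps (0 = black background)
label_palette <- function(n) {
  base <- c("#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#FFFF33",
            "#A65628", "#F781BF", "#66C2A5", "#FC8D62", "#8DA0CB", "#E78AC3")
  rep(base, length.out = max(n, 1))
}

# write an integer label matrix (rows = y) as an RGB PNG
write_label_png <- function(labels, path) {
  n <- max(labels)
  pal <- c("#000000", label_palette(n))
  col <- grDevices::col2rgb(pal[labels + 1L]) / 255
  img <- array(0, dim = c(nrow(labels), ncol(labels), 3))
  img[, , 1] <- matrix(col[1, ], nrow(labels))
  img[, , 2] <- matrix(col[2, ], nrow(labels))
  img[, , 3] <- matrix(col[3, ], nrow(labels))
  png::writePNG(img, path)
  invisible(path)
}

#' Render a single-ion image
#'
#' Grayscale intensity image of one feature bin on the pixel grid, with the
#' display range clipped at a high quantile (default 0.99) as is standard for
#' MSI ion images; clipping affects rendering only, never statistics.
#'
#' @param fm A `feature_matrix`.
#' @param bin Column index or name.
#' @param path PNG output path.
#' @param clip_quantile Upper display quantile (default 0.99).
#' @return The image matrix (rows = y), invisibly.
#' @export
render_ion_image <- function(fm, bin, path = NULL, clip_quantile = 0.99) {
  v <- fm$values[, bin]
  hi <- stats::quantile(v, clip_quantile, names = FALSE)
  if (hi <= 0) hi <- max(v, 1e-12)
  v <- pmin(v, hi) / hi
  dims <- c(max(fm$coords[, 1]) + 1L, max(fm$coords[, 2]) + 1L)
  img <- matrix(0, dims[2], dims[1])
  img[cbind(fm$coords[, 2] + 1L, fm$coords[, 1] + 1L)] <- v
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}

#' Render all pipeline output surfaces
#'
#' Writes per-species ion images, the segmentation label map, ROI masks, the
#' per-plaque enrichment bar-plot data as CSV, the group statistics, and the
#' SPSC heatmap (PNG + exact CSV) into `out_dir`.
#'
#' @param features A `feature_matrix`.
#' @param rois An `roi_set` (may be empty).
#' @param seg Optional `segmentation_result`.
#' @param enrichment_table Optional `enrichment_table`.
#' @param group_stats Optional `group_stat_table`.
#' @param spsc_matrix Optional `spsc_matrix`.
#' @param annotated_bins Optional named vector mapping bin column names to
#'   species labels (controls which ion images are rendered; default: all
#'   bins under their column names).
#' @param out_dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
render_outputs <- function(features, rois = NULL, seg = NULL,
                           enrichment_table = NULL, group_stats = NULL,
                           spsc_matrix = NULL, annotated_bins = NULL,
                           out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(f) files <<- c(files, f)

  bins <- annotated_bins %||%
    stats::setNames(colnames(features$values), colnames(features$values))
  for (i in seq_along(bins)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", bins[i])
    f <- file.path(out_dir, sprintf("ion_%s.png", safe))
    render_ion_image(features, names(bins)[i], f)
    put(f)
  }
  if (!is.null(seg)) {
    f <- file.path(out_dir, "segmentation_map.png")
    write_label_png(label_matrix(seg$coords, seg$labels), f)
    put(f)
    f <- file.path(out_dir, "segmentation_labels.csv")
    utils::write.csv(data.frame(x = seg$coords[, 1], y = seg$coords[, 2],
                                cluster = seg$labels), f, row.names = FALSE)
    put(f)
  }
  if (!is.null(rois)) {
    f <- file.path(out_dir, "rois.csv")
    export_roi_set(rois, f, png_prefix = file.path(out_dir, "roi_mask"))
    put(c(f, file.path(out_dir, c("roi_mask_plaque.png", "roi_mask_control.png"))))
  }
  if (!is.null(enrichment_table)) {
    f <- file.path(out_dir, "enrichment.csv")
    utils::write.csv(enrichment_table, f, row.names = FALSE)
    put(f)
  }
  if (!is.null(group_stats)) {
    f <- file.path(out_dir, "group_stats.csv")
    utils::write.csv(group_stats, f, row.names = FALSE)
    put(f)
  }
  if (!is.null(spsc_matrix)) {
    f <- file.path(out_dir, "spsc.csv")
    write_spsc_csv(spsc_matrix, f)
    put(f)
    f <- file.path(out_dir, "spsc_heatmap.png")
    grDevices::png(f, width = 640, height = 640)
    op <- graphics::par(mar = c(8, 8, 2, 2))
    n <- ncol(spsc_matrix)
    graphics::image(seq_len(n), seq_len(n), t(unclass(spsc_matrix))[, n:1],
                    zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE))
    labs <- colnames(spsc_matrix) %||% seq_len(n)
    graphics::axis(1, seq_len(n), labs, las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(n), rev(labs), las = 2, cex.axis = 0.6)
    graphics::par(op)
    grDevices::dev.off()
    put(f)
  }
  invisible(files)
}
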