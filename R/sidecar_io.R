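# Tabular side-car files: per-ROI average spectra as CSV and peak-bin borders
# as tab-delimited text.

#' Build a table of per-ROI average spectra
#'
#' @param dataset An `msi_dataset` (typically TIC-normalized).
#' @param roi_pixels Named list mapping ROI identifiers to pixel index vectors
#'   (each with >= 1 pixel).
#' @return A `roi_spectrum_table`: data.frame with `roi_id`, `mz`, `intensity`.
#' @export
roi_spectrum_table <- function(dataset, roi_pixels) {
  stopifnot(is.list(roi_pixels), length(roi_pixels) > 0)
  if (is.null(names(roi_pixels)) || any(!nzchar(names(roi_pixels)))) {
    stop("`roi_pixels` must be a named list", call. = FALSE)
  }
  if (any(vapply(roi_pixels, length, integer(1)) == 0L)) {
    stop("every ROI must contain at least one pixel", call. = FALSE)
  }
  rows <- lapply(names(roi_pixels), function(id) {
    s <- mean_spectrum(dataset, roi_pixels[[id]])
    data.frame(roi_id = id, mz = s$mz, intensity = s$intensity,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("roi_spectrum_table", "data.frame"))
}

#' Export / read per-ROI average spectra as CSV
#'
#' Columns `roi_id`, `mz`, `intensity`; numeric values carry 9 significant
#' digits so the round trip is lossless at that precision.
#'
#' @param table A `roi_spectrum_table` (or compatible data.frame).
#' @param path CSV path.
#' @return `path` invisibly (writer); `roi_spectrum_table` (reader).
#' @export
export_roi_csv <- function(table, path) {
  stopifnot(all(c("roi_id", "mz", "intensity") %in% names(table)))
  df <- data.frame(roi_id = table$roi_id,
                   mz = signif(table$mz, 9),
                   intensity = signif(table$intensity, 9))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_roi_csv
#' @export
read_roi_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty ROI CSV: ", path, call. = FALSE)
  fields <- strsplit(lines, ",")
  bad <- which(vapply(fields, length, integer(1)) != 3L)
  if (length(bad)) {
    stop("malformed ROI CSV row at line ", bad[1], " of ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  suppressWarnings({
    mz_ok <- !is.na(as.numeric(df$mz))
    int_ok <- !is.na(as.numeric(df$intensity))
  })
  if (!all(mz_ok) || !all(int_ok)) {
    stop("malformed ROI CSV row at line ",
         which(!(mz_ok & int_ok))[1] + 1L, " of ", path, call. = FALSE)
  }
  structure(df, class = c("roi_spectrum_table", "data.frame"))
}

#' Export / read peak-bin borders as tab-delimited text
#'
#' Columns `peak_center`, `left_border`, `right_border` at 6 decimal places;
#' rows with `left >= right` are rejected.
#'
#' @param bins A `peak_bins` object.
#' @param path Output TSV path.
#' @return `path` invisibly (writer); `peak_bins` (reader).
#' @export
write_bin_borders <- function(bins, path) {
  stopifnot(inherits(bins, "peak_bins"))
  df <- data.frame(peak_center = sprintf("%.6f", bins$center),
                   left_border = sprintf("%.6f", bins$left),
                   right_border = sprintf("%.6f", bins$right))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bin_borders
#' @export
read_bin_borders <- function(path) {
  df <- utils::read.delim(path)
  if (any(df$left_border >= df$right_border)) {
    stop("bin borders file has left >= right", call. = FALSE)
  }
  peak_bins(df$peak_center, df$left_border, df$right_border)
}
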