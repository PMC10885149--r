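# Accurate-mass library construction and ppm matching for [M-H]- peaks.

SUPPORTED_ADDUCTS <- c("[M-H]-")

normalize_adduct <- function(adduct) {
  a <- gsub("−", "-", adduct)  # accept the typographic minus
  if (!a %in% SUPPORTED_ADDUCTS) {
    stop("unsupported adduct \"", adduct, "\"; supported: ",
         paste(SUPPORTED_ADDUCTS, collapse = ", "), call. = FALSE)
  }
  a
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' Currently the negative-mode deprotonated adduct `[M-H]-` is supported:
#' m/z = M - 1.00727646 Da (proton mass, electron-corrected).
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param adduct Adduct label, default `"[M-H]-"`.
#' @return Adduct m/z (> 0).
#' @examples
#' adduct_mz(891.6469)  # ST(d18:1/24:0) -> 890.6396
#' @export
adduct_mz <- function(neutral_mass, adduct = "[M-H]-") {
  normalize_adduct(adduct)
  stopifnot_scalar_number(neutral_mass, "neutral_mass")
  mz <- neutral_mass - PROTON_MASS
  if (mz <= 0) {
    stop("neutral mass ", neutral_mass, " Da yields a non-positive [M-H]- m/z",
         call. = FALSE)
  }
  mz
}

#' Built-in brain lipid reference panel
#'
#' A curated panel of sphingolipid and glycerophospholipid species observed in
#' negative-ion-mode MALDI-MSI of human brain tissue, with the published
#' reference masses used for validation (`reference_mass`, Da), low- and
#' high-mass-resolution observed `[M-H]-` values (`tof_mz`, `orbitrap_mz`) and
#' a `flag` column. Flag `"theor_typo"` marks a species whose printed
#' reference mass is internally inconsistent with its own observed value (the
#' parser-computed mass is used instead); flag `"excluded"` marks a species
#' whose reference row is internally inconsistent and which is therefore left
#' out of mass libraries built from the panel. Several species are listed in
#' the source material under an unresolved-shorthand `alias` (e.g. lyso
#' species written as `PE(18:0)`, or `CPA(18:0)` written `LPA(18:0)`); the
#' parser accepts both spellings. The TOF column contains typographically
#' truncated entries and is retained as metadata only, never used for
#' matching.
#'
#' @param include_excluded Keep rows flagged `"excluded"` (default `FALSE`).
#' @return data.frame with columns `lipid_class`, `name`, `alias`,
#'   `reference_mass`, `tof_mz`, `orbitrap_mz`, `flag`.
#' @export
brain_lipid_panel <- function(include_excluded = FALSE) {
  path <- system.file("extdata", "brain_lipid_panel.csv", package = "plaquemap",
                      mustWork = TRUE)
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(lipid_class = "character",
                                          name = "character",
                                          alias = "character",
                                          flag = "character"))
  if (!include_excluded) panel <- panel[panel$flag != "excluded", , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Build an accurate-mass library from shorthand names
#'
#' Parses each name, computes the neutral monoisotopic mass from its
#' constructed molecular formula, and tabulates the adduct m/z values sorted
#' ascending. Duplicate (name, adduct) pairs are dropped.
#'
#' @param names Character vector of shorthand lipid names, or a data.frame
#'   with a `name` column (e.g. [brain_lipid_panel()]).
#' @param adducts Adduct labels to generate; default `"[M-H]-"`.
#' @return A `mass_library`: data.frame with columns `name`, `lipid_class`,
#'   `neutral_mass`, `adduct`, `mz`, sorted by `mz`.
#' @examples
#' lib <- build_mass_library(c("ST(d18:1/24:0)", "GM1(d18:1/18:0)"))
#' @export
build_mass_library <- function(names, adducts = "[M-H]-") {
  if (is.data.frame(names)) names <- names$name
  if (!length(names)) stop("empty species list", call. = FALSE)
  adducts <- vapply(adducts, normalize_adduct, character(1), USE.NAMES = FALSE)
  species <- lapply(names, parse_lipid_name)
  entries <- do.call(rbind, lapply(species, function(sp) {
    data.frame(name = sp$name,
               lipid_class = sp$lipid_class,
               neutral_mass = sp$neutral_mass,
               adduct = adducts,
               mz = vapply(adducts, function(a) adduct_mz(sp$neutral_mass, a),
                           numeric(1)),
               stringsAsFactors = FALSE)
  }))
  entries <- entries[!duplicated(entries[c("name", "adduct")]), , drop = FALSE]
  entries <- entries[order(entries$mz, entries$name), , drop = FALSE]
  rownames(entries) <- NULL
  structure(entries, class = c("mass_library", "data.frame"))
}

#' @export
print.mass_library <- function(x, ...) {
  cat(sprintf("<mass_library> %d entries, m/z %.4f - %.4f, adducts: %s\n",
              nrow(x), min(x$mz), max(x$mz),
              paste(unique(x$adduct), collapse = ", ")))
  invisible(x)
}

#' Match observed peaks against a mass library at ppm tolerance
#'
#' For each observed m/z, every library entry within `tol_ppm` is returned;
#' hits for one observed peak are ordered by increasing absolute ppm error
#' (ties broken by species name). The signed error is
#' `1e6 * (observed - theoretical) / theoretical`.
#'
#' @param observed Numeric vector of observed m/z values.
#' @param library A `mass_library`.
#' @param tol_ppm Tolerance in parts per million (default 2).
#' @return data.frame with columns `observed_mz`, `name`, `adduct`,
#'   `theoretical_mz`, `ppm_error`. Zero rows when nothing matches.
#' @export
match_peaks <- function(observed, library, tol_ppm = 2) {
  if (!inherits(library, "mass_library") || !is.data.frame(library) ||
      nrow(library) == 0L) {
    stop("`library` must be a non-empty mass_library", call. = FALSE)
  }
  stopifnot(tol_ppm > 0)
  observed <- as.numeric(observed)
  mz <- library$mz   # ascending
  out <- vector("list", length(observed))
  for (i in seq_along(observed)) {
    o <- observed[i]
    lo <- o / (1 + tol_ppm * 1e-6)
    hi <- o / (1 - tol_ppm * 1e-6)
    j1 <- findInterval(lo, mz, left.open = TRUE) + 1L
    j2 <- findInterval(hi, mz)
    if (j2 < j1) next
    idx <- j1:j2
    ppm <- 1e6 * (o - mz[idx]) / mz[idx]
    keep <- abs(ppm) <= tol_ppm
    if (!any(keep)) next
    idx <- idx[keep]; ppm <- ppm[keep]
    ord <- order(abs(ppm), library$name[idx])
    out[[i]] <- data.frame(observed_mz = o,
                           name = library$name[idx][ord],
                           adduct = library$adduct[idx][ord],
                           theoretical_mz = mz[idx][ord],
                           ppm_error = ppm[ord],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(observed_mz = numeric(0), name = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm_error = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Best library hit per observed peak
#'
#' One row per observed m/z: the library entry with the smallest absolute ppm
#' error (ties broken by species name), or `NA` fields when nothing lies
#' within the tolerance.
#'
#' @inheritParams match_peaks
#' @return data.frame with one row per element of `observed`.
#' @export
best_hits <- function(observed, library, tol_ppm = 2) {
  hits <- match_peaks(observed, library, tol_ppm)
  out <- data.frame(observed_mz = as.numeric(observed),
                    name = NA_character_, adduct = NA_character_,
                    theoretical_mz = NA_real_, ppm_error = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(observed)) {
    h <- hits[hits$observed_mz == observed[i], , drop = FALSE]
    if (nrow(h)) out[i, c("name", "adduct", "theoretical_mz", "ppm_error")] <-
        h[1L, c("name", "adduct", "theoretical_mz", "ppm_error")]
  }
  out
}

#' Write / read an annotation report CSV
#'
#' Columns: `observed_mz`, `species`, `adduct`, `theoretical_mz`, `ppm_error`.
#'
#' @param hits data.frame as returned by [match_peaks()] or [best_hits()].
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); data.frame (reader).
#' @export
write_annotation_csv <- function(hits, path) {
  out <- data.frame(observed_mz = hits$observed_mz, species = hits$name,
                    adduct = hits$adduct, theoretical_mz = hits$theoretical_mz,
                    ppm_error = hits$ppm_error)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a species panel CSV
#'
#' Accepts columns `name` (required) and optional `lipid_class`, `formula`,
#' `neutral_mass`; when `neutral_mass` is absent it is computed from the
#' parsed name.
#'
#' @param path CSV path (UTF-8, decimal point).
#' @return data.frame with `name`, `lipid_class`, `neutral_mass`.
#' @export
read_species_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"name" %in% names(df)) stop("species panel CSV needs a `name` column",
                                   call. = FALSE)
  sp <- lapply(df$name, parse_lipid_name)
  df$lipid_class <- vapply(sp, `[[`, character(1), "lipid_class")
  if (!"neutral_mass" %in% names(df)) {
    df$neutral_mass <- vapply(sp, `[[`, numeric(1), "neutral_mass")
  }
  df
}
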