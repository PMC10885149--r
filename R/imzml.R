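# imzML 1.1 reading and writing (continuous and processed binary mode,
# profile and centroid spectra). The .ibd binary companion starts with the
# 16-byte UUID also declared in the XML; m/z values are stored as 64-bit and
# intensities as 32-bit floats (the common vendor-converter layout). The
# declared ibd SHA-1 checksum is verified on read.

format_uuid <- function(hex32) {
  paste(substr(hex32, 1, 8), substr(hex32, 9, 12), substr(hex32, 13, 16),
        substr(hex32, 17, 20), substr(hex32, 21, 32), sep = "-")
}

uuid_to_raw <- function(uuid) {
  hex <- gsub("[{}-]", "", tolower(uuid))
  stopifnot(nchar(hex) == 32L)
  as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

cv <- function(ref, acc, name, value = NULL, unit = NULL) {
  v <- if (!is.null(value)) sprintf(' value="%s"', value) else ' value=""'
  u <- if (!is.null(unit)) {
    sprintf(' unitCvRef="UO" unitAccession="%s" unitName="%s"',
            unit[1], unit[2])
  } else ""
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s%s/>',
          ref, acc, name, v, u)
}

#' Write an MSI dataset as an imzML/ibd file pair
#'
#' @param dataset An `msi_dataset`.
#' @param path Output path; the `.imzML` extension is added if missing and the
#'   `.ibd` companion is written alongside.
#' @param axis_mode `"auto"` keeps the dataset's own storage mode;
#'   `"continuous"` requires a shared m/z axis; `"processed"` stores per-pixel
#'   axes.
#' @return Named character vector with the `imzml` and `ibd` paths, invisibly.
#' @export
write_imzml <- function(dataset, path, axis_mode = c("auto", "continuous",
                                                     "processed")) {
  d <- dataset
  stopifnot(inherits(d, "msi_dataset"))
  axis_mode <- match.arg(axis_mode)
  if (axis_mode == "auto") axis_mode <- if (d$continuous) "continuous" else "processed"
  if (axis_mode == "continuous" && !d$continuous) {
    stop("continuous output requested but the dataset has per-pixel axes; ",
         "resample onto a shared axis first", call. = FALSE)
  }
  path <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  imzml_path <- paste0(path, ".imzML")
  ibd_path <- paste0(path, ".ibd")
  n <- n_pixels(d)

  # deterministic UUID derived from the payload so that identical datasets
  # produce identical file pairs
  uuid_hex <- digest::digest(list(d$coords, d$mz, d$intensity, axis_mode),
                             algo = "md5")
  uuid <- format_uuid(uuid_hex)

  con <- file(ibd_path, "wb")
  writeBin(uuid_to_raw(uuid), con)
  offset <- 16
  mz_off <- mz_len <- int_off <- int_len <- numeric(n)
  if (axis_mode == "continuous") {
    writeBin(as.numeric(d$mz), con, size = 8L, endian = "little")
    shared_off <- offset
    shared_len <- length(d$mz)
    offset <- offset + 8 * shared_len
    for (i in seq_len(n)) {
      y <- as.numeric(d$intensity[i, ])
      writeBin(y, con, size = 4L, endian = "little")
      mz_off[i] <- shared_off; mz_len[i] <- shared_len
      int_off[i] <- offset; int_len[i] <- length(y)
      offset <- offset + 4 * length(y)
    }
  } else {
    for (i in seq_len(n)) {
      s <- get_spectrum(d, i)
      writeBin(as.numeric(s$mz), con, size = 8L, endian = "little")
      mz_off[i] <- offset; mz_len[i] <- length(s$mz)
      offset <- offset + 8 * length(s$mz)
      writeBin(as.numeric(s$intensity), con, size = 4L, endian = "little")
      int_off[i] <- offset; int_len[i] <- length(s$intensity)
      offset <- offset + 4 * length(s$intensity)
    }
  }
  close(con)
  sha1 <- digest::digest(file = ibd_path, algo = "sha1")

  coords_x <- d$coords[, 1] - min(d$coords[, 1]) + d$coord_offset[1]
  y <- d$coords[, 2] - min(d$coords[, 2]) + d$coord_offset[2]
  dims <- grid_dims(d)
  mode_cv <- if (axis_mode == "continuous") {
    cv("IMS", "IMS:1000030", "continuous")
  } else {
    cv("IMS", "IMS:1000031", "processed")
  }
  spec_type_cv <- if (d$centroided) {
    cv("MS", "MS:1000127", "centroid spectrum")
  } else {
    cv("MS", "MS:1000128", "profile spectrum")
  }

  header <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>\n',
    '<fileDescription><fileContent>',
    cv("MS", "MS:1000579", "MS1 spectrum"),
    mode_cv, spec_type_cv,
    cv("IMS", "IMS:1000080", "universally unique identifier",
       paste0("{", uuid, "}")),
    cv("IMS", "IMS:1000091", "ibd SHA-1", sha1),
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv("MS", "MS:1000576", "no compression"),
    cv("MS", "MS:1000514", "m/z array", unit = c("MS:1000040", "m/z")),
    cv("MS", "MS:1000523", "64-bit float"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    cv("MS", "MS:1000576", "no compression"),
    cv("MS", "MS:1000515", "intensity array",
       unit = c("MS:1000131", "number of detector counts")),
    cv("MS", "MS:1000521", "32-bit float"),
    cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>\n',
    '<softwareList count="1"><software id="plaquemap" version="0.1.0"/></softwareList>\n',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv("IMS", "IMS:1000042", "max count of pixels x", dims[["nx"]]),
    cv("IMS", "IMS:1000043", "max count of pixels y", dims[["ny"]]),
    cv("IMS", "IMS:1000046", "pixel size (x)", d$pixel_size_um,
       unit = c("UO:0000017", "micrometer")),
    '</scanSettings></scanSettingsList>\n',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/></instrumentConfigurationList>\n',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="plaquemap">',
    cv("MS", "MS:1000544", "Conversion to mzML"),
    '</processingMethod></dataProcessing></dataProcessingList>\n',
    sprintf('<run defaultInstrumentConfigurationRef="IC1" id="%s">\n',
            xml_escape(basename(path))),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="export">\n', n)
  )

  spectra <- sprintf(paste0(
    '<spectrum defaultArrayLength="%d" id="spectrum=%d" index="%d">',
    '<referenceableParamGroupRef ref="spectrum-defaults"/>',
    '<scanList count="1">', cv("MS", "MS:1000795", "no combination"),
    '<scan instrumentConfigurationRef="IC1">',
    '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
    '</scan></scanList>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="mzArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%.0f"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>',
    '<binary/></binaryDataArray>',
    '<binaryDataArray encodedLength="0">',
    '<referenceableParamGroupRef ref="intensityArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%.0f"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>',
    '<binary/></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    int_len, seq_len(n), seq_len(n) - 1L, coords_x, y,
    mz_off, mz_len, 8 * mz_len, int_off, int_len, 4 * int_len)

  # spectrum-level defaults referenced by every spectrum
  defaults <- paste0(
    '<referenceableParamGroup id="spectrum-defaults">',
    cv("MS", "MS:1000579", "MS1 spectrum"),
    cv("MS", "MS:1000511", "ms level", "1"),
    cv("MS", "MS:1000129", "negative scan"),
    spec_type_cv,
    '</referenceableParamGroup>')
  header <- sub('</referenceableParamGroupList>',
                paste0(defaults, '</referenceableParamGroupList>'),
                header, fixed = TRUE)

  out <- file(imzml_path, "wb")
  writeLines(c(header, spectra, '</spectrumList></run></mzML>'), out,
             sep = "\n", useBytes = TRUE)
  close(out)
  # fix referenceableParamGroupList count (2 groups + spectrum defaults)
  txt <- readLines(imzml_path)
  txt <- sub('referenceableParamGroupList count="2"',
             'referenceableParamGroupList count="3"', txt)
  writeLines(txt, imzml_path, useBytes = TRUE)
  invisible(c(imzml = imzml_path, ibd = ibd_path))
}

read_cv_values <- function(doc, xpath) {
  nodes <- xml2::xml_find_all(doc, xpath)
  xml2::xml_attr(nodes, "value")
}

#' Read an imzML file into an MSI dataset
#'
#' Supports continuous and processed binary mode, profile and centroid
#' spectra, 32/64-bit float arrays, and verifies the ibd UUID and (when
#' declared) its SHA-1 checksum. imzML's 1-based pixel positions are stored
#' 0-based internally with the offset recorded.
#'
#' @param path Path to the `.imzML` file (the `.ibd` must sit alongside).
#' @param validate_checksum Verify the declared ibd SHA-1 (default `TRUE`).
#' @return An `msi_dataset`.
#' @export
read_imzml <- function(path, validate_checksum = TRUE) {
  if (!file.exists(path)) stop("no such imzML file: ", path, call. = FALSE)
  ibd_path <- paste0(sub("\\.imzML$", "", path, ignore.case = TRUE), ".ibd")
  if (!file.exists(ibd_path)) {
    stop("missing ibd companion for ", path, " (expected ", ibd_path, ")",
         call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  fc <- "/mzML/fileDescription/fileContent/cvParam"
  accs <- xml2::xml_attr(xml2::xml_find_all(doc, fc), "accession")
  continuous <- "IMS:1000030" %in% accs
  processed <- "IMS:1000031" %in% accs
  if (!continuous && !processed) {
    stop("imzML file declares neither continuous nor processed binary mode",
         call. = FALSE)
  }
  centroided <- any(xml2::xml_attr(xml2::xml_find_all(
    doc, "//cvParam[@accession='MS:1000127']"), "accession") == "MS:1000127")

  declared_uuid <- read_cv_values(doc, paste0(fc, "[@accession='IMS:1000080']"))
  declared_sha1 <- read_cv_values(doc, paste0(fc, "[@accession='IMS:1000091']"))
  ibd_con <- file(ibd_path, "rb")
  on.exit(close(ibd_con), add = TRUE)
  file_uuid <- paste(format(readBin(ibd_con, "raw", 16L)), collapse = "")
  if (length(declared_uuid) &&
      tolower(gsub("[{}-]", "", declared_uuid[1])) != tolower(file_uuid)) {
    stop("ibd UUID does not match the UUID declared in the imzML header",
         call. = FALSE)
  }
  if (validate_checksum && length(declared_sha1)) {
    actual <- digest::digest(file = ibd_path, algo = "sha1")
    if (tolower(actual) != tolower(declared_sha1[1])) {
      stop("ibd SHA-1 checksum mismatch (file corrupt or truncated)",
           call. = FALSE)
    }
  }

  # which referenceable param group is the m/z / intensity array, and its precision
  groups <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  group_ids <- xml2::xml_attr(groups, "id")
  mz_group <- int_group <- NA_character_
  mz_size <- int_size <- NA_integer_
  for (i in seq_along(groups)) {
    a <- xml2::xml_attr(xml2::xml_find_all(groups[[i]], "cvParam"), "accession")
    size <- if ("MS:1000523" %in% a) 8L else if ("MS:1000521" %in% a) 4L else NA_integer_
    if ("MS:1000514" %in% a) { mz_group <- group_ids[i]; mz_size <- size }
    if ("MS:1000515" %in% a) { int_group <- group_ids[i]; int_size <- size }
  }
  if (is.na(mz_group) || is.na(int_group)) {
    stop("could not identify the m/z and intensity array param groups",
         call. = FALSE)
  }
  if (is.na(mz_size) || is.na(int_size)) {
    stop("unsupported binary data precision (only 32/64-bit float supported)",
         call. = FALSE)
  }

  px <- as.integer(read_cv_values(
    doc, "//spectrum/scanList/scan/cvParam[@accession='IMS:1000050']"))
  py <- as.integer(read_cv_values(
    doc, "//spectrum/scanList/scan/cvParam[@accession='IMS:1000051']"))
  n <- length(px)
  if (n == 0L) stop("imzML file contains no spectra", call. = FALSE)

  arrays <- xml2::xml_find_all(doc, "//spectrum/binaryDataArrayList/binaryDataArray")
  refs <- xml2::xml_attr(
    xml2::xml_find_first(arrays, "referenceableParamGroupRef"), "ref")
  get_num <- function(acc) as.numeric(xml2::xml_attr(
    xml2::xml_find_first(arrays, sprintf("cvParam[@accession='%s']", acc)),
    "value"))
  offs <- get_num("IMS:1000102")
  lens <- get_num("IMS:1000103")
  if (length(arrays) != 2L * n || anyNA(refs) || anyNA(offs) || anyNA(lens)) {
    stop("malformed spectrum binary array metadata", call. = FALSE)
  }
  is_mz <- refs == mz_group
  mz_off <- offs[is_mz]; mz_len <- lens[is_mz]
  int_off <- offs[!is_mz]; int_len <- lens[!is_mz]
  if (length(mz_off) != n || length(int_off) != n) {
    stop("each spectrum must declare one m/z and one intensity array",
         call. = FALSE)
  }
  ibd_size <- file.size(ibd_path)
  need <- max(c(mz_off + mz_len * mz_size, int_off + int_len * int_size))
  if (need > ibd_size) {
    stop(sprintf("ibd file is shorter (%d bytes) than the declared offsets require (%d)",
                 ibd_size, need), call. = FALSE)
  }

  read_arr <- function(off, len, size) {
    seek(ibd_con, where = off, origin = "start")
    readBin(ibd_con, "double", n = len, size = size, endian = "little")
  }

  x0 <- min(px); y0 <- min(py)
  coords <- cbind(x = px - x0, y = py - y0)

  pixel_size <- read_cv_values(doc,
    "//scanSettings/cvParam[@accession='IMS:1000046']")
  pixel_size <- if (length(pixel_size)) as.numeric(pixel_size[1]) else 10

  if (continuous) {
    mz <- read_arr(mz_off[1], mz_len[1], mz_size)
    if (is.unsorted(mz, strictly = TRUE)) {
      stop("non-monotone m/z axis in imzML file", call. = FALSE)
    }
    intensity <- matrix(0, n, mz_len[1])
    for (i in seq_len(n)) {
      intensity[i, ] <- read_arr(int_off[i], int_len[i], int_size)
    }
  } else {
    mz <- vector("list", n)
    intensity <- vector("list", n)
    for (i in seq_len(n)) {
      mz[[i]] <- read_arr(mz_off[i], mz_len[i], mz_size)
      if (is.unsorted(mz[[i]], strictly = TRUE)) {
        stop("non-monotone m/z axis in spectrum ", i, call. = FALSE)
      }
      intensity[[i]] <- read_arr(int_off[i], int_len[i], int_size)
    }
  }

  msi_dataset(coords, mz, intensity, centroided = centroided,
              pixel_size_um = pixel_size, source = normalizePath(path),
              coord_offset = c(x0, y0))
}
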