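#' Load an MSI dataset
#'
#' Reads a peak-matched dataset either from an imzML file (continuous
#' mode, or processed mode with a common m/z axis across spectra) or from
#' a delimited matrix file written by [write_peak_matrix()]. Pixels are
#' ordered row-major from the imzML 1-based x/y coordinates
#' (`col = x`, `row = y`); grid cells without a spectrum are zero-filled
#' with a warning, since the spatial filters need a full grid.
#'
#' @param path file path.
#' @param format `"imzml"` or `"matrix"`; guessed from the extension when
#'   missing.
#' @param shape optional `c(n_rows, n_cols)` for matrix files without an
#'   embedded shape header.
#' @return An `msi_dataset`.
#' @export
load_dataset <- function(path, format = c("auto", "imzml", "matrix"),
                         shape = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml"
              else "matrix"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "imzml") read_imzml(path) else read_peak_matrix(path, shape)
}

# ---- delimited matrix format ------------------------------------------

#' Read / write a delimited peak matrix
#'
#' Plain-text interchange for peak-matched data: an optional first line
#' `#shape <tab> n_rows <tab> n_cols`, a header line of m/z values, then
#' one tab-separated row of intensities per pixel (row-major order).
#'
#' @param path file path.
#' @param shape optional `c(n_rows, n_cols)`; required when the file has
#'   no `#shape` line.
#' @return `read_peak_matrix()` returns an `msi_dataset`;
#'   `write_peak_matrix()` returns `path` invisibly.
#' @export
read_peak_matrix <- function(path, shape = NULL) {
  first <- readLines(path, n = 1L)
  skip <- 0L
  if (startsWith(first, "#shape")) {
    parts <- strsplit(first, "\t")[[1]]
    shape <- as.integer(parts[2:3])
    skip <- 1L
  }
  if (is.null(shape)) {
    stop("matrix file has no #shape line and no 'shape' was given",
         call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = skip,
                           check.names = FALSE)
  mz <- as.numeric(colnames(tab))
  if (anyNA(mz)) stop("matrix header must contain numeric m/z values",
                      call. = FALSE)
  msi_dataset(as.matrix(tab), mz, shape)
}

#' @rdname read_peak_matrix
#' @param ds an `msi_dataset`.
#' @export
write_peak_matrix <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#shape", ds$shape[1], ds$shape[2], sep = "\t"), con)
  writeLines(paste(format(ds$mz, digits = 15), collapse = "\t"), con)
  utils::write.table(ds$intensities, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# ---- imzML ------------------------------------------------------------

IMS_CV <- c(continuous = "IMS:1000030", processed = "IMS:1000031",
            x = "IMS:1000050", y = "IMS:1000051",
            offset = "IMS:1000102", length = "IMS:1000103",
            encoded_length = "IMS:1000104",
            max_x = "IMS:1000042", max_y = "IMS:1000043")

#' Read an imzML file
#'
#' Minimal imzML reader for peak-matched data: supports continuous mode
#' (one shared m/z array) and processed mode only when every spectrum
#' carries the identical m/z axis (pre-matched peaks). Binary data are
#' read from the sibling `.ibd` file; 32- and 64-bit floats are
#' understood. Spectra are placed on the grid via their 1-based x/y
#' coordinates; missing grid cells become zero rows (with a warning).
#'
#' @param path path to the `.imzML` file; the `.ibd` must sit next to it.
#' @return An `msi_dataset`.
#' @export
read_imzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("missing .ibd file: ", ibd_path,
                                   call. = FALSE)
  mode_cont <- length(xml2::xml_find_all(
    doc, sprintf(".//fileContent/cvParam[@accession='%s']",
                 IMS_CV["continuous"]))) > 0
  mode_proc <- length(xml2::xml_find_all(
    doc, sprintf(".//fileContent/cvParam[@accession='%s']",
                 IMS_CV["processed"]))) > 0
  if (!mode_cont && !mode_proc) {
    stop("imzML file declares neither continuous nor processed mode",
         call. = FALSE)
  }
  spectra <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (!length(spectra)) stop("imzML file contains no spectra",
                             call. = FALSE)
  get_cv <- function(node, acc) {
    n <- xml2::xml_find_first(node,
           sprintf(".//cvParam[@accession='%s']", acc))
    as.numeric(xml2::xml_attr(n, "value"))
  }
  ibd <- file(ibd_path, "rb")
  on.exit(close(ibd))
  read_array <- function(offset, n, bytes) {
    seek(ibd, where = offset)
    readBin(ibd, what = "double", n = n, size = bytes)
  }
  mz_ref <- NULL
  coords <- matrix(0L, length(spectra), 2L)
  intens_list <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    sp <- spectra[[i]]
    coords[i, ] <- c(get_cv(sp, IMS_CV["x"]), get_cv(sp, IMS_CV["y"]))
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    for (arr in arrays) {
      is_mz <- length(xml2::xml_find_all(arr,
        ".//cvParam[@accession='MS:1000514']")) > 0
      bytes <- if (length(xml2::xml_find_all(arr,
        ".//cvParam[@accession='MS:1000521']")) > 0) 4L else 8L
      if (is_mz && mode_cont && !is.null(mz_ref)) next # shared axis
      off <- get_cv(arr, IMS_CV["offset"])
      len <- get_cv(arr, IMS_CV["length"])
      vals <- read_array(off, len, bytes)
      if (is_mz) {
        if (is.null(mz_ref)) {
          mz_ref <- vals
        } else if (mode_proc && !isTRUE(all.equal(mz_ref, vals,
                                                  tolerance = 1e-9))) {
          stop("processed-mode imzML without a common m/z axis: run peak ",
               "matching upstream first", call. = FALSE)
        }
      } else {
        intens_list[[i]] <- vals
      }
    }
  }
  if (is.null(mz_ref)) stop("no m/z array found", call. = FALSE)
  n_cols <- max(coords[, 1]); n_rows <- max(coords[, 2])
  if (anyDuplicated(paste(coords[, 1], coords[, 2]))) {
    stop("inconsistent imzML coordinates: duplicated pixel", call. = FALSE)
  }
  mat <- matrix(0, n_rows * n_cols, length(mz_ref))
  for (i in seq_along(spectra)) {
    if (length(intens_list[[i]]) != length(mz_ref)) {
      stop("spectrum intensity length does not match the m/z axis",
           call. = FALSE)
    }
    p <- (coords[i, 2] - 1L) * n_cols + coords[i, 1] # row-major pixel
    mat[p, ] <- intens_list[[i]]
  }
  n_missing <- n_rows * n_cols - nrow(coords)
  if (n_missing > 0) {
    warning(sprintf("%d grid cell(s) had no spectrum; zero-filled",
                    n_missing), call. = FALSE)
  }
  msi_dataset(mat, mz_ref, c(n_rows, n_cols))
}

#' Write an imzML file (continuous mode)
#'
#' Writes the dataset as continuous-mode imzML: one shared 64-bit m/z
#' array followed by one 64-bit intensity array per pixel in the `.ibd`
#' sibling file. No checksum is embedded (the reader ignores checksums).
#'
#' @param ds an `msi_dataset`.
#' @param path output `.imzML` path; the `.ibd` is written next to it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(ds, path) {
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  con <- file(ibd_path, "wb")
  writeBin(uuid, con)
  writeBin(as.double(ds$mz), con, size = 8L)
  mz_offset <- 16L
  mz_bytes <- 8L * length(ds$mz)
  n_pix <- n_pixels(ds)
  offsets <- mz_offset + mz_bytes + (seq_len(n_pix) - 1L) * mz_bytes
  for (p in seq_len(n_pix)) {
    writeBin(as.double(ds$intensities[p, ]), con, size = 8L)
  }
  close(con)

  nr <- ds$shape[1]; nc <- ds$shape[2]
  spectra <- character(n_pix)
  for (p in seq_len(n_pix)) {
    x <- (p - 1L) %% nc + 1L
    y <- (p - 1L) %/% nc + 1L
    spectra[p] <- paste0(
      sprintf('   <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
              p - 1L, p, length(ds$mz)),
      '    <scanList count="1"><scan>\n',
      sprintf('     <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n', x),
      sprintf('     <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n', y),
      '    </scan></scanList>\n',
      '    <binaryDataArrayList count="2">\n',
      '     <binaryDataArray encodedLength="0">\n',
      '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n', mz_offset),
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', length(ds$mz)),
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', mz_bytes),
      '      <binary/>\n',
      '     </binaryDataArray>\n',
      '     <binaryDataArray encodedLength="0">\n',
      '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%d"/>\n', offsets[p]),
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n', length(ds$mz)),
      sprintf('      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n', mz_bytes),
      '      <binary/>\n',
      '     </binaryDataArray>\n',
      '    </binaryDataArrayList>\n',
      '   </spectrum>\n')
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    ' <fileDescription>\n',
    '  <fileContent>\n',
    '   <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>\n',
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
            paste(format(uuid), collapse = "")),
    '  </fileContent>\n',
    ' </fileDescription>\n',
    ' <scanSettingsList count="1">\n',
    '  <scanSettings id="scansettings1">\n',
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n', nc),
    sprintf('   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n', nr),
    '  </scanSettings>\n',
    ' </scanSettingsList>\n',
    ' <run id="run1">\n',
    sprintf('  <spectrumList count="%d">\n', n_pix),
    paste(spectra, collapse = ""),
    '  </spectrumList>\n',
    ' </run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
  invisible(path)
}

# ---- external rasters -------------------------------------------------

#' Import an external raster as a reference image or ROI
#'
#' Reads a PNG or TIFF already registered to the MSI grid (registration
#' itself is out of scope) and converts it to a grayscale `msi_image`
#' (mean of the color channels). Dimensions must match the dataset grid
#' exactly; see [resize_nearest()] for a simple helper when they do not.
#'
#' @param path path to a `.png` or `.tif(f)` file.
#' @return An `msi_image` with `method = "external"`.
#' @export
read_raster <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::readTIFF(path)
  } else stop("unsupported raster format (use PNG or TIFF)", call. = FALSE)
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  msi_image(img, method = "external")
}

#' Nearest-neighbour resize of an image
#'
#' Convenience helper for external rasters whose pixel count differs from
#' the MSI grid. Nearest-neighbour only; proper registration must happen
#' upstream.
#'
#' @param img `msi_image` or matrix.
#' @param shape target `c(n_rows, n_cols)`.
#' @return An `msi_image` of the requested shape.
#' @export
resize_nearest <- function(img, shape) {
  v <- image_values(img)
  shape <- as.integer(shape)
  ri <- pmin(nrow(v), pmax(1L, round(seq(1, nrow(v), length.out = shape[1]))))
  ci <- pmin(ncol(v), pmax(1L, round(seq(1, ncol(v), length.out = shape[2]))))
  msi_image(v[ri, ci, drop = FALSE], method = "external")
}
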