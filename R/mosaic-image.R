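#' Mosaic image container
#'
#' A `mosaic_image` wraps a 2D real-valued intensity matrix together with the
#' bookkeeping needed to undo sanitization later: a mask of originally-NaN
#' pixels (non-rectangular scan ROIs leave NaN background), the range of the
#' original finite pixels, and an optional saturation level (the detector
#' ceiling, known for integer TIFFs).
#'
#' @param pixels Numeric matrix, at least 2 x 2.
#' @param saturation_level Optional scalar: intensities at or above this value
#'   are considered fully saturated (set automatically for 8/16-bit TIFFs).
#' @return An object of class `mosaic_image` with fields `pixels`,
#'   `nan_mask`, `source_range`, `shape`, `saturation_level`.
#' @export
mosaic_image <- function(pixels, saturation_level = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    sf_stop("argument", "pixels must be a numeric matrix")
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    sf_stop("argument", "image must be at least 2 x 2 (got %d x %d)",
            nrow(pixels), ncol(pixels))
  storage.mode(pixels) <- "double"
  nan_mask <- is.na(pixels)
  fin <- pixels[is.finite(pixels)]
  if (length(fin) == 0L) sf_stop("empty_image", "image contains no finite pixels")
  structure(list(
    pixels = pixels,
    nan_mask = nan_mask,
    source_range = range(fin),
    shape = dim(pixels),
    saturation_level = saturation_level
  ), class = "mosaic_image")
}

as_mosaic <- function(x) {
  if (inherits(x, "mosaic_image")) x else mosaic_image(x)
}

#' @export
as.matrix.mosaic_image <- function(x, ...) x$pixels

#' @export
print.mosaic_image <- function(x, ...) {
  cat(sprintf("mosaic_image: %d x %d px, finite range [%g, %g], %d NaN px\n",
              x$shape[1], x$shape[2], x$source_range[1], x$source_range[2],
              sum(x$nan_mask)))
  invisible(x)
}

#' Read a grayscale mosaic image
#'
#' Reads single-channel 2D images from TIFF/OME-TIFF (8/16-bit integer or
#' 32-bit float) or from plain-text numeric matrices (TSV/CSV; `NA`/`NaN`
#' and `Inf` tokens supported). Integer TIFF data are returned on their
#' native scale (0..255 / 0..65535) and the saturation level is recorded.
#'
#' @param path Path to a `.tif`/`.tiff` or text matrix file.
#' @return A [mosaic_image()].
#' @export
read_mosaic <- function(path) {
  if (!file.exists(path)) sf_stop("io", "cannot read '%s': file does not exist", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    x <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e) sf_stop("io", "cannot read TIFF '%s': %s",
                                              path, conditionMessage(e)))
    bits <- attr(x, "bits.per.sample") %||% NA_integer_
    sat <- NULL
    if (identical(bits, 32L)) {
      # 32-bit data are stored as IEEE floats; as.is misreads them, so take
      # the plain read, which returns float samples unmodified.
      x <- tiff::readTIFF(path, info = TRUE)
    } else if (is.finite(bits)) {
      sat <- 2^bits - 1
    }
    dims <- dim(x)
    if (length(dims) == 3L) {
      if (dims[3] == 1L) x <- x[, , 1L]
      else sf_stop("unsupported_format",
                   "only single-channel 2D images are supported (got shape %s)",
                   paste(dims, collapse = " x "))
    } else if (length(dims) != 2L) {
      sf_stop("unsupported_format", "unsupported image shape: %s",
              paste(dims, collapse = " x "))
    }
    m <- matrix(as.numeric(x), nrow(x), ncol(x))
    mosaic_image(m, saturation_level = sat)
  } else {
    sep <- if (ext == "csv") "," else ""
    x <- tryCatch(as.matrix(read.table(path, sep = sep, header = FALSE)),
                  error = function(e) sf_stop("io", "cannot read '%s': %s",
                                              path, conditionMessage(e)))
    storage.mode(x) <- "double"
    dimnames(x) <- NULL
    mosaic_image(x)
  }
}

#' Write a grayscale mosaic image
#'
#' `format = "text"` writes an exact TSV matrix (NaN preserved).
#' `"float01"` writes 32-bit float TIFF and requires finite values in
#' \[0, 1\] (the only float range the TIFF writer stores faithfully);
#' NaN pixels are written as 0 with a warning. `"uint16"`/`"uint8"`
#' affine-scale the finite range onto the integer range (a lossy,
#' warned operation). `"auto"` picks `"float01"` when values fit,
#' else `"uint16"`.
#'
#' @param x A [mosaic_image()] or numeric matrix.
#' @param path Output path.
#' @param format One of `"auto"`, `"float01"`, `"uint16"`, `"uint8"`, `"text"`.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(x, path,
                         format = c("auto", "float01", "uint16", "uint8", "text")) {
  format <- match.arg(format)
  m <- as.matrix(as_mosaic(x))
  ext <- tolower(tools::file_ext(path))
  if (format == "text" || ext %in% c("tsv", "txt", "csv")) {
    write.table(m, path, sep = if (ext == "csv") "," else "\t",
                row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  fin <- is.finite(m)
  if (format == "auto")
    format <- if (all(m[fin] >= 0 & m[fin] <= 1)) "float01" else "uint16"
  if (any(!fin)) {
    warning("non-finite pixels written as 0 in ", format, " output")
    m[!fin] <- 0
  }
  if (format == "float01") {
    if (any(m < 0 | m > 1))
      sf_stop("argument", "float01 output requires values in [0, 1]; rescale or use uint16")
    tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  } else {
    rng <- range(m)
    if (diff(rng) > 0) {
      warning(sprintf("intensities affine-scaled from [%g, %g] onto %s for output",
                      rng[1], rng[2], format))
      m <- (m - rng[1]) / diff(rng)
    } else m[] <- 0
    tiff::writeTIFF(m, path, bits.per.sample = if (format == "uint8") 8L else 16L)
  }
  invisible(path)
}
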