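#' Read a 2D grayscale image
#'
#' Supported containers: 8/16-bit TIFF (read at native integer values),
#' 32-bit float TIFF, 8-bit PNG (promoted to 0--255 with the promotion scale
#' recorded in the `scale` attribute), and raw binary with a JSON sidecar
#' (`<path>.json`) giving `shape` (rows, cols), `dtype` (`"uint8"`,
#' `"uint16"`, `"float32"`, `"float64"`) and optional `endianness`.
#'
#' @param path Image file path (`.tif`, `.tiff`, `.png`, or `.raw`).
#' @return Numeric matrix; multi-channel inputs are reduced to their first
#'   channel.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = {
      x <- tiff::readTIFF(path, info = TRUE)
      fmt <- attr(x, "sample.format")
      bits <- attr(x, "bits.per.sample")
      if (is.null(bits)) bits <- 16L
      is_float <- identical(fmt, "float") || bits == 32
      if (!is_float)
        x <- round(x * (2^bits - 1))  # undo the reader's [0,1] normalization
      sidecar <- paste0(path, ".json")
      if (file.exists(sidecar)) {
        meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        if (!is.null(meta$scale)) x <- x * meta$scale + meta$offset
      }
      x
    },
    png = {
      x <- png::readPNG(path)
      x <- x * 255
      attr(x, "scale") <- 255
      x
    },
    raw = read_raw_sidecar(path),
    stop_invalid(sprintf("unsupported image format '.%s'", ext))
  )
  if (length(dim(img)) == 3) {
    sc <- attr(img, "scale")
    img <- img[, , 1]
    attr(img, "scale") <- sc
  }
  storage.mode(img) <- "double"
  img
}

read_raw_sidecar <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) sidecar <- sub("\\.raw$", ".json", path)
  if (!file.exists(sidecar))
    stop_invalid("raw input requires a JSON sidecar (<path>.json)")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shape <- as.integer(meta$shape)
  dtype <- meta$dtype
  endian <- if (is.null(meta$endianness)) "little" else meta$endianness
  spec <- switch(dtype,
    uint8 = list(what = "integer", size = 1, signed = FALSE),
    uint16 = list(what = "integer", size = 2, signed = FALSE),
    float32 = list(what = "numeric", size = 4, signed = TRUE),
    float64 = list(what = "numeric", size = 8, signed = TRUE),
    stop_invalid(sprintf("unsupported raw dtype '%s'", dtype))
  )
  n_expect <- prod(shape)
  payload <- file.size(path) / spec$size
  if (payload != n_expect)
    stop_invalid(sprintf(
      "sidecar integrity error: payload holds %g values, sidecar shape needs %d",
      payload, n_expect))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = spec$what, n = n_expect, size = spec$size,
               signed = spec$signed, endian = endian)
  matrix(v, nrow = shape[1], ncol = shape[2], byrow = TRUE)
}

#' Write a 2D grayscale image
#'
#' 16-bit TIFF writes are lossless round trips for integer data in
#' `[0, 65535]`; `bits = 32` writes a 32-bit float TIFF for metric maps and
#' other non-integer data (unit-range samples plus a `<path>.json` sidecar
#' carrying the affine map back to the data range).
#'
#' @param img Numeric matrix.
#' @param path Output path (`.tif`/`.tiff`).
#' @param bits 16 (integer, default) or 32 (float).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, bits = 16) {
  assert_image(img, "img")
  if (bits == 16) {
    if (any(img < 0) || any(img > 65535))
      stop_invalid("16-bit write requires values in [0, 65535]")
    tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16)
  } else if (bits == 32) {
    # float TIFF samples are stored on [0, 1]; keep the affine map back to
    # the data range in a JSON sidecar that read_image() re-applies
    offset <- min(img)
    scale <- max(img) - offset
    if (scale == 0) scale <- 1
    tiff::writeTIFF((img - offset) / scale, path, bits.per.sample = 32,
                    reduce = FALSE)
    jsonlite::write_json(list(offset = offset, scale = scale),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    stop_invalid("bits must be 16 or 32")
  }
  invisible(path)
}
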