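# Frame ingestion and validation. A frame is a plain numeric matrix of
# luminance values in [0, 1]; rows index y (top to bottom), columns index x.

REC601 <- c(0.299, 0.587, 0.114)

#' Coerce an image to a grayscale frame
#'
#' Accepts a numeric matrix (already grayscale) or an `H x W x C` array as
#' returned by [png::readPNG()] / [tiff::readTIFF()]. Color input is
#' converted to luminance with Rec. 601 weights (0.299 R + 0.587 G +
#' 0.114 B); an alpha channel, if present, is dropped. Values are clamped
#' to `[0, 1]`.
#'
#' @param x Matrix or 3-d array of intensities in `[0, 1]`.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
as_frame <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    nch <- dim(x)[3L]
    x <- if (nch >= 3L) {
      REC601[1] * x[, , 1L] + REC601[2] * x[, , 2L] + REC601[3] * x[, , 3L]
    } else {
      x[, , 1L]
    }
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("frame must be a numeric matrix or H x W x C array", call. = FALSE)
  if (!all(is.finite(x)))
    stop("frame contains non-finite values", call. = FALSE)
  pmin(pmax(x, 0), 1)
}

# Validate a frame for scoring: finite numeric matrix, both dimensions at
# least `min_dim` pixels.
validate_frame <- function(frame, min_dim = 16L) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("frame must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(frame)))
    stop("frame contains non-finite values", call. = FALSE)
  if (nrow(frame) < min_dim || ncol(frame) < min_dim)
    stop(sprintf("frame must be at least %d x %d pixels for scoring", min_dim, min_dim),
         call. = FALSE)
  invisible(frame)
}

#' Read a still image as a frame
#'
#' Reads a PNG or TIFF file and converts it to a grayscale frame via
#' [as_frame()].
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric luminance matrix in `[0, 1]`.
#' @export
read_frame <- function(path) {
  if (!file.exists(path))
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG/TIFF supported): %s", ext, path),
         call. = FALSE)
  )
  as_frame(img)
}

#' Write a frame to a PNG file
#'
#' @param frame Numeric matrix in `[0, 1]`.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_frame_png <- function(frame, path) {
  frame <- as_frame(frame)
  png::writePNG(frame, target = path)
  invisible(path)
}
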