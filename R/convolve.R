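# Separable filtering with reflective (edge-inclusive, symmetric) border
# handling. These primitives back both the steerable derivative bank and the
# Gaussian blur used by the phantom generator, so the two share one border
# convention.

#' Sampled one-dimensional Gaussian kernel
#'
#' The kernel is sampled on integer offsets `-radius..radius` and normalized
#' to unit sum, so smoothing preserves the mean of a constant image.
#'
#' @param sigma Gaussian scale in pixels (> 0).
#' @param radius Half-width in pixels; defaults to `ceiling(3 * sigma)`.
#' @return Numeric vector of length `2 * radius + 1`.
#' @keywords internal
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  x <- seq.int(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Sampled first-derivative-of-Gaussian kernel
#'
#' Derivative of the unit-sum Gaussian of [gaussian_kernel()]:
#' `-x / sigma^2 * g(x)`. Antisymmetric, zero response on constants.
#'
#' @inheritParams gaussian_kernel
#' @keywords internal
gaussian_deriv_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  g <- gaussian_kernel(sigma, radius)
  x <- seq.int(-radius, radius)
  -x / sigma^2 * g
}

# Pad a matrix by symmetric reflection including the edge pixel
# (..., m[2], m[1] | m[1], m[2], ...). Pad widths must not exceed the
# corresponding dimension.
pad_reflect <- function(m, rpad, cpad) {
  nr <- nrow(m); nc <- ncol(m)
  if (rpad > nr || cpad > nc)
    stop("image too small for requested border padding", call. = FALSE)
  ri <- c(if (rpad > 0) rpad:1, seq_len(nr), if (rpad > 0) nr:(nr - rpad + 1L))
  ci <- c(if (cpad > 0) cpad:1, seq_len(nc), if (cpad > 0) nc:(nc - cpad + 1L))
  m[ri, ci, drop = FALSE]
}

# Separable linear filtering (correlation convention): rows are image y,
# columns are image x; `kcol` runs along x, `krow` along y. Reflective
# borders; output has the input's dimensions.
filter_separable <- function(img, krow, kcol) {
  rr <- (length(krow) - 1L) %/% 2L
  rc <- (length(kcol) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  p <- pad_reflect(img, 0L, rc)
  out <- matrix(0, nr, nc)
  for (i in seq_along(kcol))
    out <- out + kcol[i] * p[, i:(i + nc - 1L), drop = FALSE]
  p <- pad_reflect(out, rr, 0L)
  out <- matrix(0, nr, nc)
  for (i in seq_along(krow))
    out <- out + krow[i] * p[i:(i + nr - 1L), , drop = FALSE]
  out
}

#' Gaussian blur with reflective borders
#'
#' @param img Numeric matrix (grayscale frame).
#' @param sigma Blur scale in pixels; `0` returns the input unchanged.
#' @return Blurred matrix, same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img), is.numeric(sigma), length(sigma) == 1L)
  if (sigma < 0) stop("`sigma` must be non-negative", call. = FALSE)
  if (sigma == 0) return(img)
  g <- gaussian_kernel(sigma)
  filter_separable(img, g, g)
}
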