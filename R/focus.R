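# The SFIL focus measure: a steerable first-order Gaussian-derivative filter
# bank. A filter steered to orientation theta is
#   cos(theta) * G_x + sin(theta) * G_y
# with G_x, G_y the partial derivatives of an isotropic Gaussian of scale
# sigma. Per pixel the bank is reduced to the maximum absolute response over
# orientations; the frame score is the mean of that feature over the frame
# interior (a border margin of ceiling(3 * sigma) pixels is excluded to keep
# reflection artifacts out of the aggregate). The score is linear in image
# intensity by construction; the calibration stage absorbs overall scale.

# Both basis responses at scale sigma (correlation convention,
# reflective borders): gx = d/dx (columns), gy = d/dy (rows).
gaussian_basis_responses <- function(frame, sigma) {
  g <- gaussian_kernel(sigma)
  dg <- gaussian_deriv_kernel(sigma)
  list(
    gx = filter_separable(frame, krow = g, kcol = dg),
    gy = filter_separable(frame, krow = dg, kcol = g)
  )
}

#' Steered Gaussian-derivative response map
#'
#' Filters a frame with the first-order Gaussian-derivative kernel steered
#' to orientation `theta`: `cos(theta) * G_x + sin(theta) * G_y`. `theta = 0`
#' is the horizontal derivative (responds to vertical edges); `theta = pi/2`
#' the vertical derivative. Borders are handled by symmetric reflection.
#'
#' @param frame Numeric luminance matrix (see [as_frame()]).
#' @param theta Orientation in radians.
#' @param sigma Gaussian scale in pixels (> 0).
#' @return Response matrix with the frame's dimensions.
#' @export
oriented_response <- function(frame, theta, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  if (!is.matrix(frame) || !is.numeric(frame) || !all(is.finite(frame)))
    stop("frame must be a finite numeric matrix", call. = FALSE)
  b <- gaussian_basis_responses(frame, sigma)
  cos(theta) * b$gx + sin(theta) * b$gy
}

new_focus_score <- function(value, measure, params) {
  structure(list(value = value, measure = measure, params = params),
            class = "focus_score")
}

#' @export
print.focus_score <- function(x, ...) {
  p <- paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<focus_score> %s(%s) = %.6g\n", x$measure, p, x$value))
  invisible(x)
}

#' @export
as.numeric.focus_score <- function(x, ...) x$value

# Fast path returning the bare SFIL value; shared by sfil_score() and the
# clip scorer.
sfil_value <- function(frame, sigma = 1, n_orientations = 4L) {
  validate_frame(frame)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("`sigma` must be a single positive number", call. = FALSE)
  n_orientations <- as.integer(n_orientations)
  if (is.na(n_orientations) || n_orientations < 2L)
    stop("`n_orientations` must be an integer >= 2", call. = FALSE)
  margin <- as.integer(ceiling(3 * sigma))
  if (nrow(frame) <= 2L * margin || ncol(frame) <= 2L * margin)
    stop(sprintf("frame (%d x %d) smaller than twice the border margin (%d px)",
                 nrow(frame), ncol(frame), margin), call. = FALSE)
  b <- gaussian_basis_responses(frame, sigma)
  thetas <- (seq_len(n_orientations) - 1L) * pi / n_orientations
  feat <- abs(cos(thetas[1L]) * b$gx + sin(thetas[1L]) * b$gy)
  for (th in thetas[-1L])
    feat <- pmax(feat, abs(cos(th) * b$gx + sin(th) * b$gy))
  rows <- (margin + 1L):(nrow(frame) - margin)
  cols <- (margin + 1L):(ncol(frame) - margin)
  mean(feat[rows, cols])
}

#' SFIL focus score of a frame
#'
#' Computes steered responses at orientations `k * pi / n_orientations`,
#' `k = 0 .. n_orientations - 1`, takes the per-pixel maximum absolute
#' response over the bank, and averages it over the frame interior
#' (excluding a `ceiling(3 * sigma)`-pixel border). Higher values indicate
#' crisper in-focus edges; a constant frame scores exactly 0.
#'
#' @inheritParams oriented_response
#' @param sigma Filter scale in pixels; default 1.
#' @param n_orientations Number of evenly spaced orientations on `[0, pi)`;
#'   default 4 (0, 45, 90, 135 degrees).
#' @return A `focus_score` object with fields `value`, `measure`, `params`.
#' @examples
#' frame <- matrix(rep(c(0, 1), length.out = 24 * 24), 24, 24)
#' sfil_score(frame)
#' @export
sfil_score <- function(frame, sigma = 1, n_orientations = 4L) {
  v <- sfil_value(frame, sigma, n_orientations)
  new_focus_score(v, "sfil",
                  list(sigma = sigma, n_orientations = as.integer(n_orientations)))
}

# 3x3 neighbour shifts with reflective borders; used by the classical
# reference measures below.
sobel_responses <- function(frame) {
  smooth <- c(1, 2, 1) / 4
  deriv <- c(-1, 0, 1) / 2
  list(
    sx = filter_separable(frame, krow = smooth, kcol = deriv),
    sy = filter_separable(frame, krow = deriv, kcol = smooth)
  )
}

laplacian_response <- function(frame) {
  p <- pad_reflect(frame, 1L, 1L)
  nr <- nrow(frame); nc <- ncol(frame)
  ctr <- function(dr, dc) p[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc), drop = FALSE]
  ctr(-1L, 0L) + ctr(1L, 0L) + ctr(0L, -1L) + ctr(0L, 1L) - 4 * ctr(0L, 0L)
}

#' Classical reference focus measures
#'
#' Two standard no-reference sharpness scores under the same border
#' convention as [sfil_score()] (reflective padding, a 1-pixel margin --
#' the kernel radius -- excluded from aggregation):
#' `tenengrad` is the mean squared Sobel gradient magnitude; and
#' `laplacian_variance` is the population variance of the 4-neighbour
#' Laplacian response.
#'
#' @inheritParams sfil_score
#' @param method One of `"tenengrad"`, `"laplacian_variance"`.
#' @return A `focus_score` object.
#' @export
reference_score <- function(frame, method = c("tenengrad", "laplacian_variance")) {
  method <- match.arg(method)
  validate_frame(frame)
  rows <- 2L:(nrow(frame) - 1L)
  cols <- 2L:(ncol(frame) - 1L)
  v <- switch(method,
    tenengrad = {
      s <- sobel_responses(frame)
      mean((s$sx^2 + s$sy^2)[rows, cols])
    },
    laplacian_variance = {
      l <- laplacian_response(frame)[rows, cols]
      mean((l - mean(l))^2)
    }
  )
  new_focus_score(v, method, list())
}
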