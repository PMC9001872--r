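# Synthetic endoscopy-like phantoms. Real colonoscopy video cannot ship with
# the package, so every downstream stage is exercised on generated frames
# with known ground truth: a dark radial lumen gradient, random curvilinear
# vessel strokes (the crisp oriented edges SFIL responds to), optional
# saturated specular discs, and a band-controlled Gaussian blur. Band 4
# ("good") is nearly unblurred; band 1 ("poor") heavily blurred.

# Run `code` under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards: generators are pure functions of their inputs.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default blur ladder for the four quality bands
#'
#' Gaussian blur sigma, in pixels, applied when generating a phantom of each
#' band (1 = poor .. 4 = good). Chosen so the four SFIL score distributions
#' are cleanly separated at the default 256 x 256 frame size.
#'
#' @return Named numeric vector `c("1" = 6, "2" = 3, "3" = 1.5, "4" = 0.5)`.
#' @export
default_blur_ladder <- function() c("1" = 6, "2" = 3, "3" = 1.5, "4" = 0.5)

#' Specification of a synthetic phantom frame
#'
#' @param band Ground-truth quality band in 1..4 (1 = poor, 4 = good).
#' @param width,height Frame size in pixels.
#' @param blur_sigma Gaussian blur in pixels applied after compositing;
#'   defaults to the band's entry in [default_blur_ladder()]. Must be
#'   >= 0 (0 = no smoothing) and is strictly decreasing in band under the
#'   default ladder.
#' @param texture_density Vessel strokes per pixel of frame area
#'   (default 6e-4, about 39 strokes at 256 x 256).
#' @param highlight_count Number of saturated specular discs (>= 0).
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   frame.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(band, width = 256L, height = 256L, blur_sigma = NULL,
                         texture_density = 6e-4, highlight_count = 3L,
                         seed = 1L) {
  if (!is.numeric(band) || length(band) != 1L || !(band %in% 1:4))
    stop("`band` must be one of 1, 2, 3, 4", call. = FALSE)
  if (width < 1 || height < 1)
    stop("frame dimensions must be positive", call. = FALSE)
  if (is.null(blur_sigma)) blur_sigma <- unname(default_blur_ladder()[as.character(band)])
  if (!is.numeric(blur_sigma) || length(blur_sigma) != 1L || !is.finite(blur_sigma) ||
      blur_sigma < 0)
    stop("`blur_sigma` must be a single non-negative number", call. = FALSE)
  if (texture_density < 0) stop("`texture_density` must be non-negative", call. = FALSE)
  if (highlight_count < 0) stop("`highlight_count` must be non-negative", call. = FALSE)
  structure(list(band = as.integer(band), width = as.integer(width),
                 height = as.integer(height), blur_sigma = blur_sigma,
                 texture_density = texture_density,
                 highlight_count = as.integer(highlight_count),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Paint one quadratic Bezier vessel stroke (width 1-3 px, darker than the
# mucosa) onto img in place; returns the modified matrix.
paint_stroke <- function(img, w, h) {
  px <- runif(3, 1, w); py <- runif(3, 1, h)
  t <- seq(0, 1, length.out = 2L * (w + h))
  bx <- (1 - t)^2 * px[1] + 2 * (1 - t) * t * px[2] + t^2 * px[3]
  by <- (1 - t)^2 * py[1] + 2 * (1 - t) * t * py[2] + t^2 * py[3]
  wd <- sample(1:3, 1L)
  dark <- runif(1, 0.15, 0.3)
  off <- expand.grid(dr = 0:(wd - 1L), dc = 0:(wd - 1L)) # square brush
  off$dr <- off$dr - (wd - 1L) %/% 2L
  off$dc <- off$dc - (wd - 1L) %/% 2L
  xi <- round(bx); yi <- round(by)
  for (k in seq_len(nrow(off))) {
    r <- yi + off$dr[k]; c <- xi + off$dc[k]
    ok <- r >= 1 & r <= h & c >= 1 & c <= w
    idx <- (c[ok] - 1) * h + r[ok]         # linear index; dedupe so each
    idx <- idx[!duplicated(idx)]           # pixel is darkened once per pass
    img[idx] <- img[idx] - dark
  }
  img
}

#' Generate a synthetic endoscopy phantom frame
#'
#' Composites a dark central lumen gradient (with mild low-frequency mucosal
#' shading), random curvilinear vessel strokes at the requested texture
#' density, and optional saturated specular discs; then applies Gaussian
#' blur at the spec's `blur_sigma` and quantizes to 8-bit grayscale.
#' Deterministic under the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return Numeric luminance matrix in `[0, 1]` (8-bit quantized),
#'   `height x width`.
#' @export
generate_phantom_frame <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$width; h <- spec$height
  with_seed(spec$seed, {
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), times = w), h, w)
    cx <- w * (0.5 + runif(1, -0.08, 0.08))
    cy <- h * (0.5 + runif(1, -0.08, 0.08))
    r <- sqrt((xs - cx)^2 + (ys - cy)^2) / (0.5 * min(w, h))
    img <- 0.55 - 0.47 * exp(-(r / 0.9)^2)
    img <- img + 0.04 *
      sin(2 * pi * xs / w * runif(1, 1, 3) + runif(1, 0, 2 * pi)) *
      cos(2 * pi * ys / h * runif(1, 1, 3) + runif(1, 0, 2 * pi))
    n_strokes <- round(spec$texture_density * w * h)
    for (i in seq_len(n_strokes)) img <- paint_stroke(img, w, h)
    for (i in seq_len(spec$highlight_count)) {
      hx <- runif(1, 1, w); hy <- runif(1, 1, h)
      rad <- runif(1, 2, 5)
      img[(xs - hx)^2 + (ys - hy)^2 <= rad^2] <- 1
    }
    img <- pmin(pmax(img, 0), 1)
    img <- gaussian_blur(img, spec$blur_sigma)
    round(pmin(pmax(img, 0), 1) * 255) / 255
  })
}

#' Generate an out-of-body frame
#'
#' Emulates the appearance of recordings made outside the patient: a bright,
#' nearly uniform field with mild noise and a faint linear shading gradient.
#' Built to trip the [flag_out_of_body()] thresholds (high mean luminance,
#' low structure). Deterministic under `seed`.
#'
#' @param seed Integer seed.
#' @param width,height Frame size in pixels (positive).
#' @return Numeric luminance matrix in `[0, 1]` (8-bit quantized).
#' @export
generate_out_of_body_frame <- function(seed, width = 256L, height = 256L) {
  if (width < 1 || height < 1)
    stop("frame dimensions must be positive", call. = FALSE)
  w <- as.integer(width); h <- as.integer(height)
  with_seed(seed, {
    base <- runif(1, 0.82, 0.95)
    img <- matrix(base + rnorm(w * h, 0, 0.02), h, w)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    img <- img + runif(1, -0.03, 0.03) * (xs / w - 0.5)
    round(pmin(pmax(img, 0), 1) * 255) / 255
  })
}

#' Generate a synthetic clip from a band profile
#'
#' One frame per profile entry, frame `i` generated at band `band_profile[i]`
#' (blur from [default_blur_ladder()] unless the default spec overrides it),
#' timestamps spaced `1 / fps` seconds apart starting at 0. Frame seeds are
#' derived as `spec_defaults$seed + i - 1`, so a clip is reproducible from
#' (profile, fps, spec_defaults).
#'
#' @param band_profile Non-empty vector of bands in 1..4.
#' @param fps Frames per second (default 25).
#' @param spec_defaults A [phantom_spec()] providing size, texture and seed
#'   defaults (its `band`/`blur_sigma` are overridden per frame).
#' @param clip_id Identifier stored on the sequence.
#' @return A `frame_sequence`: list with `frames` (list of matrices),
#'   `timestamps` (seconds), `fps`, `clip_id`, and `ground_truth_bands`.
#' @export
generate_clip <- function(band_profile, fps = 25,
                          spec_defaults = phantom_spec(band = 4L),
                          clip_id = "clip_0001") {
  if (length(band_profile) == 0L)
    stop("`band_profile` must be non-empty", call. = FALSE)
  if (!all(band_profile %in% 1:4))
    stop("`band_profile` entries must be bands in 1..4", call. = FALSE)
  frames <- vector("list", length(band_profile))
  for (i in seq_along(band_profile)) {
    sp <- phantom_spec(band = band_profile[i], width = spec_defaults$width,
                       height = spec_defaults$height,
                       texture_density = spec_defaults$texture_density,
                       highlight_count = spec_defaults$highlight_count,
                       seed = spec_defaults$seed + i - 1L)
    frames[[i]] <- generate_phantom_frame(sp)
  }
  frame_sequence(frames, fps = fps, clip_id = clip_id,
                 ground_truth_bands = as.integer(band_profile))
}

#' Generate paired clinician ratings with controlled agreement
#'
#' Draws `n` rating pairs on the four-point scale whose absolute band
#' difference `|c1 - c2|` follows the supplied weights over categories
#' 0..3. For a given difference the lower band is uniform over the feasible
#' range and the sign of the discrepancy is a fair coin, so both raters'
#' marginals are exchangeable. Deterministic under `seed`.
#'
#' @param n Number of pairs (>= 0).
#' @param weights Non-negative weights over band differences 0, 1, 2, 3;
#'   must sum to 1. Default is the empirical inter-clinician distribution
#'   (0.624, 0.325, 0.029, 0.022).
#' @param seed Integer seed.
#' @return Data frame with columns `clip_id`, `rating_c1`, `rating_c2`.
#' @export
generate_rating_pairs <- function(n, weights = c(0.624, 0.325, 0.029, 0.022),
                                  seed = 1L) {
  if (n < 0) stop("`n` must be non-negative", call. = FALSE)
  if (length(weights) != 4L || any(!is.finite(weights)) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop("`weights` must be 4 non-negative values summing to 1", call. = FALSE)
  if (n == 0L)
    return(data.frame(clip_id = character(), rating_c1 = integer(),
                      rating_c2 = integer()))
  with_seed(seed, {
    d <- sample(0:3, n, replace = TRUE, prob = weights)
    lo <- vapply(d, function(di) sample.int(4L - di, 1L), integer(1))
    hi <- lo + d
    swap <- stats::runif(n) < 0.5
    c1 <- ifelse(swap, hi, lo)
    c2 <- ifelse(swap, lo, hi)
    data.frame(clip_id = sprintf("clip_%04d", seq_len(n)),
               rating_c1 = as.integer(c1), rating_c2 = as.integer(c2))
  })
}
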