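# Independent brute-force oracles. Each re-derives the checked quantity by
# direct enumeration (explicit nested-loop convolution, exhaustive cut-point
# triples, observation-pair counting, sign-flip enumeration) so the fast
# implementations are validated against a second route.

# Symmetric, edge-inclusive reflection of an index into 1..n.
reflect_index <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i
    if (i > n) i <- 2L * n + 1L - i
  }
  i
}

# Direct nested-loop filtering with the explicitly sampled steered
# first-order Gaussian-derivative kernel.
oracle_oriented_response <- function(frame, theta, sigma) {
  rad <- ceiling(3 * sigma)
  x <- seq.int(-rad, rad)
  g1 <- exp(-x^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  dg1 <- -x / sigma^2 * g1
  # K[dy + rad + 1, dx + rad + 1]
  K <- cos(theta) * outer(g1, dg1) + sin(theta) * outer(dg1, g1)
  nr <- nrow(frame); nc <- ncol(frame)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (dy in x) for (dx in x) {
      acc <- acc + K[dy + rad + 1L, dx + rad + 1L] *
        frame[reflect_index(r + dy, nr), reflect_index(cc + dx, nc)]
    }
    out[r, cc] <- acc
  }
  out
}

# Brute-force SFIL: materialize every steered kernel, take the explicit
# per-pixel max of absolute responses, average over the interior.
oracle_sfil <- function(frame, sigma = 1, n_orientations = 4L) {
  thetas <- (seq_len(n_orientations) - 1L) * pi / n_orientations
  resp <- lapply(thetas, function(th) abs(oracle_oriented_response(frame, th, sigma)))
  feat <- Reduce(pmax, resp)
  margin <- ceiling(3 * sigma)
  rows <- (margin + 1L):(nrow(frame) - margin)
  cols <- (margin + 1L):(ncol(frame) - margin)
  mean(feat[rows, cols])
}

# Explicit-loop Sobel magnitude-squared mean with reflective borders and a
# 1-pixel margin (matches the reference_score convention).
oracle_tenengrad <- function(frame) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 8
  nr <- nrow(frame); nc <- ncol(frame)
  acc <- 0; cnt <- 0
  for (r in 2:(nr - 1L)) for (cc in 2:(nc - 1L)) {
    sx <- 0; sy <- 0
    for (dy in -1:1) for (dx in -1:1) {
      v <- frame[reflect_index(r + dy, nr), reflect_index(cc + dx, nc)]
      sx <- sx + kx[dy + 2L, dx + 2L] * v  # derivative along x
      sy <- sy + kx[dx + 2L, dy + 2L] * v  # derivative along y
    }
    acc <- acc + sx^2 + sy^2
    cnt <- cnt + 1L
  }
  acc / cnt
}

# Exhaustive search over all ordered candidate cut-point triples; returns
# the best achievable training accuracy.
oracle_threshold_accuracy <- function(labeled) {
  s <- labeled$score; b <- labeled$band
  u <- sort(unique(s))
  cand <- (u[-length(u)] + u[-1L]) / 2
  span <- max(diff(range(u)), 1)
  while (length(cand) < 3L) cand <- c(min(u) - span, cand, max(u) + span)
  cand <- sort(unique(cand))
  m <- length(cand)
  best <- -1
  for (i in 1:(m - 2L)) for (j in (i + 1L):(m - 1L)) for (k in (j + 1L):m) {
    t <- cand[c(i, j, k)]
    pred <- 1L + (s >= t[1]) + (s >= t[2]) + (s >= t[3])
    best <- max(best, mean(pred == b))
  }
  best
}

# Gamma by enumeration over individual observation pairs.
oracle_gamma <- function(tab) {
  idx <- which(tab > 0, arr.ind = TRUE)
  a <- rep(idx[, 1], tab[idx]); b <- rep(idx[, 2], tab[idx])
  sa <- sign(outer(a, a, "-")); sb <- sign(outer(b, b, "-"))
  s <- sa * sb
  up <- upper.tri(s)
  C <- sum(s[up] > 0); D <- sum(s[up] < 0)
  list(C = C, D = D, gamma = (C - D) / (C + D))
}

# Exact Wilcoxon signed-rank two-sided p by enumerating all 2^n sign
# assignments of the midranks.
oracle_wilcoxon_p <- function(diffs) {
  d <- diffs[diffs != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs + 1e-9)
  p_ge <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Small textured phantom used across focus-measure tests.
small_phantom <- function(seed, size = 64L, band = 4L, blur_sigma = NULL,
                          density = 3e-3) {
  generate_phantom_frame(phantom_spec(band = band, width = size, height = size,
                                      blur_sigma = blur_sigma,
                                      texture_density = density, seed = seed))
}

# Calibration model fitted on a handful of small phantoms per band.
small_model <- function(per_band = 10L, size = 64L, seed = 42L, density = 3e-3) {
  labeled <- do.call(rbind, lapply(1:4, function(band) {
    score <- vapply(seq_len(per_band), function(i) {
      fr <- generate_phantom_frame(phantom_spec(
        band = band, width = size, height = size, texture_density = density,
        seed = seed + band * 1000L + i))
      lumiqc:::sfil_value(fr)
    }, numeric(1))
    data.frame(score = score, band = band)
  }))
  fit_thresholds(labeled)
}

# Clip score series built directly from a band multiset (for reduction
# tests that do not need real frames).
series_from_bands <- function(bands, oob = rep(FALSE, length(bands)),
                              clip_id = "clip_test") {
  out <- data.frame(frame_index = seq_along(bands) - 1L,
                    timestamp = (seq_along(bands) - 1) / 25,
                    score = as.numeric(bands), band = as.integer(bands),
                    out_of_body = oob)
  attr(out, "clip_id") <- clip_id
  class(out) <- c("clip_score_series", "data.frame")
  out
}
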