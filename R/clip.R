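# Clip-level scoring: per-frame SFIL + band classification, out-of-body
# flagging, and reduction of the per-frame band series to a clip estimate --
# one distinct band, a contiguous range of bands, or no estimate.

#' Flag an out-of-body frame
#'
#' A frame is flagged when it looks like a recording made outside the
#' patient: bright (mean luminance above `mean_min`) and nearly structure
#' free (luminance standard deviation below `sd_max`). In-body frames have
#' a dark lumen and textured mucosa and fail the brightness test.
#'
#' @param frame Numeric luminance matrix in `[0, 1]`.
#' @param mean_min Mean-luminance threshold (default 0.7).
#' @param sd_max Luminance-sd threshold (default 0.12).
#' @return Logical scalar.
#' @export
flag_out_of_body <- function(frame, mean_min = 0.7, sd_max = 0.12) {
  validate_frame(frame, min_dim = 1L)
  mean(frame) > mean_min && stats::sd(frame) < sd_max
}

#' Score a clip frame by frame
#'
#' Computes the SFIL score and calibrated band for every frame of a
#' sequence, and flags out-of-body frames (flagged frames keep their score
#' and band but are excluded from clip-level estimation).
#'
#' @param frames A `frame_sequence` (see [frame_sequence()]) or plain list
#'   of frame matrices.
#' @param model A fitted [fit_thresholds()] model; its stored measure
#'   parameters (sigma, number of orientations) drive the scorer.
#' @param mean_min,sd_max Out-of-body thresholds, see [flag_out_of_body()].
#' @param clip_id Identifier; defaults to the sequence's.
#' @return A `clip_score_series`: data frame with columns `frame_index`
#'   (0-based), `timestamp` (s), `score`, `band`, `out_of_body`, with the
#'   clip id as attribute `clip_id`.
#' @export
score_clip <- function(frames, model, mean_min = 0.7, sd_max = 0.12,
                       clip_id = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  if (inherits(frames, "frame_sequence")) {
    if (is.null(clip_id)) clip_id <- frames$clip_id
    ts <- frames$timestamps
    frames <- frames$frames
  } else {
    ts <- NULL
  }
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty frame sequence or list of frames",
         call. = FALSE)
  if (is.null(clip_id)) clip_id <- "clip"
  if (is.null(ts)) ts <- (seq_along(frames) - 1) / 25
  sigma <- if (!is.null(model$params$sigma)) model$params$sigma else 1
  n_or <- if (!is.null(model$params$n_orientations)) model$params$n_orientations else 4L
  score <- vapply(frames, sfil_value, numeric(1), sigma = sigma,
                  n_orientations = n_or)
  oob <- vapply(frames, flag_out_of_body, logical(1), mean_min = mean_min,
                sd_max = sd_max)
  out <- data.frame(frame_index = seq_along(frames) - 1L,
                    timestamp = ts, score = score,
                    band = classify_score(model, score),
                    out_of_body = oob)
  attr(out, "clip_id") <- clip_id
  class(out) <- c("clip_score_series", "data.frame")
  out
}

new_clip_estimate <- function(clip_id, kind, low_band = NA_integer_,
                              high_band = NA_integer_, support = NA_real_,
                              n_valid_frames) {
  structure(list(clip_id = clip_id, kind = kind,
                 low_band = low_band, high_band = high_band,
                 support = support, n_valid_frames = as.integer(n_valid_frames)),
            class = "clip_estimate")
}

#' @export
print.clip_estimate <- function(x, ...) {
  band_names <- c("poor", "almost poor", "almost good", "good")
  desc <- switch(x$kind,
    none = "no estimate",
    single = band_names[x$low_band],
    range = sprintf("%s to %s", band_names[x$low_band], band_names[x$high_band]))
  cat(sprintf("<clip_estimate> %s: %s (%s; support %.2f over %d valid frames)\n",
              x$clip_id, desc, x$kind,
              if (is.na(x$support)) NA else x$support, x$n_valid_frames))
  invisible(x)
}

#' Reduce a per-frame band series to a clip-level estimate
#'
#' Over the valid (non-out-of-body) frames, finds the shortest contiguous
#' band interval covering at least a fraction `min_support` of them.
#' Intervals span at most three bands -- the widest output the method
#' reports is a three-band range such as "poor to almost good" -- so a clip
#' whose bands only concentrate on the full 1..4 span yields no estimate,
#' as does a clip with fewer than `min_valid_frames` valid frames. Ties
#' between qualifying intervals of equal width are broken by higher
#' coverage of the interval's (lower) median band, then by the lower band.
#'
#' The result depends only on the multiset of valid frame bands, not their
#' order.
#'
#' @param series A [score_clip()] result (or data frame with columns `band`,
#'   `out_of_body`).
#' @param min_support Required fraction of valid frames inside the interval,
#'   in (0, 1]; default 0.8.
#' @param min_valid_frames Minimum number of valid frames for any estimate;
#'   default 25 (about one second at 25 fps).
#' @return A `clip_estimate` with `kind` one of `"single"`, `"range"`,
#'   `"none"`; `low_band`/`high_band` and `support` are `NA` for `"none"`.
#' @export
estimate_clip_band <- function(series, min_support = 0.8,
                               min_valid_frames = 25L) {
  if (!is.data.frame(series) || !all(c("band", "out_of_body") %in% names(series)))
    stop("`series` must be a clip score series with `band` and `out_of_body`",
         call. = FALSE)
  if (!is.numeric(min_support) || length(min_support) != 1L ||
      !is.finite(min_support) || min_support <= 0 || min_support > 1)
    stop("`min_support` must be in (0, 1]", call. = FALSE)
  clip_id <- attr(series, "clip_id")
  if (is.null(clip_id)) clip_id <- "clip"
  bands <- series$band[!series$out_of_body]
  n_valid <- length(bands)
  if (n_valid < min_valid_frames)
    return(new_clip_estimate(clip_id, "none", n_valid_frames = n_valid))
  frac <- tabulate(bands, nbins = 4L) / n_valid
  best <- NULL
  for (width in 1:3) {
    for (lo in 1:(5L - width)) {
      hi <- lo + width - 1L
      supp <- sum(frac[lo:hi])
      if (supp >= min_support - 1e-12) {
        med <- lo + (width - 1L) %/% 2L  # lower median band
        cand <- list(lo = lo, hi = hi, support = supp, med_cov = frac[med])
        if (is.null(best) || cand$med_cov > best$med_cov + 1e-12) best <- cand
      }
    }
    if (!is.null(best)) break
  }
  if (is.null(best))
    return(new_clip_estimate(clip_id, "none", n_valid_frames = n_valid))
  new_clip_estimate(clip_id,
                    kind = if (best$lo == best$hi) "single" else "range",
                    low_band = best$lo, high_band = best$hi,
                    support = best$support, n_valid_frames = n_valid)
}
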