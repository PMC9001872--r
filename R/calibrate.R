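# Ordinal threshold calibration: map continuous focus scores onto the
# four-point quality scale (1 = poor, 2 = almost poor, 3 = almost good,
# 4 = good) by an accuracy-maximizing search for three ordered cut-points.
# Candidate cuts are the midpoints between adjacent distinct sorted scores;
# the search is exact (equivalent to exhausting all ordered triples) via a
# prefix/suffix decomposition of the training accuracy.

#' Fit band thresholds from labeled scores
#'
#' Finds the strictly increasing threshold triple `(t1, t2, t3)` maximizing
#' training classification accuracy under the rule of [classify_score()].
#' Candidates are midpoints between adjacent distinct scores; among
#' accuracy-optimal triples the one maximizing the minimum inter-threshold
#' margin `min(t2 - t1, t3 - t2)` is returned (remaining ties: lowest
#' thresholds). Because only the ordering of scores enters the accuracy,
#' the achieved accuracy is invariant under any strictly increasing
#' transform applied to all scores.
#'
#' @param labeled Data frame with numeric column `score` and integer column
#'   `band` in 1..4. All four bands must be present, each with at least two
#'   scores.
#' @param measure,params Name and parameter list of the focus measure the
#'   scores came from; stored on the model so it cannot silently be applied
#'   to scores from a different measure.
#' @return A `calibration_model`: list with `thresholds` (t1 < t2 < t3),
#'   `measure`, `params`, `n_per_band`, `training_accuracy`, `n`.
#' @examples
#' lab <- data.frame(score = c(10, 11, 20, 21, 30, 31, 40, 41),
#'                   band = rep(1:4, each = 2))
#' fit_thresholds(lab)$thresholds
#' @export
fit_thresholds <- function(labeled, measure = "sfil",
                           params = list(sigma = 1, n_orientations = 4L)) {
  if (!is.data.frame(labeled) || !all(c("score", "band") %in% names(labeled)))
    stop("`labeled` must be a data frame with columns `score` and `band`",
         call. = FALSE)
  s <- as.numeric(labeled$score)
  b <- as.integer(labeled$band)
  if (any(!is.finite(s))) stop("scores must be finite", call. = FALSE)
  if (any(!(b %in% 1:4))) stop("bands must be in 1..4", call. = FALSE)
  n_per_band <- vapply(1:4, function(k) sum(b == k), integer(1))
  missing_bands <- which(n_per_band == 0L)
  if (length(missing_bands) > 0L)
    stop(sprintf("cannot fit a full model: no labeled scores for band(s) %s",
                 paste(missing_bands, collapse = ", ")), call. = FALSE)
  if (any(n_per_band < 2L))
    stop("each band needs at least 2 labeled scores", call. = FALSE)
  u <- sort(unique(s))
  if (length(u) == 1L)
    stop("degenerate data: all scores identical", call. = FALSE)
  cand <- (u[-length(u)] + u[-1L]) / 2
  # Augment with cuts outside the score range so three strictly increasing
  # thresholds always exist (accuracy is unaffected by cuts beyond the data).
  span <- max(diff(range(u)), 1)
  while (length(cand) < 3L) cand <- c(min(u) - span, cand, max(u) + span)
  cand <- sort(unique(cand))
  m <- length(cand)
  # below[j, i] = number of band-j scores strictly below cand[i]
  below <- vapply(1:4, function(k) findInterval(cand, sort(s[b == k])),
                  numeric(m))
  # accuracy(i < j < k) * n = a[i] + bb[j] + cc[k] + n4
  a <- below[, 1L] - below[, 2L]
  bb <- below[, 2L] - below[, 3L]
  cc <- below[, 3L] - below[, 4L]
  n4 <- n_per_band[4L]
  pre <- cummax(c(-Inf, a[-m]))           # pre[j]  = max a[i], i < j
  suf <- rev(cummax(rev(c(cc[-1L], -Inf)))) # suf[j] = max cc[k], k > j
  totals <- pre + bb + suf
  best <- max(totals[2:(m - 1L)])
  js <- which(totals == best & seq_len(m) > 1L & seq_len(m) < m)
  # Tie-break: among optimal triples, maximize min(t2 - t1, t3 - t2). For a
  # fixed middle cut the margin is maximized by the lowest optimal t1 and
  # the highest optimal t3, which are independent choices.
  pick <- function(j) {
    i <- which(a[seq_len(j - 1L)] == pre[j])[1L]
    k <- j + max(which(cc[(j + 1L):m] == suf[j]))
    c(i, j, k)
  }
  triples <- lapply(js, pick)
  margins <- vapply(triples, function(t3) {
    min(cand[t3[2L]] - cand[t3[1L]], cand[t3[3L]] - cand[t3[2L]])
  }, numeric(1))
  sel <- triples[[which.max(margins)]]
  thresholds <- cand[sel]
  structure(list(thresholds = thresholds, measure = measure, params = params,
                 n_per_band = n_per_band,
                 training_accuracy = (best + n4) / length(s),
                 n = length(s)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> measure=%s thresholds=(%.6g, %.6g, %.6g)\n",
              x$measure, x$thresholds[1], x$thresholds[2], x$thresholds[3]))
  cat(sprintf("  n=%d (per band: %s), training accuracy %.3f\n", x$n,
              paste(x$n_per_band, collapse = "/"), x$training_accuracy))
  invisible(x)
}

#' Classify a focus score into a quality band
#'
#' Half-open intervals, lower-closed: band 1 if `score < t1`; band 2 on
#' `[t1, t2)`; band 3 on `[t2, t3)`; band 4 if `score >= t3`. A score lying
#' exactly on a threshold is assigned to the higher band. Vectorized over
#' `score`. A `focus_score` object is accepted only if its measure and
#' parameters match the model's.
#'
#' @param model A [fit_thresholds()] model.
#' @param score Numeric vector of scores, or a single `focus_score`.
#' @return Integer band(s) in 1..4.
#' @export
classify_score <- function(model, score) {
  stopifnot(inherits(model, "calibration_model"))
  if (inherits(score, "focus_score")) {
    if (!identical(score$measure, model$measure) ||
        !isTRUE(all.equal(score$params, model$params)))
      stop(sprintf("model calibrated for %s does not apply to a %s score",
                   model$measure, score$measure), call. = FALSE)
    score <- score$value
  }
  if (!is.numeric(score) || any(!is.finite(score)))
    stop("`score` must be finite numeric", call. = FALSE)
  t <- model$thresholds
  as.integer(1L + (score >= t[1]) + (score >= t[2]) + (score >= t[3]))
}

#' Classification accuracy on a labeled set
#'
#' @inheritParams classify_score
#' @param labeled Non-empty data frame with columns `score`, `band`.
#' @return Fraction of labeled scores classified into their labeled band.
#' @export
evaluate_accuracy <- function(model, labeled) {
  if (!is.data.frame(labeled) || nrow(labeled) == 0L)
    stop("`labeled` must be a non-empty data frame", call. = FALSE)
  mean(classify_score(model, labeled$score) == as.integer(labeled$band))
}

#' Write / read a calibration model as JSON
#'
#' The serialized document embeds the measure name and parameters so a
#' reloaded model still refuses scores from a mismatched measure.
#'
#' @param model A `calibration_model`.
#' @param path JSON file path.
#' @return `write_calibration`: `path` invisibly; `read_calibration`: the
#'   model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$thresholds <- as.numeric(x$thresholds)
  x$n_per_band <- as.integer(x$n_per_band)
  x$params <- lapply(x$params, function(p) if (is.numeric(p)) p else p)
  if (!is.null(x$params$n_orientations))
    x$params$n_orientations <- as.integer(x$params$n_orientations)
  structure(x, class = "calibration_model")
}
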