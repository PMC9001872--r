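# Rater-agreement statistics for paired ordinal ratings on the four-point
# scale: contingency tables, Goodman-Kruskal gamma with a normal-theory
# significance test, the Wilcoxon signed-rank test (exact sign-flip
# distribution for small samples, tie-corrected normal approximation
# otherwise), band-difference tables, and match percentages between
# clip estimates and human ratings.

# Half-up rounding (2.45 -> 2.5 at one decimal), as printed agreement
# tables conventionally round; base round() rounds half to even.
round_half_up <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

check_bands <- function(x, what) {
  if (length(x) == 0L) stop(sprintf("`%s` must be non-empty", what), call. = FALSE)
  if (any(!(x %in% 1:4)))
    stop(sprintf("`%s` must contain bands in 1..4 only", what), call. = FALSE)
  as.integer(x)
}

as_pair_vectors <- function(pairs) {
  if (is.data.frame(pairs)) {
    if (!all(c("rating_c1", "rating_c2") %in% names(pairs)))
      stop("`pairs` must have columns `rating_c1` and `rating_c2`", call. = FALSE)
    list(a = check_bands(pairs$rating_c1, "rating_c1"),
         b = check_bands(pairs$rating_c2, "rating_c2"))
  } else stop("`pairs` must be a data frame of rating pairs", call. = FALSE)
}

#' 4 x 4 cross-tabulation of rating pairs
#'
#' @param pairs Data frame with integer columns `rating_c1`, `rating_c2`
#'   (bands 1..4).
#' @return Integer matrix of counts, rows = rater 1's band, columns =
#'   rater 2's band, with attribute `n` (total pairs) and class `crosstab`.
#' @export
crosstab <- function(pairs) {
  v <- as_pair_vectors(pairs)
  tab <- matrix(0L, 4L, 4L, dimnames = list(rating_c1 = 1:4, rating_c2 = 1:4))
  for (i in seq_along(v$a)) tab[v$a[i], v$b[i]] <- tab[v$a[i], v$b[i]] + 1L
  attr(tab, "n") <- length(v$a)
  class(tab) <- c("crosstab", class(tab))
  tab
}

#' Goodman-Kruskal gamma for an ordinal contingency table
#'
#' Gamma is `(C - D) / (C + D)` where `C` counts concordant observation
#' pairs (both variables strictly increasing across the pair) and `D`
#' discordant pairs; tied pairs are ignored. Significance uses the normal
#' approximation `z = G * sqrt((C + D) / (n * (1 - G^2)))` with a two-sided
#' p-value. At the boundary `|G| = 1` the variance collapses; the result is
#' flagged (`boundary = TRUE`) and the p-value reported as `NA` rather
#' than 0.
#'
#' @param tab A [crosstab()] or numeric matrix of non-negative counts.
#' @return A `gamma_result`: list with `gamma`, `concordant`, `discordant`,
#'   `n`, `z`, `p_value`, `boundary`.
#' @examples
#' goodman_kruskal_gamma(matrix(c(10, 5, 5, 10), 2, 2, byrow = TRUE))
#' @export
goodman_kruskal_gamma <- function(tab) {
  tab <- unclass(tab)
  if (!is.matrix(tab) || any(tab < 0) || any(!is.finite(tab)))
    stop("`tab` must be a matrix of non-negative counts", call. = FALSE)
  nr <- nrow(tab); nc <- ncol(tab)
  C <- 0; D <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    nij <- tab[i, j]
    if (nij == 0) next
    if (i < nr && j < nc)
      C <- C + nij * sum(tab[(i + 1):nr, (j + 1):nc])
    if (i < nr && j > 1)
      D <- D + nij * sum(tab[(i + 1):nr, 1:(j - 1)])
  }
  if (C + D == 0)
    stop("gamma undefined: all observation pairs are tied", call. = FALSE)
  g <- (C - D) / (C + D)
  n <- sum(tab)
  boundary <- abs(g) == 1
  z <- if (boundary) sign(g) * Inf else g * sqrt((C + D) / (n * (1 - g^2)))
  p <- if (boundary) NA_real_ else 2 * stats::pnorm(-abs(z))
  structure(list(gamma = g, concordant = C, discordant = D, n = n,
                 z = z, p_value = p, boundary = boundary),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> G = %.3f (C = %d, D = %d, n = %d), z = %.3f, p = %s%s\n",
              x$gamma, x$concordant, x$discordant, x$n, x$z,
              format.pval(x$p_value),
              if (x$boundary) " [boundary |G| = 1]" else ""))
  invisible(x)
}

# Exact distribution of W+ over the 2^n equiprobable sign assignments, for
# doubled midranks r2 (integers). Returns probabilities indexed 0..sum(r2).
signed_rank_distribution <- function(r2) {
  f <- numeric(sum(r2) + 1L)
  f[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), f[seq_len(length(f) - r)])
    f <- f + shifted
  }
  f / 2^length(r2)
}

#' Wilcoxon signed-rank test on paired ordinal ratings
#'
#' Differences `d = rating_c1 - rating_c2`; zero differences are dropped
#' (classic Wilcoxon convention), absolute differences ranked with midrank
#' ties, and the statistic is `min(W+, W-)`. For `n_effective <=
#' exact_limit` the two-sided p-value is computed from the exact sign-flip
#' distribution of `W+` (all `2^n` assignments, ties handled exactly);
#' above it, the tie-corrected normal approximation is used (no continuity
#' correction). If every difference is zero the raters agree perfectly and
#' the result is flagged degenerate with no test.
#'
#' @param pairs Data frame with columns `rating_c1`, `rating_c2`.
#' @param exact_limit Largest `n_effective` for which the exact distribution
#'   is used; default 25.
#' @return A `wilcoxon_result`: list with `statistic` (min(W+, W-)),
#'   `w_plus`, `w_minus`, `p_value`, `n_effective`, `method`, `degenerate`.
#' @export
wilcoxon_signed_rank <- function(pairs, exact_limit = 25L) {
  v <- as_pair_vectors(pairs)
  d <- v$a - v$b
  d <- d[d != 0L]
  n <- length(d)
  if (n == 0L)
    return(structure(list(statistic = NA_real_, w_plus = NA_real_,
                          w_minus = NA_real_, p_value = NA_real_,
                          n_effective = 0L, method = "none",
                          degenerate = TRUE),
                     class = "wilcoxon_result"))
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    f <- signed_rank_distribution(r2)
    w2 <- as.integer(round(2 * w_plus))
    p_le <- sum(f[seq_len(w2 + 1L)])
    p_ge <- sum(f[(w2 + 1L):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(list(statistic = min(w_plus, w_minus), w_plus = w_plus,
                 w_minus = w_minus, p_value = p, n_effective = n,
                 method = method, degenerate = FALSE),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<wilcoxon_result> degenerate: all paired differences are zero (perfect agreement)\n")
  } else {
    cat(sprintf("<wilcoxon_result> W = %.1f (W+ = %.1f, W- = %.1f), n_eff = %d, p = %s (%s)\n",
                x$statistic, x$w_plus, x$w_minus, x$n_effective,
                format.pval(x$p_value), x$method))
  }
  invisible(x)
}

#' Band-difference table for paired ratings
#'
#' Tabulates the absolute band difference `|c1 - c2|` into categories
#' 0..3, with percentages rounded half-up to one decimal place, and the
#' percentage of pairs within one band of each other.
#'
#' @param pairs Data frame with columns `rating_c1`, `rating_c2`.
#' @return A `band_difference_table`: list with `counts` (named, "0".."3"),
#'   `percentages` (one decimal), `within_one_pct` (one decimal), `n`.
#' @export
band_difference_table <- function(pairs) {
  v <- as_pair_vectors(pairs)
  d <- abs(v$a - v$b)
  n <- length(d)
  counts <- vapply(0:3, function(k) sum(d == k), integer(1))
  names(counts) <- as.character(0:3)
  pct <- round_half_up(100 * counts / n, 1L)
  structure(list(counts = counts, percentages = pct,
                 within_one_pct = round_half_up(100 * sum(d <= 1) / n, 1L),
                 n = n),
            class = "band_difference_table")
}

#' @export
print.band_difference_table <- function(x, ...) {
  cat("<band_difference_table>\n")
  cat("  |diff|  frequency  percent\n")
  for (k in 1:4)
    cat(sprintf("  %5s   %9d  %7.1f\n", names(x$counts)[k], x$counts[k],
                x$percentages[k]))
  cat(sprintf("  within one band: %.1f%% of %d pairs\n", x$within_one_pct, x$n))
  invisible(x)
}

# Single ordinal band summarizing an estimate for rank statistics: the
# (lower-)central band of its interval; NA for kind = "none".
estimate_central_band <- function(est) {
  if (est$kind == "none") return(NA_integer_)
  as.integer((est$low_band + est$high_band) %/% 2L)
}

#' Match percentages between clip estimates and human ratings
#'
#' A single-band estimate matches when its band equals the human rating; a
#' range estimate matches when the rating lies inside `[low_band,
#' high_band]` (containment convention). Also reports the share of
#' estimates that were single bands, two-band ranges, three-band ranges, or
#' no estimate.
#'
#' @param estimates List of [estimate_clip_band()] results.
#' @param ratings Data frame with columns `clip_id` and `band` (one human
#'   rating per clip). Every estimate's clip id must be present.
#' @return List with `n`, `pct_single`, `pct_range2`, `pct_range3`,
#'   `pct_none` (shares of all estimates, in percent), `exact_match_pct`
#'   (among single estimates), `range_match_pct` (among range estimates);
#'   match percentages are `NA` when the category is empty.
#' @export
match_percentages <- function(estimates, ratings) {
  if (length(estimates) == 0L) stop("`estimates` must be non-empty", call. = FALSE)
  if (!is.data.frame(ratings) || !all(c("clip_id", "band") %in% names(ratings)))
    stop("`ratings` must have columns `clip_id` and `band`", call. = FALSE)
  ids <- vapply(estimates, function(e) e$clip_id, character(1))
  miss <- setdiff(ids, ratings$clip_id)
  if (length(miss) > 0L)
    stop(sprintf("no human rating for clip id(s): %s",
                 paste(utils::head(miss, 5L), collapse = ", ")), call. = FALSE)
  rated <- check_bands(ratings$band[match(ids, ratings$clip_id)], "band")
  kind <- vapply(estimates, function(e) e$kind, character(1))
  width <- vapply(estimates, function(e) {
    if (e$kind == "none") 0L else e$high_band - e$low_band + 1L
  }, integer(1))
  n <- length(estimates)
  is_single <- kind == "single"
  is_range <- kind == "range"
  single_match <- vapply(which(is_single), function(i) {
    estimates[[i]]$low_band == rated[i]
  }, logical(1))
  range_match <- vapply(which(is_range), function(i) {
    rated[i] >= estimates[[i]]$low_band && rated[i] <= estimates[[i]]$high_band
  }, logical(1))
  list(n = n,
       pct_single = 100 * sum(is_single) / n,
       pct_range2 = 100 * sum(width == 2L) / n,
       pct_range3 = 100 * sum(width == 3L) / n,
       pct_none = 100 * sum(kind == "none") / n,
       exact_match_pct = if (any(is_single)) 100 * mean(single_match) else NA_real_,
       range_match_pct = if (any(is_range)) 100 * mean(range_match) else NA_real_)
}

#' Assemble the full agreement report
#'
#' Cross-tabulates the two raters, computes Goodman-Kruskal gamma between
#' each rater and the algorithm's per-clip band (range estimates enter as
#' their central band; clips without an estimate are excluded from the
#' gamma tables), runs the Wilcoxon signed-rank test on the rater pair,
#' builds the inter-rater band-difference table, and computes match
#' percentages against each rater.
#'
#' @param pairs Data frame with `clip_id`, `rating_c1`, `rating_c2`.
#' @param estimates List of clip estimates aligned to `pairs$clip_id`.
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(pairs, estimates) {
  v <- as_pair_vectors(pairs)
  ids <- vapply(estimates, function(e) e$clip_id, character(1))
  if (!setequal(ids, pairs$clip_id))
    stop("estimate clip ids must match `pairs$clip_id`", call. = FALSE)
  ord <- match(pairs$clip_id, ids)
  algo <- vapply(estimates[ord], estimate_central_band, integer(1))
  keep <- !is.na(algo)
  gamma_vs <- function(rater) {
    goodman_kruskal_gamma(crosstab(data.frame(rating_c1 = rater[keep],
                                              rating_c2 = algo[keep])))
  }
  structure(list(
    crosstab_c1_c2 = crosstab(pairs),
    gamma_c1_vs_algo = gamma_vs(v$a),
    gamma_c2_vs_algo = gamma_vs(v$b),
    wilcoxon_c1_vs_c2 = wilcoxon_signed_rank(pairs),
    band_difference_c1_c2 = band_difference_table(pairs),
    match_c1 = match_percentages(estimates,
                                 data.frame(clip_id = pairs$clip_id, band = v$a)),
    match_c2 = match_percentages(estimates,
                                 data.frame(clip_id = pairs$clip_id, band = v$b)),
    n = nrow(pairs)
  ), class = "agreement_report")
}
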