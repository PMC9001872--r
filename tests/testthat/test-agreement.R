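# Agreement statistics: crosstab, Goodman-Kruskal gamma, Wilcoxon
# signed-rank, band-difference tables, match percentages.

random_table <- function() {
  matrix(sample(0:20, 16, replace = TRUE), 4, 4)
}

test_that("crosstab counts pairs and preserves marginals", {
  all44 <- data.frame(rating_c1 = rep(4L, 7), rating_c2 = rep(4L, 7))
  tab <- crosstab(all44)
  expect_identical(sum(unclass(tab) != 0), 1L)
  expect_identical(unclass(tab)[4, 4], 7L)
  pairs <- generate_rating_pairs(200, seed = 5)
  tab <- crosstab(pairs)
  expect_identical(sum(tab), 200L)
  expect_equal(unname(rowSums(tab)), tabulate(pairs$rating_c1, 4L))
  expect_equal(unname(colSums(tab)), tabulate(pairs$rating_c2, 4L))
  expect_error(crosstab(data.frame(rating_c1 = 5, rating_c2 = 1)), "1..4")
})

test_that("gamma handles the textbook tables", {
  expect_error(goodman_kruskal_gamma(diag(c(5, 0, 0, 0))), "tied")
  d <- goodman_kruskal_gamma(diag(c(5, 5, 5, 5)))
  expect_equal(d$gamma, 1)
  expect_true(d$boundary)
  expect_true(is.na(d$p_value))
  anti <- goodman_kruskal_gamma(diag(4)[4:1, ] * 5)
  expect_equal(anti$gamma, -1)
  g <- goodman_kruskal_gamma(matrix(c(10, 5, 5, 10), 2, 2, byrow = TRUE))
  expect_equal(g$concordant, 100)
  expect_equal(g$discordant, 25)
  expect_equal(g$gamma, 0.6)
})

test_that("gamma matches brute-force observation-pair enumeration", {
  set.seed(19)
  for (rep in 1:25) {
    tab <- random_table()
    o <- oracle_gamma(tab)
    if (o$C + o$D == 0) next
    g <- goodman_kruskal_gamma(tab)
    expect_equal(g$concordant, o$C)
    expect_equal(g$discordant, o$D)
    expect_equal(g$gamma, o$gamma)
  }
})

test_that("gamma symmetry identities hold", {
  set.seed(29)
  for (rep in 1:10) {
    tab <- random_table()
    g <- tryCatch(goodman_kruskal_gamma(tab), error = function(e) NULL)
    if (is.null(g)) next
    expect_equal(goodman_kruskal_gamma(t(tab))$gamma, g$gamma)
    expect_equal(goodman_kruskal_gamma(tab[4:1, ])$gamma, -g$gamma)
    expect_equal(goodman_kruskal_gamma(3 * tab)$gamma, g$gamma)
  }
})

test_that("a strongly concordant rating set is significant", {
  pairs <- generate_rating_pairs(412, seed = 1)
  g <- goodman_kruskal_gamma(crosstab(pairs))
  expect_gt(g$gamma, 0.5)
  expect_lt(g$p_value, 0.005)
})

test_that("wilcoxon flags perfect agreement as degenerate", {
  w <- wilcoxon_signed_rank(data.frame(rating_c1 = rep(3L, 10),
                                       rating_c2 = rep(3L, 10)))
  expect_true(w$degenerate)
  expect_identical(w$n_effective, 0L)
  expect_true(is.na(w$p_value))
})

test_that("balanced sign flips give p = 1 under the exact distribution", {
  pairs <- data.frame(rating_c1 = c(2L, 1L, 3L, 2L), rating_c2 = c(1L, 2L, 2L, 3L))
  w <- wilcoxon_signed_rank(pairs)
  expect_equal(w$w_plus, w$w_minus)
  expect_equal(w$p_value, 1)
  expect_identical(w$method, "exact")
})

test_that("exact wilcoxon p equals full sign-flip enumeration", {
  set.seed(37)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    c1 <- sample(1:4, n, replace = TRUE)
    c2 <- pmin(pmax(c1 + sample(-2:2, n, replace = TRUE), 1L), 4L)
    if (all(c1 == c2)) next
    w <- wilcoxon_signed_rank(data.frame(rating_c1 = c1, rating_c2 = c2))
    expect_equal(w$p_value, oracle_wilcoxon_p(c1 - c2), tolerance = 1e-12)
  }
})

test_that("large-sample wilcoxon matches the tie-corrected normal reference", {
  pairs <- generate_rating_pairs(300, seed = 11)
  w <- wilcoxon_signed_rank(pairs)
  expect_identical(w$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(pairs$rating_c1, pairs$rating_c2,
                                             paired = TRUE, exact = FALSE,
                                             correct = FALSE))
  expect_equal(w$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(w$w_plus, unname(ref$statistic))
})

test_that("band-difference table reproduces printed-style percentages", {
  counts <- c(257L, 134L, 12L, 9L)
  pairs <- data.frame(rating_c1 = rep(1L, sum(counts)),
                      rating_c2 = rep(c(1L, 2L, 3L, 4L), counts))
  bd <- band_difference_table(pairs)
  expect_identical(unname(bd$counts), counts)
  expect_equal(unname(bd$percentages), c(62.4, 32.5, 2.9, 2.2))
  expect_equal(bd$within_one_pct, 94.9)
  expect_lt(abs(sum(bd$percentages) - 100), 0.2)
  same <- band_difference_table(data.frame(rating_c1 = rep(2L, 5),
                                           rating_c2 = rep(2L, 5)))
  expect_equal(unname(same$percentages), c(100, 0, 0, 0))
})

test_that("band-difference percentages sum to 100 within rounding", {
  set.seed(41)
  for (rep in 1:10) {
    pairs <- generate_rating_pairs(sample(50:400, 1), seed = rep)
    bd <- band_difference_table(pairs)
    expect_lt(abs(sum(bd$percentages) - 100), 0.2)
    expect_identical(sum(bd$counts), bd$n)
  }
})

test_that("match percentages recover planted outcome rates", {
  est <- function(id, kind, lo = NA, hi = NA) {
    structure(list(clip_id = id, kind = kind, low_band = lo, high_band = hi,
                   support = 0.9, n_valid_frames = 100L),
              class = "clip_estimate")
  }
  estimates <- list(
    est("a", "single", 4L, 4L),  # match (rating 4)
    est("b", "single", 2L, 2L),  # miss  (rating 3)
    est("c", "range", 3L, 4L),   # contains rating 3 -> match
    est("d", "range", 1L, 3L),   # rating 4 outside -> miss
    est("e", "none"))
  ratings <- data.frame(clip_id = c("a", "b", "c", "d", "e"),
                        band = c(4L, 3L, 3L, 4L, 1L))
  mp <- match_percentages(estimates, ratings)
  expect_equal(mp$pct_single, 40)
  expect_equal(mp$pct_range2, 20)
  expect_equal(mp$pct_range3, 20)
  expect_equal(mp$pct_none, 20)
  expect_equal(mp$exact_match_pct, 50)
  expect_equal(mp$range_match_pct, 50)
  expect_error(match_percentages(estimates[1], data.frame(clip_id = "z", band = 1L)),
               "clip id")
})

test_that("the assembled agreement report is internally consistent", {
  pairs <- generate_rating_pairs(40, seed = 3)
  estimates <- lapply(seq_len(40), function(i) {
    structure(list(clip_id = pairs$clip_id[i], kind = "single",
                   low_band = pairs$rating_c1[i], high_band = pairs$rating_c1[i],
                   support = 1, n_valid_frames = 50L),
              class = "clip_estimate")
  })
  rep <- agreement_report(pairs, estimates)
  expect_identical(rep$n, 40L)
  expect_identical(sum(rep$crosstab_c1_c2), 40L)
  # estimates equal C1's ratings, so C1-vs-algorithm is perfectly concordant
  expect_equal(rep$gamma_c1_vs_algo$gamma, 1)
  expect_equal(rep$match_c1$exact_match_pct, 100)
  expect_identical(rep$band_difference_c1_c2$n, 40L)
})
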