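# Clip scoring and reduction to single-band / range / no-estimate outputs.

model64 <- small_model(per_band = 8L, size = 64L, seed = 1L)
# full-size model: the generator's blur ladder separates cleanly at 256 px
model_full <- small_model(per_band = 12L, size = 256L, seed = 1L, density = 6e-4)

test_that("a clip of identical frames gets identical scores and bands", {
  f <- small_phantom(seed = 4, size = 64)
  series <- score_clip(frame_sequence(list(f, f, f)), model64)
  expect_equal(length(unique(series$score)), 1L)
  expect_equal(length(unique(series$band)), 1L)
  expect_identical(series$frame_index, 0:2)
})

test_that("an all-good synthetic clip is classified good frame by frame", {
  clip <- generate_clip(rep(4L, 6), spec_defaults = phantom_spec(4, seed = 30))
  series <- score_clip(clip, model_full)
  expect_true(all(series$band == 4L))
  expect_false(any(series$out_of_body))
  est <- estimate_clip_band(series, min_valid_frames = 5L)
  expect_identical(est$kind, "single")
  expect_identical(est$low_band, 4L)
})

test_that("a 500-frame clip at 25 fps spans 20 seconds of timestamps", {
  f <- small_phantom(seed = 2, size = 32)
  series <- score_clip(frame_sequence(rep(list(f), 500), fps = 25), model64)
  expect_identical(nrow(series), 500L)
  expect_identical(series$frame_index, 0:499)
  expect_equal(max(series$timestamp) - min(series$timestamp) + 1 / 25, 20)
})

test_that("out-of-body frames are flagged and excluded from estimation", {
  lumen <- small_phantom(seed = 11, size = 64, band = 4L)
  oob <- generate_out_of_body_frame(5, 64, 64)
  series <- score_clip(frame_sequence(c(rep(list(lumen), 30), rep(list(oob), 10))),
                       model64)
  expect_identical(sum(series$out_of_body), 10L)
  est <- estimate_clip_band(series, min_valid_frames = 25L)
  expect_identical(est$n_valid_frames, 30L)
})

test_that("clip reduction follows the shortest-qualifying-interval rule", {
  # all frames one band -> single estimate of that band
  est <- estimate_clip_band(series_from_bands(rep(4L, 50)))
  expect_identical(est[c("kind", "low_band", "high_band")],
                   list(kind = "single", low_band = 4L, high_band = 4L))
  expect_equal(est$support, 1)
  # 50/50 split over bands 3 and 4 at min_support 0.9 -> "almost good to good"
  est <- estimate_clip_band(series_from_bands(rep(c(3L, 4L), 25)),
                            min_support = 0.9)
  expect_identical(est$kind, "range")
  expect_identical(c(est$low_band, est$high_band), c(3L, 4L))
  # too few valid frames -> no estimate
  est <- estimate_clip_band(series_from_bands(rep(4L, 10)),
                            min_valid_frames = 25L)
  expect_identical(est$kind, "none")
  # bands spread over the full 1..4 span: no interval of at most three
  # bands reaches the support -> no estimate
  est <- estimate_clip_band(series_from_bands(rep(1:4, each = 25)),
                            min_support = 0.8)
  expect_identical(est$kind, "none")
  expect_identical(est$n_valid_frames, 100L)
})

test_that("reduction depends only on the multiset of valid bands", {
  set.seed(8)
  bands <- sample(1:4, 60, replace = TRUE, prob = c(0.1, 0.2, 0.5, 0.2))
  a <- estimate_clip_band(series_from_bands(bands))
  b <- estimate_clip_band(series_from_bands(sample(bands)))
  expect_identical(a[c("kind", "low_band", "high_band", "support")],
                   b[c("kind", "low_band", "high_band", "support")])
})

test_that("raising min_support never narrows the returned interval", {
  set.seed(15)
  for (rep in 1:10) {
    bands <- sample(1:4, 40, replace = TRUE)
    widths <- vapply(c(0.3, 0.5, 0.7, 0.8, 0.9, 1.0), function(ms) {
      est <- estimate_clip_band(series_from_bands(bands), min_support = ms)
      if (est$kind == "none") 4L else est$high_band - est$low_band + 1L
    }, integer(1))
    expect_true(all(diff(widths) >= 0))
  }
})

test_that("estimate kinds partition outcomes consistently", {
  set.seed(23)
  for (rep in 1:20) {
    bands <- sample(1:4, sample(5:60, 1), replace = TRUE)
    est <- estimate_clip_band(series_from_bands(bands), min_valid_frames = 10L)
    expect_true(est$kind %in% c("single", "range", "none"))
    if (est$kind == "single") expect_identical(est$low_band, est$high_band)
    if (est$kind == "range") expect_lt(est$low_band, est$high_band)
    if (est$kind == "none") {
      expect_true(is.na(est$low_band) && is.na(est$high_band))
    }
  }
})

test_that("with full support a one-band clip returns exactly that band", {
  for (b in 1:4) {
    est <- estimate_clip_band(series_from_bands(rep(b, 30)), min_support = 1.0)
    expect_identical(est$kind, "single")
    expect_identical(est$low_band, as.integer(b))
  }
})

test_that("clip scoring validates its inputs", {
  expect_error(score_clip(list(), model64), "non-empty")
  s <- series_from_bands(rep(2L, 30))
  expect_error(estimate_clip_band(s, min_support = 0), "min_support")
  expect_error(estimate_clip_band(s, min_support = 1.5), "min_support")
  expect_error(estimate_clip_band(data.frame(x = 1)), "band")
})
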