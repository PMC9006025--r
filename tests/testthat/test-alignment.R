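test_that("stream merging resamples and z-scores onto a common clock", {
  t1 <- seq(0, 4, by = 1 / 25)
  t2 <- seq(0, 4, by = 1 / 100)
  v1 <- sin(2 * pi * 2 * t1)
  v2 <- sin(2 * pi * 2 * t2)
  pair <- merge_streams(data.frame(time = t1, value = v1),
                        data.frame(time = t2, value = v2), rate = 32)
  expect_equal(attr(pair, "rate"), 32)
  # x was linearly interpolated from the 25 Hz grid: check pointwise
  # against an oracle interpolation before z-scoring
  raw <- approx(t1, v1, xout = pair$time)$y
  expect_equal(pair$x, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
  # identical series merge identically
  pair2 <- merge_streams(data.frame(time = t1, value = v1),
                         data.frame(time = t1, value = v1), rate = 32)
  expect_equal(pair2$x, pair2$y)
  # constant stream flagged degenerate
  pc <- merge_streams(data.frame(time = t1, value = v1),
                      data.frame(time = t1, value = rep(1, length(t1))),
                      rate = 32)
  expect_true(attr(pc, "degenerate"))
  # coverage gap is an error
  expect_error(
    merge_streams(data.frame(time = t1, value = v1),
                  data.frame(time = t2, value = v2),
                  window = c(0, 10)), "coverage gap")
})

test_that("the scale grid spans 125-500 ms periods exactly", {
  sc <- wavelet_scales(c(2, 8))
  expect_equal(min(sc$period), 0.125)
  expect_equal(max(sc$period), 0.5)
  expect_equal(range(sc$frequency), c(2, 8))
})

test_that("self-coherence is 1 up to smoothing error", {
  set.seed(16)
  t <- seq(0, 8, by = 1 / 64)
  x <- sin(2 * pi * 4 * t) + 0.2 * rnorm(length(t))
  pair <- merge_streams(data.frame(time = t, value = x),
                        data.frame(time = t, value = x), rate = 64)
  cw <- cross_wavelet(pair)
  expect_gt(min(cw$coherence), 0.99)
})

test_that("a 50 ms offset at 4 Hz appears as the analytic phase angle", {
  pair <- lagged_pair(0.05, noise = 0)
  cw <- cross_wavelet(pair)
  j <- which.min(abs(cw$scales$frequency - 4))
  mid <- round(length(cw$time) * c(0.3, 0.7))
  ph <- mean(cw$phase[mid[1]:mid[2], j])
  expect_equal(ph, 2 * pi * 4 * 0.05, tolerance = 0.05)  # 0.4 pi rad
})

test_that("independent noise is far less coherent than coupled sinusoids", {
  set.seed(17)
  t <- seq(0, 8, by = 1 / 32)
  mean_coh <- function(a, b) {
    p <- merge_streams(data.frame(time = t, value = a),
                       data.frame(time = t, value = b), rate = 32)
    mean(cross_wavelet(p)$coherence)
  }
  coh_noise <- mean(replicate(10, mean_coh(rnorm(length(t)),
                                           rnorm(length(t)))))
  coh_sine <- mean_coh(sin(2 * pi * 4 * t) + 0.05 * rnorm(length(t)),
                       sin(2 * pi * 4 * t) + 0.05 * rnorm(length(t)))
  expect_gt(coh_sine, 0.8)
  expect_lt(coh_noise, 0.75)
  expect_gt(coh_sine - coh_noise, 0.25)
})

test_that("surrogate masks are deterministic under a fixed seed", {
  pair <- lagged_pair(0.05)
  m1 <- significance_mask(pair, n_surrogates = 100, seed = 5)
  m2 <- significance_mask(pair, n_surrogates = 100, seed = 5)
  expect_identical(m1$mask, m2$mask)
  expect_identical(m1$p, m2$p)
  # strongly coupled sinusoids: cells at the driving 4 Hz scale are
  # overwhelmingly significant
  j4 <- which.min(abs(m1$cw$scales$frequency - 4))
  expect_gt(mean(m1$mask[, j4]), 0.8)
})

test_that("recovered phase asynchrony shifts with an injected delay", {
  for (lag in c(0.03, 0.08)) {
    pair <- lagged_pair(lag, seed = 18)
    msk <- significance_mask(pair, n_surrogates = 100, seed = 2)
    s <- summarize_alignment(msk)
    expect_equal(s$phase_asynchrony_ms, lag * 1000,
                 tolerance = 0.1 * lag * 1000 + 2)
    expect_true(s$coherence > 0.9 && s$coherence <= 1)
    expect_lt(abs(s$phase_asynchrony_ms), 500 / 2)  # half the 2 Hz period
  }
})

test_that("summaries average only significant cells; empty masks drop out", {
  pair <- lagged_pair(0.05)
  msk <- significance_mask(pair, n_surrogates = 100, seed = 5)
  s <- summarize_alignment(msk, event_id = "e1")
  expect_equal(s$coherence, mean(msk$cw$coherence[msk$mask]))
  expect_equal(s$n_significant_cells, sum(msk$mask))
  # force an empty mask -> no row
  msk0 <- msk
  msk0$mask[] <- FALSE
  expect_null(summarize_alignment(msk0))
})

test_that("windows too short for the band lower edge are truncated", {
  t <- seq(0, 0.8, by = 1 / 64)        # < 2 cycles of 2 Hz
  x <- sin(2 * pi * 6 * t)
  pair <- merge_streams(data.frame(time = t, value = x + 0.01),
                        data.frame(time = t, value = x), rate = 64)
  expect_warning(cw <- cross_wavelet(pair), "truncated")
  expect_gt(min(cw$scales$frequency), 2)
})
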