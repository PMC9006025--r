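test_that("adjusted alpha reproduces its closed form and limits", {
  expect_equal(adjusted_alpha(1, 0.9), 0.05)
  expect_equal(adjusted_alpha(4, 0, digits = NULL), 0.05 / 4)
  expect_equal(adjusted_alpha(7, 1), 0.05)
  expect_error(adjusted_alpha(3, 1.2), "r_bar")
  expect_error(adjusted_alpha(0, 0.5), "positive integer")
})

test_that("adjusted alpha is monotone in k and in r_bar", {
  ks <- 1:12
  a_k <- vapply(ks, function(k) adjusted_alpha(k, 0.3, digits = NULL),
                numeric(1))
  expect_true(all(diff(a_k) < 0))
  rs <- seq(0, 1, by = 0.1)
  a_r <- vapply(rs, function(r) adjusted_alpha(5, r, digits = NULL),
                numeric(1))
  expect_true(all(diff(a_r) > 0))
})

test_that("likelihood-ratio pseudo-R2 follows its closed form", {
  set.seed(20)
  d <- data.frame(y = rnorm(100), blur_grade = rep(1:10, 10),
                  participant_id = rep(sprintf("p%d", 1:10), each = 10))
  f0 <- gesturekit:::fit_mixed("y ~ 1 + (1 | participant_id)", d)
  # null vs itself: zero improvement
  r0 <- pseudo_r2(f0, f0)
  expect_equal(r0$delta_r2c, 0)
  expect_equal(r0$r2lr, 0)
  # LR = 10 on n = 100 -> 1 - exp(-0.1)
  expect_equal(1 - exp(-10 / 100), 0.09516258, tolerance = 1e-7)
  f2 <- gesturekit:::fit_mixed(
    "y ~ poly(blur_grade, 2) + (1 | participant_id)", d)
  lr <- as.numeric(2 * (logLik(f2) - logLik(f0)))
  expect_equal(pseudo_r2(f2, f0)$r2lr, 1 - exp(-lr / 100),
               tolerance = 1e-9)
  r2 <- pseudo_r2(f2, f0)
  expect_true(r2$r2c >= 0 && r2$r2c <= 1)
})

test_that("conditional R2 recovers known variance shares", {
  set.seed(21)
  n_g <- 40; n_per <- 50
  g <- rep(sprintf("p%02d", 1:n_g), each = n_per)
  u <- rnorm(n_g, 0, sqrt(2))[match(g, unique(g))]
  x <- rnorm(n_g * n_per)
  y <- 1 * x + u + rnorm(n_g * n_per, 0, 1)
  d <- data.frame(y = y, x = x, participant_id = g)
  full <- gesturekit:::fit_mixed("y ~ x + (1 | participant_id)", d)
  null <- gesturekit:::fit_mixed("y ~ 1 + (1 | participant_id)", d)
  r2 <- pseudo_r2(full, null)
  # truth: (1 + 2) / (1 + 2 + 1) = 0.75
  expect_equal(r2$r2c, 0.75, tolerance = 0.05)
})

test_that("random-effects build-up keeps gesture type when it matters", {
  set.seed(22)
  cfg <- generator_config(re_sd = c(dyad = 0.3, participant = 0.5,
                                    gesture_type = 0.8))
  d <- simulate_feature_table(cfg, n_dyads = 10, seed = 5)
  d$y <- log(d$size_px2)
  re <- build_random_effects(d, "y")
  expect_true(re$gesture_type_kept)
  expect_match(re$formula, "gesture_type")
  expect_error(build_random_effects(d[d$participant_id == "d01p1", ],
                                    "y"), "2 participants")
})

test_that("degenerate grouping falls back to a global participant factor", {
  set.seed(23)
  # one participant per dyad label makes dyad/participant redundant:
  # the nested fit is singular and the flat structure is substituted
  d <- data.frame(
    y = rnorm(200),
    dyad_id = rep(sprintf("d%02d", 1:20), each = 10),
    participant_id = rep(sprintf("d%02dp1", 1:20), each = 10),
    blur_grade = rep(1:10, 20))
  re <- suppressWarnings(build_random_effects(d, "y"))
  expect_false(re$nested_ok)
  expect_equal(re$formula, "(1 | participant_id)")
})

test_that("the polynomial ladder detects a generated inverted-U effect", {
  cfg <- generator_config()
  d <- simulate_feature_table(cfg, seed = 3)
  d$y <- log(d$size_px2)
  lad <- quiet_ladder(d, "y", random = "(1 | participant_id) + (1 | gesture_type)")
  expect_true(lad$converged)
  expect_true(lad$significant)
  expect_lt(lad$p, 0.01)
  expect_lt(lad$quad_vs_linear$p, 0.01)
  # the inverted-U has a negative orthogonal quadratic coefficient
  expect_lt(lad$coefficients["poly(blur_grade, 2)2", "Estimate"], 0)
  expect_true(lad$r2c >= 0 && lad$r2c <= 1)
  expect_gte(lad$delta_r2c, 0)
})

test_that("a linear-only truth does not pass the quadratic-vs-linear gate", {
  set.seed(24)
  d <- simulate_feature_table(generator_config(), effect_amp = 0,
                              n_dyads = 10, seed = 11)
  d$y <- log(d$size_px2) + 0.08 * d$blur_grade   # pure linear trend
  lad <- quiet_ladder(d, "y", random = "(1 | participant_id)")
  expect_lt(lad$p, 0.05)                  # blur matters overall
  expect_gt(lad$quad_vs_linear$p, 0.05)   # but not quadratically
  expect_false(lad$significant)
})

test_that("the modality ladder recovers an injected acoustic offset", {
  cfg <- generator_config(n_dyads = 4L, n_grades = 5L,
                          grade_duration_s = 120)
  tabs <- list()
  for (d in 1:4) for (p in 1:2) {
    pid <- sprintf("d%02dp%d", d, p)
    ses <- generate_session(cfg, sprintf("d%02d", d), pid,
                            seed = 400 + d * 10 + p,
                            streams = c("events", "acoustics"))
    tabs[[pid]] <- acoustics_by_grade(ses$acoustics, ses$events,
                                      ses$schedule, pid,
                                      sprintf("d%02d", d))
  }
  tab <- do.call(rbind, tabs)
  ml <- modality_interaction_ladder(tab, "mean_intensity_db")
  expect_true(ml$significant["modality"])
  expect_equal(ml$modality_coef, 4.36, tolerance = 0.5)
  mf <- modality_interaction_ladder(tab, "mean_f0_hz")
  expect_equal(mf$modality_coef, 3.71, tolerance = 1.0)
})

test_that("kinetic confound test separates driven from independent acoustics", {
  set.seed(25)
  n_p <- 20
  d <- expand.grid(participant_id = sprintf("p%02d", 1:n_p),
                   blur_grade = 1:10, rep = 1:4)
  d$dyad_id <- sub("p", "d", substr(d$participant_id, 1, 3))
  d$peak_velocity <- exp(rnorm(nrow(d), 6, 0.5))
  base <- rnorm(n_p, 60, 2)[match(d$participant_id,
                                  unique(d$participant_id))]
  # intensity independent of kinematics
  d$indep <- base + rnorm(nrow(d), 0, 1)
  # intensity driven by peak velocity
  d$driven <- base + 0.004 * d$peak_velocity + rnorm(nrow(d), 0, 1)
  r_ind <- suppressWarnings(kinetic_confound_test(d, "indep", "peak_velocity"))
  r_drv <- suppressWarnings(kinetic_confound_test(d, "driven", "peak_velocity"))
  expect_false(r_ind$significant)
  expect_true(r_drv$significant)
  expect_equal(unname(r_drv$coef["Estimate"]), 0.004, tolerance = 0.5)
  d$const <- 1
  expect_error(kinetic_confound_test(d, "indep", "const"), "degenerate")
})

test_that("non-converging ladders are flagged, not reported", {
  # two observations cannot support the quadratic fit: the result is a
  # flagged non-converged object with no p value, not an error
  d <- data.frame(y = c(1, 2), blur_grade = c(1, 2),
                  participant_id = c("a", "b"))
  lad <- suppressWarnings(suppressMessages(
    ladder_test(d, "y", random = "(1 | participant_id)")))
  expect_false(lad$converged)
  expect_true(is.na(lad$p))
})
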