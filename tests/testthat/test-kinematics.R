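test_that("velocity profile matches closed forms", {
  # static hands -> all-zero profile
  prof0 <- velocity_profile(static_traj(50))
  expect_equal(max(prof0$speed), 0, tolerance = 1e-9)
  # uniform 2 px/frame at 25 fps -> 50 px/s everywhere
  prof1 <- velocity_profile(hand_traj(2 * (0:99)))
  mid <- 20:80
  expect_equal(prof1$speed[mid], rep(50, length(mid)), tolerance = 0.01)
  # sinusoid at 100 fps: max speed ~ 2 pi f A within 2%
  fps <- 100; f <- 2; A <- 50
  t <- (0:499) / fps
  prof2 <- velocity_profile(hand_traj(A * sin(2 * pi * f * t), fps = fps))
  expect_equal(max(prof2$speed), 2 * pi * f * A, tolerance = 0.02)
})

test_that("event windows outside the trajectory are rejected", {
  tr <- hand_traj(0 * (0:49))
  expect_error(velocity_profile(tr, c(1, 5)), "outside")
})

test_that("peak velocity is the profile maximum", {
  expect_equal(peak_velocity(data.frame(speed = rep(50, 10))), 50)
  expect_equal(peak_velocity(data.frame(speed = c(0, 10, 80, 10))), 80)
  set.seed(8)
  v <- abs(rnorm(1000, 100, 40))
  expect_equal(peak_velocity(data.frame(speed = v)), max(v))
})

test_that("submovement counts recover the generating pulse count", {
  for (k in 1:5) {
    fx <- gesture_fixture(k)
    sm <- detect_submovements(velocity_profile(fx$traj))
    expect_equal(sm$count, k)
  }
  # all-zero profile -> none
  sm0 <- detect_submovements(velocity_profile(static_traj(60)))
  expect_equal(sm0$count, 0L)
})

test_that("pulses fused above the valley fraction count once", {
  # craft speed profiles with two bells and a controlled valley: fused
  # when the valley stays at or above half the smaller peak
  fps <- 50
  t <- seq(0, 2, by = 1 / fps)
  bell <- function(mu, a) a * exp(-(t - mu)^2 / (2 * 0.08^2))
  mk_prof <- function(v) {
    p <- data.frame(time = t, speed_right = v, speed_left = v, speed = v)
    attr(p, "fps") <- fps
    class(p) <- c("velocity_profile", "data.frame")
    p
  }
  v_fused <- bell(0.8, 100) + bell(1.0, 100)    # valley ~ 0.9 peak
  v_split <- bell(0.6, 100) + bell(1.4, 100)    # valley ~ 0
  expect_equal(detect_submovements(mk_prof(v_fused))$count, 1L)
  expect_equal(detect_submovements(mk_prof(v_split))$count, 2L)
  # out-and-back pulses always pass through zero speed: two pulses
  # remain separable even with a minimal gap
  fx_sep <- gesture_fixture(2, gap_s = 0.5)
  expect_equal(detect_submovements(velocity_profile(fx_sep$traj))$count,
               2L)
})

test_that("hold-time measures within-gesture stillness only", {
  # continuous motion -> 0
  fx1 <- gesture_fixture(1)
  expect_equal(hold_time(velocity_profile(fx1$traj)), 0)
  # two pulses separated by 0.5 s -> 0.5 s within one frame per boundary
  fx2 <- gesture_fixture(2, gap_s = 0.5)
  ht <- hold_time(velocity_profile(fx2$traj))
  expect_lt(abs(ht - 0.5), 2 / 25)
  # stillness only before onset is excluded
  sg <- synth_gesture(1, 25, 0.4, 0.5, 120, 0.1)
  disp <- c(rep(0, 50), sg$disp)          # 2 s pre-gesture rest
  ht0 <- hold_time(velocity_profile(hand_traj(disp)))
  expect_equal(ht0, 0)
})

test_that("hold plus movement time stays within the event duration", {
  for (k in 2:4) {
    fx <- gesture_fixture(k)
    prof <- velocity_profile(fx$traj)
    sm <- detect_submovements(prof)
    ht <- hold_time(prof, sm)
    move_t <- (sm$offset - sm$onset) - ht
    expect_lte(ht + move_t, fx$duration_s + 1e-9)
    expect_gte(ht, 0)
  }
})

test_that("gesture size is the union bounding box of body-relative hands", {
  # static hands -> 0
  expect_equal(gesture_size(static_traj(30))$size_px2, 0)
  # hand tracing a 100 x 50 rectangle: both hands moved together, so
  # the union spans hand separation + 100 in x, 50 in y
  n <- 101
  tr <- static_traj(n)
  j4 <- which(tr$keypoint_ids == 4L); j7 <- which(tr$keypoint_ids == 7L)
  px <- c(seq(0, 100, length.out = 26), rep(100, 25),
          seq(100, 0, length.out = 26), rep(0, 24))
  py <- c(rep(0, 26), seq(0, 50, length.out = 25), rep(50, 26),
          seq(50, 0, length.out = 24))
  for (j in c(j4, j7)) {
    tr$x[, j] <- tr$x[, j] + px
    tr$y[, j] <- tr$y[, j] + py
  }
  sz <- gesture_size(tr)
  expect_equal(sz$y_extent, 50)
  expect_equal(sz$x_extent, 160 + 100)   # rest separation + traced width
  # single-hand version gives exactly 100 x 50
  tr1 <- static_traj(n)
  tr1$x[, j4] <- tr1$x[, j7]             # overlap hands at one rest point
  tr1$y[, j4] <- tr1$y[, j7]
  tr1$x[, j4] <- tr1$x[, j4] + px; tr1$y[, j4] <- tr1$y[, j4] + py
  tr1$x[, j7] <- tr1$x[, j7] + px; tr1$y[, j7] <- tr1$y[, j7] + py
  expect_equal(gesture_size(tr1)$size_px2, 5000)
  # random cloud equals brute-force bounding box
  set.seed(9)
  tr2 <- static_traj(200)
  dx4 <- rnorm(200, 0, 30); dy4 <- rnorm(200, 0, 20)
  dx7 <- rnorm(200, 0, 30); dy7 <- rnorm(200, 0, 20)
  tr2$x[, j4] <- tr2$x[, j4] + dx4; tr2$y[, j4] <- tr2$y[, j4] + dy4
  tr2$x[, j7] <- tr2$x[, j7] + dx7; tr2$y[, j7] <- tr2$y[, j7] + dy7
  xs <- c(tr2$x[, j4], tr2$x[, j7]) - rest_xy()$`1`[1]
  ys <- c(tr2$y[, j4], tr2$y[, j7]) - rest_xy()$`1`[2]
  expect_equal(gesture_size(tr2)$size_px2,
               diff(range(xs)) * diff(range(ys)))
})

test_that("gesture depth tracks hands-to-hip distance in the side view", {
  n <- 101                               # odd: the sine peak is sampled
  ramp <- sin(pi * (0:(n - 1)) / (n - 1))
  mk_side <- function(handx) {
    keypoint_trajectory(cbind(handx, handx, rep(860, n)),
                        cbind(rep(700, n), rep(700, n), rep(760, n)),
                        matrix(1, n, 3), 25, "side", c(4L, 7L, 8L))
  }
  # hands at the hip plane -> ~0
  expect_equal(gesture_depth(mk_side(rep(860, n))), 0)
  # forward reach of 120 px
  expect_equal(gesture_depth(mk_side(860 + 120 * ramp)), 120)
  # torso lean contributing 30 px plus a 60 px reach -> ~90
  expect_equal(gesture_depth(mk_side(860 + 30 * ramp + 60 * ramp)), 90)
  # missing side view -> absent, not zero
  d <- gesture_depth(NULL)
  expect_true(is.na(d))
  expect_true(isTRUE(attr(d, "absent")))
})

test_that("nPVI matches its formula and is order sensitive", {
  expect_equal(npvi(c(5, 5, 5, 5)), 0)
  expect_equal(npvi(c(100, 200)), 100 * (100 / 150), tolerance = 1e-9)
  expect_equal(round(npvi(c(100, 200)), 2), 66.67)
  expect_false(isTRUE(all.equal(npvi(c(100, 200, 100)),
                                npvi(c(200, 100, 100)))))
  expect_warning(v <- npvi(100), "fewer than 2")
  expect_true(is.na(v))
})

test_that("gesture rate counts per grade in gestures per minute", {
  sch <- blur_schedule(2, 240)
  ev <- gesture_events(seq(1, 230, length.out = 8),
                       seq(1, 230, length.out = 8) + 1.5,
                       "interactive", "p1", "d1", schedule = sch)
  r <- gesture_rate(ev, sch)
  expect_equal(r$rate_per_min[r$blur_grade == 1], 2.0)
  expect_equal(r$rate_per_min[r$blur_grade == 2], 0)
  # Poisson sessions: mean recovered within sampling error
  set.seed(10)
  sch1 <- blur_schedule(1, 600)
  rates <- replicate(40, {
    n <- rpois(1, 3 * 10)
    if (n == 0) return(0)
    st <- sort(runif(n, 0, 598))
    e <- suppressWarnings(gesture_events(st, st + 1, "pragmatic", "p1",
                                         "d1", schedule = sch1))
    gesture_rate(e, sch1)$rate_per_min
  })
  expect_equal(mean(rates), 3, tolerance = 0.1)
})

test_that("VIF screen flags collinear features and matches car::vif", {
  set.seed(12)
  n <- 300
  X <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  v1 <- vif_screen(X)
  expect_true(all(v1$vif < 1.2))
  expect_false(any(v1$flagged))
  # cross-check against car::vif on an lm
  X$y <- rnorm(n)
  cv <- car::vif(lm(y ~ a + b + c, data = X))
  expect_equal(v1$vif, unname(cv[c("a", "b", "c")]), tolerance = 1e-8)
  # duplicated column -> flagged (infinite VIF)
  X2 <- data.frame(a = X$a, b = X$b, dup = X$a)
  v2 <- vif_screen(X2)
  expect_true(v2$flagged[v2$feature == "dup"])
  # near-collinear sum -> far above threshold
  X3 <- data.frame(a = X$a, b = X$b, s = X$a + X$b + rnorm(n, 0, 0.01))
  v3 <- vif_screen(X3)
  expect_gt(v3$vif[v3$feature == "s"], 100)
})

test_that("kinematic features scale correctly with pixel rescaling", {
  fx <- gesture_fixture(3)
  c_scale <- 2.5
  tr2 <- fx$traj
  tr2$x <- tr2$x * c_scale; tr2$y <- tr2$y * c_scale
  p1 <- velocity_profile(fx$traj); p2 <- velocity_profile(tr2)
  expect_equal(peak_velocity(p2), c_scale * peak_velocity(p1),
               tolerance = 1e-9)
  expect_equal(detect_submovements(p2)$count,
               detect_submovements(p1)$count)
  expect_equal(hold_time(p2), hold_time(p1))
  expect_equal(gesture_size(tr2)$size_px2,
               c_scale^2 * gesture_size(fx$traj)$size_px2,
               tolerance = 1e-9)
  expect_equal(mcneillian_space(tr2), mcneillian_space(fx$traj))
})
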