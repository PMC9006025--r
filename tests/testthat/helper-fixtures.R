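# Fixtures built in code: small trajectories with known kinematics.

BODY_IDS <- c(0L, 1L, 2L, 4L, 5L, 7L, 8L)

# rest positions matching the generator's skeleton
rest_xy <- function() {
  list(`0` = c(960, 300), `1` = c(960, 420), `2` = c(870, 430),
       `4` = c(880, 700), `5` = c(1050, 430), `7` = c(1040, 700),
       `8` = c(960, 760))
}

# trajectory with all keypoints static at rest
static_traj <- function(n = 50, fps = 25, ids = BODY_IDS) {
  r <- rest_xy()
  X <- sapply(ids, function(i) rep(r[[as.character(i)]][1], n))
  Y <- sapply(ids, function(i) rep(r[[as.character(i)]][2], n))
  keypoint_trajectory(X, Y, matrix(1, n, length(ids)), fps, "front", ids)
}

# trajectory whose hands follow a supplied displacement series (px) at
# 45 degrees (up and right), both hands together; optional noise
hand_traj <- function(disp, fps = 25, noise = 0, extra_offset = c(0, 0)) {
  n <- length(disp)
  r <- rest_xy()
  dxy <- disp / sqrt(2)
  X <- sapply(BODY_IDS, function(i) rep(r[[as.character(i)]][1], n))
  Y <- sapply(BODY_IDS, function(i) rep(r[[as.character(i)]][2], n))
  X[, BODY_IDS == 4] <- X[, BODY_IDS == 4] + dxy
  X[, BODY_IDS == 7] <- X[, BODY_IDS == 7] + dxy
  Y[, BODY_IDS == 4] <- Y[, BODY_IDS == 4] - dxy
  Y[, BODY_IDS == 7] <- Y[, BODY_IDS == 7] - dxy
  X <- X + extra_offset[1]; Y <- Y + extra_offset[2]
  if (noise > 0) {
    X <- X + rnorm(length(X), 0, noise)
    Y <- Y + rnorm(length(Y), 0, noise)
  }
  keypoint_trajectory(X, Y, matrix(1, n, length(BODY_IDS)), fps, "front",
                      BODY_IDS)
}

# gesture fixture: k min-jerk pulses realized as a trajectory
gesture_fixture <- function(k, fps = 25, pulse_s = 0.4, gap_s = 0.5,
                            amp = 120, margin_s = 0.1, noise = 0) {
  sg <- synth_gesture(k, fps, pulse_s, gap_s, amp, margin_s)
  list(traj = hand_traj(sg$disp, fps, noise), truth = sg$truth,
       duration_s = sg$duration_s)
}

# sinusoid pair with a fixed time lag (x leads y by lag_s)
lagged_pair <- function(lag_s, f = 4, dur = 8, rate = 64, noise = 0.05,
                        seed = 1) {
  set.seed(seed)
  t <- seq(0, dur, by = 1 / rate)
  x <- sin(2 * pi * f * t) + noise * rnorm(length(t))
  y <- sin(2 * pi * f * (t - lag_s)) + noise * rnorm(length(t))
  merge_streams(data.frame(time = t, value = x),
                data.frame(time = t, value = y), rate = rate)
}

quiet_ladder <- function(...) suppressWarnings(suppressMessages(
  ladder_test(...)))
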