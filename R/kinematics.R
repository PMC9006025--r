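# Signal-level gesture kinematics, computed from the hand keypoints
# (ids 4 and 7). Except where noted, features use the two-hand average
# trajectory; size uses the union of both hands and McNeillian space the
# more extreme hand.

smooth_positions <- function(pos, fps, cutoff_hz = 10) {
  wn <- cutoff_hz / (fps / 2)
  if (wn >= 1) return(pos)
  bf <- signal::butter(3, wn, type = "low")
  n <- nrow(pos)
  # reflect-pad before filtfilt to suppress its edge transients
  pad <- min(n - 1L, max(12L, ceiling(3 / wn)))
  apply(pos, 2, function(v) {
    if (anyNA(v)) {
      ok <- !is.na(v)
      if (sum(ok) < 10) return(v)
      v[!ok] <- approx(which(ok), v[ok], xout = which(!ok), rule = 2)$y
    }
    # demean and endpoint-pad: filtfilt sets no initial state, so a DC
    # offset (pixel coordinates are large) otherwise rings at Nyquist
    mu <- mean(v)
    vp <- c(rep(v[1], pad), v, rep(v[n], pad)) - mu
    signal::filtfilt(bf, vp)[(pad + 1):(pad + n)] + mu
  })
}

speed_from_positions <- function(pos, fps) {
  d <- sqrt(diff(pos[, 1])^2 + diff(pos[, 2])^2) * fps
  c(d[1], d)  # same length as input; first sample repeated
}

#' Hand velocity profile for a gesture event
#'
#' Frame-by-frame hand speed (px/s): positions are low-pass filtered
#' (3rd-order Butterworth, default 10 Hz cut-off) before differencing, and
#' speed is the Euclidean displacement per frame times the frame rate.
#' Returned for each hand and for the two-hand average trajectory.
#'
#' @param traj a front-view `keypoint_trajectory` containing keypoints 4
#'   and 7.
#' @param event one-row slice of a `gesture_events` table, or
#'   `c(start_s, end_s)`; `NULL` uses the whole trajectory.
#' @param cutoff_hz smoothing cut-off in Hz (applied to positions).
#' @return data.frame of class `velocity_profile`: `time`, `speed_right`,
#'   `speed_left`, `speed` (two-hand average trajectory), plus attributes
#'   `fps`.
#' @export
velocity_profile <- function(traj, event = NULL, cutoff_hz = 10) {
  window <- event_window(event)
  if (!is.null(window) &&
      (window[1] < 0 || window[2] > (traj$frames - 1) / traj$fps + 1e-9))
    stop("event outside trajectory")
  rows <- window_rows(traj, window)
  rh <- kp_xy(traj, KP_RHAND)[rows, , drop = FALSE]
  lh <- kp_xy(traj, KP_LHAND)[rows, , drop = FALSE]
  rh <- smooth_positions(rh, traj$fps, cutoff_hz)
  lh <- smooth_positions(lh, traj$fps, cutoff_hz)
  avg <- (rh + lh) / 2
  out <- data.frame(
    time = traj$times[rows],
    speed_right = speed_from_positions(rh, traj$fps),
    speed_left = speed_from_positions(lh, traj$fps),
    speed = speed_from_positions(avg, traj$fps))
  attr(out, "fps") <- traj$fps
  class(out) <- c("velocity_profile", "data.frame")
  out
}

event_window <- function(event) {
  if (is.null(event)) return(NULL)
  if (is.data.frame(event)) c(event$start_s[1], event$end_s[1])
  else as.numeric(event[1:2])
}

#' Peak velocity of a profile
#' @param profile a `velocity_profile` or numeric speed vector (px/s).
#' @return maximum speed in px/s (two-hand average for a profile).
#' @export
peak_velocity <- function(profile) {
  v <- if (is.data.frame(profile)) profile$speed else as.numeric(profile)
  if (!length(v)) stop("empty velocity profile")
  max(v, na.rm = TRUE)
}

profile_speed <- function(profile) {
  if (is.data.frame(profile))
    list(v = profile$speed, fps = attr(profile, "fps"))
  else stop("need a velocity_profile (for its frame rate)")
}

#' Detect submovements in a velocity profile
#'
#' A submovement is an individual ballistic movement (stroke, stroke
#' repetition, preparatory movement): a velocity peak exceeding
#' `move_frac` of the event's peak speed, separated from its neighbours by
#' local minima below `valley_frac` of the smaller adjacent peak. Adjacent
#' peaks whose intervening valley stays above that fraction are fused into
#' one submovement.
#'
#' @param profile a `velocity_profile` (needs >= 20 fps).
#' @param move_frac movement threshold as a fraction of peak speed.
#' @param valley_frac valley criterion as a fraction of the smaller
#'   adjacent peak.
#' @return list of class `submovements`: `count`, `peaks` (times),
#'   `boundaries` (times of separating minima), `onset`, `offset` (first
#'   onset / last offset of movement, threshold crossings), `threshold`.
#' @export
detect_submovements <- function(profile, move_frac = 0.15,
                                valley_frac = 0.5) {
  ps <- profile_speed(profile)
  v <- ps$v; fps <- ps$fps
  if (fps < 20) stop("submovement detection needs >= 20 fps")
  tm <- profile$time
  vmax <- max(v, na.rm = TRUE)
  empty <- list(count = 0L, peaks = numeric(0), boundaries = numeric(0),
                onset = NA_real_, offset = NA_real_, threshold = NA_real_)
  class(empty) <- "submovements"
  if (!is.finite(vmax) || vmax <= 0) return(empty)
  thr <- move_frac * vmax
  n <- length(v)
  is_peak <- v >= c(-Inf, head(v, -1)) & v > c(v[-1], -Inf) & v > thr
  pk <- which(is_peak)
  if (!length(pk)) return(empty)
  # fuse peaks not separated by a deep enough valley
  kept <- pk[1]
  bounds <- integer(0)
  for (p in pk[-1]) {
    prev <- kept[length(kept)]
    seg <- v[prev:p]
    vmin_i <- which.min(seg) + prev - 1L
    if (v[vmin_i] < valley_frac * min(v[prev], v[p])) {
      kept <- c(kept, p)
      bounds <- c(bounds, vmin_i)
    } else if (v[p] > v[prev]) {
      kept[length(kept)] <- p  # keep the taller of the fused pair
    }
  }
  above <- which(v > thr)
  onset_i <- min(above); offset_i <- max(above)
  structure(list(count = length(kept), peaks = tm[kept],
                 boundaries = tm[bounds], onset = tm[onset_i],
                 offset = tm[offset_i], threshold = thr),
            class = "submovements")
}

#' @export
print.submovements <- function(x, ...) {
  cat(sprintf("<submovements: %d (onset %.2f s, offset %.2f s)>\n",
              x$count, x$onset, x$offset))
  invisible(x)
}

#' Hold-time within a gesture
#'
#' Cumulative time, between the first movement onset and the last movement
#' offset, during which the hands are still: speed below `still_frac` of
#' the event peak for at least `min_hold_s` seconds. Rest before the first
#' and after the last movement is excluded by construction.
#'
#' @param profile a `velocity_profile`.
#' @param submovements optional precomputed [detect_submovements()]
#'   result.
#' @param still_frac stillness threshold as a fraction of peak speed.
#' @param min_hold_s minimum still-run duration that counts as a hold.
#' @return hold time in seconds (0 when there are no holds).
#' @export
hold_time <- function(profile, submovements = NULL, still_frac = 0.10,
                      min_hold_s = 0.2) {
  ps <- profile_speed(profile)
  v <- ps$v; fps <- ps$fps
  if (is.null(submovements)) submovements <- detect_submovements(profile)
  if (submovements$count == 0L) return(0)
  sel <- profile$time >= submovements$onset &
    profile$time <= submovements$offset
  still <- v[sel] < still_frac * max(v, na.rm = TRUE)
  runs <- rle(still)
  run_s <- runs$lengths / fps
  sum(run_s[runs$values & run_s >= min_hold_s])
}

#' Gesture size (bounding-box area)
#'
#' Maximum extension of the hands in x and y relative to the upper torso
#' (keypoint 1): the union of both hands' body-relative positions during
#' the event is bounded and the box area `x-extent * y-extent` returned.
#'
#' @param traj a front-view `keypoint_trajectory`.
#' @param event event slice or `c(start_s, end_s)`.
#' @return list: `size_px2`, `x_extent`, `y_extent`.
#' @export
gesture_size <- function(traj, event = NULL) {
  rows <- window_rows(traj, event_window(event))
  rel_r <- relative_trajectory(traj, KP_RHAND, KP_TORSO)[rows, , drop = FALSE]
  rel_l <- relative_trajectory(traj, KP_LHAND, KP_TORSO)[rows, , drop = FALSE]
  xs <- c(rel_r[, 1], rel_l[, 1]); ys <- c(rel_r[, 2], rel_l[, 2])
  xs <- xs[is.finite(xs)]; ys <- ys[is.finite(ys)]
  if (!length(xs)) stop("no finite hand positions in event")
  x_extent <- diff(range(xs)); y_extent <- diff(range(ys))
  list(size_px2 = x_extent * y_extent, x_extent = x_extent,
       y_extent = y_extent)
}

#' Gesture depth (side view)
#'
#' Maximum horizontal distance during the event between the two-hand mean
#' position and the hip keypoint (id 8), from the side-view camera. This
#' captures forward extension of the hands as well as forward lean of the
#' torso.
#'
#' @param side_traj a side-view `keypoint_trajectory` (keypoints 4, 7, 8).
#' @param event event slice or `c(start_s, end_s)`.
#' @return maximum |hand - hip| horizontal distance in px, or `NA` (with
#'   attribute `absent = TRUE`) when the side view lacks the needed
#'   keypoints.
#' @export
gesture_depth <- function(side_traj, event = NULL) {
  if (is.null(side_traj) ||
      !all(c(KP_RHAND, KP_LHAND, KP_HIP) %in% side_traj$keypoint_ids)) {
    out <- NA_real_
    attr(out, "absent") <- TRUE
    return(out)
  }
  rows <- window_rows(side_traj, event_window(event))
  hx <- (side_traj$x[rows, kp_col(side_traj, KP_RHAND)] +
           side_traj$x[rows, kp_col(side_traj, KP_LHAND)]) / 2
  hipx <- side_traj$x[rows, kp_col(side_traj, KP_HIP)]
  max(abs(hx - hipx), na.rm = TRUE)
}

#' Normalized pairwise variability index (nPVI)
#'
#' Temporal variability of successive submovement durations:
#' `100/(m-1) * sum_k |d_k - d_{k+1}| / ((d_k + d_{k+1})/2)`. Order
#' sensitive by construction; equal durations give 0.
#'
#' @param durations numeric vector of submovement durations (any unit),
#'   length >= 2.
#' @return nPVI (unitless, >= 0); `NA` with a warning for fewer than two
#'   durations.
#' @export
npvi <- function(durations) {
  m <- length(durations)
  if (m < 2) {
    warning("nPVI undefined for fewer than 2 durations")
    return(NA_real_)
  }
  d1 <- durations[-m]; d2 <- durations[-1]
  100 / (m - 1) * sum(abs(d1 - d2) / ((d1 + d2) / 2))
}

#' Gesture rate per participant and blur grade
#'
#' Number of gestures per minute within each blur grade. Grades with no
#' gestures are reported with rate 0 (every participant x grade cell is
#' returned).
#'
#' @param events a `gesture_events` table (grades assigned).
#' @param schedule a [blur_schedule()].
#' @return data.frame: `participant_id`, `dyad_id`, `blur_grade`,
#'   `n_gestures`, `rate_per_min`.
#' @export
gesture_rate <- function(events, schedule) {
  mins <- schedule$grade_duration_s / 60
  parts <- unique(events[c("participant_id", "dyad_id")])
  out <- list()
  for (i in seq_len(nrow(parts))) {
    for (g in seq_len(schedule$n_grades)) {
      n <- sum(events$participant_id == parts$participant_id[i] &
                 events$blur_grade == g)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = parts$participant_id[i],
        dyad_id = parts$dyad_id[i], blur_grade = g, n_gestures = n,
        rate_per_min = n / mins, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Variance-inflation-factor collinearity screen
#'
#' `VIF_j = 1 / (1 - R2_j)` from regressing each feature on all others
#' (computed as the diagonal of the inverse correlation matrix). Features
#' above the threshold are flagged; a perfectly collinear pair yields an
#' infinite VIF and is flagged.
#'
#' @param feature_table data.frame of numeric feature columns (n rows >
#'   number of features).
#' @param threshold flag level (default 3).
#' @return data.frame: `feature`, `vif`, `flagged`.
#' @export
vif_screen <- function(feature_table, threshold = 3) {
  X <- as.matrix(feature_table[vapply(feature_table, is.numeric,
                                      logical(1))])
  X <- X[complete.cases(X), , drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 numeric features")
  if (nrow(X) <= ncol(X)) stop("need more observations than features")
  R <- stats::cor(X)
  vifs <- tryCatch(diag(solve(R)), error = function(e)
    rep(Inf, ncol(X)))
  vifs[vifs < 0 | !is.finite(vifs)] <- Inf
  data.frame(feature = colnames(X), vif = vifs,
             flagged = vifs > threshold, row.names = NULL)
}
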