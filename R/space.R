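# McNeillian gesture space: concentric regions around the speaker's body,
# realized as nested boxes normalized to body size. Categories, ordered
# inside-out: centre-centre < centre < periphery < extra-periphery.

MCNEILL_LEVELS <- c("centre-centre", "centre", "periphery",
                    "extra-periphery")

#' Body frame for gesture-space classification
#'
#' Derives the speaker's body frame from the front-view trajectory:
#' sternum position (keypoint 1), shoulder width (|x of keypoints 2 and
#' 5|) and neck-to-hip height (keypoints 1 and 8), each summarized by the
#' median over the (event) window for robustness to tracking noise.
#'
#' @param traj front-view `keypoint_trajectory`.
#' @param event optional event slice or `c(start_s, end_s)`.
#' @return list: `sternum` (x, y), `shoulder_width`, `neck_to_hip`,
#'   `head_y`, `hip_y` (all px).
#' @export
body_frame <- function(traj, event = NULL) {
  rows <- window_rows(traj, event_window(event))
  st <- kp_xy(traj, KP_TORSO)[rows, , drop = FALSE]
  rs <- kp_xy(traj, KP_RSHOULDER)[rows, , drop = FALSE]
  ls <- kp_xy(traj, KP_LSHOULDER)[rows, , drop = FALSE]
  hip <- kp_xy(traj, KP_HIP)[rows, , drop = FALSE]
  head <- kp_xy(traj, KP_NOSE)[rows, , drop = FALSE]
  sw <- median(abs(rs[, 1] - ls[, 1]), na.rm = TRUE)
  nh <- median(abs(hip[, 2] - st[, 2]), na.rm = TRUE)
  if (!is.finite(sw) || !is.finite(nh) || sw <= 0 || nh <= 0)
    stop("body frame undeterminable (degenerate shoulder/hip geometry)")
  list(sternum = c(x = median(st[, 1], na.rm = TRUE),
                   y = median(st[, 2], na.rm = TRUE)),
       shoulder_width = sw, neck_to_hip = nh,
       head_y = median(head[, 2], na.rm = TRUE),
       hip_y = median(hip[, 2], na.rm = TRUE))
}

# region of a single (x, y) point; boundary ties go outward. The two
# inner boxes are centred on the sternum; the periphery box is bounded
# by the shoulders horizontally (one shoulder-width either side) and by
# head and hips vertically (y grows downward).
mcneill_region <- function(x, y, frame) {
  dx <- abs(x - frame$sternum["x"])
  dy <- abs(y - frame$sternum["y"])
  hw1 <- 0.25 * frame$shoulder_width; hh1 <- 0.25 * frame$neck_to_hip
  if (dx < hw1 & dy < hh1) return(1L)                     # centre-centre
  if (dx < 2 * hw1 & dy < 2 * hh1) return(2L)             # centre
  if (dx < frame$shoulder_width & y > frame$head_y & y < frame$hip_y)
    return(3L)                                            # periphery
  4L                                                      # extra-periphery
}

#' McNeillian space category of a gesture
#'
#' Classifies every hand sample during the event into the concentric-box
#' scheme (centre-centre box: sternum +/- 0.25 shoulder-width horizontally
#' and +/- 0.25 neck-to-hip vertically; centre: twice that box; periphery:
#' the box bounded by the shoulders horizontally -- one shoulder-width
#' either side of the sternum -- and by head and hips vertically; beyond:
#' extra-periphery; points on a box boundary belong to the outer region)
#' and summarizes the gesture by the most extreme region reached by
#' either hand.
#'
#' @param traj front-view `keypoint_trajectory`.
#' @param event event slice or `c(start_s, end_s)`.
#' @param frame optional precomputed [body_frame()]; defaults to the frame
#'   over the whole trajectory.
#' @return ordered factor with levels
#'   `centre-centre < centre < periphery < extra-periphery`.
#' @export
mcneillian_space <- function(traj, event = NULL, frame = NULL) {
  if (is.null(frame)) frame <- body_frame(traj)
  rows <- window_rows(traj, event_window(event))
  reg <- 1L
  for (id in c(KP_RHAND, KP_LHAND)) {
    p <- kp_xy(traj, id)[rows, , drop = FALSE]
    p <- p[is.finite(p[, 1]) & is.finite(p[, 2]), , drop = FALSE]
    for (i in seq_len(nrow(p)))
      reg <- max(reg, mcneill_region(p[i, 1], p[i, 2], frame))
  }
  factor(MCNEILL_LEVELS[reg], levels = MCNEILL_LEVELS, ordered = TRUE)
}

#' Full kinematic profile of one gesture event
#'
#' Convenience wrapper computing all signal-level features for one event:
#' peak velocity, submovement count, hold-time, size, McNeillian space,
#' depth (when a side view is available) and nPVI of the submovement
#' durations.
#'
#' @param traj front-view `keypoint_trajectory`.
#' @param event one-row `gesture_events` slice.
#' @param side_traj optional side-view trajectory for depth.
#' @param frame optional precomputed [body_frame()].
#' @param config optional list overriding thresholds: `cutoff_hz`,
#'   `move_frac`, `valley_frac`, `still_frac`, `min_hold_s`.
#' @return one-row data.frame with the feature columns plus event ids.
#' @export
kinematic_profile <- function(traj, event, side_traj = NULL, frame = NULL,
                              config = list()) {
  cfg <- utils::modifyList(list(cutoff_hz = 10, move_frac = 0.15,
                                valley_frac = 0.5, still_frac = 0.10,
                                min_hold_s = 0.2), config)
  prof <- velocity_profile(traj, event, cutoff_hz = cfg$cutoff_hz)
  sm <- detect_submovements(prof, cfg$move_frac, cfg$valley_frac)
  ht <- hold_time(prof, sm, cfg$still_frac, cfg$min_hold_s)
  sz <- gesture_size(traj, event)
  sp <- mcneillian_space(traj, event, frame)
  dp <- gesture_depth(side_traj, event)
  # submovement durations from boundaries (onset | minima | offset)
  cuts <- c(sm$onset, sm$boundaries, sm$offset)
  durs <- if (sm$count >= 2) diff(cuts) else numeric(0)
  tv <- if (length(durs) >= 2) npvi(durs)
        else if (sm$count >= 2) suppressWarnings(npvi(durs)) else NA_real_
  data.frame(participant_id = event$participant_id,
             dyad_id = event$dyad_id, blur_grade = event$blur_grade,
             gesture_type = event$gesture_type,
             start_s = event$start_s, end_s = event$end_s,
             peak_velocity = peak_velocity(prof),
             submovements = sm$count, hold_time = ht,
             size_px2 = sz$size_px2,
             mcneillian_space = as.character(sp),
             depth_px = as.numeric(dp), npvi = tv,
             stringsAsFactors = FALSE)
}
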