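# Articulator-level motion energy: summed frame-to-frame displacement of
# an articulator's keypoint(s), optionally in coordinates relative to a
# reference articulator. The correction scheme is fixed:
#   torso -> none, head -> torso, arms -> torso, fingers -> arms (same side)

ARTICULATORS <- c("torso", "head", "arms", "fingers")

#' Relative trajectory of target keypoints
#'
#' Expresses the per-frame mean position of the target keypoints relative
#' to the per-frame mean position of the reference keypoints. Rigid common
#' motion (e.g. torso sway carrying the hands) cancels exactly. Frames in
#' which the reference is fully missing are marked missing.
#'
#' @param traj a `keypoint_trajectory`.
#' @param target_keypoints,reference_keypoints keypoint id vectors.
#' @return matrix with columns `x`, `y` (pixels, relative coordinates).
#' @export
relative_trajectory <- function(traj, target_keypoints,
                                reference_keypoints) {
  jt <- kp_col(traj, target_keypoints)
  jr <- kp_col(traj, reference_keypoints)
  tx <- rowMeans(traj$x[, jt, drop = FALSE])
  ty <- rowMeans(traj$y[, jt, drop = FALSE])
  rx <- rowMeans(traj$x[, jr, drop = FALSE])
  ry <- rowMeans(traj$y[, jr, drop = FALSE])
  cbind(x = tx - rx, y = ty - ry)
}

# displacement sum of an n x 2 position matrix
path_length <- function(pos, metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  dx <- diff(pos[, 1]); dy <- diff(pos[, 2])
  steps <- if (metric == "euclidean") sqrt(dx^2 + dy^2)
           else abs(dx) + abs(dy)
  sum(steps, na.rm = TRUE)
}

window_rows <- function(traj, window) {
  if (is.null(window)) return(seq_len(traj$frames))
  i0 <- max(1L, floor(window[1] * traj$fps) + 1L)
  i1 <- min(traj$frames, floor(window[2] * traj$fps) + 1L)
  if (i1 - i0 + 1L < 2L) stop("window shorter than 2 frames")
  i0:i1
}

#' Motion energy of one articulator
#'
#' Summed frame-to-frame displacement magnitude (pixels) of the
#' articulator position over a time window. Positions are corrected by the
#' reference articulator before differencing: head by torso, arms by
#' torso, fingers by the same-side hand; torso is uncorrected. Arms and
#' fingers are computed per side and the left and right energy values
#' averaged.
#'
#' @param traj a front-view `keypoint_trajectory`.
#' @param articulator one of `"torso"`, `"head"`, `"arms"`, `"fingers"`.
#' @param window `c(start_s, end_s)` or `NULL` for the whole trajectory.
#' @param metric per-frame displacement magnitude: Euclidean norm
#'   (default, rotation-invariant) or Manhattan `|dx| + |dy|`.
#' @param corrected set `FALSE` to skip the reference correction.
#' @return list of class `articulator_energy`: `articulator`, `energy_px`,
#'   `corrected_by`, `window`.
#' @export
articulator_energy <- function(traj, articulator = ARTICULATORS,
                               window = NULL,
                               metric = c("euclidean", "manhattan"),
                               corrected = TRUE) {
  articulator <- match.arg(articulator)
  metric <- match.arg(metric)
  rows <- window_rows(traj, window)
  sub <- function(ids, ref) {
    pos <- if (corrected && !is.null(ref))
      relative_trajectory(traj, ids, ref)
    else {
      jt <- kp_col(traj, ids)
      cbind(rowMeans(traj$x[, jt, drop = FALSE]),
            rowMeans(traj$y[, jt, drop = FALSE]))
    }
    path_length(pos[rows, , drop = FALSE], metric)
  }
  energy <- switch(articulator,
    torso = sub(KP_TORSO, NULL),
    head = sub(KP_NOSE, KP_TORSO),
    arms = mean(c(sub(KP_RHAND, KP_TORSO), sub(KP_LHAND, KP_TORSO))),
    fingers = {
      have <- intersect(c(KP_RFINGERS, KP_LFINGERS), traj$keypoint_ids)
      if (!length(have)) stop("no finger-tip keypoints in trajectory")
      e <- vapply(have, function(id) {
        ref <- if (id %in% KP_RFINGERS) KP_RHAND else KP_LHAND
        sub(id, ref)
      }, numeric(1))
      mean(e)
    })
  corrected_by <- if (!corrected) "none" else switch(articulator,
    torso = "none", head = "torso", arms = "torso", fingers = "arms")
  structure(list(articulator = articulator, energy_px = energy,
                 corrected_by = corrected_by, window = window),
            class = "articulator_energy")
}

#' @export
print.articulator_energy <- function(x, ...) {
  cat(sprintf("<%s energy: %.2f px (corrected by %s)>\n", x$articulator,
              x$energy_px, x$corrected_by))
  invisible(x)
}

#' Per-event, per-articulator motion-energy table
#'
#' Computes every articulator's corrected motion energy within each
#' gesture-event window and returns the long-format table used by the
#' statistical ladder (keyed by participant, dyad, blur grade,
#' articulator).
#'
#' @param traj a front-view `keypoint_trajectory`.
#' @param events a `gesture_events` table (grades assigned).
#' @param articulators subset of [ARTICULATORS] to compute.
#' @param metric see [articulator_energy()].
#' @return data.frame: `participant_id`, `dyad_id`, `blur_grade`,
#'   `articulator`, `event_id`, `energy_px`.
#' @export
energy_by_grade <- function(traj, events,
                            articulators = c("torso", "head", "arms"),
                            metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  out <- list()
  for (i in seq_len(nrow(events))) {
    for (a in articulators) {
      en <- articulator_energy(traj, a,
                               window = c(events$start_s[i],
                                          events$end_s[i]),
                               metric = metric)
      out[[length(out) + 1L]] <- data.frame(
        participant_id = events$participant_id[i],
        dyad_id = events$dyad_id[i],
        blur_grade = events$blur_grade[i],
        articulator = a, event_id = i, energy_px = en$energy_px,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
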