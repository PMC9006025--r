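#' @importFrom stats approx coef fft lm median nextn optim pchisq plogis qlogis
#'   quantile rnorm rpois runif sd setNames var vcov dnorm predict anova
#'   as.formula logLik model.matrix filter simulate complete.cases
#' @importFrom utils read.delim write.csv read.csv head tail
NULL

# Body keypoint ids follow the 25-point pose-tracker body map:
# 0 = nose, 1 = upper torso (neck/sternum), 2/5 = right/left shoulder,
# 4/7 = right/left hand (wrist), 8 = mid-hip.  Finger tips are appended
# as ids 25:29 (right hand) and 30:34 (left hand).
KP_NOSE <- 0L
KP_TORSO <- 1L
KP_RSHOULDER <- 2L
KP_RHAND <- 4L
KP_LSHOULDER <- 5L
KP_LHAND <- 7L
KP_HIP <- 8L
KP_RFINGERS <- 25:29
KP_LFINGERS <- 30:34

required_keypoints <- function(view) {
  if (view == "side") c(KP_RHAND, KP_LHAND, KP_HIP)
  else c(KP_NOSE, KP_TORSO, KP_RSHOULDER, KP_RHAND, KP_LSHOULDER, KP_LHAND,
         KP_HIP)
}

#' Construct a keypoint trajectory
#'
#' Container for time-indexed 2-D pixel positions of body keypoints from a
#' single camera view, with per-frame tracking confidence. Positions are in
#' pixels with the origin at the top-left of the image and y increasing
#' downward (pose-tracker convention); time is seconds from session start
#' with frame index 0-based.
#'
#' @param x,y numeric matrices, frames x keypoints, pixel coordinates.
#' @param conf numeric matrix in `[0, 1]`, same shape; tracking confidence.
#' @param fps frames per second (> 0).
#' @param view `"front"` or `"side"`.
#' @param keypoint_ids integer keypoint ids labelling the columns.
#' @return An object of class `keypoint_trajectory`: a list with elements
#'   `x`, `y`, `conf`, `fps`, `view`, `keypoint_ids`, `frames` and `times`.
#' @export
keypoint_trajectory <- function(x, y, conf, fps, view = c("front", "side"),
                                keypoint_ids) {
  view <- match.arg(view)
  x <- as.matrix(x); y <- as.matrix(y); conf <- as.matrix(conf)
  stopifnot(identical(dim(x), dim(y)), identical(dim(x), dim(conf)))
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a single positive number")
  keypoint_ids <- as.integer(keypoint_ids)
  if (length(keypoint_ids) != ncol(x))
    stop("keypoint_ids length must match number of keypoint columns")
  bad <- conf > 0 & (!is.finite(x) | !is.finite(y))
  if (any(bad, na.rm = TRUE))
    stop("non-finite positions at confidence > 0")
  obj <- structure(list(
    x = x, y = y, conf = conf, fps = fps, view = view,
    keypoint_ids = keypoint_ids, frames = nrow(x),
    times = (seq_len(nrow(x)) - 1) / fps
  ), class = "keypoint_trajectory")
  obj
}

#' @export
print.keypoint_trajectory <- function(x, ...) {
  cat(sprintf("<keypoint_trajectory: %d frames @ %g fps (%.1f s), %s view, %d keypoints>\n",
              x$frames, x$fps, x$frames / x$fps, x$view,
              length(x$keypoint_ids)))
  invisible(x)
}

kp_col <- function(traj, id) {
  j <- match(as.integer(id), traj$keypoint_ids)
  if (any(is.na(j)))
    stop("keypoint ", paste(id[is.na(j)], collapse = ", "),
         " not present in trajectory")
  j
}

#' Per-keypoint positions as an n x 2 matrix
#' @param traj a `keypoint_trajectory`.
#' @param id single keypoint id.
#' @return matrix with columns x, y (pixels).
#' @export
kp_xy <- function(traj, id) {
  j <- kp_col(traj, id)
  cbind(x = traj$x[, j], y = traj$y[, j])
}

# Mark low-confidence samples missing and linearly interpolate short gaps.
# Gaps longer than max_gap_s stay NA and are reported via the "unusable"
# attribute (list of per-keypoint frame runs).
interpolate_gaps <- function(traj, conf_floor = 0.3, max_gap_s = 0.5,
                             verbose = FALSE) {
  max_gap <- max(1L, round(max_gap_s * traj$fps))
  unusable <- list()
  n <- traj$frames
  for (j in seq_along(traj$keypoint_ids)) {
    miss <- traj$conf[, j] < conf_floor | !is.finite(traj$x[, j]) |
      !is.finite(traj$y[, j])
    if (!any(miss)) next
    runs <- rle(miss)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    good <- which(!miss)
    for (k in which(runs$values)) {
      idx <- starts[k]:ends[k]
      gap_ok <- runs$lengths[k] <= max_gap && length(good) >= 2L &&
        starts[k] > 1L && ends[k] < n
      if (gap_ok) {
        traj$x[idx, j] <- approx(good, traj$x[good, j], xout = idx)$y
        traj$y[idx, j] <- approx(good, traj$y[good, j], xout = idx)$y
        if (verbose)
          message(sprintf("keypoint %d: interpolated gap of %d frames",
                          traj$keypoint_ids[j], runs$lengths[k]))
      } else {
        traj$x[idx, j] <- NA_real_
        traj$y[idx, j] <- NA_real_
        unusable[[length(unusable) + 1L]] <-
          list(keypoint = traj$keypoint_ids[j],
               frames = c(starts[k], ends[k]))
      }
    }
  }
  attr(traj, "unusable") <- unusable
  traj
}

#' Read a keypoint trajectory from file
#'
#' Reads either the per-frame JSON dialect (one object per frame holding a
#' flat `[x, y, c]` triplet per keypoint) or the equivalent flat CSV
#' (columns `frame`, then `kp<id>_x`, `kp<id>_y`, `kp<id>_c` per keypoint).
#' Samples with confidence below `conf_floor` are marked missing and
#' linearly interpolated when the gap is at most `max_gap_s` seconds;
#' longer gaps are left missing and flagged in the `"unusable"` attribute.
#'
#' @param path file path (`.json` or `.csv`).
#' @param view `"front"` or `"side"`; determines which keypoints must be
#'   present (the side view needs the hands and hip, ids 4, 7, 8).
#' @param fps frames per second; required for CSV, overrides the embedded
#'   value for JSON when supplied.
#' @param conf_floor confidence below which a sample counts as missing.
#' @param max_gap_s longest gap (seconds) bridged by linear interpolation.
#' @param verbose log interpolated gap lengths via `message()`.
#' @return a validated [keypoint_trajectory()].
#' @export
read_keypoints <- function(path, view = c("front", "side"), fps = NULL,
                           conf_floor = 0.3, max_gap_s = 0.5,
                           verbose = FALSE) {
  view <- match.arg(view)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    if (is.null(fps)) fps <- doc$fps
    ids <- as.integer(doc$keypoint_ids)
    fr <- doc$frames
    if (is.data.frame(fr)) {
      frame_idx <- fr$frame
      pts <- do.call(rbind, fr$points)
    } else {
      frame_idx <- vapply(fr, function(f) f$frame, numeric(1))
      pts <- do.call(rbind, lapply(fr, function(f) f$points))
    }
    if (is.unsorted(frame_idx, strictly = TRUE))
      stop("format error: non-monotone frame index")
    k <- length(ids)
    if (ncol(pts) != 3L * k)
      stop("format error: frame rows must hold [x,y,c] per keypoint")
    xm <- pts[, 3 * seq_len(k) - 2, drop = FALSE]
    ym <- pts[, 3 * seq_len(k) - 1, drop = FALSE]
    cm <- pts[, 3 * seq_len(k), drop = FALSE]
  } else if (ext == "csv") {
    d <- read.csv(path, check.names = FALSE)
    if (is.null(fps)) stop("fps must be supplied for CSV keypoint files")
    if (!"frame" %in% names(d)) stop("format error: missing 'frame' column")
    if (is.unsorted(d$frame, strictly = TRUE))
      stop("format error: non-monotone frame index")
    xn <- grep("^kp[0-9]+_x$", names(d), value = TRUE)
    ids <- as.integer(sub("^kp([0-9]+)_x$", "\\1", xn))
    o <- order(ids); ids <- ids[o]; xn <- xn[o]
    xm <- as.matrix(d[xn])
    ym <- as.matrix(d[sub("_x$", "_y", xn)])
    cm <- as.matrix(d[sub("_x$", "_c", xn)])
  } else stop("unsupported keypoint file extension: ", ext)
  missing_ids <- setdiff(required_keypoints(view), ids)
  if (length(missing_ids))
    stop("format error: missing required keypoint ",
         paste(missing_ids, collapse = ", "), " for view=", view)
  traj <- keypoint_trajectory(xm, ym, cm, fps = fps, view = view,
                              keypoint_ids = ids)
  interpolate_gaps(traj, conf_floor = conf_floor, max_gap_s = max_gap_s,
                   verbose = verbose)
}

#' Write a keypoint trajectory
#'
#' Writes the JSON per-frame dialect or the flat CSV read by
#' [read_keypoints()]; both round-trip all supported fields.
#'
#' @param traj a `keypoint_trajectory`.
#' @param path output path; format chosen by extension (`.json` / `.csv`).
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(traj, path) {
  ext <- tolower(tools::file_ext(path))
  k <- length(traj$keypoint_ids)
  if (ext == "json") {
    pts <- matrix(0, traj$frames, 3L * k)
    pts[, 3 * seq_len(k) - 2] <- traj$x
    pts[, 3 * seq_len(k) - 1] <- traj$y
    pts[, 3 * seq_len(k)] <- traj$conf
    frames <- lapply(seq_len(traj$frames), function(i)
      list(frame = i - 1L, points = round(pts[i, ], 4)))
    doc <- list(fps = traj$fps, view = traj$view,
                keypoint_ids = traj$keypoint_ids, frames = frames)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    d <- data.frame(frame = seq_len(traj$frames) - 1L)
    for (j in seq_len(k)) {
      id <- traj$keypoint_ids[j]
      d[[sprintf("kp%d_x", id)]] <- round(traj$x[, j], 4)
      d[[sprintf("kp%d_y", id)]] <- round(traj$y[, j], 4)
      d[[sprintf("kp%d_c", id)]] <- round(traj$conf[, j], 4)
    }
    write.csv(d, path, row.names = FALSE)
  } else stop("unsupported keypoint file extension: ", ext)
  invisible(path)
}
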