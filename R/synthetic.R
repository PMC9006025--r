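# Synthetic dyad generator. Produces full sessions -- keypoint
# trajectories, gesture annotations, acoustic series and speech envelope
# -- with every generating value recorded, so each pipeline stage can be
# validated against known ground truth. Gestures are built from
# minimum-jerk velocity pulses, the standard ballistic motor primitive:
# a gesture of k pulses has exactly k submovements, the inter-pulse
# stillness is the hold-time, and pulse amplitude fixes size and peak
# velocity analytically.

#' Generator configuration
#'
#' Defaults encode the emulated study: 20 dyads (40 participants) in
#' 40-minute conversations under 10 blur grades of 240 s each, half the
#' dyads going clear-to-blur and half blur-to-clear; four gesture types
#' with empirical frequencies and mean durations between about 1.7 and
#' 2.8 s; inverted-U (quadratic-over-grade) modulation of gesture rate,
#' size, velocity and hold-time with a linear decrease in depth; a
#' speech-with-gesture intensity offset of 4.36 dB and pitch offset of
#' 3.71 Hz; and a 2-8 Hz-band coupling between hand speed and the speech
#' envelope with a 50 ms gesture lead.
#'
#' @param ... overrides for any default field.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n_dyads = 20L, n_grades = 10L, grade_duration_s = 240, fps = 25,
    acoustic_rate = 10, envelope_rate = 100,
    # gesture occurrence
    gesture_rate_per_min = 2.2, rate_quad_amp = 0.3,
    gesture_type_probs = c(representational = 980, pragmatic = 627,
                           interactive = 1897, emblem = 83) / 3587,
    pulses_by_type = list(representational = 3:5, pragmatic = 1:3,
                          interactive = 1:3, emblem = 2:4),
    pulse_duration_s = 0.4, gap_duration_s = 0.5, event_margin_s = 0.1,
    # kinematic truth (front view, pixels)
    pulse_amplitude_px = 120, amplitude_log_sd = 0.25,
    size_quad_amp = 0.15, velocity_quad_amp = 0.15,
    hold_quad_amp = 0.15, depth_linear_slope_px = -4,
    depth_base_px = 90,
    # acoustics
    intensity_base_db = 60, f0_base_hz = 180,
    modality_intensity_offset_db = 4.36, modality_f0_offset_hz = 3.71,
    intensity_blur_amp_db = 2, f0_blur_amp_hz = 0,
    # speech-gesture coupling: positive lag = hand speed leads envelope
    coupling_lag_ms = 50, coupling_strength = 0.8, syllable_rate_hz = 4,
    # random effects and noise
    re_sd = c(dyad = 0.5, participant = 1.5, gesture_type = 0.2),
    f0_participant_sd = 15,
    cell_sd_db = 0.5, cell_sd_hz = 1.5,
    sample_sd_db = 1.5, sample_sd_hz = 8,
    keypoint_noise_px = 1, torso_sway_px = 6, torso_sway_hz = 0.1,
    speech_on_mean_s = 3, speech_off_mean_s = 2,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (any(unlist(cfg$re_sd) < 0) || cfg$gesture_rate_per_min < 0)
    stop("SDs and rates must be non-negative")
  structure(cfg, class = "generator_config")
}

# unit inverted-U over grades: 1 at mid-grade, 0 at the extremes
grade_quad_shape <- function(grade, n_grades) {
  mid <- (n_grades + 1) / 2
  1 - ((grade - mid) / ((n_grades - 1) / 2))^2
}

#' Minimum-jerk displacement and speed profiles
#'
#' The minimum-jerk trajectory over normalized time `tau = t/T`:
#' displacement `D (10 tau^3 - 15 tau^4 + 6 tau^5)` and speed
#' `30 D/T tau^2 (1 - tau)^2`, with analytic peak speed
#' `1.875 D / T` at `tau = 0.5`.
#'
#' @param t time since pulse onset (seconds, vector).
#' @param duration_s pulse duration T.
#' @param amplitude_px pulse displacement D.
#' @return data.frame: `displacement`, `speed` (0 outside `[0, T]`).
#' @export
min_jerk_pulse <- function(t, duration_s, amplitude_px) {
  tau <- pmin(pmax(t / duration_s, 0), 1)
  data.frame(
    displacement = amplitude_px * (10 * tau^3 - 15 * tau^4 + 6 * tau^5),
    speed = 30 * amplitude_px / duration_s * tau^2 * (1 - tau)^2 *
      (t >= 0 & t <= duration_s))
}

#' Build one synthetic gesture from minimum-jerk pulses
#'
#' Concatenates `k` out-and-back minimum-jerk pulses separated by still
#' gaps; the hand displacement along a fixed direction is returned on the
#' frame grid, along with the generating truth (submovement count, total
#' gap time, peak speed, amplitude).
#'
#' @param k number of pulses (= true submovement count).
#' @param fps frame rate.
#' @param pulse_s per-pulse duration.
#' @param gap_s stillness between consecutive pulses.
#' @param amplitude_px pulse displacement.
#' @param margin_s still margin before the first and after the last pulse.
#' @return list: `disp` (displacement series, px), `duration_s`, `truth`
#'   (list with `submovements`, `hold_s`, `peak_speed`, `amplitude_px`).
#' @export
synth_gesture <- function(k, fps, pulse_s = 0.4, gap_s = 0.5,
                          amplitude_px = 120, margin_s = 0.1) {
  dur <- 2 * margin_s + k * pulse_s + (k - 1) * gap_s
  t <- seq(0, dur, by = 1 / fps)
  disp <- numeric(length(t))
  for (i in seq_len(k)) {
    onset <- margin_s + (i - 1) * (pulse_s + gap_s)
    p <- min_jerk_pulse(t - onset, pulse_s, amplitude_px)
    # odd pulses move out, even pulses move back: displacement stays
    # bounded and the speed profile keeps k distinct bells
    disp <- disp + if (i %% 2 == 1) p$displacement else -p$displacement
  }
  list(disp = disp, duration_s = dur,
       truth = list(submovements = k, hold_s = (k - 1) * gap_s,
                    peak_speed = 1.875 * amplitude_px / pulse_s,
                    amplitude_px = amplitude_px))
}

#' Synthesize a glottal-like pulse train
#'
#' Band-limited source signal with known fundamental frequency: an
#' impulse train at `f0` (optionally a linear glide) convolved with an
#' exponentially decaying kernel. Used as WAV-path ground truth for the
#' pitch tracker and intensity measures.
#'
#' @param duration_s duration in seconds.
#' @param sample_rate audio rate in Hz.
#' @param f0 fundamental in Hz; length-2 vector for a linear glide.
#' @param amplitude peak amplitude on full scale.
#' @return numeric sample vector.
#' @export
synth_pulse_train <- function(duration_s, sample_rate, f0,
                              amplitude = 0.5) {
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  f <- if (length(f0) == 2) f0[1] + (f0[2] - f0[1]) * t / duration_s
       else rep(f0, n)
  phase <- cumsum(f) / sample_rate
  x <- numeric(n)
  x[c(TRUE, diff(floor(phase)) >= 1)] <- 1
  kern <- exp(-seq(0, 0.004, by = 1 / sample_rate) * 1200)
  y <- stats::convolve(x, rev(kern), type = "open")[seq_len(n)]
  amplitude * y / max(abs(y))
}

# membership scan for sorted, non-overlapping intervals (n x 2 matrix)
in_intervals <- function(times, iv) {
  if (is.null(iv) || !nrow(iv)) return(rep(FALSE, length(times)))
  bounds <- as.vector(t(iv))
  findInterval(times, bounds, rightmost.closed = TRUE) %% 2L == 1L
}

draw_speech_intervals <- function(total_s, on_mean, off_mean) {
  t <- 0; out <- list()
  while (t < total_s) {
    on <- stats::rexp(1, 1 / on_mean)
    t0 <- t; t1 <- min(t + on, total_s)
    out[[length(out) + 1L]] <- c(t0, t1)
    t <- t1 + stats::rexp(1, 1 / off_mean)
  }
  do.call(rbind, out)
}

draw_events <- function(cfg, schedule, participant_id, dyad_id,
                        speech_iv) {
  mins <- cfg$grade_duration_s / 60
  rows <- list()
  for (w in seq_len(cfg$n_grades)) {
    t0 <- (w - 1) * cfg$grade_duration_s
    g <- blur_grade_at(schedule, t0 + cfg$grade_duration_s / 2)
    q <- grade_quad_shape(g, cfg$n_grades)
    lambda <- cfg$gesture_rate_per_min * (1 + cfg$rate_quad_amp * (q - 0.5)) *
      mins
    n <- rpois(1, max(lambda, 0))
    if (n == 0) next
    types <- sample(names(cfg$gesture_type_probs), n, replace = TRUE,
                    prob = cfg$gesture_type_probs)
    for (i in seq_len(n)) {
      k <- sample(cfg$pulses_by_type[[types[i]]], 1)
      dur <- 2 * cfg$event_margin_s + k * cfg$pulse_duration_s +
        (k - 1) * cfg$gap_duration_s
      # place inside a speech interval overlapping this grade window
      iv <- speech_iv[speech_iv[, 2] > t0 &
                        speech_iv[, 1] < t0 + cfg$grade_duration_s, ,
                      drop = FALSE]
      if (!nrow(iv)) next
      j <- sample(nrow(iv), 1)
      lo <- max(iv[j, 1], t0)
      hi <- min(iv[j, 2], t0 + cfg$grade_duration_s) - dur
      start <- if (hi > lo) runif(1, lo, hi) else lo
      rows[[length(rows) + 1L]] <- data.frame(
        start_s = start, end_s = start + dur, gesture_type = types[i],
        participant_id = participant_id, dyad_id = dyad_id,
        blur_grade = g, k = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(NULL)
  d <- do.call(rbind, rows)
  d <- d[order(d$start_s), , drop = FALSE]
  # one articulator set per speaker: drop events that would overlap the
  # previous one or its post-gesture retraction (1.5 s spacing)
  keep <- rep(TRUE, nrow(d))
  last_end <- -Inf
  for (i in seq_len(nrow(d))) {
    if (d$start_s[i] < last_end + 1.5) keep[i] <- FALSE
    else last_end <- d$end_s[i]
  }
  d[keep, , drop = FALSE]
}

base_skeleton <- function() {
  # rest positions, px, 1920x1080 front view; y grows downward
  list(`0` = c(960, 300), `1` = c(960, 420), `2` = c(870, 430),
       `5` = c(1050, 430), `4` = c(880, 700), `7` = c(1040, 700),
       `8` = c(960, 760))
}

#' Generate one synthetic participant session
#'
#' Realizes a full session for one participant under the configured study
#' conditions: gesture events placed inside speech spurts with
#' minimum-jerk hand kinematics (front and side view), grade-dependent
#' quadratic effects on rate/size/velocity/hold and a linear depth
#' decrease, a speech envelope coupled to hand speed at the configured
#' lag, and intensity/F0 series carrying the modality offsets. Which
#' streams are materialized is selectable; the truth record always stores
#' the generating values.
#'
#' @param cfg a [generator_config()].
#' @param dyad_id,participant_id identifiers.
#' @param direction blur schedule direction for this dyad.
#' @param seed RNG seed for this session (derive per session).
#' @param streams subset of `c("events", "keypoints", "acoustics",
#'   "envelope")`.
#' @return list of class `synthetic_session`: `schedule`, `events`,
#'   `front`, `side`, `acoustics` (time/intensity_db/f0_hz),
#'   `envelope` (time/value), `hand_speed` (time/value), `speech_intervals`,
#'   `truth`.
#' @export
generate_session <- function(cfg, dyad_id = "d01",
                             participant_id = "d01p1",
                             direction = "clear_to_blur", seed = 1L,
                             streams = c("events", "keypoints",
                                         "acoustics", "envelope")) {
  set.seed(seed)
  schedule <- blur_schedule(cfg$n_grades, cfg$grade_duration_s, direction)
  total_s <- schedule$session_length_s
  if (cfg$gesture_rate_per_min * total_s / 60 > total_s /
      (2 * cfg$event_margin_s + cfg$pulse_duration_s))
    stop("infeasible gesture rate for session length")
  speech_iv <- draw_speech_intervals(total_s, cfg$speech_on_mean_s,
                                     cfg$speech_off_mean_s)
  re_participant <- rnorm(1, 0, cfg$re_sd[["participant"]])
  re_dyad <- rnorm(1, 0, cfg$re_sd[["dyad"]])
  f0_re <- rnorm(1, 0, cfg$f0_participant_sd)
  ev <- draw_events(cfg, schedule, participant_id, dyad_id, speech_iv)
  if (is.null(ev))
    ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                     gesture_type = character(0),
                     participant_id = character(0),
                     dyad_id = character(0), blur_grade = integer(0),
                     k = integer(0))
  # per-event kinematic truth; annotated end matches the realized
  # gesture duration (gaps are grade-modulated)
  q <- grade_quad_shape(ev$blur_grade, cfg$n_grades)
  amp <- cfg$pulse_amplitude_px * (1 + cfg$size_quad_amp * q) *
    exp(rnorm(nrow(ev), 0, cfg$amplitude_log_sd))
  gaps <- cfg$gap_duration_s * (1 + cfg$hold_quad_amp * (q - 0.5))
  if (nrow(ev))
    ev$end_s <- ev$start_s + 2 * cfg$event_margin_s +
      ev$k * cfg$pulse_duration_s + (ev$k - 1) * gaps
  depth <- pmax(cfg$depth_base_px +
                  cfg$depth_linear_slope_px * (ev$blur_grade - 1), 5)
  # union-bounding-box size: the hands rest 160 px apart in x and move
  # together at 45 degrees, so the box is (sep + D/sqrt2) x (D/sqrt2)
  hand_sep <- 160
  truth_events <- cbind(ev, amplitude_px = amp, gap_s = gaps,
                        depth_px = depth,
                        peak_speed = 1.875 * amp / cfg$pulse_duration_s,
                        hold_s = (ev$k - 1) * gaps,
                        size_px2 = (hand_sep + amp / sqrt(2)) *
                          (amp / sqrt(2)))
  out <- list(schedule = schedule,
              events = gesture_events(ev$start_s, ev$end_s,
                                      ev$gesture_type, participant_id,
                                      dyad_id, schedule = schedule),
              speech_intervals = speech_iv,
              truth = list(events = truth_events,
                           re_participant = re_participant,
                           re_dyad = re_dyad, f0_re = f0_re,
                           config = cfg))
  n_frames <- total_s * cfg$fps + 1
  tt <- (seq_len(n_frames) - 1) / cfg$fps
  # hand displacement series shared by keypoints and coupling
  need_kin <- any(c("keypoints", "envelope") %in% streams)
  if (need_kin) {
    hand_disp <- numeric(n_frames)
    for (i in seq_len(nrow(ev))) {
      sg <- synth_gesture(ev$k[i], cfg$fps, cfg$pulse_duration_s,
                          gaps[i], amp[i], cfg$event_margin_s)
      i0 <- round(ev$start_s[i] * cfg$fps) + 1L
      idx <- i0:min(i0 + length(sg$disp) - 1L, n_frames)
      hand_disp[idx] <- hand_disp[idx] + sg$disp[seq_along(idx)]
      # odd pulse counts leave the hand displaced; retract slowly after
      # the event so no frame-step artefact enters any analysis window
      final <- sg$disp[length(idx)]
      if (abs(final) > 1e-9) {
        r0 <- idx[length(idx)] + 1L
        if (r0 <= n_frames) {
          ret <- min_jerk_pulse(
            (seq_len(round(1.2 * cfg$fps)) - 1) / cfg$fps, 1.2, final)
          ridx <- r0:min(r0 + length(ret$displacement) - 1L, n_frames)
          hand_disp[ridx] <- hand_disp[ridx] +
            final - ret$displacement[seq_along(ridx)]
        }
      }
    }
    speed <- c(0, abs(diff(hand_disp))) * cfg$fps
    out$hand_speed <- data.frame(time = tt, value = speed)
  }
  if ("keypoints" %in% streams) {
    sk <- base_skeleton()
    sway <- cfg$torso_sway_px * sin(2 * pi * cfg$torso_sway_hz * tt)
    ids <- as.integer(names(sk))
    X <- sapply(ids, function(id) sk[[as.character(id)]][1] + sway)
    Y <- sapply(ids, function(id) rep(sk[[as.character(id)]][2],
                                      n_frames))
    # gesture motion on both hands, 45 degrees up and to the right for
    # both: the two-hand average trajectory (which the kinematic
    # features use) then carries the full analytic displacement
    dxy <- hand_disp / sqrt(2)
    X[, ids == 4] <- X[, ids == 4] + dxy
    X[, ids == 7] <- X[, ids == 7] + dxy
    Y[, ids == 4] <- Y[, ids == 4] - dxy
    Y[, ids == 7] <- Y[, ids == 7] - dxy
    X <- X + rnorm(length(X), 0, cfg$keypoint_noise_px)
    Y <- Y + rnorm(length(Y), 0, cfg$keypoint_noise_px)
    conf <- matrix(1, n_frames, length(ids))
    out$front <- keypoint_trajectory(X, Y, conf, cfg$fps, "front", ids)
    # side view: x = forward axis; hands reach forward during events
    side_ids <- c(4L, 7L, 8L)
    # hands rest at the hip plane, so event depth equals the reach truth
    sx <- matrix(rep(c(860, 860, 860), each = n_frames), n_frames, 3)
    sy <- matrix(rep(c(700, 700, 760), each = n_frames), n_frames, 3)
    reach <- numeric(n_frames)
    for (i in seq_len(nrow(ev))) {
      i0 <- round(ev$start_s[i] * cfg$fps) + 1L
      i1 <- min(round(ev$end_s[i] * cfg$fps) + 1L, n_frames)
      ramp <- sin(pi * seq(0, 1, length.out = i1 - i0 + 1L))
      reach[i0:i1] <- pmax(reach[i0:i1], depth[i] * ramp)
    }
    sx[, 1] <- sx[, 1] + reach
    sx[, 2] <- sx[, 2] + reach
    sx <- sx + rnorm(length(sx), 0, cfg$keypoint_noise_px)
    sy <- sy + rnorm(length(sy), 0, cfg$keypoint_noise_px)
    out$side <- keypoint_trajectory(sx, sy,
                                    matrix(1, n_frames, 3), cfg$fps,
                                    "side", side_ids)
  }
  if ("acoustics" %in% streams) {
    ta <- seq(0, total_s, by = 1 / cfg$acoustic_rate)
    speaking <- in_intervals(ta, speech_iv)
    grade <- blur_grade_at(schedule, ta)
    qg <- grade_quad_shape(grade, cfg$n_grades)
    gesturing <- assign_modality(ta, out$events) == "speech_with_gesture"
    # modality-specific blur lift is centred over grades so the modality
    # offset stays the marginal with-vs-without difference
    qc <- qg - mean(grade_quad_shape(seq_len(cfg$n_grades),
                                     cfg$n_grades))
    cell <- interaction(grade, gesturing)
    cell_eff_db <- rnorm(nlevels(cell), 0, cfg$cell_sd_db)[cell]
    cell_eff_hz <- rnorm(nlevels(cell), 0, cfg$cell_sd_hz)[cell]
    intensity <- cfg$intensity_base_db + re_dyad + re_participant +
      cfg$modality_intensity_offset_db * gesturing +
      cfg$intensity_blur_amp_db * qc * gesturing +
      cell_eff_db + rnorm(length(ta), 0, cfg$sample_sd_db)
    f0 <- cfg$f0_base_hz + f0_re +
      cfg$modality_f0_offset_hz * gesturing +
      cfg$f0_blur_amp_hz * qc * gesturing +
      cell_eff_hz + rnorm(length(ta), 0, cfg$sample_sd_hz)
    intensity[!speaking] <- NA_real_
    f0[!speaking] <- NA_real_
    out$acoustics <- data.frame(time = ta, intensity_db = intensity,
                                f0_hz = f0)
  }
  if ("envelope" %in% streams) {
    te <- seq(0, total_s, by = 1 / cfg$envelope_rate)
    speaking_e <- in_intervals(te, speech_iv)
    syll <- 0.5 + 0.4 * sin(2 * pi * cfg$syllable_rate_hz * te)
    hs <- approx(out$hand_speed$time, out$hand_speed$value,
                 xout = te - cfg$coupling_lag_ms / 1000, rule = 2)$y
    hs_max <- max(hs, 1e-9)
    env <- (syll + cfg$coupling_strength * hs / hs_max) * speaking_e +
      0.02 + 0.02 * abs(rnorm(length(te)))
    out$envelope <- data.frame(time = te, value = env)
    out$truth$expected_phase_ms <- -cfg$coupling_lag_ms
  }
  class(out) <- "synthetic_session"
  out
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session: %s, %d gestures, %s>\n",
              x$events$participant_id[1] %||% "?", nrow(x$events),
              format(x$schedule$direction)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Generate a full synthetic study on disk
#'
#' Writes one directory per participant (`d01p1/`, ...) holding the
#' input-format files the readers consume -- keypoints (`front.json`,
#' `side.csv`), annotations (`events.tsv`), acoustic series
#' (`acoustics.csv`), envelope (`envelope.csv`), schedule
#' (`schedule.yaml`) -- plus a study-level `truth.csv` with one row per
#' generated gesture.
#'
#' @param cfg a [generator_config()].
#' @param dir output directory (created).
#' @param streams passed to [generate_session()]; dropping
#'   `"keypoints"` skips trajectory synthesis, which dominates run time.
#' @param seed study-level seed; session seeds are derived from it.
#' @return invisible list: `dir`, `participants`, `truth` (data.frame).
#' @export
generate_study <- function(cfg, dir, streams = c("events", "keypoints",
                                                 "acoustics", "envelope"),
                           seed = cfg$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth_all <- list()
  participants <- character(0)
  for (d in seq_len(cfg$n_dyads)) {
    direction <- if (d %% 2 == 1) "clear_to_blur" else "blur_to_clear"
    dyad_id <- sprintf("d%02d", d)
    for (p in 1:2) {
      pid <- sprintf("%sp%d", dyad_id, p)
      ses <- generate_session(cfg, dyad_id, pid, direction,
                              seed = seed * 1000L + d * 10L + p,
                              streams = streams)
      pdir <- file.path(dir, pid)
      dir.create(pdir, showWarnings = FALSE)
      write_annotations(ses$events, file.path(pdir, "events.tsv"))
      yaml::write_yaml(list(n_grades = cfg$n_grades,
                            grade_duration_s = cfg$grade_duration_s,
                            direction = direction, fps = cfg$fps),
                       file.path(pdir, "schedule.yaml"))
      if (!is.null(ses$front))
        write_keypoints(ses$front, file.path(pdir, "front.json"))
      if (!is.null(ses$side))
        write_keypoints(ses$side, file.path(pdir, "side.csv"))
      if (!is.null(ses$acoustics))
        write.csv(ses$acoustics, file.path(pdir, "acoustics.csv"),
                  row.names = FALSE)
      if (!is.null(ses$envelope))
        write.csv(ses$envelope, file.path(pdir, "envelope.csv"),
                  row.names = FALSE)
      if (nrow(ses$truth$events))
        truth_all[[pid]] <- ses$truth$events
      participants <- c(participants, pid)
    }
  }
  truth <- do.call(rbind, truth_all)
  write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(dir = dir, participants = participants, truth = truth))
}

#' Simulate a per-event kinematic feature table from the statistical truth
#'
#' Draws gesture-level feature values directly from the generator's
#' statistical model (grade-quadratic fixed effect, dyad / participant /
#' gesture-type random intercepts, log-normal residual) without signal
#' synthesis. This is the fast path for calibration and power studies of
#' the model-comparison ladder.
#'
#' @param cfg a [generator_config()].
#' @param effect_amp quadratic effect amplitude on the log scale
#'   (0 simulates the null).
#' @param n_dyads,events_per_grade optionally override the study scale.
#' @param seed RNG seed.
#' @param response name of the simulated feature column.
#' @return data.frame: `dyad_id`, `participant_id`, `gesture_type`,
#'   `blur_grade`, `<response>` (positive, log-normal).
#' @export
simulate_feature_table <- function(cfg = generator_config(),
                                   effect_amp = cfg$size_quad_amp,
                                   n_dyads = cfg$n_dyads,
                                   events_per_grade = NULL, seed = 1L,
                                   response = "size_px2") {
  set.seed(seed)
  rate_events <- cfg$gesture_rate_per_min * cfg$grade_duration_s / 60
  type_re <- rnorm(length(cfg$gesture_type_probs), 0,
                   cfg$re_sd[["gesture_type"]])
  names(type_re) <- names(cfg$gesture_type_probs)
  rows <- list()
  for (d in seq_len(n_dyads)) {
    dyad_re <- rnorm(1, 0, cfg$re_sd[["dyad"]])
    for (p in 1:2) {
      part_re <- rnorm(1, 0, 0.3)
      pid <- sprintf("d%02dp%d", d, p)
      for (g in seq_len(cfg$n_grades)) {
        n <- if (is.null(events_per_grade))
          rpois(1, rate_events) else events_per_grade
        if (n == 0) next
        types <- sample(names(cfg$gesture_type_probs), n, replace = TRUE,
                        prob = cfg$gesture_type_probs)
        q <- grade_quad_shape(g, cfg$n_grades)
        mu <- log(cfg$pulse_amplitude_px^2) + 0.1 * dyad_re + part_re +
          type_re[types] + effect_amp * q
        rows[[length(rows) + 1L]] <- data.frame(
          dyad_id = sprintf("d%02d", d), participant_id = pid,
          gesture_type = types, blur_grade = g,
          value = exp(mu + rnorm(n, 0, 0.5)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "value"] <- response
  out
}
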