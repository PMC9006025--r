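GESTURE_TYPES <- c("representational", "pragmatic", "interactive",
                   "emblem", "deictic")

#' Blur schedule
#'
#' The stepped visual-degradation schedule: `n_grades` contiguous windows of
#' `grade_duration_s` seconds each. Grade 1 is the clearest image and grade
#' `n_grades` the most blurred; under `direction = "clear_to_blur"` the
#' session starts clear (window 1 -> grade 1), under `"blur_to_clear"` it
#' starts fully blurred (window 1 -> grade `n_grades`).
#'
#' @param n_grades number of blur steps (default 10).
#' @param grade_duration_s seconds per step (default 240).
#' @param direction `"clear_to_blur"` or `"blur_to_clear"`.
#' @return object of class `blur_schedule`.
#' @export
blur_schedule <- function(n_grades = 10L, grade_duration_s = 240,
                          direction = c("clear_to_blur", "blur_to_clear")) {
  direction <- match.arg(direction)
  stopifnot(n_grades >= 1, grade_duration_s > 0)
  structure(list(n_grades = as.integer(n_grades),
                 grade_duration_s = grade_duration_s,
                 direction = direction,
                 session_length_s = n_grades * grade_duration_s),
            class = "blur_schedule")
}

#' @export
print.blur_schedule <- function(x, ...) {
  cat(sprintf("<blur_schedule: %d grades x %g s, %s (%g s total)>\n",
              x$n_grades, x$grade_duration_s, x$direction,
              x$session_length_s))
  invisible(x)
}

#' Blur grade at given session times
#'
#' Maps times (seconds from session start) to blur grades by the schedule's
#' contiguous windows. Times at a window boundary belong to the later
#' window; times at or beyond session end are clamped into the last window.
#'
#' @param schedule a [blur_schedule()].
#' @param time_s numeric vector of session times in seconds.
#' @return integer vector of blur grades in `1:n_grades`.
#' @export
blur_grade_at <- function(schedule, time_s) {
  w <- pmin(pmax(floor(time_s / schedule$grade_duration_s) + 1L, 1L),
            schedule$n_grades)
  if (schedule$direction == "blur_to_clear")
    w <- schedule$n_grades + 1L - w
  as.integer(w)
}

#' Read gesture-event annotations
#'
#' Reads an ELAN-export-like TSV with columns `start`, `end`, `type`,
#' `participant`, `dyad` (times in seconds). Events are sorted by start
#' time and assigned a blur grade from the schedule by their midpoint
#' (events may straddle a window boundary). Overlapping events for the
#' same participant produce a warning but are kept.
#'
#' @param path TSV path.
#' @param schedule a [blur_schedule()] used for grade assignment.
#' @return data.frame of class `gesture_events` with columns `start_s`,
#'   `end_s`, `gesture_type`, `participant_id`, `dyad_id`, `blur_grade`.
#' @export
read_annotations <- function(path, schedule) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("start", "end", "type", "participant", "dyad")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("annotation TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  gesture_events(start_s = d$start, end_s = d$end, gesture_type = d$type,
                 participant_id = d$participant, dyad_id = d$dyad,
                 schedule = schedule)
}

#' Construct a gesture-event table
#'
#' @param start_s,end_s event boundaries in seconds (`end_s > start_s`).
#' @param gesture_type one of `representational`, `pragmatic`,
#'   `interactive`, `emblem`, `deictic`.
#' @param participant_id,dyad_id identifiers.
#' @param schedule optional [blur_schedule()]; when given, `blur_grade` is
#'   assigned from the event midpoint.
#' @param blur_grade explicit grades (used when no schedule is given).
#' @return sorted data.frame of class `gesture_events`.
#' @export
gesture_events <- function(start_s, end_s, gesture_type, participant_id,
                           dyad_id, schedule = NULL, blur_grade = NA_integer_) {
  if (!length(start_s)) {
    d <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    gesture_type = character(0),
                    participant_id = character(0),
                    dyad_id = character(0), blur_grade = integer(0),
                    stringsAsFactors = FALSE)
    class(d) <- c("gesture_events", "data.frame")
    return(d)
  }
  if (any(end_s <= start_s)) stop("event end must be after start")
  bad <- setdiff(unique(gesture_type), GESTURE_TYPES)
  if (length(bad)) stop("unknown gesture type(s): ",
                        paste(bad, collapse = ", "))
  d <- data.frame(start_s = start_s, end_s = end_s,
                  gesture_type = gesture_type,
                  participant_id = as.character(participant_id),
                  dyad_id = as.character(dyad_id),
                  blur_grade = as.integer(blur_grade),
                  stringsAsFactors = FALSE)
  if (!is.null(schedule))
    d$blur_grade <- blur_grade_at(schedule, (d$start_s + d$end_s) / 2)
  d <- d[order(d$start_s), , drop = FALSE]
  rownames(d) <- NULL
  for (p in unique(d$participant_id)) {
    e <- d[d$participant_id == p, ]
    if (nrow(e) > 1 && any(e$start_s[-1] < e$end_s[-nrow(e)]))
      warning("overlapping gesture events for participant ", p,
              " (kept)", call. = FALSE)
  }
  class(d) <- c("gesture_events", "data.frame")
  d
}

#' Write gesture events as annotation TSV
#' @param events a `gesture_events` table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path) {
  out <- data.frame(start = events$start_s, end = events$end_s,
                    type = events$gesture_type,
                    participant = events$participant_id,
                    dyad = events$dyad_id)
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Label speech samples by gesture co-occurrence
#'
#' Splits speech time into the two modality streams: a sample is
#' `speech_with_gesture` when it falls inside any gesture event of the same
#' participant, else `speech_only`. Sample times and event times must share
#' the session clock; a declared clock drift larger than one frame is
#' rejected.
#'
#' @param times numeric vector of sample times (seconds, session clock).
#' @param events a `gesture_events` table (one participant's events).
#' @param clock_drift_s declared audio/video clock drift in seconds.
#' @param frame_s duration of one video frame (drift tolerance unit).
#' @return character vector (`"speech_only"` / `"speech_with_gesture"`)
#'   parallel to `times`.
#' @export
assign_modality <- function(times, events, clock_drift_s = 0,
                            frame_s = 1 / 25) {
  if (abs(clock_drift_s) > frame_s)
    stop("audio/video clock drift exceeds one frame; resynchronize first")
  lab <- rep("speech_only", length(times))
  if (nrow(events)) {
    # membership via sorted boundary scan; events may overlap
    for (i in seq_len(nrow(events))) {
      inside <- times >= events$start_s[i] & times <= events$end_s[i]
      lab[inside] <- "speech_with_gesture"
    }
  }
  lab
}
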