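# Speech acoustics: amplitude envelope, framewise intensity and F0.
# The dB reference is the conventional 2e-5 on the normalized full scale;
# absolute calibration is irrelevant because every analysis is a
# within-recording contrast.

DB_REF <- 2e-5

hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' Speech amplitude envelope
#'
#' Magnitude of the analytic (Hilbert) signal, low-pass filtered and
#' resampled to a slow analysis rate. The default 8 Hz low-pass keeps the
#' syllabic modulation that carries speech rhythm while discarding the
#' carrier.
#'
#' @param samples mono audio on full scale, or a list as from [read_wav()].
#' @param sample_rate audio sampling rate (ignored when `samples` is a
#'   `read_wav()` list).
#' @param target_rate output envelope rate in Hz (default 100).
#' @param lowpass_hz envelope low-pass cut-off (default 8).
#' @return data.frame with columns `time` (s) and `envelope` (linear
#'   amplitude, >= 0).
#' @export
amplitude_envelope <- function(samples, sample_rate = NULL,
                               target_rate = 100, lowpass_hz = 8) {
  if (is.list(samples)) {
    sample_rate <- samples$sample_rate; samples <- samples$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required")
  if (!length(samples)) stop("empty audio")
  if (max(abs(samples)) >= 1)
    warning("audio at or beyond full scale; possible clipping")
  env <- hilbert_envelope(samples - mean(samples))
  wn <- lowpass_hz / (sample_rate / 2)
  if (wn < 1) {
    bf <- signal::butter(3, wn, type = "low")
    env <- signal::filtfilt(bf, env)
  }
  env[env < 0] <- 0
  t_in <- (seq_along(env) - 1) / sample_rate
  t_out <- seq(0, t_in[length(t_in)], by = 1 / target_rate)
  data.frame(time = t_out,
             envelope = approx(t_in, env, xout = t_out, rule = 2)$y)
}

frame_starts <- function(n, sr, frame_s, hop_s) {
  flen <- max(2L, round(frame_s * sr))
  hop <- max(1L, round(hop_s * sr))
  starts <- seq(1L, n - flen + 1L, by = hop)
  list(starts = starts, flen = flen)
}

#' Framewise intensity track
#'
#' Short-time intensity in dB: `10 log10(mean square / ref^2)` over 30 ms
#' frames with a 10 ms hop.
#'
#' @inheritParams amplitude_envelope
#' @param frame_s,hop_s frame length and hop in seconds.
#' @return data.frame with `time` (frame centre, s) and `intensity_db`.
#' @export
intensity_track <- function(samples, sample_rate = NULL, frame_s = 0.03,
                            hop_s = 0.01) {
  if (is.list(samples)) {
    sample_rate <- samples$sample_rate; samples <- samples$samples
  }
  fr <- frame_starts(length(samples), sample_rate, frame_s, hop_s)
  idb <- vapply(fr$starts, function(s) {
    seg <- samples[s:(s + fr$flen - 1L)]
    ms <- mean(seg^2)
    if (ms <= 0) -Inf else 10 * log10(ms / DB_REF^2)
  }, numeric(1))
  data.frame(time = (fr$starts - 1 + fr$flen / 2) / sample_rate,
             intensity_db = idb)
}

#' Maximum intensity in a window
#'
#' @inheritParams intensity_track
#' @param window `c(start_s, end_s)`; `NULL` means the whole recording.
#' @return maximum framewise intensity in dB; `-Inf` (with a warning) for
#'   an all-zero window.
#' @export
max_intensity_db <- function(samples, sample_rate = NULL, window = NULL,
                             frame_s = 0.03, hop_s = 0.01) {
  tr <- intensity_track(samples, sample_rate, frame_s, hop_s)
  if (!is.null(window))
    tr <- tr[tr$time >= window[1] & tr$time <= window[2], , drop = FALSE]
  if (!nrow(tr)) stop("window outside audio")
  m <- max(tr$intensity_db)
  if (!is.finite(m)) warning("silent window: intensity undefined (-Inf)")
  m
}

# Normalized autocorrelation F0 estimate for one frame. Subharmonic
# (octave-down) errors are avoided by taking the *shortest* lag whose peak
# is within peak_slack of the strongest peak.
acf_f0_frame <- function(seg, sr, fmin, fmax, voicing_threshold = 0.45,
                         peak_slack = 0.85) {
  seg <- seg - mean(seg)
  e0 <- sum(seg^2)
  if (e0 <= 0) return(NA_real_)
  lag_min <- max(2L, floor(sr / fmax))
  lag_max <- min(length(seg) - 2L, ceiling(sr / fmin))
  if (lag_max <= lag_min) return(NA_real_)
  n <- length(seg)
  ac <- vapply(lag_min:lag_max, function(l)
    sum(seg[1:(n - l)] * seg[(l + 1):n]) /
      sqrt(sum(seg[1:(n - l)]^2) * sum(seg[(l + 1):n]^2)), numeric(1))
  lags <- lag_min:lag_max
  i <- which(ac >= c(-Inf, head(ac, -1)) & ac >= c(ac[-1], -Inf))
  peaks <- i[ac[i] >= voicing_threshold]
  if (!length(peaks)) return(NA_real_)
  best <- max(ac[peaks])
  cand <- peaks[ac[peaks] >= peak_slack * best]
  j <- cand[1]
  # parabolic interpolation around the chosen peak
  if (j > 1 && j < length(ac)) {
    y1 <- ac[j - 1]; y2 <- ac[j]; y3 <- ac[j + 1]
    denom <- y1 - 2 * y2 + y3
    d <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
  } else d <- 0
  sr / (lags[j] + d)
}

#' Framewise F0 track
#'
#' Autocorrelation pitch tracker bounded to `[fmin, fmax]`; frames whose
#' normalized autocorrelation peak falls below the voicing threshold are
#' unvoiced (`NA`).
#'
#' @inheritParams amplitude_envelope
#' @param fmin,fmax F0 search band in Hz (defaults 75-500).
#' @param frame_s,hop_s frame length and hop in seconds.
#' @param voicing_threshold minimum normalized autocorrelation peak for a
#'   frame to count as voiced.
#' @return data.frame with `time` and `f0_hz` (`NA` where unvoiced).
#' @export
f0_track <- function(samples, sample_rate = NULL, fmin = 75, fmax = 500,
                     frame_s = 0.04, hop_s = 0.01,
                     voicing_threshold = 0.45) {
  if (is.list(samples)) {
    sample_rate <- samples$sample_rate; samples <- samples$samples
  }
  fr <- frame_starts(length(samples), sample_rate, frame_s, hop_s)
  f0 <- vapply(fr$starts, function(s)
    acf_f0_frame(samples[s:(s + fr$flen - 1L)], sample_rate, fmin, fmax,
                 voicing_threshold), numeric(1))
  data.frame(time = (fr$starts - 1 + fr$flen / 2) / sample_rate,
             f0_hz = f0)
}

#' Maximum F0 in a window
#'
#' @inheritParams f0_track
#' @param window `c(start_s, end_s)`; `NULL` means the whole recording.
#' @return maximum F0 (Hz) over voiced frames; `NA` when no frame is
#'   voiced.
#' @export
max_f0 <- function(samples, sample_rate = NULL, window = NULL, fmin = 75,
                   fmax = 500, frame_s = 0.04, hop_s = 0.01,
                   voicing_threshold = 0.45) {
  tr <- f0_track(samples, sample_rate, fmin, fmax, frame_s, hop_s,
                 voicing_threshold)
  if (!is.null(window))
    tr <- tr[tr$time >= window[1] & tr$time <= window[2], , drop = FALSE]
  if (!nrow(tr)) stop("window outside audio")
  if (all(is.na(tr$f0_hz))) return(NA_real_)
  max(tr$f0_hz, na.rm = TRUE)
}

#' Per-grade, per-modality acoustic means
#'
#' Splits an acoustic time series into the speech-with-gesture and
#' speech-only streams (see [assign_modality()]) and averages each per
#' blur grade.
#'
#' @param series data.frame with columns `time` plus one or more acoustic
#'   value columns (e.g. `intensity_db`, `f0_hz`); `NA` values (unvoiced
#'   frames, silence) are dropped from the means.
#' @param events `gesture_events` for the same participant.
#' @param schedule a [blur_schedule()].
#' @param participant_id,dyad_id identifiers copied into the output.
#' @return long data.frame: `participant_id`, `dyad_id`, `blur_grade`,
#'   `modality`, one `mean_<col>` per value column, `n_samples`. Grades
#'   with no usable samples yield no row.
#' @export
acoustics_by_grade <- function(series, events, schedule,
                               participant_id = "p1", dyad_id = "d1") {
  value_cols <- setdiff(names(series), "time")
  grade <- blur_grade_at(schedule, series$time)
  modality <- assign_modality(series$time, events)
  out <- list()
  for (g in sort(unique(grade))) for (m in unique(modality)) {
    sel <- grade == g & modality == m
    if (!any(sel)) next
    row <- data.frame(participant_id = participant_id, dyad_id = dyad_id,
                      blur_grade = g, modality = m,
                      stringsAsFactors = FALSE)
    n_ok <- 0L
    for (v in value_cols) {
      vals <- series[[v]][sel]
      vals <- vals[is.finite(vals)]
      row[[paste0("mean_", v)]] <- if (length(vals)) mean(vals) else NA_real_
      n_ok <- max(n_ok, length(vals))
    }
    row$n_samples <- n_ok
    if (n_ok > 0) out[[length(out) + 1L]] <- row
  }
  do.call(rbind, out)
}
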