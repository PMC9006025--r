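# Continuous Morlet wavelet machinery for speech-gesture coupling.
# The analysis band is 2-8 Hz (periods 500 ms down to 125 ms), the
# syllable-rate band in which speech rhythm and gesture velocity co-occur.

MORLET_OMEGA0 <- 6
# Fourier factor: period per unit scale for the omega0 = 6 Morlet
morlet_fourier_factor <- function(omega0 = MORLET_OMEGA0)
  4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Wavelet scale grid for a frequency band
#'
#' Log-spaced periods whose extremes equal the band's period bounds
#' exactly: the default 2-8 Hz band gives periods from 125 to 500 ms.
#'
#' @param band `c(fmin, fmax)` in Hz.
#' @param n_scales number of scales (log-spaced in period).
#' @return data.frame: `period` (s), `frequency` (Hz), `scale` (Morlet
#'   scale units).
#' @export
wavelet_scales <- function(band = c(2, 8), n_scales = 16L) {
  periods <- exp(seq(log(1 / band[2]), log(1 / band[1]),
                     length.out = n_scales))
  data.frame(period = periods, frequency = 1 / periods,
             scale = periods / morlet_fourier_factor())
}

# CWT of a real series via FFT; returns n x n_scales complex matrix
morlet_cwt <- function(x, dt, scales) {
  n <- length(x)
  npad <- nextn(n, 2)
  xp <- c(x - mean(x), rep(0, npad - n))
  X <- fft(xp)
  omega <- 2 * pi * c(0:(npad / 2), -((npad / 2 - 1):1)) / (npad * dt)
  W <- matrix(0i, n, length(scales))
  for (j in seq_along(scales)) {
    s <- scales[j]
    psi <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-(s * omega - MORLET_OMEGA0)^2 / 2) * (omega > 0)
    w <- fft(X * psi, inverse = TRUE) / npad
    W[, j] <- w[seq_len(n)]
  }
  W
}

# Gaussian smoothing in time (width proportional to scale) and a 3-point
# boxcar across scales, applied to a (possibly complex) field.
smooth_field <- function(F, dt, scales) {
  n <- nrow(F)
  for (j in seq_along(scales)) {
    s <- scales[j] / dt
    half <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    re <- stats::filter(c(rep(0, half), Re(F[, j]), rep(0, half)), k,
                        sides = 2)
    im <- stats::filter(c(rep(0, half), Im(F[, j]), rep(0, half)), k,
                        sides = 2)
    F[, j] <- complex(real = re[(half + 1):(half + n)],
                      imaginary = im[(half + 1):(half + n)])
  }
  if (length(scales) >= 3) {
    G <- F
    for (j in seq_along(scales)) {
      jj <- max(1, j - 1):min(length(scales), j + 1)
      G[, j] <- rowMeans(F[, jj, drop = FALSE])
    }
    F <- G
  }
  F
}

#' Merge kinematic and acoustic streams onto a common clock
#'
#' Linearly resamples both series to a common rate over their shared
#' window and z-scores each (per event). Degenerate (constant) series are
#' flagged rather than z-scored.
#'
#' @param x,y data.frames with columns `time` and `value` (e.g. hand
#'   speed and speech envelope).
#' @param rate common rate in Hz (>= 32 recommended for the 2-8 Hz band).
#' @param window optional `c(start_s, end_s)`; defaults to the overlap of
#'   the two series.
#' @return data.frame of class `merged_pair`: `time`, `x`, `y`;
#'   attributes `rate` and `degenerate`.
#' @export
merge_streams <- function(x, y, rate = 32, window = NULL) {
  if (is.null(window))
    window <- c(max(min(x$time), min(y$time)),
                min(max(x$time), max(y$time)))
  if (window[2] <= window[1]) stop("streams do not overlap in time")
  if (min(x$time) > window[1] + 1e-9 || max(x$time) < window[2] - 1e-9 ||
      min(y$time) > window[1] + 1e-9 || max(y$time) < window[2] - 1e-9)
    stop("coverage gap: a stream does not span the requested window")
  t_out <- seq(window[1], window[2], by = 1 / rate)
  zx <- approx(x$time, x$value, xout = t_out)$y
  zy <- approx(y$time, y$value, xout = t_out)$y
  degenerate <- sd(zx) == 0 || sd(zy) == 0
  z <- function(v) if (sd(v) > 0) (v - mean(v)) / sd(v) else v - mean(v)
  out <- data.frame(time = t_out, x = z(zx), y = z(zy))
  attr(out, "rate") <- rate
  attr(out, "degenerate") <- degenerate
  class(out) <- c("merged_pair", "data.frame")
  out
}

#' Cross-wavelet coherence and phase
#'
#' Morlet cross-wavelet analysis of a merged pair: the cross-spectrum is
#' smoothed over time (Gaussian, width proportional to scale) and scale
#' (3-point boxcar) and normalized by the smoothed auto-spectra, giving
#' squared coherence in `[0, 1]` and a phase angle per (time, scale)
#' cell. Positive phase means the `x` stream leads.
#'
#' @param pair a `merged_pair` from [merge_streams()].
#' @param band `c(fmin, fmax)` in Hz (default 2-8).
#' @param n_scales scales spanning the band.
#' @return list of class `cross_wavelet`: `time`, `scales` (data.frame
#'   from [wavelet_scales()]), `coherence` and `phase` (n x n_scales
#'   matrices), `rate`.
#' @export
cross_wavelet <- function(pair, band = c(2, 8), n_scales = 16L) {
  rate <- attr(pair, "rate")
  dt <- 1 / rate
  dur <- nrow(pair) * dt
  if (dur < 2 / band[1]) {
    fmin_ok <- 2 / dur
    warning(sprintf(
      "window too short for %g Hz; band truncated to [%.2f, %g] Hz",
      band[1], fmin_ok, band[2]))
    band <- c(fmin_ok, band[2])
  }
  sc <- wavelet_scales(band, n_scales)
  Wx <- morlet_cwt(pair$x, dt, sc$scale)
  Wy <- morlet_cwt(pair$y, dt, sc$scale)
  S12 <- smooth_field(Wx * Conj(Wy), dt, sc$scale)
  S11 <- Re(smooth_field(Mod(Wx)^2 + 0i, dt, sc$scale))
  S22 <- Re(smooth_field(Mod(Wy)^2 + 0i, dt, sc$scale))
  coh <- Mod(S12)^2 / (S11 * S22)
  coh[!is.finite(coh)] <- 0
  coh[coh > 1] <- 1
  structure(list(time = pair$time, scales = sc, coherence = coh,
                 phase = Arg(S12), power = Mod(S12), rate = rate),
            class = "cross_wavelet")
}

#' @export
print.cross_wavelet <- function(x, ...) {
  cat(sprintf(
    "<cross_wavelet: %d samples x %d scales (%.3g-%.3g Hz), mean coherence %.2f>\n",
    length(x$time), nrow(x$scales), min(x$scales$frequency),
    max(x$scales$frequency), mean(x$coherence)))
  invisible(x)
}

# phase-randomized surrogate preserving the amplitude spectrum
phase_randomize <- function(v) {
  n <- length(v)
  V <- fft(v)
  half <- floor((n - 1) / 2)
  ph <- runif(half, 0, 2 * pi)
  rot <- rep(1 + 0i, n)
  rot[2:(half + 1)] <- exp(1i * ph)
  rot[n:(n - half + 1)] <- Conj(rot[2:(half + 1)])
  Re(fft(V * rot, inverse = TRUE) / n)
}

#' Surrogate significance mask for cross-wavelet coherence
#'
#' Builds a cell-wise null distribution by recomputing coherence on
#' surrogate pairs (both streams phase-randomized independently,
#' preserving their amplitude spectra) and returns the mask of cells whose
#' observed coherence exceeds the null at `p < alpha`
#' (`p = (1 + #{surrogate >= observed}) / (n + 1)`).
#'
#' @param pair a `merged_pair`.
#' @param n_surrogates number of surrogate pairs (>= 100).
#' @param seed RNG seed fixing the surrogate draw.
#' @param alpha cell-wise significance level.
#' @inheritParams cross_wavelet
#' @return list of class `coherence_mask`: the observed `cw`
#'   (`cross_wavelet`), `p` (matrix), `mask` (logical matrix), `alpha`,
#'   `n_surrogates`.
#' @export
significance_mask <- function(pair, n_surrogates = 300L, seed = 1L,
                              alpha = 0.05, band = c(2, 8),
                              n_scales = 16L) {
  if (n_surrogates < 100L) stop("need at least 100 surrogates")
  cw <- suppressWarnings(cross_wavelet(pair, band, n_scales))
  exceed <- matrix(0L, nrow(cw$coherence), ncol(cw$coherence))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (b in seq_len(n_surrogates)) {
    sp <- pair
    sp$x <- phase_randomize(pair$x)
    sp$y <- phase_randomize(pair$y)
    attr(sp, "rate") <- attr(pair, "rate")
    sc <- suppressWarnings(cross_wavelet(sp, band, n_scales))
    exceed <- exceed + (sc$coherence >= cw$coherence)
  }
  p <- (1 + exceed) / (n_surrogates + 1)
  structure(list(cw = cw, p = p, mask = p < alpha, alpha = alpha,
                 n_surrogates = n_surrogates),
            class = "coherence_mask")
}

#' Summarize significant coupling for one event
#'
#' Mean coherence over significant cells, and the phase asynchrony in ms:
#' within each scale the cross-power-weighted circular mean of
#' significant-cell phases is converted to time via
#' `dt = phase / (2 pi f)` at that scale's frequency, and scales are
#' combined weighted by their significant cross-power. Power weighting
#' matters because a narrowband signal is coherent at every scale but its
#' phase tracks the signal's own frequency; weighting by cross-power
#' concentrates the summary on the scales that carry it. Positive
#' asynchrony means the `x` stream (speech, by the package's convention)
#' leads. An event with an empty mask contributes no row.
#'
#' @param masked a `coherence_mask` from [significance_mask()].
#' @param event_id identifier copied into the output.
#' @return one-row data.frame (`event_id`, `coherence`,
#'   `phase_asynchrony_ms`, `n_significant_cells`) or `NULL` when no cell
#'   is significant.
#' @export
summarize_alignment <- function(masked, event_id = 1L) {
  cw <- masked$cw
  if (!any(masked$mask)) return(NULL)
  coh <- mean(cw$coherence[masked$mask])
  ms_by_scale <- numeric(0); wts <- numeric(0)
  for (j in seq_len(ncol(masked$mask))) {
    sel <- masked$mask[, j]
    if (!any(sel)) next
    w <- cw$power[sel, j]
    phi <- Arg(sum(w * exp(1i * cw$phase[sel, j])))  # circular mean
    f <- cw$scales$frequency[j]
    ms_by_scale <- c(ms_by_scale, phi / (2 * pi * f) * 1000)
    wts <- c(wts, sum(w))
  }
  data.frame(event_id = event_id, coherence = coh,
             phase_asynchrony_ms = sum(ms_by_scale * wts) / sum(wts),
             n_significant_cells = sum(masked$mask))
}
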