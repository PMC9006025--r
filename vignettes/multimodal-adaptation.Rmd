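---
title: "Quantifying multimodal adaptation to degraded visibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying multimodal adaptation to degraded visibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gesturekit)
```

## The scientific problem

When two people converse over a video link whose image quality degrades in
steps, both channels of their communication system can adapt: the visual
channel (co-speech hand gestures, and bodily movement more broadly) and the
auditory channel (speech acoustics). `gesturekit` implements a multi-scale
analysis of that adaptation for dyadic conversation under a stepped
Gaussian-blur schedule — ten grades of 240 s each, run clear-to-blur for
half the dyads and blur-to-clear for the other half — at three levels:

* **articulator level** — motion energy of torso, head, arms and fingers,
  with reference-articulator correction;
* **system level** — cross-wavelet coherence and phase asynchrony between
  the speech amplitude envelope and hand velocity in the 2–8 Hz band;
* **signal level** — per-gesture kinematic features (peak velocity,
  submovements, hold-time, size, McNeillian space, depth, nPVI), gesture
  rate, and speech acoustics (maximum intensity, maximum F0) split into
  speech-with-gesture and speech-only streams.

A polynomial mixed-model comparison ladder then asks, for each feature,
whether blur grade has a (second-order) effect, and the speech analyses add
a modality main effect, a blur × modality interaction, and kinetic-confound
models. Because the motivating study's raw audio/video recordings are not
redistributable, the package ships a synthetic dyad generator with known
ground truth; every stage of the pipeline is validated against it.

## Input data model

Keypoint trajectories follow the 25-point pose-tracker body map (0 = nose,
1 = upper torso/sternum, 2/5 = shoulders, 4/7 = hands, 8 = mid-hip), with
finger tips appended as ids 25–29 (right) and 30–34 (left). Coordinates
are pixels, origin top-left, y increasing downward; time is seconds from
session start with a 0-based frame index. Two on-disk encodings round-trip
losslessly: a per-frame JSON dialect (one object per frame with a flat
`[x, y, c]` triplet per keypoint) and a flat CSV. Gesture annotations are
ELAN-export-like TSVs (`start`, `end`, `type`, `participant`, `dyad`) with
a closed five-way gesture typology (representational, pragmatic,
interactive, emblem, deictic). Audio is mono WAV (PCM16 or float32); all
analyses are within-recording contrasts, so samples stay on the
normalized full scale with the conventional 2×10⁻⁵ dB reference.

Tracking confidence below 0.3 marks a sample missing; gaps up to 0.5 s are
bridged by linear interpolation and longer gaps are left missing and
flagged. The source study does not document its missing-data policy, so
both numbers are configurable arguments of `read_keypoints()`; the
defaults are ordinary practice for 25–30 fps pose tracking.

Events are mapped to blur grades by their midpoint — an event may straddle
a grade boundary, and the midpoint is the least arbitrary single label.
Reversing the schedule direction exactly reverses the grade labels, which
the tests assert as an invariant.

## Motion energy

Motion energy of an articulator over a window is the summed frame-to-frame
displacement magnitude of its (corrected) position. Two decisions are
deliberately explicit because the verbal definition under-determines them:

* **Magnitude.** The per-frame step is the Euclidean norm ‖Δ(x, y)‖ by
  default (rotation-invariant); `|Δx| + |Δy|` is available behind the
  `metric` argument since the field's verbal phrasing ("difference in x, y
  values") admits either reading.
* **Correction.** Head, arms and fingers are corrected by subtracting the
  reference articulator's position *before* differencing (head and arms by
  the torso, each hand's finger tips by that hand). Subtracting positions,
  rather than subtracting energies, keeps energy non-negative and nulls
  rigid common motion *exactly*: a whole-body translation leaves corrected
  head/arm/finger energy at literal zero while torso energy is positive.
  The tests pin this identity down, along with translation invariance and
  additivity over window partitions.

Left and right arm (and finger) energies are computed per side and then
averaged, matching the reported left/right averaging.

## Gesture kinematics

Hand positions (keypoints 4 and 7) are low-pass filtered with a 3rd-order
Butterworth at 10 Hz before differencing — tracking noise at 25 fps
otherwise dominates the velocity signal. Two implementation notes matter
for reproducibility: the filter is applied forward-backward for zero phase
lag, the series is demeaned and endpoint-padded first (pixel coordinates
carry a large DC offset that otherwise rings at Nyquist), and speed is
‖Δposition‖ × fps. Features are computed on the two-hand average
trajectory, except size (union of both hands) and gesture space (most
extreme hand).

* **Submovements** are velocity peaks above 15% of the event's peak speed,
  separated by local minima below 0.5 of the smaller adjacent peak;
  adjacent peaks failing the valley criterion fuse into one ballistic
  unit. The original thresholds live in unpublished analysis code, so
  these are declared defaults (both configurable), chosen to be robust on
  noisy pixel data; the acceptance tests show they recover generated pulse
  counts exactly without noise and at ≥ 95% accuracy under 1 px noise.
* **Hold-time** sums still runs (speed < 10% of peak for ≥ 0.2 s) between
  the first movement onset and last offset, so rest before and after the
  gesture never counts. A minimum-jerk pulse of duration T spends ~8% of T
  below the 10% threshold at each tail, which is why recovered hold-times
  sit within about one frame per boundary of the generated gap time.
* **Size** is the x-extent × y-extent of the union of both hands'
  positions relative to the sternum. With two hands this box includes the
  static inter-hand separation; the generator's truth record uses the same
  definition, so recovery is tested like-for-like.
* **McNeillian space** realizes the concentric scheme as nested boxes
  normalized to body size: centre-centre = sternum ± 0.25 shoulder-width
  (x) and ± 0.25 neck-to-hip (y); centre = twice that box; periphery =
  the box bounded by the shoulders horizontally (± 1 shoulder-width) and
  by head and hips vertically; beyond is extra-periphery. Points exactly
  on a boundary go outward. A gesture is summarized by the most extreme
  region either hand visits — the mapping from a frame-wise category
  series to one label per gesture is not spelled out in the source, and
  "most extreme region visited" is the reading consistent with reporting
  a probability of peripheral use per gesture.
* **Depth** is the side-view maximum of |two-hand mean x − hip x|, so it
  captures forward reach and forward torso lean together; a missing side
  view yields `NA` flagged absent, never zero.
* **nPVI** is `100/(m−1) Σ |dₖ−dₖ₊₁| / ((dₖ+dₖ₊₁)/2)` over successive
  submovement durations; it is undefined (flagged missing) for fewer than
  two durations.
* **VIF.** The collinearity screen computes `1/(1−R²ⱼ)` as the diagonal of
  the inverse correlation matrix and flags values above 3; a test
  cross-checks it against `car::vif`.

## Speech acoustics

The amplitude envelope is the magnitude of the analytic (Hilbert) signal,
low-passed at 8 Hz and resampled to 100 Hz — this keeps the syllabic
modulation that the coupling analysis needs. Intensity is framewise
`10·log₁₀(mean-square/ref²)` over 30 ms frames with a 10 ms hop; maximum
intensity is the frame maximum in the window, `−Inf`-flagged for silence.
F0 comes from a normalized-autocorrelation tracker bounded to 75–500 Hz
(40 ms frames, 10 ms hop, voicing threshold 0.45); among autocorrelation
peaks within 85% of the strongest, the shortest lag wins, which suppresses
octave-down errors (< 1% on synthetic pulse trains across 100–400 Hz, an
asserted property). The modality split is sample-wise: a sample is
speech-with-gesture when it overlaps any of the speaker's gesture events.
Per-grade means are taken per participant × grade × modality, dropping
unvoiced/silent samples.

## Speech–gesture coupling

Hand speed and envelope are linearly resampled onto a common ≥ 32 Hz grid
over the event window and z-scored per event. The cross-wavelet analysis
uses a complex Morlet mother (ω₀ = 6) on a log-spaced scale grid whose
extreme periods equal the band bounds exactly (125–500 ms for 2–8 Hz).
Coherence is the smoothed cross-spectrum normalized by the smoothed
auto-spectra, with Gaussian time-smoothing (width proportional to scale)
and a 3-point boxcar across scales; a signal's coherence with itself is 1
up to smoothing error.

Significance is assessed cell-wise against surrogate pairs — both streams
phase-randomized independently, preserving their amplitude spectra — with
`p = (1 + #{surrogate ≥ observed})/(n + 1)` and a default n = 300, all
under a fixed seed. Under independence the significant-cell fraction sits
at the nominal 5% (a calibration the acceptance suite measures over 200
noise pairs).

Per-event summaries average coherence over significant cells. Phase is
converted to milliseconds at each cell's own frequency and aggregated by a
**cross-power-weighted** circular mean within scale, then across scales
weighted by significant cross-power. The power weighting is the one
non-obvious choice: a narrowband signal is coherent at *every* scale, but
its wavelet phase tracks the signal's own frequency, so an unweighted
average across scales converts phase at the wrong frequencies and biases
the ms value by ~15%; weighting by cross-power concentrates the summary on
scales that actually carry signal and brings a 50 ms injected lag back
within ~2 ms. The sign convention is positive = first stream (speech)
leads. How the original analysis aggregated cell values per event is not
described; this choice is declared, not inferred.

## Statistical ladder

Blur grade always enters as an orthogonal second-order polynomial
(`poly(blur_grade, 2)`), so linear and quadratic terms are decorrelated.
All LRTs compare maximum-likelihood (not REML) fits — the standard
validity condition for fixed-effect likelihood-ratio tests. The random
structure starts from nested dyad/participant intercepts, tests a
gesture-type intercept by LRT, and substitutes a single global participant
factor when the nested fit is singular or fails to converge.

The ladder fits random-effects-only, linear, and quadratic models. Its
headline p is the quadratic-vs-null LRT (2 df); the quadratic-vs-linear
LRT (1 df) is reported alongside, and a "quadratic effect" is declared
only when both pass. Type-I calibration is therefore measured on the
headline test, where the rejection rate under the null should equal the
nominal level (the acceptance suite checks 0.03–0.07 at α = 0.05 over 500
reduced-scale simulations; the conjunction is necessarily more
conservative).

Families follow the response: gaussian for features analysed on the log
scale, Poisson for submovement counts, Gamma(log) for strictly positive
skewed features, and a cumulative-link (proportional-odds) model for the
ordinal gesture-space outcome. The gaussian/Poisson/Gamma ladders are
fitted with `lme4`. The ordinal ladder uses an in-package cumulative-link
mixed model — logit link, one random intercept, maximum likelihood via
15-node Gauss–Hermite quadrature — reported with likelihood-ratio
statistics and Wald z values; tests pin it against `MASS::polr` in the
zero-variance limit and against a 15-node `glmer` binomial fit in the
two-category case (log-likelihoods agree to < 0.001). Its single random
intercept corresponds to the global-participant fallback structure.

Pseudo-R² values: conditional R² uses the variance-components
decomposition (fixed-effect variance from `Xβ̂`; random-effect variance
from the conditional-minus-marginal prediction, which covers random
slopes; residual variance σ² for gaussian, `log(1 + 1/λ̄)` for Poisson-log
and `trigamma(1/dispersion)` for Gamma-log). ΔR²C subtracts the null
model's value, and R²LR = 1 − exp(−LR/n). A simulation test recovers a
known 0.75 variance share within ±0.05.

The correlation-adjusted alpha is `α / k^(1 − r̄)` with 3-decimal
reporting. It reproduces the two published worked values this package
treats as exact anchors (k = 6, r̄ = 0.283 → 0.014; k = 2, r̄ = 0.002 →
0.025) and is monotone decreasing in k and increasing in r̄. A third
published value (k = 4, r̄ = 0.342 → 0.024) does not follow from this — or
any simple — closed form (the formula gives 0.020); the online tool that
produced it is not verifiable, so that value is documented here as a known
discrepancy rather than targeted.

## The synthetic dyad generator

`generator_config()` defaults *are* the emulated study conditions: 20
dyads (40 participants), 10 grades × 240 s, direction alternating across
dyads; four gesture types drawn with the empirical frequencies
(representational 27%, pragmatic 17%, interactive 53%, emblem 2%) and
realized as 1–5 minimum-jerk pulses whose counts per type put mean event
durations in the 1.7–2.8 s range.

The minimum-jerk pulse is the atomic submovement — the standard ballistic
motor-control primitive — because it makes every feature analytic: a pulse
of amplitude D and duration T has peak speed 1.875·D/T, k pulses mean k
submovements, and the inter-pulse stillness is the hold-time. Pulses
alternate out/back; an odd pulse count leaves the hand displaced, so a
slow (1.2 s) retraction follows each such event and events are spaced
≥ 1.5 s so the retraction never contaminates a neighbouring window.

Grade effects enter as a unit inverted-U over grades (1 at mid-grade, 0 at
the extremes) scaling amplitude (size, peak velocity), inter-pulse gaps
(hold-time) and gesture rate, plus a linear decrease in side-view depth —
the qualitative effect pattern under emulation. Acoustic series carry a
4.36 dB speech-with-gesture intensity offset and a 3.71 Hz pitch offset
(the published coefficients serve as generating truths), dyad- and
participant-level random intercepts, and a modality-specific quadratic
intensity lift over grades that is *mean-centred across grades* so the
modality offset remains the marginal with-vs-without difference the ladder
estimates. The speech envelope is a ~4 Hz syllabic oscillation plus a
hand-speed-coupled component at a configurable lag (default 50 ms, hand
leading, i.e. an expected phase asynchrony of −50 ms with speech-leading
positive). A WAV path (`synth_pulse_train()`) supplies glottal-pulse-train
audio with known F0 for the acoustic oracles.

What the generator does **not** emulate: real pose-tracker failure modes
(identity swaps, occlusion-correlated confidence), articulated limb
kinematics (hands translate along a fixed direction), linguistic content,
turn-taking structure, and inter-participant coordination. Passing
recovery tests therefore demonstrates the *pipeline's* correctness on
signals with known structure, not that real conversational data would
yield any particular result.

## Numerical choices and degenerate inputs

* Orthogonal polynomials for grade; ML fits for all LRTs; singular fits
  flagged and never silently reported.
* Constant streams are flagged degenerate before z-scoring; windows too
  short for two cycles of the band's lower edge truncate the band with a
  warning; empty significance masks contribute no alignment row.
* Silence gives `−Inf` intensity (flagged), unvoiced audio `NA` F0; a
  grade with no usable samples yields no acoustic row rather than a zero.
* Boundary ties in gesture space go outward; blur windows are left-closed
  with session-end times clamped into the last window.
* Every stochastic step (surrogates, generator, simulations) takes an
  explicit seed, and the surrogate driver restores the caller's RNG
  state.

## Problem sizes used in the shipped tests

The test-suite defaults are the package's chosen verification scales:
unit fixtures run at 25–100 fps on seconds-long windows; ladder
calibration uses 500 null simulations at 5 dyads × 10 grades × 2 events
per cell with power measured over 40 studies at the full 20-dyad scale;
coherence calibration uses 200 independent 4 s noise pairs with 100
surrogates each; and the end-to-end modality recovery generates the full
40-participant acoustic study. These sizes give stable Monte-Carlo
estimates for every asserted band while keeping a complete run in the
minutes range.

## Known limitations

* The cross-wavelet smoothing mirrors the conceptual design of the
  standard wavelet-coherence toolchain, not any package's exact numerics;
  coherence values are therefore comparable within this package, not
  across implementations.
* The CLMM supports one random intercept (the fallback structure); nested
  dyad/participant ordinal models are out of scope.
* The F0 tracker is a plain autocorrelation method adequate for clean and
  moderately noisy speech-like signals; creaky or very noisy voice would
  need a dedicated tracker.
* Depth conflates forward reach and torso lean by construction (that is
  its definition); interpreting it as pure hand extension would be wrong.
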