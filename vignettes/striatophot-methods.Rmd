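---
title: "Methods: photometry normalization, bout segmentation and stimulation metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photometry normalization, bout segmentation and stimulation metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(striatophot)
```

## The measurement problem

Fiber photometry records bulk fluorescence from a genetically encoded
indicator (here GCaMP8s for striatal spiny-projection-neuron calcium, or the
red dopamine sensor rDA3m) through a chronically implanted fiber. The raw
demodulated trace mixes the biological signal with two dominant nuisance
processes: slow photobleaching (multiplicative decay of fluorescence over
minutes) and motion or mechanical artifacts (fast additive excursions). A
simultaneously acquired 405 nm UV channel excites the indicator at its
isosbestic point, so it carries the same artifacts and bleaching but
(ideally) no activity signal, and can be used as a reference.

`striatophot` implements two normalization chains, locomotion bout
segmentation of treadmill / open-field velocity, peri-event statistics of
the normalized activity, and stimulation-locked dopamine amplitude metrics,
together with a synthetic-session generator whose ground truth makes every
step testable.

## The GCaMP chain (`normalize_gcamp()`)

1. **Sliding-percentile baseline.** F0 for each channel is the 10th
   percentile of the raw trace in a 5 s window centred on each sample
   (`f0_window_s`, `f0_percentile`). A low percentile rides under the
   calcium transients while tracking bleaching. Windows are clipped at the
   session bounds (they shrink at the edges) rather than padded — padding
   would fabricate data. The percentile interpolates linearly between order
   statistics (the `quantile()` type 7 rule); the rule is pinned because
   determinism requires one, and the test-suite oracle uses the same rule.
2. **Pre-normalization.** Each channel becomes (F − F0)/F0, with a guard
   requiring F0 to stay above `baseline_epsilon_rel` × median(F0).
3. **Reference filtering.** The reference dF/F0 is low-pass filtered with a
   second-order Butterworth at 3 Hz. Filtering is zero-phase
   (forward–backward): the analysis is offline, and a causal pass would
   delay the reference by tens of milliseconds, biasing the event-aligned
   timing statistics below. The forward–backward pass squares the magnitude
   response, so a pure tone at frequency f is attenuated by
   1/(1 + (f/fc)^4). The implementation pads with an odd reflection of
   about 3/fc seconds before filtering so that start-up transients of the
   underlying recursive filter decay inside the pad, keeping the DC gain 1
   to numerical precision.
4. **RANSAC referencing.** An affine map from the filtered reference to the
   normalized signal is fitted by random-sample consensus
   (`fit_reference()`): candidate lines through random sample pairs,
   consensus sets by absolute residual, OLS refit of the winning set. The
   defaults (100 iterations, 2-point candidates, seeded) are exposed in the
   configuration. The inlier band defaults to one raw median absolute
   deviation of the *response* about its median — the convention of
   scikit-learn's `RANSACRegressor`, which published photometry pipelines
   build on. The alternative of scaling the band to the OLS *residuals*
   fails in an instructive way: on sessions where artifacts are sparse, the
   residual MAD collapses to the noise scale, the consensus set becomes the
   dense near-origin cloud of artifact-free samples, and the very samples
   that determine the slope are rejected as outliers — the referencing then
   removes nothing. With the response-scaled band the artifact extent stays
   in the consensus, while large deviations (e.g. gross corruption) are
   still rejected.
5. **Subtraction.** The transformed reference (the "UV dF/F") is subtracted
   from the normalized signal; the difference is the final dF/F.
6. **QC gate.** A session is included only if max dF/F exceeds 1.5% and the
   correlation between the GCaMP trace and the UV reference stays below
   0.6. The amplitude threshold is read as dF/F expressed in percent
   (max(dff) > 0.015): with typical axonal GCaMP signals of a few percent, a
   threshold of 1.5 *fractional* units would exclude everything. For the
   correlation operand we use the *pre-subtraction* normalized GCaMP trace
   against the UV dF/F: the final dF/F is the OLS residual of the
   transformed reference over (nearly) the whole session and is therefore
   orthogonal to it by construction, which would make the gate vacuous. A
   session dominated by shared artifacts shows a pre-subtraction correlation
   near 1 and is excluded, which is exactly what the gate is for. Both the
   thresholds and the operand (`qc_corr_operand`) are configuration fields.
7. **z-score.** dF/F is z-scored with the mean and standard deviation of the
   entire recording session.

Because both channels are divided by their own F0, scaling both raw
channels by a common factor leaves the final dF/F unchanged; this chain
linearity is verified in the tests.

If the filtered reference is numerically constant it carries no artifact
information; the chain then skips the affine fit (`transformed = 0`,
`dff = prenorm_signal`) instead of failing, and records the degenerate fit.

## The rDA3m chain (`normalize_rdam()`)

Optogenetic stimulation of striatal projection neurons causes large,
sustained shifts in dopamine release. A sliding-percentile baseline would
track such shifts and flatten them out, so the stimulation chain fits the
RANSAC affine map directly between the *raw* demodulated UV reference and
the *raw* rDA3m signal. The referenced signal F = slope·reference +
intercept estimates what the sensor channel would look like without
dopamine dynamics (bleaching, gain, offset, shared artifacts); dF = signal −
F and dF/F = dF/F (with a positive-divisor guard). RANSAC matters here:
during long stimulation trials a substantial fraction of samples deviates
from the baseline relation, and an ordinary regression would split the
difference.

This referencing is exact when both channels bleach with proportional time
courses. The synthetic stimulation generator therefore shares one bleaching
shape between channels by default (with channel-specific gains/offsets);
with strongly divergent per-channel kinetics a single time-invariant affine
map cannot represent the relation and slow residual drift remains — a known
limitation of the method, not of the implementation.

## Locomotion bout segmentation

Treadmill velocity comes from a rotary encoder (0–3.3 V, 10 cm/s at 2.5 V,
so 4 cm/s per volt through zero; `encoder_to_velocity()`). Segmentation
(`segment_treadmill()`) applies, in order:

* threshold at 0.25 cm/s (absolute velocity by default; the encoder also
  reports direction, and whether backward walking counts as movement is a
  configuration flag, `velocity_mode`);
* sub-threshold runs qualify as **rest** only when strictly longer than
  0.8 s; shorter dips are absorbed into the surrounding movement, so they
  neither split a bout nor count as rest;
* the resulting movement periods are **excluded** (flagged, not dropped)
  when shorter than 0.5 s or with mean velocity below 0.5 cm/s — retaining
  them keeps the output auditable, and downstream peri-event analysis skips
  them;
* bout onset is the threshold crossing ending a rest period, offset the
  crossing followed by a rest period.

All intervals are half-open [onset, offset) in seconds and a sample exactly
at the threshold counts as sub-threshold, so plateaus at the threshold
resolve deterministically. Movement, rest and excluded intervals partition
the session (a property test).

Open-field ambulation bouts are runs above 2 cm/s lasting more than 0.5 s;
runs separated by gaps shorter than 0.5 s are merged before the duration
rule is applied (the merge reading of "separated by > 0.5 s"; the
alternative — enforcing separation only when counting — differs only for
back-to-back short runs). Immobility bouts apply the same logic to a
percent-pixel-change activity series (video, typically 15 Hz) with the
inequality inverted (< 2%); the pipeline takes the activity series as
input abstractly — video decoding is out of scope — and a velocity-derived
proxy can substitute, flagged in the output metadata.

## Peri-event analysis

For locomotion analyses the z-scored trace is decimated to 100 Hz
(anti-aliased, zero-phase; `perievent_rate_hz`) — 1 kHz oversamples ~1 s
indicator kernels ~1000-fold — and aligned on non-excluded movement bout
onsets and offsets over [−1, 1] s (`align_events()`). Events without a full
window inside the session are dropped and counted. Two session-level
statistics mirror the figure-level analyses:

* `max_timing()` — the time of the maximum of the session-mean aligned
  trace in the closed [−1, 1] s search window; ties break to the earliest
  time (a flat trace reports −1 s).
* `offset_slope()` — the OLS slope of the session-mean trace against
  relative time on [−0.5, 0.5) s around offset, in z-units/s.

For stimulation sessions (`stim_metrics()`), per trial and on raw dF/F (not
z-scored — amplitudes in dF/F units are comparable across animals): baseline
= mean over [−2, 0) s before onset; reduction = mean over [−0.2, 0) s before
offset; onset peak = mean over [0.35, 0.45) s after onset; post-stimulus =
mean over [3, 8) s after offset — each minus the baseline. With the default
`window_minus_baseline` sign convention, sustained suppression is negative
and the onset peak positive, which is what the one-sample left-/right-tailed
tests applied to these quantities require; the literal
`baseline_minus_window` subtraction order is available as a configuration
value. All metrics are exactly invariant to adding a constant to the trace.

## The statistics layer

`t_test()` wraps the classical one-sample, paired and pooled-variance
unpaired t-tests (Welch available) with left/right/two-tailed alternatives
behind one result record, adding explicit degenerate-variance handling: a
zero-variance input reports t = 0 and p = 1 for a zero effect, or signed
infinity with the limiting p for a nonzero effect, with a flag, rather than
erroring. `group_report()` assembles per-group n / mean ± SEM / median
(min–max) tables with the requested test and the conventional star codes
(*p<0.05, **p<0.01, ***p<0.001). Type-I error calibration of every
kind/tail at α = 0.05 over 10⁴ null replicates is part of the test suite.
Two-way ANOVA is deliberately not wrapped: no quantity computed here relies
on it, and `stats::aov()` is available to users directly.

## What the generator emulates — and what it does not

`simulate_photometry()` composes signal = bleach × (baseline + transients +
coupling ramp) + gain × artifact + noise, and reference = bleach′ ×
baseline′ + gain′ × artifact + offset′ + noise′:

* **Bleaching**: double-exponential, multiplicative, channel-specific
  (defaults: amplitudes 0.10/0.05 of baseline with time constants
  100/1000 s — order-of-magnitude choices for minutes-long sessions, not
  claims about any dataset).
* **Artifacts**: one waveform (Gaussian bumps, SD 150 ms — mechanical
  timescale, mostly below the 3 Hz reference corner; random sign by
  default, `positive_only` available), entering both channels affinely
  (default reference gain 0.8). This is exactly the model the referencing
  assumes; real optical artifacts can be less shared.
* **Transients**: difference-of-exponentials kernel (rise 50 ms, decay 1 s,
  GCaMP8s-like), log-normal amplitudes around 5% of baseline, Poisson rate
  0.5/s during movement vs 0.05/s at rest.
* **Offset coupling**: `patch_like` adds a deterministic ramp rising from
  0.5 s before each movement offset to a peak 0.25 s after it;
  `matrix_like` holds a movement plateau that declines over the final
  0.5 s. These encode the qualitative activity phenotypes the peri-event
  statistics are meant to separate, with amplitudes comparable to the
  transients.
* **Velocity**: gamma-distributed rest (mean 4 s) and movement (mean 3 s,
  ~4 cm/s) epochs with 0.3 s ramps; rest noise is clipped below 0.2 cm/s so
  that fixed-schedule sessions are *exactly* recoverable — a deliberately
  clean regime that gives sharp acceptance tests; a noisy mode
  (`velocity_rest_sd`) exists for robustness checks.
* **Stimulation** (`simulate_stim_session()`): 2/5/15 s trials (10 per
  duration by default, shuffled) with ≥ 45 s gaps; per trial a sustained
  fractional shift (default −0.2, exponential rise/return, τ = 0.2 s), an
  optional onset Gaussian peak at +0.4 s and an optional rebound Gaussian
  (center +5 s, SD 1 s) after offset. The ground truth stores each trial's
  injected response averaged over the very analysis windows the metrics
  use, evaluated directly from the noiseless generative response — so
  recovery tests compare the pipeline against an independent evaluation,
  not against itself.

Everything is deterministic given (parameters, seed); the generator
restores the caller's RNG state.

Passing tests on these sessions show that the pipeline recovers what the
generative model injects under its assumptions (affinely shared artifacts,
proportional bleaching, additive components). They cannot show robustness
to what the generator does not model: hemodynamic contamination, sensor
saturation and nonlinearity, spectral bleed-through, non-affine artifacts,
wheel slippage, or video-tracking noise.

## Numerical choices and problem sizes

* Percentile interpolation: type 7; window edge policy: clipped.
* Filter edge policy: odd-reflection padding, ~3/fc s.
* Tie-breaks: earliest time for `max_timing()`; threshold equality goes to
  the sub-threshold side in segmentation.
* All analysis windows are half-open [a, b) on the sample grid; a sample at
  time t belongs to the window containing t (no double counting at joints).
* RANSAC threshold floor: 1e-12 × (1 + max|signal|), so exactly affine
  data with zero MAD still yields a full consensus set.
* The test suite runs sessions of 20-60 s at the native 1 kHz (the
  timing/slope cohort study uses 20 replicates × 2 cohorts × 7 sessions of
  60 s; the stimulation recovery study 20 sessions of ~6 trials each), and
  the statistics calibration uses 10⁴ replicates — sizes chosen so the
  whole suite completes in minutes on one CPU while leaving every estimate
  comfortably inside its tolerance.

## Known limitations

* Artifact removal is structurally limited by two interactions. Artifacts
  with appreciable energy above the 3 Hz reference corner are partially
  stripped from the reference before the fit, so their high-frequency part
  cannot be cancelled (a 2nd-order Butterworth is gentle: ~17% amplitude
  loss already at 2 Hz). Conversely, deep negative-going artifacts wider
  than ~10% of the 5 s baseline window are captured by the 10th-percentile
  F0 and distort both channels nonlinearly. In either regime the residual
  artifact correlation after referencing is of order 0.1–0.3 rather than
  ~0; the artifact-removal tests therefore use slow, positive-going,
  frequent artifacts — the regime the chain's model actually covers — and
  the accuracy of the fitted slope (hence the residual) improves roughly
  with the square root of the number of independent artifact events.
* The rDA3m chain assumes a time-invariant affine channel relation; slow
  divergence between channel bleaching kinetics leaves residual drift.
* The QC correlation threshold (0.6) and amplitude threshold (1.5%) are the
  published inclusion values; they are not re-derived here and their
  appropriateness for other sensors or preparations is untested.
* Bout segmentation operates on uniformly sampled velocity; irregular video
  tracking must be resampled (linear interpolation is the intended route)
  before segmentation.
* The open-field immobility measure expects a precomputed percent
  pixel-change series; no video processing is provided.
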