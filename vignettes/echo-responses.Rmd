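---
title: "Measuring omitted-stimulus (echo) responses in A1 calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring omitted-stimulus (echo) responses in A1 calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echotune)
```

## The phenomenon and the measurement problem

Rhythmic sensory stimulation entrains cortical activity beyond the
stimulus itself: after a train of pure tones at a fixed inter-stimulus
interval (ISI) ends, some primary auditory cortex (A1) neurons produce
additional Ca²⁺ transients at the times where the next tones would have
occurred. These omitted-stimulus or *echo* responses are reported to occur
1–5 times after a 20-tone, 2-s-ISI train, in roughly one in six L2/3
neurons, with smaller amplitudes and longer, more variable latencies than
sound-evoked responses, and preferentially after trains at the neuron's
best frequency (BF), while neighbouring neurons may echo to very different
frequencies.

Quantifying this from bulk-loaded dye imaging (Cal-520 class indicators)
requires a chain of decisions — baseline estimation, event detection,
what counts as "a response at the anticipated time", how to separate echo
neurons from spontaneously active ones — that the primary literature
names but does not fully specify. This vignette documents every such
decision in `echotune`, the reasoning behind it, and what the package's
parameter-recovery tests do and do not demonstrate.

## From fluorescence to events

**Baseline and Δf/f.** `compute_dff()` uses the 25th percentile of the
entire single-trial trace as `f0` (linear-interpolation convention,
`stats::quantile` type 7, fixed and tested because percentile variants
disagree on short traces). A percentile baseline is robust to activity:
with sparse transients, well under a quarter of frames are event-occupied,
so `f0` tracks the resting level. One consequence worth knowing: with
zero-mean noise the 25th percentile sits ~0.67 noise SD *below* the mean
resting level, so Δf/f carries a small positive offset. All window
measures in the package are differences (peak minus window start) or fits
with a free offset, so this cancels everywhere it could matter.

**Noise.** `estimate_noise_sd()` returns
`1.4826 · MAD(diff(dff)) / sqrt(2)`. First differencing whitens the slow
transients (kernel increments between adjacent frames are small relative
to noise), and the MAD ignores the sparse large increments at event
onsets. The estimate is within 10% of truth on pure noise and within 15%
with events superimposed (tested).

**Transient detection.** `detect_transients()` operationalizes the
peak-amplitude plus rising-rate criterion:

| parameter | default | units | role |
|---|---|---|---|
| `amp_thresh_sd` | 3 | × noise SD | excursion threshold |
| `min_dur_s` | 0.1 | s | supra-threshold frames required |
| `rise_thresh` | 0.1 | Δf/f·s⁻¹ | onset-to-peak rise rate |
| `min_separation_s` | 0.2 | s | onset separation / dip merging |

Three refinements came out of validating the detector against the
generator's event log rather than from first principles, and they matter
in exactly the regimes this analysis lives in:

1. *Dip merging.* A transient whose decay grazes the threshold re-crosses
   it repeatedly; excursions separated by sub-threshold dips shorter than
   `min_separation_s` are merged, and `min_dur_s` counts only
   supra-threshold frames (otherwise merged noise blips forge events).
2. *Peak splitting.* Rhythmic responses at a 2-s ISI ride on each other's
   0.7-s decay and can form one long excursion; local maxima separated by
   valleys at least `2 × amp_thresh_sd · σ̂` deep are split into distinct
   events. Real chained transients fall nearly to baseline between peaks
   and split cleanly; noise ripple on a decay tail does not reach the
   prominence bound.
3. *Local pre-onset baseline.* A peak must exceed the median Δf/f of the
   0.3 s before its onset by one threshold. Without this, the decay tail
   of a large transient hovering near the absolute threshold re-triggers
   "events" ~2 s after the true one — precisely at the next anticipated
   time, where they would masquerade as echoes.

The rise-rate default of 0.1 Δf/f·s⁻¹ deserves a note. With the transient
kernel used here (rise τ = 0.07 s, decay τ = 0.7 s, time-to-peak
≈ 0.18 s) an event peaking at 0.05–0.08 Δf/f — the reported scale of echo
responses — rises from the detection threshold to its peak at roughly
0.2–0.4 Δf/f·s⁻¹. A substantially higher rise threshold (e.g. 0.5) would
reject the very class of events the analysis targets; 0.1 passes them
while noise is already excluded by the amplitude-duration criteria.

Onsets are threshold crossings linearly interpolated between the
straddling frames (for split events, crossings of the valley level plus
one threshold). A detected onset therefore lags the true kernel onset by
the time the rising kernel needs to reach the threshold — about 10 ms for
a 0.1-Δf/f event and about 20 ms for a 0.05-Δf/f event at the default
settings. This deterministic offset is invisible in real data but matters
when comparing recovered latencies with generator parameters (see
*Calibration*).

## Anticipated-time windows and echo classification

`build_windows()` lays out three window families per train: a 0.5-s sound
window after every tone onset; echo windows of half-width 0.75 s centred
at `t_end + k·ISI` for `k = 1..5` (`t_end` = onset of the train's last
tone; the 1–5 range covers the reported echo counts and 0.75 s
accommodates the ~0.24-s mean echo latency plus its dispersion while
keeping adjacent windows disjoint at a 2-s ISI); and five matched-width
baseline windows tiling the silence just before the train onset.

`classify_echo()` is this package's explicit operationalization of "echo
neuron" (the primary literature reports a fraction without stating a
criterion): count detected onsets in all echo windows of all trains, and
compare with a homogeneous Poisson null at the neuron's own spontaneous
rate, `p = P(Pois(λ̂·T_win) ≥ N)`; echo neurons have `N ≥ 1` and
`p < α = 0.05`.

The null rate comes from `estimate_spont_rate()` on stimulus-free time —
everything outside the trains and their echo windows, where each train's
block extends to the end of its last echo window so that responses to the
train's final tones cannot leak into "free" time. The pipeline adds a
Jeffreys-style pseudo-count (`(N_free + 0.5) / T_free`): the plain
maximum-likelihood rate is exactly zero for the many sparsely firing
neurons with no free-time event, and a zero-rate null declares *any*
single window event infinitely significant, inflating the false-positive
rate to ~10%. With regularization the test is valid and somewhat
conservative (empirical false-positive rate ~2–4% at α = 0.05 on
pure-spontaneous simulations; tested at n = 1000).

Two operating characteristics follow from the discreteness of this test
and should temper interpretation of echo fractions:

* A neuron with a *single* echo event can never reach significance
  against any realistic spontaneous rate (one event in ~80 s of windows
  is unremarkable), and two-event neurons are borderline. Sensitivity is
  therefore structurally ~0.65–0.75 when echo counts are uniform on 1–5.
* Conversely the measured fraction includes a small false-positive
  contribution (~1–2% of non-echo neurons).

Both effects are quantified by the recovery tests and absorbed by the
calibration (below), mirroring the fact that any published echo fraction
is itself the output of an imperfect classifier applied to real data.

## Tuning, best frequency, ΔFrequency

`build_tuning_curve()` integrates Δf/f over 500 ms from each tone onset
(trapezoidal rule, matching the closed-form kernel integral to <2%) and
averages the 20 repetitions per frequency. `fit_gaussian()` fits
`a·exp(−(x−μ)²/2σ²) + c` on `x = log2(f / 1 kHz)` by Levenberg–Marquardt
with two starts (argmax and response centroid); a fit is rejected
(`converged = FALSE`, argmax fallback) when the optimizer fails or σ
exceeds the stimulus band. Fitting on the log2 axis makes the best
frequency `BF = 2^μ · 1 kHz` invariant to the frequency unit; BF is
clamped to the stimulus band. On noiseless Gaussian curves parameters are
recovered to 1e-6; on default-noise synthetic neurons ≥90% of BFs land
within half a stimulus step of truth (tested).

`delta_frequency()` records `log2(f_echo / BF)` per distinct echo-evoking
frequency, in octaves — the natural unit on a log-spaced grid, with one
stimulus step equal to `log2(20)/10 ≈ 0.43` oct, which is also the default
histogram bin of `delta_histogram()`. Population tuning
(`average_tuning()`) aligns normalized curves on BF before averaging.

## Population statistics and pooling rules

`summarize_population()` follows the reporting semantics of the
experimental literature:

* **Echo fraction**: computed per session, then mean ± SEM across
  sessions (the "n mice" semantics of a population percentage).
* **Amplitudes**: pooled over *all* neurons. A neuron contributes its mean
  classified-echo-event peak amplitude when it has echoes, and otherwise
  its mean peak-mode amplitude over anticipated-time windows — the
  activity level at those times. This convention is forced by arithmetic:
  a mean echo amplitude of ~0.055 Δf/f with an SEM of ~0.003 at n ≈ 780
  implies a zero-inflated distribution (per-event echo amplitudes several
  times larger, most neurons near the noise floor), and the paired
  echo-versus-baseline contrast over all neurons only points in the
  reported direction if non-echo neurons contribute their (noise-level)
  window amplitude rather than zero. The per-event mean is also reported
  (`amp_echo_event_mean`).
* The k = 1 anticipated-time window is excluded from the no-response
  fallback level: the preceding train's response decay overlaps it and
  systematically depresses its max-minus-start measure, which would bias
  the paired contrast.
* **Latencies**: pooled over responding neurons only (sound: neurons with
  ≥1 responsive sound window; echo: classified echo neurons), since a
  latency does not exist where nothing responded.
* **Tests**: paired Wilcoxon signed-rank for echo amplitude vs baseline
  activity within neurons; unpaired Wilcoxon rank-sum for sound vs echo
  amplitude and latency (the unpaired choice follows the reporting
  convention of the experimental literature even though both quantities
  come from the same neurons). Both fronts delegate to
  `stats::wilcox.test` and are verified against brute-force enumeration
  of the exact null in the test suite.

`spatial_heterogeneity()` quantifies what published maps show
qualitatively: the statistic is the mean |Δoctave| of echo frequencies
over neuron pairs within `r_um = 50` µm ("adjacent" neurons in a
~200 × 200 µm field), and the null shuffles frequency labels across echo
neuron positions (9999 permutations, seeded). Small p means local
similarity (tonotopic clustering); a mixed map gives a non-significant p.
Under label exchangeability the p-value is uniform/valid (KS-tested over
replicate maps), and a synthetic smooth gradient is detected with
p < 0.05.

## The synthetic forward model

`synthesize_trace()` generates
`f(t) = F₀ · (1 + Σ kernels + noise)` with unit-peak double-exponential
kernels (rise 0.07 s, decay 0.7 s — a fast synthetic dye responding to
one or a few action potentials; both configurable). Kernels are placed at
spontaneous Poisson times, at every tone onset with amplitude
`A · exp(−Δoct²/2σ_tune²)` (Gaussian tuning in log2 distance from BF), and
— for echo neurons — at `t_end + k·ISI` for `k = 1..n_echo` after the
train at the echo frequency. Latencies are per-neuron means plus
per-event Gaussian jitter (SD 0.05 s sound, 0.15 s echo), truncated at
zero. Every kernel is logged, making the generator the oracle for
detector and classifier tests. Sessions default to 40 Hz sampling (a
resonant-scanner figure; the source experiments do not state a frame
rate), trains ordered lowest-to-highest frequency, 30-s inter-train gaps
and 30 s of pre-train silence (ordering, gaps and session length are
likewise unstated upstream and are configurable here).

**What the model emulates:** transient kinetics and peak-SNR regimes,
Gaussian frequency tuning with realistic width dispersion, spontaneous
event statistics, between-neuron heterogeneity of amplitudes, latencies
and noise (needed to reproduce published SEMs at n ≈ 800), the 1–5 echo
event range, echo frequencies tied to BF with one-step jitter
(probability 0.2) so the ΔFrequency distribution has finite width, and a
spatially unstructured echo-frequency map. **What it does not emulate:**
optics and PSF, motion artifacts, neuropil contamination, dye buffering
nonlinearity, spike-train biophysics, trial-to-trial adaptation, or any
true tonotopic gradient. Passing recovery tests therefore demonstrates
that the *analysis* is consistent and unbiased under its own model
assumptions — not that those assumptions exhaust real imaging data.

## Calibration

The preset returned by `calibration_preset("anesthetized")` is tuned so
that the *complete pipeline*, run on 8 synthetic sessions × 100 neurons,
reproduces the published population statistics (targets stored in
`$targets`): echo fraction 15.7%, echo/baseline/sound amplitudes
0.055/0.014/0.083 Δf/f, sound/echo latencies 0.083/0.237 s, with the
published contrast directions at p < 0.001. Calibrating the pipeline
*output* — not the raw parameter draws — is deliberate, because the
published numbers are themselves measurements:

* The true prevalence parameter (0.222) exceeds the 15.7% target because
  the Poisson-null classifier misses most 1–2-event echo neurons (and
  adds ~1% false positives); the recovered fraction, not the flag count,
  is what the published percentage corresponds to.
* Kernel-onset latency parameters (0.067 s sound, 0.30 s echo mean) are
  below/above their measured targets because detected onsets lag kernel
  onsets by the threshold-crossing time and zero-truncated jitter shifts
  means upward.
* The per-event echo amplitude parameter (0.292 Δf/f) is several times
  the 0.055 target because the target is an all-neuron mean dominated by
  non-echo neurons at the ~0.014 noise floor.
* Imaging noise (SD 0.0058 Δf/f) is set by the baseline-activity target:
  0.014 Δf/f is the expected max-minus-start of ~µ + 2.2σ noise
  fluctuations over a 1.5-s window at 40 Hz.
* The spontaneous rate (0.003 events/s) reflects sparse activity under
  isoflurane anesthesia; note that the classifier's power depends
  steeply on it. The `"awake"` preset differs only in spontaneous rate
  (0.012/s) and noise (0.008), consistent with desynchronized cortical
  state, and is otherwise uncalibrated.

The recovery tests (`tests/testthat/test-acceptance.R`) assert each
pooled statistic within 3 SEM of its target on the 8 × 100 study, the
ΔFrequency centre within 3 SE of zero octaves, detector recall/precision
≥ 0.95 at peak SNR 10, classifier false positives at or below α, and
spatial permutation validity. The 8 × 100 size matches the study design
the targets describe (8 animals, ~100 neurons per field) and keeps the
full suite a few minutes long; `scripts/acceptance.R` recomputes the same
statistics from scratch under any seed.

## Numerical choices and degenerate inputs

Percentile type 7 everywhere; trapezoidal integration with interpolated
window endpoints; sub-frame onset interpolation; ties in
`best_frequency()` resolved by the first argmax; flat tuning curves give
`converged = FALSE` fits and a missing BF; all-zero traces yield empty
event lists, `p_spont = 1` and `NA` summaries (never silent zeros);
baselines `f0 ≤ 0` are refused rather than divided by; duplicate-free
exact Wilcoxon nulls are used up to n = 25 and tie-corrected normal
approximations beyond; permutation p-values use the add-one convention
`(1 + #{null ≤ obs}) / (n_perm + 1)`, which is valid (never
anti-conservative) at any `n_perm`.

## Known limitations

* The echo criterion tests total event counts against a homogeneous
  Poisson null; it does not use the within-window timing of events, and
  single-event echo neurons are undetectable in principle. A
  timing-sensitive test could improve sensitivity.
* No deconvolution/peeling: amplitudes are window measures on Δf/f, so
  overlapping events within ~1 decay constant bias peak measures upward.
* The no-neuropil, no-motion forward model makes the recovery tests
  necessary rather than sufficient evidence of field readiness.
* The awake preset is a state change of two parameters, not a validated
  calibration.
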