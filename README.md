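# echotune

Analysis of omitted-stimulus ("echo") responses in layer-2/3 auditory
cortex two-photon Ca²⁺ imaging.

When a pure tone is repeated rhythmically (e.g. 20 tones at a 2-s
inter-stimulus interval) and then stops, a subset of A1 neurons keeps
producing Ca²⁺ transients at the anticipated times of the missing tones —
one to five "echoes" at multiples of the ISI after the last tone. These
responses are frequency specific: the tone frequency whose train elicits
echoes in a neuron lies close to that neuron's best frequency, yet
neighbouring neurons echo to very different frequencies. `echotune` is for
experimenters and analysts who want to quantify this phenomenon in ROI
fluorescence traces: it classifies echo neurons against an explicit
statistical null, measures amplitudes and latencies, builds frequency
tuning curves, and tests the spatial organization of the echo-frequency
map. Because raw imaging data of this kind are rarely shared, the package
also contains a calibrated forward model of Cal-520-like traces, so every
stage of the pipeline is verifiable by parameter recovery.

## The method in brief

* **Normalization.** Per ROI, `Δf/f = (f − f0)/f0`, where `f0` is the 25th
  percentile (linear interpolation) of the whole single-trial trace.
* **Transient detection.** Events are contiguous excursions above
  `k·σ̂` (`k = 3`, `σ̂ = 1.4826·MAD(diff Δf/f)/√2`) lasting ≥ 0.1 s with an
  onset-to-peak rise rate ≥ 0.1 Δf/f·s⁻¹; rhythmic transients riding on
  each other's decay are resolved by prominence-based peak splitting, and
  onsets are threshold crossings interpolated between frames.
* **Echo classification.** For each train ending at `t_end` (onset of its
  last tone), windows of half-width 0.75 s are centred at the anticipated
  times `t_end + k·ISI`, `k = 1..5`. With `N` detected onsets in those
  windows across all trains and a spontaneous rate `λ̂` estimated from
  stimulus-free epochs, `p = P(Pois(λ̂·T_win) ≥ N)`; a neuron is an echo
  neuron when `N ≥ 1` and `p < 0.05`.
* **Tuning.** Per frequency, the 500-ms trapezoidal response integral
  averaged over the 20 tones; tuning curves are fitted with
  `a·exp(−(x−μ)²/2σ²) + c` on `x = log2(f/1 kHz)`; the best frequency is
  `2^μ`·1 kHz (argmax fallback). `ΔFrequency = log2(f_echo / BF)` in
  octaves.
* **Population statistics.** Echo fraction is averaged per session
  (mean ± SEM across sessions); amplitudes pool over all neurons and
  latencies over responding neurons; contrasts use Wilcoxon signed-rank
  (paired) and rank-sum (unpaired) tests. Spatial heterogeneity of the
  echo-frequency map is tested by permuting frequency labels over echo
  neuron positions and comparing the mean pairwise |Δoctave| within 50 µm.

## Worked example

```r
library(echotune)

ses <- synthesize_session(n_neurons = 60, seed = 7)   # one imaging plane
res <- analyze_session(ses, seed = 7)                 # full pipeline
print(summarize_population(list(res$summaries)))
```

```
<population_summary> 60 neurons / 1 sessions
  echo fraction  16.7% +/- NA%
  amplitudes (df/f): echo 0.0724, baseline 0.0139, sound 0.0845
  latencies (s): sound 0.084, echo 0.231
```

Ten of the 60 simulated neurons are classified as echo neurons (16.7%; the
SEM needs more than one session). Echo transients at the anticipated times
average 0.072 Δf/f against a 0.014 Δf/f baseline activity level, sound
responses are larger (0.084 Δf/f), and echoes lag their anticipated times
(231 ms) far more than sound responses lag tone onsets (84 ms).
`res$delta` holds the per-neuron octave distance between echo frequency
and best frequency (12 records here, mean 0.05 oct ≈ 0), and
`res$spatial` the permutation test of local echo-frequency similarity
(p = 0.42 on this small plane: no tonotopic clustering among its echo
neurons).

The same pipeline runs from a shell:

```sh
Rscript inst/cli/echotune.R simulate --config config.yaml
Rscript inst/cli/echotune.R analyze  --config config.yaml
Rscript inst/cli/echotune.R report   --results echotune_results
```

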