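# oromotorquant

Quantitative analysis of orofacial motor function: speech acoustics, EMG,
facial kinematics and swallowing, with bootstrap inference for
two-condition (stimulation OFF vs ON) designs.

## The problem

Interventions such as deep-brain stimulation of the motor thalamus can
change how a person speaks and swallows. Quantifying that change from
bedside recordings requires a stack of signal-level metrics — each simple,
but easy to get subtly wrong — plus an inference layer that makes no
distributional assumptions about small, irregular clinical samples. This
package implements that stack as tested, reusable R functions for
researchers in motor speech disorders, neuromodulation and clinical
neurophysiology:

* **Speech intensity** — short-time spectrogram (25 ms Hann, 5 ms hop,
  50–10000 Hz), per-trial median of the median-filtered in-band power
  trace; condition changes banded at ±5 dB into clinical categories.
* **Voice breaks** — filtered-autocorrelation pitch tracking (75–400 Hz,
  voicing threshold 0.25), glottal-pulse extraction, and counting of
  inter-pulse intervals strictly longer than 16.67 ms.
* **CPPS** — smoothed cepstral peak prominence: the dB height of the
  cepstral peak above its least-squares trend line, averaged over frames;
  falls as dysphonia rises.
* **Formants** — LPC pipeline: pre-emphasis `1 − 0.63 z⁻¹`, 15 ms Hamming
  frames at 80% overlap, model order `round(Fs/1000) + 2`, root gates at
  90 Hz frequency / 400 Hz bandwidth, per-vowel median smoothing,
  100-point spline time-warp, truncation to points 15–85, and percent
  change of F1/F2 between conditions.
* **EMG** — stimulation-triggered MEP area under the curve (rectified
  average, 10–75 ms window), and voluntary-EMG envelopes (zero-phase
  2nd-order Butterworth 60–500 Hz bandpass → rectify → 6 Hz low-pass)
  with per-movement AUC z-scored against the OFF condition.
* **Kinematics & swallowing** — landmark movement amplitude/velocity,
  shoelace mouth-aperture area, videofluoroscopic swallow duration
  (frames / fps) and residue area normalized to the frame.
* **Inference** — percentile bootstrap of the difference in means
  (10,000 resamples, two-tailed CIs at α ∈ {0.05, 0.01, 0.001},
  reject when 0 is outside the CI, starred `*`/`**`/`***`), Bonferroni
  correction, paired t (and sign-flip permutation) tests, percent change
  vs the OFF median.
* **Synthetic data** — a source-filter vowel/word generator (impulse train
  through a cascade of second-order resonators), EMG burst and landmark
  trajectory generators, and two-condition dataset synthesis with known
  ground truth for every metric, so the entire pipeline is testable end to
  end.

Everything user-facing takes and returns tidy tables (tibbles), pipes
cleanly, and has `tidy()`/`glance()`/`autoplot()` methods where a model
object is involved.

## Worked example

Generate a synthetic OFF/ON dataset with a +6 dB intensity effect and a
+8% F1 shift injected into the ON condition, then run the speech pipeline:

```r
library(oromotorquant)

ds <- synth_condition_dataset(
  condition_effect_spec(
    n_trials = 10,
    effects  = list(intensity_db = 6, f1_pct = 8),
    base     = vowel_spec(f0 = 120, duration = 0.35),
    seed     = 42
  )
)
res <- run_speech_pipeline(ds$manifest, run_config(seed = 42))

res$intensity_comparison[, c("word", "n_off", "n_on", "delta_db",
                             "category", "stars")]
#> # A tibble: 1 × 6
#>   word  n_off  n_on delta_db category       stars
#>   <chr> <int> <int>    <dbl> <fct>          <chr>
#> 1 ba       10    10     5.86 large_increase ***

res$formant_comparison
#> # A tibble: 2 × 6
#>   formant mean_off mean_on pct_change vowel stars
#>   <chr>      <dbl>   <dbl>      <dbl> <chr> <chr>
#> 1 F1          700.    752.     7.54   AA    ***
#> 2 F2         1210.   1210.    -0.0584 AA    ns
```

The injected +6 dB level shift is recovered as +5.86 dB (trial-to-trial
level jitter is part of the generator) and classified in the
clinically-relevant `large_increase` band with bootstrap significance at
α = 0.001; the +8% F1 shift is recovered as +7.5% while F2, which was not
shifted, stays at 0. The same comparison is available directly:

```r
b <- bootstrap_diff_means(
  res$trial_metrics$intensity_db[res$trial_metrics$condition == "ON"],
  res$trial_metrics$intensity_db[res$trial_metrics$condition == "OFF"],
  seed = 42
)
glance(b)
#> # A tibble: 1 × 6
#>   observed_diff   n_x   n_y n_resamples  seed stars
#>           <dbl> <int> <int>       <dbl> <dbl> <chr>
#> 1          5.86    10    10       10000    42 ***
```

`tidy(b)` gives the CI per alpha; `autoplot(b)` draws the resampling
distribution. EMG, kinematic and swallow inputs go through
`run_motor_pipeline()`; real recordings enter via `read_wav()`,
`parse_textgrid()`, `read_manifest()`, `read_emg_csv()` and
`read_landmarks()`. A thin command-line wrapper over the same functions
lives at `inst/scripts/oromotorquant.R`
(`synth`, `analyze-speech`, `compare` subcommands).

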