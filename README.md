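# ckcpipe — corticokinematic coherence from EEG and wrist kinematics

Corticokinematic coherence (CKC) measures the frequency-domain coupling
between cortical activity and limb kinematics during continuous periodic
movement, and is a candidate bedside marker of proprioceptive function —
for example in post-stroke assessment, where a physiotherapist can move
the patient's wrist at a steady 2 Hz while EEG and a hand-mounted
accelerometer are recorded. `ckcpipe` is an R implementation of the full
analysis chain for such recordings, aimed at researchers in sensorimotor
neurophysiology:

- **Kinematics**: accelerometer 8th-bit-flip repair, zero-phase
  Kaiser-FIR high-pass + double integration to displacement, PCA main
  axis, prominence-based peak detection, and movement-regularity
  statistics (median/IQR of peak-to-peak periods, cycles before
  metronome compensation).
- **EEG preprocessing**: channel exclusion, deterministic EOG blink
  regression, 0.5–195 Hz zero-phase bandpass, gel-bridge detection by
  windowed electrical distance with spherical-spline repair, and a
  surface-Laplacian (current source density, CSD) transform whose
  regularization constant λ is selected **per recording** by
  leave-one-out cross-validation over centro-parietal electrodes.
- **Coherence**: Welch magnitude-squared coherence
  `C_xy = |P_xy|² / (P_xx P_yy)` between CSD-EEG and an accelerometer
  summary, with classical mean and robust **median** averaging across
  segments, over a 16-cell grid (magnitude/PCA × mean/median ×
  1/0.5/0.25/0.125 Hz resolution), plus peak/SNR/lateralization metrics
  (SNR in dB against the 3 Hz baseline bin).
- **Group metrics**: contra- vs ipsilateral contrasts, frequency
  specificity at 2 and 4 Hz against ±0.5 Hz neighbours, method-grid SNR
  summaries, and cross-condition Spearman correlations.
- **Synthetic recordings**: a generator of coupled EEG + accelerometer
  blocks with known ground truth (jittered 2 Hz movement with metronome
  drift correction, focal phase-locked cortical source at F0 and F1 over
  1/f background, blinks, gel bridges, bit flips, clock offset/drift),
  so the whole chain is testable without any external data.

## Worked example

Simulate one study-condition block (140 s, 2 Hz passive right-wrist
movement, coupled source over C3), run the pipeline, and read off the
headline numbers:

```r
library(ckcpipe)

cfg  <- sim_config(duration_s = 140, seed = 1)   # study-condition defaults
rec  <- simulate_recording(cfg)

# movement regularity from the accelerometer alone
kinematics_summary(rec$accel)[, 1:5]
#>   median_period_ms iqr_period_ms median_cycles_before_compensation n_peaks polarity
#> 1         500.9141      15.53931                                 2     279      max
#> 2         500.9141      15.53931                                 1     279      min

# preprocessing + cross-validated CSD + coherence
csd  <- preprocess_recording(rec)
csd$provenance$csd$lambda
#> [1] 0.001
acc  <- prepare_accel(csd$accel, csd$events, csd$fs_hz, ncol(csd$eeg), "magnitude")
spec <- ckc_coherence(csd$eeg, acc, csd$fs_hz, segment_s = 2, averaging = "median")
peak_metrics(spec, csd$montage, hand = "right")[, c("f0_peak", "f0_peak_channel",
                                                    "f1_peak", "snr_f0_db",
                                                    "contra", "ipsi")]
#>     f0_peak f0_peak_channel   f1_peak snr_f0_db    contra      ipsi
#> 1 0.9932508              C3 0.9707887   26.3046 0.7352338 0.3502241
```

Reading: the recovered movement period is ~500 ms (the 2 Hz protocol
rate) with an IQR in the configured ~20 ms regime; cross-validation
picks λ = 10⁻³ for this noisy recording; coherence peaks at the source
electrode C3 with C(2 Hz) ≈ 0.99, 26 dB above the 3 Hz baseline; and the electrode set
contralateral to the moved hand carries about twice the mean coherence
of the ipsilateral set.

The `analysis/` directory holds the numbered cohort workflow
(`01_simulate_cohort.R` … `05_group_metrics.R`): 12 synthetic subjects ×
2 hands through the same chain, writing tidy tables under `results/`
(kinematics summary, per-block λ selection, the subject × method-grid
CKC table, lateralization/frequency-specificity/correlation summaries).
Run them in order with `Rscript analysis/01_simulate_cohort.R` etc.

A methods vignette (`vignettes/ckc-methods.Rmd`) documents the model,
the tunable parameters and defaults, the numerical choices, what the
synthetic generator does and does not emulate, and known limitations.

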