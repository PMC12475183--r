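---
title: "Corticokinematic coherence from EEG and wrist kinematics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corticokinematic coherence from EEG and wrist kinematics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckcpipe)
```

## The measurement

Corticokinematic coherence (CKC) is the frequency-domain coupling between
cortical activity and limb kinematics during continuous periodic movement.
When a hand is moved passively at a steady rate F0 (here 2 Hz), the
proprioceptive afference drives sensorimotor cortex at F0 and — because
flexors and extensors are stretched alternately, producing two afferent
bursts per cycle — even more reliably at the first harmonic F1 = 2·F0.
`ckcpipe` implements the full analysis chain from raw 3-axis wrist
acceleration and multi-channel EEG to CKC spectra and group-level
contrasts, with a synthetic generator of coupled recordings so that every
stage can be validated against known ground truth.

The coherence statistic is the magnitude-squared coherence

$$C_{xy}(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)},$$

estimated by Welch's method (Hann window, constant detrending, 80%
segment overlap) between a current-source-density (CSD) transformed EEG
channel and a one-dimensional summary of the acceleration. Two estimator
families are computed throughout: the classical mean across segment
periodograms, and a robust variant that takes the **median** across
segments — applied to $P_{xx}$, $P_{yy}$ and to the real and imaginary
parts of $P_{xy}$ separately, since no canonical complex median exists.
Segment lengths of 1, 2, 4 and 8 s give frequency resolutions of 1, 0.5,
0.25 and 0.125 Hz; together with the two accelerometer summaries
(Euclidean magnitude after per-axis median subtraction, which removes the
gravity offset, and the first principal component) this yields the
16-cell method grid the analysis compares. Signal quality at a target
frequency is summarized as
$\mathrm{SNR} = 20\log_{10} (C(f_\mathrm{target})/C(3\,\mathrm{Hz}))$;
the 3 Hz baseline bin exists at every tested resolution and sits between
the two targets.

## Kinematics chain

The accelerometer stream (1094 Hz nominal, 16-bit over ±4 g, individually
timestamped, TTL-synchronized to the EEG) is processed as:

1. **8th-bit flip repair.** Single-sample excursions whose consecutive
   first differences exceed 127 resolution steps in opposite directions
   are rebuilt from the nearest unflagged neighbours, iteratively for
   adjacent runs. The rule is deliberately literal: on a moving signal
   with per-sample slope $s$ a ±128-step flip only produces the
   double-threshold pattern when $|s|\approx 0$, so slope-masked flips
   pass through. The residual singletons are attenuated roughly 100-fold
   by the smoothing below and do not move detected peaks.
2. **Displacement by double integration.** Per axis, twice: zero-phase
   Kaiser-window FIR high-pass (0.2 Hz cutoff, 0.2 Hz transition width,
   40 dB target attenuation; 12209 taps at 1094 Hz from the standard
   Kaiser tap estimate, with the low-pass prototype normalized to exact
   unit DC gain so constants are annihilated exactly), cumulative
   trapezoidal integration, then subtraction of the *median signal* — a
   running median over a 1 s window. A running baseline is used because a
   global median merely re-centres the trace, whereas integration drift
   is time-varying and concentrates at the block edges; with the running
   median the peak detector recovers 100% of the extrema whose two flanks
   are inside the observed window. The FIR is applied by FFT convolution
   with odd-reflection padding and exact group-delay compensation, so
   peak times are not delayed.
3. **Main axis.** PCA across the three displacement axes; the first
   component is kept. The PCA sign is pinned (positive correlation with
   the largest-variance raw axis) for reproducibility, but the physical
   polarity of the sensor is unknowable in principle, which is why all
   period statistics are computed for maximum- and minimum-based peaks
   alike.
4. **Peak detection.** 100-sample moving average, then local maxima with
   a minimal distance of 300 samples and minimal prominence of 1% of the
   smoothed signal range (a from-scratch prominence implementation, since
   no installed R routine provides it).
5. **Period statistics.** Median and IQR of peak-to-peak intervals per
   polarity, and the *cycles-before-compensation* statistic: the median
   length of maximal runs of periods strictly above or strictly below the
   block median. A period exactly equal to the median closes the current
   run and belongs to none — "above or below" excludes equality; ties are
   rare on real-valued data but the convention is pinned and tested.

## EEG chain

TP9/TP10 (and O1/O2 where montages differ across sessions) are excluded;
blink artifacts are removed; the EEG is bandpass filtered 0.5–195 Hz
(zero-phase Butterworth, forward–backward); gel bridges are detected and
repaired; and the data are transformed to CSD with a per-recording
regularization constant.

**Blink removal.** An ICA route is standard in this literature but no ICA
implementation is available to this package, and the pipeline benefits
from a deterministic alternative: each EEG channel's regression
coefficients on the EOG channels are estimated on 1 Hz high-passed copies
(two independent 1/f processes develop large spurious covariance at low
frequencies; the high-pass restores honest degrees of freedom), a
coefficient is kept only when the channel–EOG correlation on those copies
exceeds 0.1 (so EOG-uncorrelated channels are untouched), and the fitted
raw-EOG contribution is subtracted from the unfiltered signal — the same
fit-filtered/apply-unfiltered scheme ICA pipelines use. On synthetic
recordings this removes ≥ 50% of frontal 0.5–4 Hz blink variance while
changing source-channel F0 coherence by < 1%.

**Gel-bridge detection.** The electrical distance of a channel pair is
the variance of the difference signal, computed in non-overlapping 2 s
windows and summarized by the median across windows. Pairs below 1/16 of
the across-pairs median distance are flagged (a relative cutoff, so the
statistic is invariant to global amplitude scaling), capped at 10 pairs
per recording. From each pair, the member with higher broadband variance
relative to its non-bridged neighbours is re-estimated by spherical-spline
interpolation — the more likely contaminated one.

**CSD with cross-validated regularization.** The spherical-spline surface
Laplacian uses Legendre expansions of the spline kernel $G$ (stiffness
$m = 3$) and the CSD kernel $H$ ($m - 1$), truncated at 50 terms, with
the candidate constant λ added to the diagonal of $G$ and coefficients
solved under the zero-sum constraint; the resulting linear operator
annihilates spatially constant fields (rows sum to ~0) and is applied to
every sample. λ is selected per recording by leave-one-out
cross-validation over the centro-parietal/midline electrode rows (F, FC,
C, CP, P): for each λ ∈ {10⁻⁷…10⁻³} and each subset channel, the
channel's voltage over four 50 ms windows is re-estimated from all
remaining channels and the global RMSE across channels and windows picks
the winner. Three choices here were genuinely open and are pinned as
follows: the CV error is computed in the **voltage domain** (the
quantity with an observable ground truth at the left-out electrode),
ties prefer the **larger** λ (more smoothing, more conservative), and
"the middle of the recording" is made concrete as windows centred at
45%, 48%, 52% and 55% of the block. On synthetic data the selected λ is
smallest for noiseless smooth fields and increases monotonically with
injected sensor noise, as it should.

**Montage.** An idealized 10–10 montage (63 channels incl. O1/O2) is
generated on the unit sphere from the proportional placement scheme:
midline and outer-ring electrodes at 10%-of-arc steps, inner rows by
great-circle interpolation. Real caps deviate from ideal geometry by a
few degrees; none of the spline machinery depends on the idealization
beyond that.

## Synchronization and coherence

Accelerometer time is mapped to EEG time by a two-point linear fit on the
first and last TTL events (residuals on synthetic clock offset/drift are
at numerical precision; the contract requires < 1 ms). Axes are median
subtracted (gravity), low-pass filtered at 50 Hz, resampled to 2000 Hz on
the EEG grid, and summarized (magnitude or PCA). Frequency-bin lookups
(2, 3, 4 Hz and the ±0.5/±1 Hz neighbours) use exact grid matches — all
targets are multiples of every tested resolution — never interpolation.
Coherence values are clipped to [0, 1]; zero-power bins report 0.

One estimator property worth knowing: with 80% overlap, the coherence of
*independent* noise against a strongly periodic reference is biased above
the classical 1/K floor specifically at the reference's line frequencies,
because the overlap-induced correlation between segment spectra sums
coherently when the reference phase advances deterministically. The
package's noise-floor tests therefore calibrate the floor from
same-configuration Monte-Carlo runs rather than from neighbouring bins.
The general overlapped-Welch bias for independent signals matches
$1/K_\mathrm{eff}$ with $K_\mathrm{eff}$ computed from the Hann overlap
correlations, which the tests verify to within a few percent.

## The synthetic generator

`sim_config()` defines a block; its defaults are the study conditions:
140 s blocks, 2 Hz movement, EEG at 2000 Hz (63 channels, nose
reference), accelerometer at 1094 Hz over ±4 g. Movement is built from
half-cycles whose durations jitter around 250 ms, with the moving agent
correcting phase drift toward the metronome at gain 0.5 per half-cycle —
a drift-corrected construction under which the period IQR equals
√2·1.349·σ of the half-cycle noise regardless of the gain, so
`period_jitter_ms` (default 23 ms, the middle of the observed 20–26 ms
regime) directly parameterizes the period IQR. The displacement is
$A(\cos\phi + 0.2\cos 2\phi)$ (amplitude 15 mm, a comfortable passive
range; the second harmonic makes the trajectory non-sinusoidal, as real
wrist kinematics are, so the acceleration carries F1 power). The
acceleration uses an angular-rate-squared profile interpolated across
half-cycle midpoints so it stays continuous when cycle durations drift —
a real limb does not jerk instantaneously — which also keeps per-sample
steps far below the 127-step bit-flip threshold. Gravity is a constant
1 g offset on one sensor axis, and the 3-axis projection uses a random
but fixed orientation, so the magnitude-summary median subtraction and
the PCA axis recovery both have real work to do.

The EEG is per-channel 1/f background (α = 1, 10 µV SD) plus a coupled
source $\cos\phi + h\cos 2\phi$ (harmonic ratio h = 0.5 by default; the
true cortical F1/F0 amplitude ratio is unreported in this literature, so
it is a free, documented parameter) weighted by a Gaussian falloff
(σ = 0.35 chord units) centred on the contralateral central electrode,
with `source_snr` (default 1.0) setting the source-to-background variance
ratio at the focus. Blinks are smooth 350 ms transients at frontal
channels, mirrored more strongly into the EOG pair. Gel bridges replace
both members by their average; accelerometer bit flips flip the 8th bit
of individual samples.

What the generator does **not** emulate: volume conduction from a
biophysical head model (the focal Gaussian topography suffices for
recovery tests but is not a forward solution), EMG or movement artifacts
in the EEG, line noise, electrode drift, heterogeneous per-channel noise,
or the physiotherapist's visual feedback loop beyond the drift-correction
gain. Passing tests therefore demonstrate that the pipeline recovers what
it claims from signals with the stated structure — not that real
recordings have that structure. In particular the default coupling gives
near-saturated coherence at the source (≈ 0.95–1.0), far stronger than
typical empirical EEG CKC (~0.1); this is intentional for unambiguous
recovery oracles, and the `source_snr` dial covers the weak-coupling
regime. Relatedly, at the 1 Hz resolution the 3 Hz baseline bin absorbs
spectral leakage from near-saturated 2 and 4 Hz peaks, which depresses
the 1 Hz-resolution SNR on synthetic data more than on weakly coupled
real data.

## Problem sizes and determinism

Everything is deterministic given a seed; identical config + seed gives
bit-identical recordings. The test-suite simulations use 10–30 s blocks
and 6–25 Monte-Carlo replicates per property (e.g. contralateral
dominance at F1 is required in ≥ 95% of 25 independent recordings); the
end-to-end checks and the acceptance script run full 140 s blocks through
the complete pipeline. The cohort workflow under `analysis/` uses 12
subjects × 2 hands × 60 s blocks. These sizes are the package's choices
for a reproducible desk-scale validation; all of them scale up by
changing one argument.

## Known limitations

- The bit-flip detector inherits the literal 127-step double-threshold
  rule and misses flips on steep slopes (see above); its guarantee is
  exact repair wherever the rule fires.
- The regression-based blink removal cannot separate sources that ICA
  could; it removes what is linearly predictable from the EOG above the
  fit edge.
- The spherical-spline CSD assumes a spherical head and idealized
  electrode positions; λ selection compensates per recording for spatial
  noise, not for geometry error.
- Group-level routines delegate all inferential statistics to base R
  (`shapiro.test`, `wilcox.test`, `t.test`, `cor.test`); the package's
  contribution there is constructing their exact inputs, including the
  contra/ipsi assignment, the dominant-hand mapping (laterality quotient
  > 40 right, < −40 left, sign decides in between) and the explicitly
  uncorrected multiple-comparison policy (a Holm option exists behind the
  \code{p_adjust} flag of \code{condition_correlations}).
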