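---
title: "Kalman-filter fall detection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kalman-filter fall detection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallsense)
```

## The detection problem

A waist-worn triaxial accelerometer sees a fall as two superimposed
signatures: a short high-amplitude impact, and a *sustained change of the
gravity direction* (the wearer ends up horizontal). Activities of daily
living (ADLs) produce one signature or the other, but rarely both: walking
and jogging are high-amplitude but periodic with no orientation change;
sitting down or turning in bed change orientation without a hard impact;
a jump is an impact whose bias returns to rest. `fallsense` implements a
threshold detector over a fused feature that multiplies the two signatures,
plus a gait-periodicity veto that discards candidates raised during
periodic locomotion.

All pipeline arithmetic is carried out in raw ADC bits. With the device
configuration assumed throughout (13-bit two's-complement ADC over ±16 G),
one gravity is exactly 256 bits, and the vertical axis (y) of an upright
wearer reads about −256 bits at rest.

## Pipeline

For each sample $k$ at 25 Hz (files recorded at 200 Hz are stride-decimated
by 8 first; no anti-alias prefilter, mirroring a device that natively
samples at 25 Hz):

1. **Low-pass stage.** A 4th-order Butterworth IIR low-pass with 5 Hz
   cut-off, realized as two cascaded biquads (direct form II transposed)
   with zero initial conditions. Each section is normalized to unity DC
   gain. The cascade is causal and streaming: chunked and batch filtering
   produce bit-identical outputs.
2. **Impact branch.** Sample differencing
   $\Delta \vec a[k] = \vec a[k]-\vec a[k-1]$ removes the gravity bias, and
   $$J_1[k] = \sqrt{\tfrac{1}{3}\left(\Delta a_x^2+\Delta a_y^2+\Delta a_z^2\right)}$$
   (the sum-vector magnitude) responds to impacts.
3. **Orientation branch.** A 4-state Kalman smoother with identity
   transition and output matrices ($A=C=I_4$) filters the measurement
   $\vec y[k] = (a_x, a_y, a_z,\, a_y - b_{ay}[k-1])$, where $b_{ay}$ is the
   running mean of the smoothed vertical state $x_2$ over the last second
   (25 samples). States $x_{1..3}$ are heavily smoothed orientation
   estimates; $x_4$ is a zero-bias quasi-sinusoid during periodic gait.
   The standard-deviation magnitude
   $$J_2[k] = \sqrt{\tfrac{1}{3}\left(\sigma_1^2+\sigma_2^2+\sigma_3^2\right)}$$
   uses the per-axis population standard deviation of $x_{1..3}$ over a 1 s
   sliding window and responds to orientation change.
4. **Fusion and threshold.**
   $$J_3[k] = \max(\tilde J_1[k]) \cdot \max(\tilde J_2[k])^2$$
   with both sliding-max windows $\tilde J_i$ of length $N=25$ (1 s). The
   windowed maxima align the two branches (the smoother peaks later than the
   impact); the square prioritizes orientation change, the more accurate of
   the two features. A candidate opens when $J_3 \ge$ threshold
   (deployment default 40 000).
5. **Periodicity veto.** The 3 s of $x_4$ after a candidate are analyzed by
   zero crossings; if a stable gait-band oscillation persists, the wearer is
   still walking or jogging and the candidate is vetoed ($J_3$ is zeroed
   over the vetoed span). After a true fall the periodic signal disappears
   and the candidate is confirmed.

## Kalman smoother parameters

Only the ratio of the process and measurement noise variances matters for
the steady-state gains. Defaults (squared standard deviations):

| parameter | default | meaning |
|---|---|---|
| `q_std` | 0.001 | process noise std, all four states |
| `r_std_xyz` | 0.05 | measurement noise std, acceleration channels |
| `r_std_x4` | 0.01 | measurement noise std, de-biased vertical channel |

These place the orientation states at a steady gain of ≈0.02 (time constant
≈2 s: flat during gait, responsive to posture change) and $x_4$ at ≈0.095
(enough bandwidth to follow gait-band oscillation while suppressing
impact peaks). `tune_heuristic()` reproduces the manual tuning schedule —
shrink the Q standard deviations by 10, 5, 2, then the R ones, watching a
flatness diagnostic for $x_{1..3}$ and a crossing-regularity diagnostic for
$x_4$ — as an advisory report; it selects nothing automatically, because
the detector is deliberately insensitive to small changes in these values.

Initialization uses the upright-rest prior ($x_2[0] = b_{ay}[0] = -256$
bits, i.e. −1 G) with $P[0]=Q$; an uninformative zero start is available as
`init = "zero"`. The bias tracker feeds the *previous* step's mean into the
fourth measurement, keeping the recursion strictly causal, and averages a
partially filled window during the first second.

Covariances are re-symmetrized after every update, and the implementation
is checked against an independently coded Joseph-form filter (≤ 1e−9 over
random steps and trajectories) plus the scalar-filter decoupling that
$A=C=I$ with diagonal noise implies.

## Quantifying "stable periodicity"

The veto needs a concrete definition of stability; the package uses, over
the 3 s post-candidate window of $x_4$:

* **Local debias.** A centered 1 s moving average is subtracted first. The
  global bias tracker is itself perturbed by the candidate impact, leaving
  a multi-second decaying offset on $x_4$ that would otherwise hide the
  crossings of an ongoing gait oscillation. Ten samples at each end of the
  debiased window are discarded, where the partial-window average distorts
  crossing positions.
* **Half-period extraction.** Sample counts between sign changes, with
  exact zeros inheriting the previous sign. A single displaced crossing
  splits one period into a pair like (7, 12); adjacent pairs summing to one
  full period (within tolerance) are merged back.
* **Period estimate.** Twice the mean of the half-periods within ±25% of
  their median, rounded to the nearest sample. On a noiseless integer-period
  sinusoid the crossing spacings alternate between ⌊p/2⌋ and ⌈p/2⌉, and this
  estimator recovers p exactly — a median-based representative cannot
  recover odd periods, which is why the mean is used.
* **Stability.** At least `min_halfperiods = 4` in-tolerance half-periods,
  a period inside the gait band (0.4–2.0 s), and an oscillation amplitude of
  at least 5 bits, measured as the *median over crossing intervals of the
  peak excursion within each interval*. Genuine gait sustains its amplitude
  on every half cycle; the late crossings of an impact-decay tail enclose
  only sub-bit wiggles and fail this floor. This per-cycle measure replaced
  a window-level quantile precisely because the decay tail of one synthetic
  fall inflated the latter enough to fake a veto.

Consequence of the trimmed 55-sample core: gait slower than ≈1.1 s period
cannot accumulate four half-periods within 3 s, so very slow walking is
outside the effective veto range. This is a conservative failure — a
missing veto can only create a false positive, never mask a fall.

A truncated post-window (stream ends before 3 s) always confirms: missing
a real fall is costlier than a late false alarm.

## Detection logic

Detection is suppressed for the first 2 s of a stream while the feature
windows fill and the smoother converges (the window handling at stream
start is otherwise undefined). While a candidate is pending no new
candidate can open; a confirmed alarm is followed by a 10 s refractory
period. A file is predicted to contain a fall iff at least one candidate is
confirmed. Raising the threshold never increases the confirmed-event count,
and disabling the veto never decreases it.

## Threshold training and evaluation

`train_threshold()` scans the midpoints between consecutive distinct
per-file scores (max post-warm-up $J_3$, after veto zeroing when the veto
is on) plus sentinels below and above, classifies *fall iff score ≥ t*, and
maximizes balanced accuracy $(SEN+SPE)/2$ — balanced because ADL files far
outnumber falls. Among tied maximizers the smallest candidate is returned:
training falls come from protected, mostly young volunteers, and real falls
of elderly people are slower, so the lower threshold is chosen to avoid
false negatives. When the veto is active during scoring, candidates are
raised at the fixed deployment threshold (40 000), since the trained
threshold does not exist yet at scoring time.

`cross_validate()` deals files into stratified folds (seeded shuffle within
class, round-robin across folds: fold sizes and per-fold class counts each
differ by at most one) and trains on k−1 folds per round. Files are
canonically ordered by name first, making the result invariant to corpus
assembly order. Reported are per-fold rates, fold-mean ± sd, the fold-mean
confusion matrix, and pooled rates — fold-mean and pooled differ slightly
and both are given. `kappa_report()` provides the observed accuracy, the
standard Cohen chance term (product of marginals) with its kappa, and a
prevalence-based variant whose chance term is the fall-class ground-truth
proportion; both are reported because published summaries of this detector
family use the prevalence-style term (0.3990 on a 451-file fold with 180
falls) rather than the standard one (0.5204).

## The synthetic generator

`gen_recording()` emulates the signal structure the detector assumes, in
bits at 25 Hz (or 200 Hz, sampling the same continuous-time model):

* **rest** — $(0, -256, 0)$ plus i.i.d. Gaussian noise (default σ = 3 bits),
  rounded to integers and clamped to the 13-bit range;
* **walk / jog / stairs** — vertical sinusoid about −256 (defaults: 40 bits
  at 1.0 s, 80 bits at 0.8 s, 55 bits at 0.9 s) with smaller out-of-phase
  harmonics on x and z, seeded random phase;
* **sit transition / bed turn** — smooth sigmoid rotation of the gravity
  vector (25° over ≈2 s toward x; 90° over ≈3 s toward z) with no impact;
* **jump** — a biphasic impact envelope (default 600 bits) with the bias
  returning to rest;
* **falls** — a 1500-bit biphasic impact coincident with a fast 90° gravity
  rotation to the post-fall axis; `jog_trip_fall` prefixes 6 s of jogging;
* a single-sample spike of configurable amplitude can be injected into any
  activity to exercise the false-positive/veto path.

Amplitude defaults were fixed once so that, under the default pipeline,
fall files exceed the 40 000 operating threshold with a wide margin while
every ADL stays below 20 000; a sweep over 30 corpus seeds gives a global
margin of roughly 900 (ADL max) vs 145 000 (fall min). The `hard` corpus
preset adds jogs with 3000-bit spikes, fast bed turns, and soft partial
falls (700-bit impact, 70° rotation) whose scores overlap the un-vetoed
spike artefacts — the configuration on which the veto's specificity gain
is measured. What the generator does **not** model: biomechanically
realistic fall dynamics, colored sensor noise, device repositioning,
subject-to-subject variability, or the long-tailed activity mix of free
living. Perfect cross-validation scores on the separable corpus therefore
demonstrate correctness of the pipeline and harness, not expected field
accuracy.

## Numerical choices

* RMS in both features includes the ÷3 under the root (the literal RMS
  convention); population (÷N) standard deviation in $J_2$. Any constant
  factor is absorbed by the trained threshold.
* State arithmetic in double precision; measurements stay integer bits.
* Exact zeros in crossing detection inherit the previous sign, so a sample
  landing on zero is never counted twice.
* The problem sizes used by the test-suite and the acceptance script — 15 s
  recordings, 60-file default and 40-file hard corpora, 10- and 7-fold
  cross-validation, 200 seeded period-recovery trials — were chosen as the
  smallest sizes at which every property is exercised with comfortable
  margins.

## Known limitations

* The veto assumes the vertical axis carries gravity; a device worn
  laterally defeats the bias tracker.
* Very slow gait (period ≳ 1.1 s) is outside the effective veto range of a
  3 s window with the 4-half-period requirement (see above).
* Thresholds trained on the synthetic corpus are on the synthetic amplitude
  scale; deployment on real recordings should train on real scores or use
  the 40 000 operating point.
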