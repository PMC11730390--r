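---
title: "Neonatal fNIRS speech discrimination: models, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neonatal fNIRS speech discrimination: models, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonirs)
```

## The scientific question

Newborns discriminate natural (forward) speech from time-reversed
speech, and the cortical response to this contrast is measurable with
functional near-infrared spectroscopy (fNIRS). `neonirs` implements a
complete analysis chain for a block-design neonatal paradigm —
alternating 15-s forward and reverse speech blocks separated by 15–30 s
silences, recorded with a 24-channel bilateral probe at 10 Hz and two
wavelengths (695/830 nm) — together with a synthetic-cohort generator,
per-subject discrimination metrics, a hemispheric laterality index, and
the cohort-level statistics that link neonatal lateralization to
language outcomes at preschool age.

The per-subject quantities are:

* **SP** — the absolute difference in mean HbO response between the
  forward and reverse condition, averaged over all retained channels;
* **SP~L~, SP~R~** — the same restricted to left / right hemisphere
  channels;
* **LI~SP~** = 100·(SP~L~ − SP~R~)/(SP~L~ + SP~R~) — the laterality
  index, +100 for complete left dominance, −100 for complete right
  dominance, undefined when both sides are exactly zero.

Absolute values are used because roughly half of neonates show
*inverted* responses (HbO decreases, HbR increases under stimulation);
algebraic values would cancel in group averages. Signed variants are
provided for analyses run separately within the positive and inverted
groups.

## The preprocessing chain

The chain runs in a fixed, logged order: optical density → SNR channel
pruning → motion detection → spline correction → wavelet correction →
band-pass → modified Beer–Lambert → epoching/averaging.

**Optical density.** ΔOD = −log10(I / Ī) per channel and wavelength,
with Ī the recording mean.

**Channel pruning.** A channel is kept iff mean(I)/sd(I) ≥ 2 at both
wavelengths (the common fNIRS SNR convention; the threshold is the
discard rule "SNR < 2"). Zero-variance channels are formally infinite
SNR: retained and logged.

**Motion detection.** A sample is flagged when the excursion
(max − min) within any 0.5-s window covering it exceeds either 50
channel-sds or 0.4 OD, at either wavelength; flags are dilated by 1 s
on each side. The "channel sd" is estimated robustly as
`mad(diff(x))/sqrt(2)` (the innovation scale). This choice matters: a
sustained baseline-shift artifact inflates any direct spread estimate
of the same series (a mid-recording step inflates even `mad(x)` to
about half the step height), which would raise the detection threshold
on exactly the channels that need correction. The innovation scale is
insensitive to level changes and slow oscillations, so the threshold
reflects the physiological noise floor.

**Spline correction.** Within each flagged segment a cubic smoothing
spline (parameter p = 0.99, mapped to `smooth.spline(spar = 1 − p)`) is
fitted; the segment is replaced by `v − s + line`, with `line`
interpolating the fit's boundary values, so the artifact's shape is
removed while the segment stays continuous with its neighbours. The
fit's level change across the segment estimates the artifact's
persistent baseline shift; only when it exceeds `step_min` (0.05 OD,
about 15–20 physiological sds) is everything after the segment
re-leveled by that constant. Spike corrections therefore leave samples
outside the flagged segment *exactly* unchanged. We initially
re-leveled after every flagged segment using windowed data means; this
injects an offset error of the order of the genuine hemodynamic change
across the segment at every spike, and with tens of spikes per
recording those offsets — turned into transients by the subsequent
high-pass — dominated the SP error budget. Conditioning re-leveling on
an evident level change removes that failure mode while still
correcting true step artifacts.

**Wavelet correction.** A periodized multilevel Daubechies-2 transform
(after symmetric padding to a power of two, maximum dyadic depth) is
applied per channel/wavelength; at thresholded detail levels,
coefficients outside [Q1 − α·IQR, Q3 + α·IQR] with α = 0.50 are set to
zero, and the series is reconstructed. Thresholding is restricted to
detail levels whose frequency band lies entirely above
`f_protect = 0.06 Hz`. The rationale: the block-design response is
confined below ~0.05 Hz, and at those coarse levels the "outliers" that
the quartile rule removes *are* the response — zeroing every level
attenuated the recovered discrimination amplitude by 70–95% even on
noise-free data. Motion transients are broadband and dominated by fast
scales, so the restricted rule removes them while leaving the
hemodynamic band to the spline/band-pass stages. `alpha = Inf` disables
zeroing and reconstructs the input to 1e-10 (the perfect-reconstruction
test).

**Band-pass.** 3rd-order Butterworth, 0.01–0.50 Hz, applied forward and
backward (zero phase). The series is demeaned and reflect-padded by
2/f_lo before `signal::filtfilt`, whose recursion has no
initial-state handling; without the padding, any residual DC level
produces ~100-s edge transients.

**Modified Beer–Lambert.** Per channel and sample the 2×2 system
ΔOD(λ) = [ε~HbO~(λ)·ΔHbO + ε~HbR~(λ)·ΔHbR]·d·DPF(λ) is solved for
(ΔHbO, ΔHbR) in µM. The DPF uses the general wavelength/age equation
(5.31 at 695 nm, 4.67 at 830 nm for a neonate). The package ships one
two-wavelength extinction table used self-consistently by the simulator
and the inversion, so round-trip correctness never depends on a
particular literature compilation; absolute concentration scale enters
all metrics as a common factor and cancels in LI~SP~.

**Epoching.** Blocks are epoched over [−2, 25) s (half-open, 270
samples at 10 Hz) with the mean of the continuous series over [−5, 0) s
subtracted per channel (baseline correction follows filtering, matching
the narrative order of the chain). A trial is rejected when more than
10% of its samples (epoch plus baseline, averaged over channels) remain
flagged; additionally, single channels whose own flagged fraction
exceeds the tolerance are dropped from that trial only, because motion
contamination is channel-local. Whole-trial counts feed the inclusion
bookkeeping. A subject is included iff at least 18 channels and at
least 50% of trials survive — both boundaries inclusive.

## The synthetic cohort generator

The generator emulates the study conditions the analysis assumes, so
that every downstream stage is testable without any recording:

* 24-channel bilateral probe (12 per hemisphere), 10 Hz, 695/830 nm.
  The source–detector separation defaults to 3 cm, a typical neonatal
  probe distance; distance rescales concentrations linearly and cancels
  in LI. (A millimetre-scale separation would not produce a cortical
  fNIRS channel.)
* Pseudo-randomized schedules: 10 blocks per condition, 15 s each,
  silences uniform in 15–30 s, no more than two consecutive blocks of
  one condition. Total duration is not constrained — it is implied by
  the draws.
* Responses: boxcar convolved with a single-gamma kernel
  (time-to-peak 7 s, no undershoot). The analysis uses only window
  means, so kernel shape is a simulator convenience; amplitudes are
  parameterized directly as designed window-mean responses (µM) per
  condition and hemisphere. HbR is tied to HbO by a factor of −1/3.
  Inverted responders (default fraction 49/92) have the whole HbO
  response sign-flipped, HbR therefore flipped oppositely.
* Group truth distributions: per-hemisphere discrimination amplitudes
  drawn from zero-truncated normals, term larger than preterm
  (defaults: term SP~L~ 0.17 ± 0.14, SP~R~ 0.15 ± 0.12 µM; preterm
  0.10 ± 0.09, 0.11 ± 0.09 µM). Truncation raises realized means
  slightly above the nominal parameters.
* Physiological noise per channel: slow drift (0.5 µM at ~0.004 Hz),
  a ~0.1 Hz low-frequency oscillation (0.2 µM), respiration (~0.7 Hz,
  0.15 µM), cardiac pulsation (~2.5 Hz, 0.3 µM), white noise
  (0.05 µM/sample) — chosen so the 0.01–0.50 Hz band-pass removes
  cardiac and most drift, matching the pipeline's assumptions.
* Motion artifacts in OD: half-sine spikes (0.2–1.0 OD, 0.2–1 s,
  0.2/min/channel) and step baseline shifts (0.2–0.5 OD,
  0.02/min/channel), Poisson occurrences. Magnitudes are the clearly
  pathological, detectable artifact class that the spline/wavelet
  steps target; rates are set so channel retention (~23–24 of 24) and
  trial retention (~100%) match the cohort the generator emulates.
* Outcomes: phonological short-term memory z = group mean +
  slope·(LI/100) + noise, with slope 1 and residual sd 0.78 calibrated
  so the implied population rank correlation with LI is 0.50 (the
  design target; `implied_outcome_rank_cor()` recomputes it by
  simulation). Sentence production and morphological rules share a
  rank correlation of 0.52 through a normal copula; comprehension is
  independent. Group means/sds default to values typical of a mixed
  preterm/term follow-up cohort.

What the generator does **not** emulate: optode-scalp coupling physics,
photon transport and partial-volume effects, spatially correlated
physiology across channels, serial correlation of artifacts, real
HRF-shape variability, and any acoustic property of the stimuli.
Passing tests therefore demonstrate the correctness and robustness of
the *analysis*, not claims about real infant data.

## Statistics

The cohort stage provides: a Lilliefors-corrected Kolmogorov–Smirnov
normality screen (`nortest::lillie.test`); the mixed 2×2×2
repeated-measures ANOVA (within: condition, hemisphere; between: group)
via `aov` with `Error(subject/(condition*hemisphere))`, reporting
partial η² = SS~effect~/(SS~effect~ + SS~error~) per stratum; paired
and two-sample t tests reporting both tail conventions (the output
labels which is which, since published post-hoc values can follow
either); Mann–Whitney U with tie-corrected z and an exact p (from the
exact U distribution, symmetric-extremeness definition) for
min(n) ≤ 8 without ties; Spearman correlation as Pearson-on-average
ranks with a t-approximation p and full-enumeration exact p for n < 10
without ties; Bonferroni families with flag ⇔ p < 0.05/family size
(default family 16, the full 4×4 metric-by-outcome grid, configurable);
slope homogeneity as the F-test of the group×covariate interaction in
`lm(outcome ~ group*covariate)`; the SES composite
mean(edu~mother~, edu~father~, (income−1)·4/7 + 1); and z-score
classification with z < −2 strictly "reduced" (a score of exactly −2
counts as below-average).

Degenerate inputs are handled explicitly: zero-variance t-test inputs
are flagged rather than erroring; an ANOVA effect with no sum of
squares at the data scale reports F = 0 (not a 0/0 artifact); an
undefined laterality (both hemispheres exactly zero) is flagged and the
subject excluded from laterality analyses with pairwise deletion.

## Numerical choices and test scales

Key tolerances: the Beer–Lambert forward/inverse round trip is exact to
1e-6 relative error end-to-end with noise and filtering off (measured
~1e-14); the wavelet transform reconstructs to 1e-10; ANOVA F
statistics match an independent brute-force sums-of-squares partition
and squared contrast-t oracles to 1e-8; baseline means vanish to 1e-10
by construction.

Simulation sizes used by the test suite were chosen to give stable
Monte-Carlo verdicts at interactive runtimes: 400 seeded schedules for
the constraint scan, 40 subjects spanning designed LI ∈ [−80, 80] for
parameter recovery (the designed per-subject amplitude sum is 0.27 µM,
the typical cohort magnitude), 100 seeded datasets for the ANOVA
oracle, and 500 replicates of n = 45 cohorts (drawn at truth level,
without signal synthesis) for the outcome-coupling and null-control
checks.

## Known limitations

* The spline and wavelet corrections are not bit-compatible with any
  existing fNIRS toolbox; they implement the same artifact classes with
  the package's own, documented parameterizations.
* The per-hemisphere aggregation averages the per-channel
  forward-reverse differences first and then takes the absolute value;
  the alternative order (absolute first) is available via
  `aggregation = "abs_first"` for sensitivity analysis.
* The response window behind "mean hemodynamic changes" defaults to
  0–25 s post onset (the full post-stimulus epoch); no published window
  exists to pin it further, so it is exposed as a parameter.
* Whether group comparisons should be read one- or two-tailed is left
  to the reader: both are always reported.
* LI is undefined for subjects with no measurable discrimination on
  either side; such subjects are excluded pairwise, and analyses report
  per-cell n.
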