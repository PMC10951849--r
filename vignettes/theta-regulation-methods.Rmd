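---
title: "Methods: simulating and analysing theta-band EEG correlates of emotion regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing theta-band EEG correlates of emotion regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Cognitive reappraisal — deliberately reinterpreting an aversive stimulus to
blunt its emotional impact — engages a frontal control network whose
electrophysiological signature is an increase in induced theta-band
(3.5–8.5 Hz) oscillatory power over right-frontal sensors in the seconds
following the regulation instruction. In clinical populations with emotion
regulation deficits (here: borderline personality disorder, BPD, contrasted
with matched controls), this regulation-associated theta increase and the
accompanying theta-band coupling between the right dorsolateral prefrontal
region and the rest of the cortex are attenuated.

`thetareg` implements the full analysis chain for a two-group
cognitive-reappraisal EEG study — induced time–frequency analysis,
sensor-level cluster-mass permutation statistics, eLORETA source imaging
with baseline-normalised theta power, volume-conduction-robust connectivity
via the multivariate interaction measure (MIM), and the behavioural
ANOVA/regression models — together with a synthetic-cohort generator, so
that every stage is testable against planted ground truth without access to
participant recordings.

# The simulated paradigm

Each trial follows the picture-viewing/instruction paradigm: an affective
picture appears at t = −3 s, a spoken one-word instruction at t = 0
("maintain" or "decrease"), and analysis epochs span −6 s to +7 s at
t = 0-referenced time. Three conditions are generated in equal numbers —
neutral pictures with the maintain instruction, negative pictures with
maintain, negative pictures with reappraise — across three blocks of 50
trials (pseudo-randomised with at most three consecutive repeats of a
condition per block; blocks are separated by breaks, so the constraint is
per-block).

Sensor data are the projection, through an analytic single-sphere dipole
leadfield over a 64-channel extended 10/20 montage, of:

1. **Background sources**: 12 cortical 1/f (power exponent 1) noise sources
   at random voxels with random orientations, fresh each trial.
2. **Evoked transients**: damped 5-Hz waveforms after picture onset
   (posterior source; 20 % stronger for negative pictures) and after the
   instruction (central source), identical across trials within a
   condition — these are exactly what event-related-potential subtraction
   must remove.
3. **The induced theta effect**: a 6-Hz oscillator at a right-frontal voxel
   (under electrode F6) with uniform random phase per trial — the mechanism
   that lets it survive ERP subtraction — active during the regulation
   window (1–5 s, raised-cosine ramps). Its amplitude is
   `theta_base_amp` (1.0) in every condition and rises by
   `theta_effect_size` in the reappraisal condition only: 1.0 for controls,
   0.4 for the BPD group. The group asymmetry is the planted effect every
   downstream test must recover.
4. **A coupled partner source**: the same oscillation at a central voxel,
   phase-lagged by `coupling_lag` (π/2) and scaled by `coupling_rel_amp`
   (0.8). The non-zero lag produces a genuinely imaginary cross-spectrum,
   i.e. connectivity that MIM is designed to detect; its amplitude scales
   with the condition amplitude, so the reappraisal boost also plants a
   connectivity contrast.
5. **Sensor noise**: 0.5 µV white noise per channel, plus an optional
   blink-like frontal artifact (`artifact_amplitude`, off by default) used
   to exercise the ICA cleanup.

Amplitudes were chosen once so that the planted theta reaches a
sensor-level signal-to-background ratio of roughly 3–5 within the analysis
box — a strong but physiologically plausible induced response — giving the
recovery studies adequate power at desk-scale cohort sizes. Behavioural
ratings (0–100) and ERQ facet scores are drawn from truncated normal
distributions with the study population's group means and SDs (BPD:
reappraisal rating 42 ± 21, maintenance 58 ± 25, ERQ-R 21 ± 8, ERQ-S
15 ± 5; controls: 35 ± 19, 56 ± 21, 27 ± 7, 12 ± 5). An optional slope
(`erq_theta_slope`) couples a participant's planted theta increment to
their ERQ-R score for regression-recovery experiments.

**What the generator does not emulate**: realistic head geometry (a
homogeneous sphere replaces a boundary-element model — it preserves every
property the tests rely on: linearity, exact forward solutions, volume
conduction), non-stationary background dynamics, muscle artifacts, real
ocular geometry, and inter-individual anatomical variability. Passing tests
demonstrate the *statistical machinery* is correct and calibrated, not that
effect sizes transfer to real recordings.

# The head model and forward solution

Electrode positions are built geometrically from the 10/10 nomenclature
(outer ring at 72° inclination, row arcs interpolated through the midline),
and source voxels form a Fibonacci lattice on a shell at 0.75 of the scalp
radius (cortex-like, strictly inside the sensor sphere; coordinates are
also reported in mm with a 90-mm scalp for annotation). The forward model
is the closed-form potential of a current dipole in a homogeneous
insulated sphere, obtained by summing the classical Legendre series with
generating functions; the test suite verifies it against an independently
coded truncated-series implementation to 1e−10. The leadfield is
average-referenced, matching the re-referenced data.

# Preprocessing

The chain mirrors standard practice: segmentation into 13-s epochs
(−6…+7 s), zero-phase 4th-order Butterworth filtering (0.3 Hz high-pass,
100 Hz low-pass clipped below Nyquist when necessary, 48–52 Hz band-stop),
linear detrend and demean, spherical-spline interpolation of bad channels
(order m = 4), deterministic artifact rejection (a trial is dropped when
the across-trial z-score of its peak amplitude or of its >30 Hz power
exceeds 4 — a scriptable replacement for interactive inspection),
common-average re-referencing, and ICA-based ocular cleanup (FastICA with
symmetric decorrelation; components correlating with the frontopolar proxy
above |r| = 0.7 are subtracted). Only identified components are removed, so
the operation is the identity when nothing crosses the threshold.
Provenance flags record the applied stages and warn when stages run out of
canonical order. Zero-phase filtering avoids latency distortion of the
1–5 s analysis window; epochs are filtered per-epoch, and all analysis
windows keep ≥ 1 s distance from epoch edges, outside the measured edge
transients.

# Induced time–frequency analysis

The per-condition trial-average (the evoked potential) is subtracted from
each trial before spectral analysis; what remains is induced activity.
Power is computed with a sliding 2-s Hanning window every 50 ms at 1–30 Hz
in 0.5-Hz steps (a 2-s window makes the 0.5-Hz grid coincide with DFT bins
at any integer sampling rate; the window centred at t covers t ± 1 s).
Amplitude normalisation is such that a sinusoid of amplitude A yields
power A²/2 (its variance, in µV²) — pinned by an analytic single-tone test
at 3 %. Baseline correction subtracts, per channel and frequency, the mean
power in the 1.2–0.2 s window before picture onset (−4.2…−3.2 s). The
regulation contrast is the participant's reappraisal-minus-maintenance
difference, and the theta summary averages it over 3.5–8.5 Hz × 1–5 s per
channel.

# Sensor-level cluster statistics

Group differences in the theta summaries are tested with the cluster-mass
permutation procedure: per-channel pooled-variance two-sided t statistics;
channels with p < 0.05 seed clusters; clusters are sign-consistent
connected components on the channel neighbour graph (Delaunay triangulation
of the azimuthal projection by default; a distance rule is available);
the cluster statistic is the summed t. The null distribution is the
maximum absolute cluster mass over random relabellings with full
re-computation per permutation, and p = (b + 1)/(N + 1). The max-|mass|
construction gives two-sided family-wise control; the add-one rule is the
standard finite-sample adjustment, and no minimum-neighbour constraint is
imposed on cluster membership. Pooled-variance t (rather than Welch) is the
classical choice for balanced groups. The default permutation count is
10 000 (Monte-Carlo SE of a p ≈ 0.05 is then ≈ 0.002); publication-scale
analyses use 100 000.

# eLORETA source analysis

Trials are re-segmented to the regulation phase (1–5 s) and the baseline
(−4.2…−3.2 s); each segment is Hanning-tapered and zero-padded to a common
4-s length so both share one frequency grid, and the complex coefficients
are taken at 3.5–8.5 Hz in 0.5-Hz steps. Coefficients are scaled as power
spectral density (µV²/Hz), which makes the regulation/baseline ratio of a
stationary process 1 despite the different segment lengths — the
calibration the power-ratio normalisation relies on.

The eLORETA inverse iterates per-voxel 3×3 weights to the fixed point
W_v = (K_vᵀ M K_v)^{1/2}, M = pinv(Σ_v K_v W_v⁻¹ K_vᵀ + αI) on the
average-reference subspace (tolerance 1e−6 on the relative weight change,
cap 100 iterations). Its defining property — exact localisation of point
sources in noiseless data as α → 0 — is asserted for every voxel and
orientation of a test grid. The default regularisation is α = 0.05 of the
trace-normalised sensor covariance; the noiseless tests use α ≈ 0 where
the choice is immaterial. Per-voxel source power is the squared norm of
the 3-D projected coefficient, averaged over trials and summed over the 11
band bins; the power ratio divides regulation by baseline power within
each condition (condition-specific baselines), and the contrast subtracts
the maintenance ratio from the reappraisal ratio.

Voxel-wise inference permutes group labels of the per-participant
contrasts (mean-difference statistic, add-one p, two-sided by default with
a one-sided option). No multiple-comparison correction is applied at the
voxel level — the output records this — and significant voxels are grouped
into contiguous clusters by a distance rule (1.6 × the median
nearest-neighbour spacing; the shell grid is not a cubic lattice, so this
replaces a fixed 26-neighbourhood) with centroids reported in mm.

# MIM connectivity

For voxels i, j with band-averaged cross-spectral blocks S_ii, S_jj, S_ij
(3×3, from the eLORETA source coefficients),

MIM_ij = tr[(Re S_ii)⁻¹ · Im S_ij · (Re S_jj)⁻¹ · (Im S_ij)ᵀ],

the sum of the three eigenvalues of that product; the trace form is used
because the two are algebraically identical and the trace is cheaper, with
an explicit test pinning trace = Σ eigenvalues. MIM vanishes identically
for any instantaneous (real) linear mixture of independent sources —
volume conduction cannot produce it — and is invariant to any non-singular
real remixing within each voxel's 3-D space, a stronger property than the
orientation-rotation invariance usually quoted; both are tested. Cross-
spectra are averaged over the 11 theta bins before MIM (one value per
pair; per-bin cross-spectra are available behind a flag), near-singular
real parts receive a logged 1e−12-relative ridge, and the voxel-to-whole-
brain map averages MIM over all partner voxels, excluding the self-pair
(MIM measures interactions *between* areas). The whole-brain map is
O(V²); the default 400-voxel grid keeps one participant-condition under a
minute, and the desk-scale studies use 40–100 voxels.

# Behavioural statistics

The emotion ratings enter a classical split-plot (mixed two-way) ANOVA —
group between participants, condition within — with Bonferroni-corrected
simple effects computed only when the interaction is significant,
otherwise main effects are reported. The split-plot denominator degrees of
freedom (n − 2 for both strata in the 2×2 balanced case) are reported
as such; observation-level df variants found in the literature are not
reverse-engineered. The ERQ facets are analysed identically, with facet as
the within factor. The regression predicts the cluster-mean theta contrast
from ERQ-Reappraisal, ERQ-Suppression and the rating difference (OLS with
intercept, per-predictor two-sided t, Bonferroni over the three
predictors, collinearity guarded by a condition-number check at 1e8).

# Numerical choices and degenerate inputs

* Permutation ties: the identity relabelling reproduces the observed
  statistic up to floating-point rounding between the vectorised and the
  direct computation; comparisons use a 1e−9 relative tolerance so exact
  ties count as exceedances, keeping p ≥ 1/(N + 1) sharp.
* Degenerate ANOVA inputs (zero effect and zero error) report F = 0.
* Zero pooled variance in the t map yields ±Inf with a warning (0 when the
  means also tie).
* rtruncnorm with sd = 0 is the clamped point mass; 1/f spectra zero the
  DC bin.
* Seeds: every stochastic stage takes an explicit seed; child seeds are
  derived with a fixed linear-congruential map and stay below 2³¹.

# Study scales used by the validation suite

The tests and the acceptance script run the full machinery at desk scale,
chosen once: planted-effect recovery uses 50 cohorts of 8 + 8 participants,
24 trials (8 per condition) at 50 Hz on a 48-voxel grid with 500
permutations; the null calibration uses 500 synthetic datasets of 12 + 12
participants over 64 channels at 500 permutations; MIM nullity uses 50
datasets of 20 independent sources × 200 trials on a 40-voxel grid with 40
trial shuffles; localisation uses a 100-voxel grid (300 dipoles); the
induced-specificity check uses the paradigm's full 150-trial count. A 50-Hz
simulation rate is ample for a 3.5–8.5 Hz analysis (the 2-s window still
yields the 0.5-Hz grid); the full-scale configuration (25 + 25, 150 trials,
250 Hz, up to 2839 voxels, 100 000 permutations) is a parameter change, not
a code path change.

A note on the MIM nullity study's null: shuffling trials independently per
voxel destroys cross-voxel phase consistency but also the real-part
correlation structure, which slightly changes the sampling variance of the
imaginary cross-spectrum — the per-dataset "map mean below the null's 95th
percentile" event is therefore only approximately a 95% event (empirically
its rate moves between roughly 0.7 and 0.95 across master seeds). What
volume-conduction robustness actually guarantees is the absence of
systematic inflation: genuine phase-lagged coupling pushes the observed
map far above the shuffled null (permutation p ≈ 10⁻³ in the recovery
study) and would drive the rate to zero. The study therefore asserts a
majority bound on the per-dataset rate together with a pooled grand-mean
versus pooled-null comparison, and reports both.

# Known limitations

* The spherical head model localises on its own grid; no claim is made
  about anatomical (atlas-level) accuracy, and "mm" coordinates are
  nominal annotations on the sphere.
* eLORETA weights are fit once per leadfield (they are data-independent);
  data-adaptive regularisation is not implemented.
* The ICA step targets one dominant non-Gaussian ocular component; with a
  largely Gaussian background, the remaining components are rotationally
  unstable (a warning is emitted at the iteration cap) — harmless for
  subtract-only cleanup, but not a general-purpose ICA.
* Artifact rejection uses plain (not robust) z-scores, so it assumes a
  majority of clean trials.
* The behavioural simulator draws condition means independently per
  participant; it does not model trial-level rating dynamics.
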