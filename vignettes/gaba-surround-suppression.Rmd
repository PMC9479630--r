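---
title: "Methods: edited-MRS GABA quantification and surround-suppression psychophysics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edited-MRS GABA quantification and surround-suppression psychophysics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabasupp)
```

# The scientific problem

Amblyopia is a developmental disorder in which one eye (the amblyopic,
non-dominant eye, NDE) loses acuity that cannot be restored optically, and in
which perception through the amblyopic eye is chronically suppressed by input
from the fellow (dominant) eye. Animal work implicates intracortical
GABAergic inhibition in both interocular suppression and surround
suppression. `gabasupp` implements, end to end, an analysis that links a
magnetic-resonance-spectroscopy (MRS) proxy for visual-cortical GABA — the
creatine-referenced integral of the edited GABA resonance, GABA:Cr — to
psychophysical measures of surround suppression measured dichoptically and
monocularly in both eyes, in people with amblyopia (PWA) and normally
sighted persons (NSP).

Because the raw study data are not bundled, the package ships a first-class
synthetic-cohort generator with known ground truth. Every downstream stage
(spectral quantification, staircase threshold extraction, normalization,
ratio construction, inference) is exercised against planted values.

# Edited-MRS quantification

## Signal model and preprocessing

A scan is a set of paired On/Off block spectra (each a 10-transient average;
16 blocks per editing state, 1024 complex points, stored in a plain-text
`rda`-dialect bundle). Quantification proceeds as:

1. **Preprocessing** (`preprocess()`): the time-domain signal is
   reconstructed, the first point is halved, the FID is zero-padded from
   1024 to 4096 points and apodized with a Gaussian window
   `w(t) = exp(-(pi * LB * t)^2 / (4 ln 2))`, `LB = 4` Hz. We define "4-Hz
   Gaussian apodization" as the window adding 4 Hz of Gaussian full width at
   half maximum; the convention matters only through the (negligible)
   integration-window tail leakage. Halving the first point removes the
   flat spectral baseline that a one-sided FID otherwise produces under the
   discrete Fourier transform; without it, window-integral ratios are
   biased by roughly 3% because the two integration windows have different
   widths.
2. **Creatine-referenced correction**
   (`phase_and_frequency_correct()` / `apply_pair_correction()`): for each
   Off-resonance block, the frequency shift in ±0.1 ppm that maximizes the
   interpolated creatine peak modulus at 3.00 ppm is found by grid search
   with golden-section refinement; the zero-order phase is then the argument
   of the complex peak value (the phase maximizing the real part at a point
   is analytic, so it is profiled rather than searched). The same
   correction is applied to the paired On-resonance block. The original
   procedure was manual; this automation recovers planted corruptions to
   within 0.05 rad and 0.005 ppm. Blocks whose creatine peak does not rise
   at least 5x above the Rayleigh-estimated noise floor are flagged
   uncorrectable and dropped as pairs.
3. **Quality control** (`qc_blocks()`): per editing state, the across-block
   mean and SD of the real part are computed at every frequency bin; a
   block's deviant count is the number of bins beyond 2 SD. Blocks
   exceeding `max_deviant` are excluded. The default threshold (10% of
   bins) sits far above the ~4.6% of bins a clean Gaussian block puts past
   2 SD, so clean synthetic cohorts lose essentially no blocks, while a
   localized artifact a few hundred bins wide is excluded exactly. The
   study's own exclusion rate (7.7%) was a data-dependent outcome that also
   folded in visual inspection; only the tally rule is automated here. QC
   is exclusion-only: retained blocks are never modified.
4. **Averaging and integration** (`difference_and_sum()`,
   `integrate_peak()`): the edited difference `mean(On) - mean(Off)`
   isolates GABA; the sum carries creatine. GABA is integrated over
   2.85-3.15 ppm in the difference spectrum and creatine over 2.93-3.10 ppm
   in the summed spectrum, by the trapezoid rule on the real part over
   closed windows with bin-center membership. Whether the original analysis
   integrated the real part or the magnitude is not stated; the real part
   is the default and an optional linear endpoint-baseline subtraction is
   available behind a flag (off by default). `gaba_cr_ratio()` reports the
   ratio; per-subject values average the subject's retained scans.

## The synthetic spectra

`synthesize_scan()` builds the minimal spectrum that makes both integration
windows meaningful: a creatine CH3 singlet at 3.00 ppm in both editing
states (the reference), creatine CH2 (3.92 ppm), NAA (2.01 ppm) and residual
water (4.7 ppm) for realism, and a GABA pseudo-doublet at 3.00 ± 0.015 ppm
present only in On-resonance blocks so that it survives in the difference.
Line shapes are Gaussian (3 Hz intrinsic width) so tails outside the windows
are negligible; with the windows above, the noiseless chain recovers a
planted ratio to well under 2%. Because the summed spectrum contains
creatine twice plus the edited GABA signal, the planted amplitude `g`
solves `g / (2 A_cr + g) = r` exactly. Each block pair shares a random
phase error (SD 0.05 rad) and frequency offset (SD 0.003 ppm) emulating
scanner drift, which the correction stage must undo; noise is complex
Gaussian, scaled so `snr` is the creatine peak height over the per-bin
spectral noise SD.

J-coupling evolution, macromolecule baselines, and lineshape distortions are
deliberately out of scope: the generator validates the analysis chain, not
the spectroscopy. Consequently, passing tests show the pipeline recovers
what it assumes; they do not certify performance on real spectra with
co-edited macromolecules.

**Spectral SNR default.** `cohort_spec(snr_spectra = 60)`: the creatine
amplitude SNR of a 10-transient average from a 27 ml occipital voxel at 3 T
is typically well above 50. At this operating point the per-subject
measurement SD of GABA:Cr under the full protocol (4 scans x 16 block
pairs) is a fraction of the planted between-subject SD (0.004,
matching a standard error of 0.001 at n = 14), which is the regime in which
a rank correlation of -0.6 is observable at n = 14 at all — the regime the
study itself reports.

# Staircase psychophysics

The 4AFC contrast-increment task is modeled with a Weibull observer,
`p(x) = 0.25 + (0.75 - lapse) * (1 - exp(-(x / alpha)^beta))`, defaults
`beta = 3`, `lapse = 0.02`. With these values the 70.7%-correct level that a
2-up/1-down (transformed up-down) staircase tracks lies within half a
percent of `alpha`, so `alpha` is directly the cell's generating threshold.

`run_staircase()` implements the rule: two consecutive correct responses
multiply the increment by `10^-0.125`, each error by `10^+0.125`; a reversal
is logged at each direction change; the staircase stops at 12 reversals and
the threshold is the mean of the last six reversals taken in the log domain
(a geometric mean — the natural average for a multiplicative step; the
original description says only "average"). "2-up, 1-down" is read as the
standard transformed rule tracking 70.7% correct: the variant tracking 29.3%
would place thresholds below chance performance in a 4AFC task, which is
not meaningful. Steps before the first direction change are not reversals.
Staircases start at 10x the generating threshold (capped at the ceiling of
0.7, one minus the 30% pedestal contrast); a staircase pinned at the
ceiling for 10 consecutive trials is declared unmeasurable, mirroring the
observation that some amblyopic eyes cannot do the task under a
maximum-contrast dichoptic surround. Cells aggregate four staircases by
geometric mean of the converged ones and are flagged unstable below four.

Trial logs store the physical eye (OS/OD), not DE/NDE: for NSP the
dominance labels are *defined* by the measured baseline thresholds, so they
are an output of the analysis (`assign_eye_dominance()`, with an exact tie
broken to the right eye as DE, with a warning), not a property of raw data.
`fit_thresholds()` replays each log through the rule, taking the starting
level from the log's first increment — the level track is fully determined
by the start and the response sequence.

# Suppression measures

`normalize_points()` divides each surround-cell threshold *and* its surround
contrast by the baseline (no-surround) threshold of the same subject and
annulus-viewing eye, yielding relative thresholds and relative surround
contrasts. This removes intrinsic contrast-discrimination differences
between eyes and subjects; all downstream ratios are invariant to per-eye
baseline rescaling by construction.

`select_reference_contrast()` picks the single relative surround contrast at
which one point per subject-eye-condition is extracted. Candidates (40
log-spaced values in [1, 20]) are scored by the fraction of the eight
conditions whose across-subject mean nearest-point relative threshold
exceeds 1; ties are broken by the between-eye bias (absolute difference in
mean log relative contrast actually used for DE vs NDE), then by proximity
to the pooled median log relative contrast, then downward. The full score
surface is returned for audit rather than asserting a unique optimum, and
on study-sized synthetic cohorts the selection lands in the 2-10 range over
which the original results were reported as robust. Nearest-point distance
is measured in log contrast (a multiplicative quantity); equidistant ties
resolve to the lower contrast. Missing cells propagate as missing data
(pairwise deletion), not subject exclusion.

From the selected points, `suppression_ratio()` forms NDE:DE ratios per
configuration and orientation (values > 1: the amblyopic eye is suppressed
more than it suppresses) and `osss_ratio()` forms iso:cross ratios per eye
and configuration (values > 1: orientation-selective surround suppression).
The abandoned parametric fit of threshold-versus-contrast curves is not
implemented; only the nearest-point approach is.

# Synthetic cohort

`generate_cohort()` plants, among PWA, a Gaussian-copula rank correlation
between true GABA:Cr and the depth of amblyopia (interocular logMAR
difference): latent normals with Pearson correlation `2 sin(pi rho / 6)`
are pushed through monotone margins (normal for GABA:Cr; log-normal,
median 0.48 logMAR, for depth), so the population Spearman correlation is
exactly the requested value. Dominant-eye acuities are uniform on
[-0.20, 0.08] logMAR and the amblyopic eye is worse by the drawn depth; NSP
acuities sit near 0 in both eyes (the study reports no NSP acuity table, so
a small jitter of SD 0.03 logMAR is assumed). True baseline thresholds are
log-normal (median 3% contrast), with the amblyopic eye elevated by
`1 + 1.5 * depth`; surround cells generate at
`baseline * (1 + w * C / baseline)` with condition-specific weights `w`
planting iso > cross everywhere and, for PWA, a strongly asymmetric
dichoptic pattern (dominant suppresses amblyopic far more than the
reverse). `default_suppression_weights(pwa_asymmetry = FALSE)` yields the
matched null cohort used for false-positive checks. Surround contrast sets
default to four values from 8% to 90% Michelson, identical across
conditions within a participant, as in the task design; the per-participant
individualization of the tested range is not emulated.

# Inference

All correlation inference is Spearman on midranks with permutation nulls:
`perm_test_rho()` shuffles one vector (default 100,000 draws, add-one
corrected two-tailed p, exact enumeration available at small n);
`perm_test_delta_rho_eyes()` swaps each subject's DE/NDE values — the
exchangeability that holds under "no eye difference" with a shared
regressor; `perm_test_region_specificity()` resamples subjects with
replacement to build the bootstrap distribution of the visual-minus-motor
correlation difference (a label-permutation variant is provided; subject
resampling is the default since the original description mentions a
bootstrap). `fisher_z_compare()` implements the r-to-z comparison;
`bootstrap_linear_ci()` the subject-resampled confidence band of the linear
fit. The omnibus ANOVA is a fixed-effects factorial (Type-II sums of
squares via `car::Anova`, robust to mild imbalance) reporting the
orientation main effect and the full configuration x eye x group factorial;
whether the original treated subject as a random effect is unstated, so
exact replication of published F values is not an acceptance surface. No
multiple-comparison correction is applied anywhere, matching the original
analysis. Permutation p-values are never exactly zero by construction.

# Problem sizes and numerical choices

- Property-style checks run at deliberately chosen sizes: copula planting is
  verified at n = 500 (sampling SD of the rank correlation ~0.03);
  staircase convergence over 10,000 trials; permutation-test calibration
  over 500 null datasets at 2,000 draws each; planted-correlation sign
  recovery over 20 cohorts of 14 PWA at the full MRS protocol; the
  behavioral pipeline on a 16 + 15 cohort with 8 PWA / 14 NSP in the
  psychophysical arm, mirroring the study's arms.
- Identical seeds give bit-identical cohorts, spectra, trial logs, and
  permutation p-values; every generator routes through one seeded RNG
  scope that restores the caller's RNG state.
- Degenerate inputs are explicit: zero rank variance aborts permutation
  tests; an all-equal ANOVA table reports F = 0; a facilitation-only data
  set refuses to select a reference contrast; unconverged staircases yield
  flagged missing thresholds.

# Limitations

The generator's observer has no lapses of attention beyond the symmetric
lapse rate, no learning, and no session effects; its spectra lack
macromolecule contamination and frequency drift within a block. Passing
acceptance therefore demonstrates internal consistency of the analysis
chain and correct recovery of planted structure at study-realistic noise
levels — not clinical validity on real scans or observers. Real-data
replication of the published F, t, and correlation values would require the
original per-subject data, which are outside the package's scope.
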