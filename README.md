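# gabasupp

Visual-cortical GABA and perceptual surround suppression in amblyopia: a
tested, reusable R implementation of the full analysis chain, from edited
magnetic-resonance-spectroscopy (MRS) block spectra and raw psychophysical
trial logs to permutation-tested brain–behavior correlations — exercised end
to end on synthetic cohorts with known ground truth.

It is aimed at vision scientists and MRS methodologists who want the
individual stages (MEGA-PRESS-style GABA:Cr quantification, transformed
up-down staircase analysis, baseline-normalized suppression ratios,
permutation/bootstrap inference) as well-specified, independently testable
functions.

## The measures

**GABA:Cr.** Paired On/Off edited block spectra are zero-padded (1024 to
4096 points), Gaussian-apodized (4 Hz), phase- and frequency-corrected
against the creatine peak at 3.00 ppm (corrections estimated on each
Off-resonance block and applied to its paired On-resonance block), and
screened by an automated deviant-bin tally (bins > 2 SD from the
across-block mean). Then

```
GABA:Cr = ∫ 2.85–3.15 ppm Re[ mean(On) − mean(Off) ] dppm
          ─────────────────────────────────────────────────
          ∫ 2.93–3.10 ppm Re[ mean(On) + mean(Off) ] dppm
```

**Suppression.** Contrast-discrimination thresholds come from 2-up/1-down
staircases (0.125 log-unit steps, 12 reversals, threshold = geometric mean
of the last six reversals) on a 4AFC contrast-increment task. Each surround
cell threshold `T` at surround contrast `C` is normalized by the baseline
(no-surround) threshold `T0` of the same eye: relative threshold
`T̂ = T/T0`, relative surround contrast `Ĉ = C/T0`. One point per
subject–eye–condition is extracted at the data-driven reference contrast
`Ĉ*` (nearest point in log contrast), and two ratio families follow:

- interocular suppression `R = T̂(NDE) / T̂(DE)` per configuration and
  orientation (R > 1: the amblyopic eye is suppressed more than it
  suppresses),
- orientation selectivity `Q = T̂(iso) / T̂(cross)` per eye and
  configuration.

**Inference.** Spearman ρ on midranks with permutation nulls (100,000
shuffles by default), per-subject eye-swap permutation for interocular
correlation differences, subject-resampled bootstrap for regional
specificity, Fisher r-to-z for comparing correlations, bootstrap confidence
bands for linear fits, one/two-sample t tests and Cohen's d, and a Type-II
factorial ANOVA. Depth of amblyopia is the interocular logMAR difference.

## Worked example

```r
library(gabasupp)

## quantify a synthetic edited scan with a planted ratio of 0.09
scan <- synthesize_scan(true_gaba_cr = 0.09, snr = 60, seed = 7)
gaba_cr_ratio(scan)
#> <metabolite_estimate> GABA:Cr = 0.0895 (32 blocks used, 0.0% excluded)

## a small synthetic cohort, full behavioral + MRS pipeline
co  <- generate_cohort(cohort_spec(n_pwa = 8, n_nsp = 8, seed = 11))
sim <- simulate_sessions(co)
mrs <- quantify_cohort_mrs(co, scans_per_subject = 2)
ana <- analyze_cohort(co$records, sim$trials, mrs = mrs)
ana
#> <supp_analysis> 16 subjects, 544 cells, reference C* = 5.42
#>   mean NDE:DE ratio (dichoptic): 1.47 | mean iso:cross ratio: 1.41

## GABA:Cr vs depth of amblyopia among the amblyopic subjects
pwa <- co$records[co$records$group == "PWA", ]
perm_test_rho(mrs$gaba_cr[match(pwa$subject_id, mrs$subject_id)],
              depth_of_amblyopia(pwa), n_perm = 10000, seed = 2)
#> Spearman rho = -0.857 (n = 8), permutation p = 0.009299 (10000 shuffles)

## comparing two correlations from different voxels
fisher_z_compare(-0.61, 14, 0.10, 11)
#> Fisher r-to-z: z = -1.742, two-tailed p = 0.082 (rho1 = -0.61 n1 = 14; rho2 = 0.10 n2 = 11)
```

Reading of the output: the reference relative surround contrast selected
from the pooled data (5.42) falls in the 2–10 range over which the analysis
is designed to be robust; the dichoptic NDE:DE ratio above 1 reflects the
planted asymmetry (the dominant eye suppresses the amblyopic eye more than
the reverse); the iso:cross ratio above 1 is orientation-selective surround
suppression; and the negative ρ recovers the planted coupling between lower
GABA:Cr and deeper amblyopia. The generator's defaults (cohort sizes,
planted ρ = −0.61, GABA:Cr 0.09 ± 0.004, staircase and protocol constants)
are documented in `?cohort_spec` and the methods vignette
(`vignettes/gaba-surround-suppression.Rmd`).

A 16-row clinical table of persons with amblyopia ships as a fixture
(`load_table1_fixture()`), including the two subjects whose MRS data are
flagged for exclusion.

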