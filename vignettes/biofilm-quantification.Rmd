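---
title: "Quantifying in situ oral biofilms: thickness, biovolume, pH and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in situ oral biofilms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmq)
```

## Scope and model of the data

`biofilmq` implements the quantitative chain of an in situ oral-biofilm
intervention study in which biofilms are grown on glass carriers worn on
intraoral splints, treated with matrix-degrading enzymes or a control
solution, and then measured by three imaging modalities plus a clustered
statistical analysis:

1. **OCT thickness.** Optical coherence tomography yields a 3D intensity
   volume (default voxel size 4 x 4 x 1.45 um). Mean biofilm thickness is
   obtained by despeckling each B-scan with a disk median filter, a single
   global intensity threshold, and per-A-scan counting of foreground voxels
   scaled by the axial resolution.
2. **CLSM biovolume.** Sparse confocal z-stacks (three slices per field of
   view) are segmented per stack and converted to biovolume with the
   Cavalieri principle: the sum of section areas times the section spacing.
3. **Ratiometric pH.** A dual-emission pH dye gives a green/red ratio that
   falls monotonically with pH over the calibrated range 4.0-7.8. A
   five-parameter logistic is fitted to a 20-point buffer series and
   inverted analytically; extracellular pH is the mean of per-pixel pH over
   a mask that excludes bright microbial cells and sub-floor background.
4. **Trial statistics.** Thickness-ranked pair randomization (permuted
   blocks of 2), consensus outlier screening (robust z, IQR fences, Cook's
   distance, equal-tailed interval; flagged by at least half the methods),
   gamma regression with a log link for positive outcomes (exp(coefficient)
   is a ratio of means), linear regression for pH differences, and
   participant-level cluster bootstrap inference.

Every input has a synthetic generator with exact ground truth, so the whole
pipeline is testable end to end without clinical data.

## OCT thickness estimation

The volume is treated as `lateral x lateral x depth`; a B-scan is one
`lateral x depth` plane, an A-scan one depth column. The chain is

```{r oct}
sim <- gen_oct_volume(c(32, 32, 64), mean_thickness = 20, seed = 1)
res <- quantify_oct(sim$volume)  # filter -> threshold -> segment -> count
c(truth = sim$truth$mean_thickness, estimate = res$mean_thickness)
```

Design choices that the reader should know about:

* **Median filter.** Disk-shaped structuring element, default radius 5 px,
  applied per 2D B-scan. Borders use symmetric (reflect) padding, the
  common default of image-processing libraries. An important geometric
  consequence of any rank filter is that structures whose axial extent is
  smaller than about half the disk height would be erased in the interior
  of an image; because the simulated biofilm is attached at the first depth
  index (the carrier surface at the top of the cropped scan), reflection at
  that border preserves thin layers down to about 3 axial voxels. Layers of
  1-2 voxels (below ~3 um) are below the method's resolution.
* **Threshold.** The study's acquisition protocol does not pin down how
  the global threshold was chosen; the package defaults to Otsu's
  between-class variance maximization on the filtered volume's histogram
  (256 equal-width bins for continuous data, native levels for integer
  data), with a `fixed` override. A completely signal-free (constant)
  volume has a degenerate histogram; `quantify_oct()` returns zero
  thickness in that case rather than failing, while `select_threshold()`
  called directly reports the degeneracy.
* **Averaging.** Columns with no foreground count as zero thickness, so
  the mean refers to the whole scanned area, not just covered area.
* **Speckle model.** The generator multiplies foreground voxels by
  gamma(shape 3, mean 1) noise - fully developed speckle after the
  instrument's 3-frame scan averaging - and adds Gaussian noise
  (sd = background/4) to the background. Refractive-index correction,
  attenuation and substrate reflections are out of scope; the generator
  renders biofilm signal only.
* **Height field.** Low-pass-filtered Gaussian noise (smoothing sigma 8
  voxels, relative SD 0.25) rescaled to the requested mean and clipped at
  zero, then quantized to whole axial voxels; the quantized field is the
  ground truth. The roughness defaults are pragmatic choices - the study
  reports no roughness distribution for its biofilms.

On synthetic volumes (64 x 64 x 128, foreground/background 10:1, planted
means 5-50 um) the estimate tracks the truth to within two axial voxels;
the residual bias is a roughly one-voxel erosion at the biofilm surface
where the median filter sees a mixed neighbourhood.

## Cavalieri biovolume

`quantify_stack()` uses one threshold per stack, computed on the pooled
histogram of its slices, because the slices of one field of view share
illumination; per-slice Otsu would make areas non-comparable across
slices. The estimator is the plain product-sum `sum(areas) * spacing`
without section-profile corrections - the canonical Cavalieri form, exactly
testable against voxel counts. Slice spacing has **no default**: it is a
physical acquisition constant that must accompany the data. Pearson
correlation (with Fisher-z interval) compares paired OCT and CLSM
quantifications of the same biofilms.

```{r clsm}
stack <- gen_clsm_stack(c(128, 128), n_slices = 3, object_density = 0.05,
                        pixel_size = 0.5, slice_spacing = 2, seed = 7)
quantify_stack(stack$stack)$biovolume - stack$truth$true_biovolume
```

## pH calibration and ratiometry

The calibration family is the asymmetric five-parameter logistic
`R(pH) = d + (a - d) / (1 + (pH/c)^b)^g`, strictly decreasing for
`a > d`, `b, g > 0`, with a closed-form inverse. The package always fits
the curve to the supplied buffer table rather than transcribing published
coefficients: the printed form of such equations is typeset ambiguously
more often than not, while the buffer series itself (pH 4.0-7.8 in steps
of 0.2) identifies the curve to machine precision when noiseless. Fits are
validated for strict monotonicity over the data range and rejected
otherwise.

```{r calib}
model <- fit_calibration(gen_calibration_table(noise_sd = 0, seed = 1))
max(abs(ratio_to_ph(calib_curve(seq(4, 7.8, 0.1), model$params), model) -
          seq(4, 7.8, 0.1)))
```

Default generating parameters (`default_calib_params()`) give a ratio of
about 1.18 at pH 4.0 falling to 0.28 at pH 7.8 with an inflection near pH
5.8, in line with published calibrations of this dye family.

**Averaging order.** Per-pixel conversion to pH followed by the arithmetic
mean is the default (`avg = "pixel-ph"`); converting the mean ratio once
(`avg = "mean-ratio"`) is also available, and the two differ under the
nonlinear map. The per-pixel order treats each pixel as an independent pH
measurement, which matches how ratiometric images are usually reported as
pH maps.

**Cell and background exclusion.** The mask keeps pixels with red-channel
intensity above a noise floor and below a cell threshold. The cell
threshold is Otsu-derived on the above-floor red intensities, but the
split is only accepted as a genuine cell class when the upper class mean
is at least twice the lower class mean; without that guard, Otsu would
bisect the dye's own noise distribution in cell-free images and silently
discard half of the usable pixels. The floor is a fixed fraction (5% of
the 99th-percentile red intensity) rather than Otsu-derived, because
dye-filled fields of view need not contain any dark background at all, and
a histogram split of a unimodal image is meaningless. Both thresholds are
overridable. Out-of-range ratios are clamped to the calibration domain and
counted in the result.

With 5% relative noise in each channel, the mean extracellular pH of a
128 x 128 field is recovered to well within 0.05 units across the
calibrated range; the residual error is dominated by the curvature of the
inverse map near the domain ends, not by averaging noise.

## Trial statistics

**Randomization.** Within one participant, biofilms are ranked by
pre-treatment thickness, consecutive pairs are formed, and one member of
each pair goes to each arm by an independent fair coin (permuted blocks of
size 2). Arm sizes are exactly balanced on every call and the assignment
distribution is uniform over the `2^(n/2)` possibilities.

**Outlier screening.** Four rules vote per record: robust z-score
(|x - median| / (1.4826 MAD) >= 3.29), IQR fences with factor 1.7, Cook's
distance above 4/n from the gamma working model, and the central 99.9%
equal-tailed interval of the empirical distribution. A record is excluded
when flagged by at least half (ceiling) of the methods that could run.
These thresholds are the conventional defaults of composite outlier
frameworks and are all overridable; screening applies to raw outcomes
within an analysis stratum, with Cook's distance computed on the working
model. Note that with fewer than ~1000 observations the empirical 99.9%
interval necessarily flags the sample extremes, which is why the consensus
vote, not any single rule, decides.

**Effect models.** Positive outcomes (thickness, biovolume) use
`glm(family = Gamma(link = "log"))`: a group-only design reproduces group
arithmetic means exactly (a likelihood identity used as a test oracle),
and a pre-treatment covariate enters linearly on the log scale. pH uses
ordinary linear regression, reported as a mean difference. The split-mouth
cross-over structure is handled by participant-level clustering (plus an
optional period term), not by random effects - inference comes from the
bootstrap, not the model's own covariance.

**Cluster bootstrap.** Participants are resampled with replacement, all
their records travelling together; each replicate is refitted via
`glm.fit` on row-indexed design matrices (identical estimates to `glm`,
considerably faster). Percentile intervals (2000 replicates by default;
`stats::quantile` type 7) and a two-sided p-value from the
normal-approximation Wald statistic (original coefficient over bootstrap
SE) are reported. Replicates whose resampled design is rank deficient or
fails to converge are dropped and counted; more than 20% failures aborts.

**Known limitation - small-cluster undercoverage.** With few clusters the
cluster bootstrap is known to be optimistic: the bootstrap SE is biased
down by roughly `sqrt((G - 1)/G)` for `G` clusters, and neither the
percentile nor the Wald construction accounts for the SE's own sampling
noise (approximately a t with G - 1 degrees of freedom). For the trial's
G = 11 participants this predicts actual coverage near 91% for a nominal
95% interval, and the package's own null-coverage study (see
`tests/testthat/test-acceptance.R` and `scripts/acceptance.R`, 500 outer
replicates of 11 clusters of 12 at B = 500) measures coverage consistent
with that prediction. The procedure is reported as specified - percentile
intervals from participant resampling - and users should read its nominal
level with this caveat; at conventional trial sizes the intervals are
mildly anticonservative.

```{r trial}
sim <- gen_trial_dataset(n_participants = 11, n_per_arm = 6,
                         effect_ratio = 1.2, seed = 42)
boot <- cluster_bootstrap(sim$table, outcome ~ treatment + pre_value,
                          B = 500, seed = 1)
effect_report(boot)
```

## What the synthetic generators do and do not emulate

The generators reproduce the *geometry and statistics* the estimators rely
on: surface-attached layers with controllable mean and roughness under
multiplicative speckle; disk-shaped cell clusters on dark background;
two-channel images whose ratio follows a known monotone calibration with
bright cells to exclude; gamma outcomes with multiplicative cluster and
treatment effects and grossly aberrant planted records (at least 10x the
global mean, multiplicative because outcomes are positive). They do **not**
emulate wave-optics speckle correlation, confocal point-spread functions,
dye photophysics, substrate reflections, or biofilm internal structure.
Passing recovery tests on these phantoms therefore validates the
estimators' arithmetic and their behaviour under the modelled noise, not
instrument-specific artefact handling.

Problem sizes used in the shipped validation runs (64 x 64 x 128 OCT
volumes, 128 x 128 pH fields, 500 outer bootstrap replicates at B = 500)
were chosen so that each stage's check exercises realistic dimensions
while the whole suite remains convenient to rerun; all sizes are
parameters, and larger runs only tighten the Monte-Carlo error.

## Numerical notes

* Generators restore the caller's RNG state (`withr::with_seed`); identical
  parameters and seed reproduce outputs bit for bit.
* Otsu ties (several cuts with equal between-class variance, e.g. empty
  histogram gaps between well-separated classes) resolve to the lowest
  optimal cut; for integer data the reported threshold is the midpoint
  between the last background level and the next level, so it lies strictly
  between separated classes.
* The 5PL inverse is evaluated only strictly inside the fitted asymptotes;
  at or beyond the calibrated ratio range the domain endpoints are
  returned (clamping) or an error is raised, by caller's choice.
* `mad()` uses the consistency constant 1.4826, so the robust z threshold
  3.29 corresponds to the normal 99.9% point.
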