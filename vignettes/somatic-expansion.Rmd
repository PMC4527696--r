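---
title: "Quantifying somatic CAG-repeat expansion and its phenotypic consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying somatic CAG-repeat expansion and its phenotypic consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somex)
```

## The measurement problem

Disease-length CAG tracts (here, in a knock-in mouse Huntingtin allele)
continue to expand somatically with age, at tissue-specific rates that
depend on the base-excision-repair glycosylase OGG1. Fragment analysis of
PCR products over the repeat gives, per sample, a table of peak sizes (bp)
and intensities. Three quantities have to be separated:

* the **inherited allele**: the germline repeat length, estimated as the
  midpoint of a Gaussian fitted to the birth/tail reference sample;
* the **somatic change distribution**: the signed difference between the
  repeat classes measured at the age of interest and the inherited
  midpoint, carried as a frequency distribution over integer
  &Delta;-repeats;
* **PCR stutter**: satellite peaks one and two repeat units below (and
  occasionally one above) each true class, which are an amplification
  artifact, not biology.

`somex` implements the full chain — peak tables &rarr; repeat
distributions &rarr; allele fits &rarr; somatic-change distributions —
plus the population statistics used to compare genotypes
(quantile cells with animal-level bootstrap, age-window summaries,
interaction and independence checks) and the motor-phenotype analyses
(rotarod scoring, covariate regression, percentile–performance
association, onset-delay detection). A synthetic cohort generator
produces data with the same statistical structure, so every stage is
testable end to end without any external measurement.

## Peak model and separable least squares

A repeat distribution is modeled as one or two Gaussian peaks evaluated on
the integer repeat grid,

$$ y_i = \sum_k h_k \exp\!\left(-\frac{(x_i-\mu_k)^2}{2\sigma_k^2}\right) + \varepsilon_i. $$

Midpoints $\mu_k$ and widths $\sigma_k$ are the nonlinear parameters;
heights $h_k$ are linear and solved by (non-negative) linear regression at
every iterate — a variable-projection scheme, optimized by bounded
quasi-Newton with an iteration cap of 200 and relative convergence of
1e-10. Widths are bounded below at 0.25 repeats so point-mass references
cannot drive the optimizer degenerate. Initialization takes the two
highest local maxima at least 3 classes apart (or a symmetric split of the
single mode); a second symmetric-split start guards against merged optima.
The test suite checks the scheme against a dense grid-search oracle at
0.1-repeat resolution: on random two-peak mixtures the fitted RSS is
within 1% of the grid optimum (usually below it — the fitter has per-peak
widths and continuous parameters).

For homozygotes the two fitted components are classified by separation $s$
relative to mean width $w$: *coincident* ($s < 0.5w$, refit as one peak),
*separated* ($s > 4w$), else *partial*. Resolution happens once per
animal, on the birth reference.

## Normalization and the homozygote split

Heterozygous samples subtract the rounded fitted midpoint. For resolved
homozygotes we split the age distribution's mass **equally between the two
alleles at the mixture median**: the lower half of the cumulative mass is
referenced to the lower midpoint and the upper half to the upper one, with
the boundary class divided fractionally. Because the two alleles
contribute equal template copies, this makes the frequency-weighted mean
change identically `mean(distribution) − mean(midpoints)`, which is
unbiased. The more obvious rule — assign each class to the nearer
midpoint — systematically truncates the lower allele's expansion ladder
(its large gains are mis-assigned to the upper allele as small ones) and
under-recovers the pooled mean by about one repeat at the default
inherited spread; we rejected it for that reason. The individual
&Delta;-classes between the two midpoints remain ambiguous under any
distribution-level rule; only the mean is protected.

Stutter correction inverts the geometric ladder (ratios `stutter_decay`,
`stutter_plus1`) by active-set non-negative least squares on the dense
support. `peaks_to_distribution()` leaves correction **off** by default —
third-party peak lists should be taken as-is unless the ladder ratios are
known — but `process_cohort()` turns it **on**, because the generator's
ratios are recorded in the run's calibration sidecar and leaving the
ladder in shifts every centroid by a constant ≈ 0.3 repeats, which a
mean-recovery analysis cannot tolerate at small means.

## The synthetic cohort: what it emulates

The generator's defaults are the study conditions the analyses are
calibrated against; each is a single number a practitioner can override
through `cohort_config()`.

* **Inherited alleles**: rounded Gaussian, mean 117, SD 12 repeats; one
  draw per disease allele, independent within homozygotes.
* **Somatic change law**: gamma-distributed magnitudes discretized to the
  nearest integer, sign-flipped to contractions with probability 0.05; the
  gamma mean is inflated by $1/(1-2p)$ so the configured stratum mean is
  the *net* mean change. Shape 1.5 gives the right-skew seen in measured
  distributions. A per-animal-per-tissue gamma factor (mean 1, CV 0.4)
  supplies the between-animal heterogeneity that drives the reported
  standard errors.
* **Expansion means**: the default table carries the age-window
  calibration values per zygosity (heterozygote cells derived so the
  equal-weight combination reproduces the combined values), zero-sum
  regional offsets that preserve the window means while ordering the
  knockout effect HIP > CBL > STR > CTX, and the 10-week homozygote
  striatum anchored at 4.89 / 2.04 repeats. The window means and the
  absolute regional differences cannot both be held exactly (the source
  values are from unbalanced real data); the window means take priority
  because the age-window analyses compare against them directly. Windows
  past 40 weeks use status-independent means — expansion catches up when
  backup repair pathways take over.
* **Traces**: each repeat class renders a main peak at
  `flank_bp + 3n` bp with stutter satellites (decay 0.35, plus-one 0.10)
  and multiplicative lognormal noise (CV 0.05). A within-sample spread
  kernel (`pcr_spread`, SD 1 repeat) reproduces the finite width of real
  birth peaks; without it a birth sample would be a single point and peak
  fitting would be meaningless. The bp &harr; repeat calibration
  (`flank_bp`, default 80) is shared by renderer and parser; it is not
  derivable from primer sequences and must be supplied for real data.
* **Motor phenotype**: `grand_mean` (91.9 s) is the cohort-average rotarod
  time; the female (+7.7 s), knockout (+11 s) and HD-homozygous
  (−23.7 s) effects are deviations centered over the cohort's
  composition. Daily best times are drawn at SD `residual_sd` (20 s),
  capped at 120 s, with the two remaining attempts constructed below the
  best — drawing three raw attempts and maximizing would displace every
  score by the expectation of a 3-draw maximum. Homozygous genotypes
  decline linearly after their onset week (15 with OGG1, 45 without) at
  5 s/week down to a 25 s floor. The slope is deliberately steep: a
  decline much shallower than ~3 s/week produces median deficits inside
  the onset-containing 10-week age window that are smaller than any
  margin distinguishable from sampling noise at 16–24 animals per group,
  i.e. onset would be undetectable by construction at the study's own
  design resolution; the reported collapse of the worst quartile to 25 s
  soon after onset supports the steeper value. Grip failure is one
  Bernoulli outcome per day with a genotype- and age-dependent logit
  calibrated so ~62% of 40-week ogg1-intact homozygotes fail the 5-day
  test. Animals carry their age group's designated assessment age (the
  window's upper bound): cohorts are aged to a target week, tested over
  five days, and sacrificed.

What the generator does **not** emulate: raw electropherogram scanlines
(peak tables are the interface), pedigree structure, linkage between the
two inherited alleles, within-tissue spatial heterogeneity, learning
effects across test days, and any coupling between an animal's expansion
level and its motor performance unless `expansion_coupling` is set.
Passing tests therefore demonstrate that the *pipeline* recovers what the
generator encodes under realistic artifact structure — not that real
tissue obeys the gamma law or the linear decline.

## Population statistics

Pooling weights animals equally (not molecules), so high-signal samples
cannot dominate; "combined and adjusted" genotype groups are stratified
pools with equal stratum weights. Percentile cells use weighted
nearest-rank quantiles (smallest support value whose cumulative frequency
reaches $p/100$), which keeps cell values on the integer &Delta; grid.
Cell standard errors and two-sided p-values come from resampling animals
with replacement (default 2000 replicates, fixed seed, p floored at
$2/(n_\mathrm{boot}+1)$), respecting the clustering of repeats within
animals. Significance codes follow the convention `*` p&le;0.05, `†`
p&le;0.01, `‡` p&le;0.005.

The interaction check (zygosity × knockout status on per-animal mean
change), the inherited-length independence check (per-tissue slope
p-values), and the percentile–performance association (per-animal
quantile values against score, adjusted for zygosity, knockout status,
age and sex; 20-rpm scores per the reporting convention) are ordinary
least-squares fits via `stats::lm`; no multiple-testing correction is
applied to the association grid because its source reports unadjusted
p-values. Under null generators all three hold their nominal 5% false
positive rate within ±2% (verified at 400–500 replicates in the test
suite).

## Onset detection

Onset is detected per genotype against a wild-type reference by
**baseline-adjusted median deficits**: deficit(g) = (reference median −
genotype median), centered by the earliest shared age group, so constant
genotype offsets — which are present from the first age group — do not
register as decline. The earliest group whose adjusted deficit exceeds the
margin, with the exceedance persisting into the next group (trailing
groups count alone), is the onset group, reported by its midpoint week.
The default margin is 1.5 × the reference group's interquartile range —
the Tukey outer-fence factor applied to the wild-type spread. At 1 × IQR,
sampling noise in group medians (≈ 2.5 s at 20 animals/group) produces
occasional false early triggers in slow-declining arms; 1.5 × IQR keeps
the false-trigger rate near zero while a post-onset deficit of ≥ 25 s is
still detected essentially always.

## Numerical choices and degenerate inputs

* Rounding is half-away-from-zero throughout; ties cannot occur for exact
  3-bp spacing.
* Distributions renormalize after every thresholding or correction step;
  an empty result is a typed error (`somex_empty_distribution`), never a
  silent zero.
* A reference with fewer than 3 support points returns a degenerate point
  fit (midpoint = weighted mean, width at the 0.25 bound) instead of an
  error, so noiseless point-mass references stay usable.
* The 120 s rotarod cap censors the upper tail of the best cells
  (expected time ≈ 96 s at default noise), attenuating recovered effects
  by ≈ 7% (female), ≈ 11% (knockout) and ≈ 6% (HD) of their configured
  sizes at `residual_sd = 20`; the package fits plain least squares
  regardless, matching the source protocol, and the tests characterize
  the attenuation rather than switching to a censored model.
* Regression-calibration cohorts are simulated at ages 5–15 weeks, before
  either decline onset, because the intercept effects are only
  identifiable where the decline terms are inactive.

## Problem sizes used in validation

The shipped validation suite runs, per fixed seed: 20,000 birth samples
for the inherited-allele recovery; 20 animals per arm for the 10-week
striatum recovery; 20 animals per stratum across four regions for the
age-window recovery; 30 per arm for the regional-effect recovery; 600
animals for the covariate regression; 50 replicate cohorts of 300 animals
for the onset-delay rate; and 400–500 replicates for the null
calibrations. These sizes put Monte-Carlo error comfortably inside each
check's tolerance while keeping the whole suite in the ten-minute range
on one CPU.

## Known limitations

* Absolute repeat calibration is only as good as the supplied `flank_bp`;
  there is no internal ladder.
* The equal-mass homozygote split protects the mean change, not the shape
  of the &Delta; distribution between the two midpoints.
* Stutter correction assumes the configured geometric ladder; it does not
  estimate ratios from data.
* Quantile-cell p-values are bootstrap-based and inherit its granularity
  at small group sizes.
* `two_sample_z()` implements the documented
  $(m_1-m_2)/\sqrt{se_1^2+se_2^2}$ form; on the published striatum
  summary values it gives 1.58, and we found no standard formula that
  reproduces the printed 4.50 from those numbers — the discrepancy is
  flagged rather than tuned away.
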