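---
title: "Quantifying cranial fluctuating asymmetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cranial fluctuating asymmetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctasym)
```

## The scientific problem

Fluctuating asymmetry (FA) — small, random, individual-specific departures
from bilateral symmetry in a trait that is symmetric on average — is widely
used as a morphological proxy for developmental instability: the noisier an
individual's development, the less precisely its left and right sides mirror
each other. Distinguishing FA from two confounders is the whole analytical
problem:

* **directional asymmetry (DA)**, the population-average left–right
  difference shared by everyone (e.g. a consistent skew), and
* **measurement error**, which masquerades as asymmetry whenever a landmark
  is digitized slightly differently on the two sides.

A cranium is a single structure with internal (*object*) symmetry, so
left/right sides cannot be separated into two objects. The standard
geometric-morphometric treatment is therefore: digitize a configuration of
3D landmarks (here 13 bilateral pairs plus 8 midline points, 34 landmarks),
**twice per specimen**, and analyze each configuration jointly with its
reflected, relabeled mirror image.

## Superimposition with object symmetry

Each configuration is mirrored by negating one coordinate axis and swapping
the labels within every bilateral pair (`reflect_relabel()`); midline
landmarks keep their labels. Because generalized Procrustes analysis (GPA)
removes orientation, the mirroring plane need not coincide with the
anatomical midsagittal plane — any fixed reflection serves.

All `2nr` shapes (n individuals × r replicates, originals and mirrors)
enter one GPA (`gpa()`): configurations are centered, scaled to unit
centroid size, and rotated by least squares to the running consensus until
the consensus stabilizes. Three numerical choices matter:

* **Proper rotations only.** Rotation matrices are constrained to
  determinant +1; reflection enters the analysis only through the explicit
  mirroring step, never through the rotation solver.
* **Symmetrized consensus.** A set closed under reflect-relabel has a
  reflection-invariant consensus in the limit; we enforce this exactly at
  every iteration by averaging the consensus with its own reflection. A
  useful consequence (and a tested invariant): the aligned mirror is then
  *exactly* the reflect-relabel image of the aligned original, so the
  symmetric and asymmetric components below are exactly orthogonal.
* **Convergence.** Iteration stops when the root-mean-square change of the
  consensus falls below 1e-10 (or at 100 iterations); on the data sizes
  used here convergence takes a handful of iterations.

Scaling to unit centroid size means deviations are treated directly in the
aligned coordinate space without a formal tangent-space projection. At the
asymmetry magnitudes this analysis targets (FA scores around 0.015 in
Procrustes units) the curvature of shape space is negligible; this is an
approximation and is documented as such.

## Symmetric/asymmetric decomposition and FA scores

For each observation with aligned original $o$ and aligned mirror $m$ and
consensus $c$:

$$\text{sym} = \tfrac12 (o + m) - c, \qquad \text{asym} = \tfrac12 (o - m).$$

The two components live in the reflection-invariant and anti-invariant
subspaces (dimensions $3p + 2u - 4$ and $3p + u - 3$ for $p$ pairs and $u$
midline points in 3D, after removing similarity transforms), are exactly
orthogonal, and sum to the observation's total deviation (a Pythagorean
identity verified per observation in the tests).

The **DA vector** is the mean asymmetric component across all observations.
The per-individual **Procrustes FA score** is

$$\text{FA}_i = \lVert \bar a_i - \overline{a} \rVert,$$

the Procrustes norm of the individual's replicate-averaged asymmetric
component after subtracting DA. Replicates are averaged before the norm is
taken, so digitizing noise partially cancels; no degrees-of-freedom
rescaling is applied (the archival tooling this mirrors does not publish
its exact normalization, so the definition above is used consistently and
stated explicitly).

One subtlety the test suite makes explicit: an asymmetry vector injected
into raw coordinates is recovered only after projecting out the similarity
directions (translations, scale, and the three infinitesimal rotations of
the template), because superimposition absorbs those components. Oracles
for recovery tests must therefore compare against the projected vector, not
the raw one.

## Procrustes ANOVA

The replicate design supports a two-factor decomposition with individuals
and sides as main effects:

| Stratum | SS | df |
|---|---|---|
| individual | $r \sum_i \lVert \bar s_i \rVert^2$ | $(n-1)(3p+2u-4)$ |
| side (DA) | $nr \lVert \overline a \rVert^2$ | $3p+u-3$ |
| individual × side (FA) | $r \sum_i \lVert \bar a_i - \overline a \rVert^2$ | $(n-1)(3p+u-3)$ |
| error | replicate deviations, both components | $(r-1)\,n\,(d_{sym}+d_{asym})$ |

F ratios follow the mixed-model expectations: individual and side are
tested over the individual-by-side mean square and the interaction over
measurement error; p-values are parametric (Goodall-style F at the
Procrustes df). Permutation tests are out of scope. With a single
digitization per specimen the error stratum is empty and the fit refuses to
run, since FA cannot then be separated from measurement error.

**Percent variation is reported as SS shares.** Verbal descriptions of
this quantity sometimes attribute it to mean squares, but the percent-
variation columns of published tables of this kind are reproduced by SS
shares, which is what `percent_variation()` computes (a documented,
deliberate choice).

## Mixed models of FA scores

FA scores are modelled with linear mixed-effect models fitted by REML via
`lme4`/`lmerTest` — the same engine practitioners use for this analysis —
with Satterthwaite fractional denominator df for the t tests. We did not
re-derive the REML optimizer: the modelling stage is standard, the package
wraps it behind `fa_lmm()`, and the in-house effort is reserved for the
morphometric machinery above. Coding choices:

* sex: factor, reference female; age at death: continuous years;
* decade of birth: a single linear trend per decade from 1950 (model
  summaries of this design report one estimate for decade, not level-wise
  contrasts — hence a trend term, an interpretation documented here);
* exactly one hurricane-related term per model: exposed yes/no; number of
  hurricanes (categorical 0/1/2, reference 0); or developmental stage at
  exposure (fetal/juvenile/adult, reference fetal, exposed subset only);
* matriline: always the (only) random intercept. A matriline variance
  estimated at the zero boundary is kept at 0 and flagged (`singular`).

`fa_model_suite()` runs the four standard variants (all individuals with
exposed-yes/no; never-exposed subset without a hurricane term; all
individuals with hurricane count; exposed subset with stage at exposure).
Post hoc Tukey pairwise contrasts of stage at exposure (the three pairs
fetal–juvenile, fetal–adult, juvenile–adult) use `multcomp` z statistics
with step-down Bonferroni–Holm adjustment.

`power_simulation()` estimates power curves by simulation: effects are
parameterized as **percent change in the mean FA score** (the natural scale
for a non-negative score whose absolute value is superimposition-specific),
injected into score-level simulations (or any user-supplied simulator,
e.g. a full landmark-level pipeline), refitted, and tallied at the chosen
α with a Monte-Carlo standard error.

## The synthetic-data generator

`simulate_dataset()` builds data with exactly the statistical structure the
analysis assumes, so every stage is testable without access to physical
specimens:

1. a random symmetric template (pairs mirrored across x = 0, midline on
   the plane), unit centroid size;
2. per individual: a symmetric deviation (pairs $(a,b,c)/(-a,b,c)$,
   midline $(0,b,c)$; SD `sigma_sym`) and an asymmetric FA deviation
   (pairs $(a,b,c)/(a,-b,-c)$, midline $(a,0,0)$; SD `sigma_fa`, scaled by
   a group factor κ for exposure groups), plus a fixed DA vector of norm
   `da_magnitude`;
3. per replicate: iid coordinate noise `sigma_err`;
4. per configuration: an arbitrary random rotation, translation and
   scaling, which the superimposition must undo.

The two deviation constructions are exact eigenvectors of reflect-relabel
(+1 and −1), hence exactly orthogonal — verified in the tests, together
with the subspace rank counts ($3p+2u$ and $3p+u$ before similarity
removal, consistent with the df formulas after it).

**Default magnitudes** (`sigma_err = 0.0027`, `sigma_fa = 0.001`,
`sigma_sym = 0.008`, `da_magnitude = 0.0046`) were derived once,
analytically, from expected mean squares: with per-direction error variance
$\sigma_e^2$, the strata expectations are $MS_{err} \approx \sigma_e^2$,
$MS_{FA} \approx \sigma_e^2 + r\,c_a\sigma_{fa}^2$,
$MS_{ind} \approx \sigma_e^2 + r\,c_s\sigma_{sym}^2$ and
$MS_{side} \approx MS_{FA} + nr\,\delta^2$ (the $c$'s are subspace
normalization constants of the generator draws). Solving these so that the
variance strata occupy roughly 91 / 0.3 / 3.6 / 5 percent of total
variation — the regime reported for replicate-digitized cranial data, with
an FA-to-error F ratio near 1.5 — also lands the implied mean FA score at
≈ 0.0156, consistent with the ≈ 0.015 typical of such studies. These are
calibrated defaults, not ground truth; they make the default scenario
*realistic*, not a replica of any particular sample.

Metadata mirror the study composition: 275 individuals (154 F / 121 M),
101 hurricane-exposed (10 fetal / 50 juvenile / 41 adult at exposure; 78
with one hurricane, 23 with two), 174 never exposed, births across
1950–2005, 20 maternal lineages (a realistic count for a closed colony;
the source material does not state one), ages 0.75–31 years with skeletal
maturity at 8 years in males and 15 in females. Exposure is injected as a
multiplicative inflation of `sigma_fa` (the minimal mechanism by which a
developmental insult raises FA); matriline affects only the score-level
generator (`simulate_scores()`, defaults mean 0.015, residual SD 0.004,
matriline SD 0.001), keeping the two generators composable.

What the generator does **not** emulate: anatomically realistic cranial
geometry, landmark-specific error covariance (real digitizing error is
anisotropic and landmark-dependent), allometry, age- or sex-dependent FA,
and non-Gaussian tails in the score distribution (real FA score SDs tend
to exceed the isotropic ideal — 0.004 observed against ≈ 0.0017 implied by
an isotropic model). Passing tests on synthetic data therefore demonstrate
the *correctness of the machinery* under the stated model, not robustness
to every pathology of real specimens.

## Degenerate inputs, tie-breaks, tolerances

* Configurations with missing or non-finite coordinates are rejected —
  no imputation rule exists for this design, so none is invented.
* Zero-centroid-size (degenerate) configurations abort the fit.
* `r = 1` designs abort with an explanatory message (see above).
* An all-identical decomposition yields zero SS, a warning, and undefined
  p-values rather than NaN arithmetic.
* Component orthogonality and the Pythagorean identity are enforced at
  1e-9; consensus reflection-invariance at 1e-6; GPA invariance of FA
  scores under random rigid motions and scalings of the inputs at 1e-6.
* Exact-equality expectations (involution, determinism of the generator)
  are asserted bitwise.

## Problem sizes used in the shipped checks

The test suite exercises the full study design (275 × 2 × 34 landmarks)
where the claim depends on it — the df column, the end-to-end detection of
a 40% fetal FA inflation (20 pipeline replicates, power reported with its
Monte-Carlo SE) — and reduced designs elsewhere: null calibration of the
interaction F uses 200 seeds at n = 15 with 3 pairs + 2 midline points;
mixed-model type-I calibration uses 1000 score-level simulations at
n = 150; parameter recovery uses 200 simulations at n = 300. These sizes
were chosen to give Monte-Carlo standard errors comfortably inside the
asserted bands while keeping a full check run in minutes on one core.

## Known limitations

* The FA-score normalization of the archival tooling is not published;
  scale comparisons across software should use relative, not absolute,
  scores.
* Parametric Goodall-style F tests assume isotropic, independent
  variation across shape dimensions; permutation alternatives are not
  implemented.
* Procrustes data are analyzed without tangent projection (see above).
* The power analysis parameterizes effects as percent change in mean FA;
  other effect-size conventions (e.g. percent of variance) require the
  user-supplied simulator path.
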