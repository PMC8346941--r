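---
title: "Deriving hemoglobin reference cutoffs from multi-survey biomarker data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving hemoglobin reference cutoffs from multi-survey biomarker data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbref)
```

## The estimand and the workflow

Anemia screening rests on fixed hemoglobin (Hb) cutoffs — 11.0 g/dL for
preschool children, 12.0 g/dL for nonpregnant women — that are statistical
in origin: the fifth percentile (P5) of Hb in a healthy reference
population. `hbref` re-derives that lower reference limit from
individual-level, multi-survey biomarker data in four stages:

1. **Pre-adjustment** of measured Hb for altitude and smoking;
2. **Case definition**: an apparently healthy subpopulation selected on
   ferritin, vitamin A, inflammation, and malaria status;
3. **Estimation and pooling**: per-survey empirical P5 with a
   Woodruff-type CI, pooled by REML random-effects meta-analysis, with a
   linear quantile mixed model quantifying how much P5 variation is
   between-survey;
4. **Physiological validation**: the Hb-for-sTfR (soluble transferrin
   receptor) curve, whose second inflection point marks the Hb level at
   which compensatory erythropoietic drive accelerates.

Because the microdata such analyses use are access-restricted, the package
also contains a first-class synthetic generator that emulates the assumed
data structure with a planted, analytically known truth table; all
statistical guarantees quoted below are verified against it in the test
suite.

## Hb pre-adjustment

Altitude raises Hb; the correction subtracted from measured Hb is the
standard CDC/WHO polynomial `c(A) = -0.032 A + 0.022 A²` with `A` in
thousands of feet (`A = meters × 0.0032808`), applied only at or above
1000 m — below that no adjustment is needed. Women who smoke lose a flat
0.3 g/dL (the WHO any-smoker decrement; intensity-graded decrements are out
of scope). Records without altitude or smoking data pass through
unadjusted, mirroring survey-by-survey availability. Two policy decisions
are deliberate: adjustments are applied exactly once (the record set is
tagged, re-adjustment is an error), and a nonpositive adjusted Hb raises an
error rather than being clipped — silent truncation would bias the lower
tail that is the estimand.

## The apparently healthy case definition

Thresholds are inclusive on the healthy side: ferritin ≥ 12 ng/mL
(children) / 15 ng/mL (women), RBP or retinol ≥ 20.1 µg/dL, CRP
≤ 0.5 mg/dL, AGP ≤ 1 g/L, no known malaria. Optional markers follow
"where measured" semantics: an unmeasured marker never excludes a record,
and when only one of CRP/AGP is measured that one decides (both measured:
both must pass). Ferritin and vitamin A are used without
inflammation-regression adjustment, because inflamed individuals are
excluded outright. Surveys with fewer than 100 healthy records are dropped
whole (configurable), since a tail percentile on fewer records is not
robust. Two monotonicity properties are tested: raising any threshold can
only shrink the healthy set, and deleting an optional column can only grow
it.

## Per-survey P5 and the Woodruff interval

The quantile convention is fixed to the left-continuous inverse ECDF (order
statistic `x_(⌈np⌉)`, sample-quantile type 1): "quantile ranking" admits
several conventions, and this one makes the CI construction
self-consistent, because estimate and interval endpoints come from the same
step function. Ties at the 0.1 g/dL instrument resolution are handled by
the same order-statistic rule, without jittering.

The CI inverts a Wald interval on the ECDF proportion:
`SE(p̂) = sqrt(p(1-p)/n)` at design effect 1 (the cohort is treated as
simple random sampling; analyses are unweighted), bounds `p ± z·SE` mapped
through the empirical quantile function, and `se_q` reported as the CI
half-width over `z`. For n too small for the bounds to stay inside (0, 1)
the interval is undefined and the package raises an error rather than
truncating. Simulation places empirical coverage at n = 1000 within
[93%, 97%] at nominal 95%.

## REML pooling and heterogeneity

Survey estimates are pooled under `y_i = µ + u_i + e_i`,
`u_i ~ N(0, τ²)`, `e_i ~ N(0, v_i)` with `v_i` the squared Woodruff SEs.
τ² maximizes the restricted likelihood by Fisher scoring with a
nonnegativity projection (tolerance 1e-8, max 200 iterations,
step-halving); the estimate is verified in tests against a brute-force grid
search of the restricted likelihood (step 1e-4) and against an independent
meta-analysis implementation. µ̂ is the inverse-variance weighted mean at
the converged weights, with a normal-quantile Wald CI (no Knapp–Hartung,
matching the Wald-style intervals the workflow reports elsewhere).
Heterogeneity is summarized by τ — an SD in g/dL, directly comparable to
the between-survey spread — and by Cochran Q at fixed-effect weights, the
conventional choice when the weighting is not otherwise specified.

## The quantile mixed model and its ICC

Whether pooling is defensible is judged at the quantile of interest, not at
the mean: the package fits a linear quantile mixed model at p = 0.05 using
the asymmetric Laplace (ALD) working likelihood with a survey random
intercept, fixed effects intercept + mean-centered age + age² (+ sex for
children). Age enters in years by default (children's months divided
by 12), putting the slope on the conventional per-year scale; the unit is a
config switch.

**Integration.** The marginal likelihood integrates the random intercept
against `N(0, ψ²)`. Plain Gauss–Hermite quadrature is inaccurate here
whenever the cluster likelihood is much narrower than ψ (large clusters,
small ALD scale) — errors reached 0.1 log-likelihood units at 31 nodes in
our checks. The package instead evaluates the integral **exactly**: the
summed check loss is piecewise linear in the intercept with breakpoints at
the cluster residuals, so on each segment the integrand is
`exp(a + b·u)·φ(u; 0, ψ²)`, a closed-form normal-probability term, and the
cluster likelihood is a log-sum-exp over segments. Gauss–Hermite remains
available (`method = "gh"`) for comparison. Optimization is Nelder–Mead
over `(β, log σ, √ψ)` with three seeded, jittered restarts against local
optima; the maximized likelihood is verified against an adaptive-quadrature
grid-search oracle on a toy problem.

**The ICC.** The variance decomposition at the quantile uses the ALD
residual variance `σ_e² = σ²(1−2p+2p²)/(p²(1−p)²)`:
`ICC_between = ψ²/(ψ² + σ_e²)`. No standard print-out defines this
quantity; it is the standard construction for quantile mixed models and is
an assumption of the method, stated here prominently. One practical
consequence: under Gaussian within-survey noise the ALD working scale
converges to `σ_w·φ(z_p)`, so `σ_e²` is about 4.3 σ_w² at p = 0.05 and the
ICC is substantially smaller than the naive variance fraction
τ²/(τ² + σ_w²). Parameter-recovery tests therefore plant the fraction in
the model's own error law (ALD noise), where ψ²/(ψ² + σ_e²) is exactly the
generated fraction; the truth table records both that value and the naive
fraction.

Significance of the random intercept uses a likelihood-ratio test against
the `ψ = 0` model, referred to the 50:50 mixture of a point mass at zero
and χ²₁ — the boundary-corrected null for a variance component.

## The Hb–sTfR curve and its inflection points

sTfR rises with tissue iron deficiency and erythropoietic drive, so the
shape of E[Hb | sTfR] carries physiological information: an initial
inflection on the sTfR axis (tissue iron deficiency onset) and a second
inflection past which Hb declines in a linear "erythropoietic drive" phase.
This analysis deliberately uses **all** records with sTfR and Hb — no
healthy filter — to span the full range of iron states.

The curve is a restricted (natural) cubic spline with 5 knots at Harrell's
default quantiles (0.05, 0.275, 0.50, 0.725, 0.95 of sTfR; explicit knots
are accepted). Its second derivative is piecewise linear with breakpoints
at the knots and identically zero outside the boundary knots, so
inflection points — sign-change roots of f″ — are found exactly on each
linear piece, in increasing sTfR order; phrased differently, the
"derivative equation" is solved in closed form and no numerical ODE solver
is involved. Curvature at roundoff scale (a fit to exactly linear data) is
treated as zero, and fewer than two sign changes raises an "insufficient
curvature" error rather than returning a fabricated point.

The CI for the second inflection's Hb is a nonparametric pairs (case)
bootstrap with the BCa correction: median-bias `z₀ = Φ⁻¹(#{θ* < θ̂}/B)` and
jackknife-skewness acceleration. Resamples where the statistic fails (no
second inflection) are dropped and counted; more than 10% failures aborts
the interval. For large n a grouped (delete-block) jackknife is available
for the acceleration term; it converges to the delete-one value and cuts
the cost of the n spline refits. Given (data, B, seed) the interval is
reproducible bit for bit.

Two numerical caveats are worth stating. First, at very large n the CI
becomes narrower than the small bias induced by estimating knot locations
from sample quantiles, so the planted value can fall just outside an
extremely tight interval; coverage checks therefore run at n = 5000, a
realistic single-group scale. Second, the default B in the config is 5000;
tests and the analysis scripts use B = 999 for speed, which the BCa
construction tolerates well.

## The synthetic generator

`synth_config()` defines the study conditions; its defaults are calibrated
once to look like a multinational anemia-survey compilation and are
documented as illustrative, not as reproduction targets:

- 22 (children) / 21 (women) surveys of 500–3000 individuals;
- healthy-component Hb mean 11.9 / 13.1 g/dL, within-survey SD 1.4 g/dL,
  between-survey SD τ = 0.55 g/dL (which puts the model-based ICC at P5
  near 3.5%, the magnitude reported for such compilations);
- child age slope +0.19 g/dL per year (a location-shift model, so the slope
  holds at every quantile), women −0.03;
- unhealthy mixture fraction 0.60 (children) / 0.44 (women), shifted
  −0.8 g/dL, each unhealthy member violating at least one healthy-criteria
  threshold through its generated biomarkers;
- surveys measure vitamin A / malaria / altitude / smoking with
  probabilities 0.8 / 0.5 / 0.4 / 0.5, and the generator **adds** the
  altitude and smoking increments that the adjustment stage later removes;
- a planted two-inflection restricted-cubic-spline Hb–sTfR law
  (`rcs_curve_from_d2()` builds it from curvature values at the knots, so
  the true inflection coordinates are known in closed form), with the sTfR
  marginal lognormal, truncated at its 0.975 quantile to emulate a finite
  assay range, and spline knots placed at the truncated marginal's true
  quantiles so the planted curve lies in (essentially) the basis the
  analysis fits.

The truth table records every planted parameter, including the analytic
healthy-component P5 — obtained by numeric inversion of the age-by-noise
convolution CDF (Gauss–Legendre over the uniform age distribution), not by
Monte Carlo — and both between-survey variance fractions discussed above.
Randomness uses R's default Mersenne–Twister with the seed recorded in the
truth table and run manifests; within R this gives bit-level
reproducibility across platforms, which is the property the workflow needs.

What the generator does **not** emulate: country-specific Hb distributions,
assay error structure and inter-assay sTfR harmonization, survey design
weights, hemoglobinopathies, or correlated biomarker panels. Passing tests
demonstrate that the estimators recover what was planted under the assumed
structure — they are statements about the software, not about any real
population.

## Problem sizes and runtime choices

The test suite and scripts choose sizes that keep full runs to minutes:
coverage of the Woodruff interval uses 2000 replicates at n = 1000; REML
recovery 200 replicates at k = 25; quantile-mixed-model recovery 20
replicates at 22 surveys × 150 records (with the null case at 22 × 600);
inflection-recovery coverage 100 replicates at n = 5000 with B = 999; the
ICC analysis script caps each survey at 400 records. These are analysis
choices — estimates at these sizes are stable to the tolerances tested —
and all are parameters, not constants.

## Known limitations

- The ALD-based ICC is model-defined; other reasonable decompositions at a
  quantile would give different percentages.
- REML pooling treats the Woodruff SEs as known sampling variances.
- The inflection-point machinery requires genuine curvature; monotone but
  nearly linear relationships correctly error out rather than yielding a
  threshold.
- Survey weights are intentionally unsupported; all estimates are
  unweighted.
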