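---
title: "Reduced-order CT-FFR: model, calibration, and virtual trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order CT-FFR: model, calibration, and virtual trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctffr)
```

## The problem

Fractional flow reserve (FFR) — the mean pressure distal to a coronary
stenosis divided by aortic pressure under maximal hyperemia — is the
reference standard for deciding whether a stenosis causes ischemia
(FFR < 0.80).  CT-FFR estimates it non-invasively by simulating blood flow
on vessel geometry extracted from CT angiography.  The decisive ingredient
is not the flow solver but the *boundary conditions*: microvascular
resistance under hyperemia cannot be measured from CT, so its parameters
must be calibrated against invasively measured FFR and then frozen before
prospective use.

This package implements that workflow at reduced order: a 1-D network model
of the coronary tree, a calibration layer that fits the boundary parameters
by minimizing the mean squared error (MSE) against measured FFR, a seeded
virtual-cohort generator, and the full diagnostic-performance analysis a
validation trial reports (sensitivity/specificity with confidence
intervals, AUC, Bland–Altman agreement, per-FFR-bin accuracy, gray-zone
stratification, and univariate logistic screening of misdiagnosis risk
factors).

## The hemodynamic model

A vessel tree is a set of centerline segments, each sampled as
(arc length, lumen radius, reference radius) triples at a default step of
0.25 mm — fine enough to resolve 1–2 mm stenosis throats.  The reference
("disease-free") wall is the linear taper of the healthy segment; a lesion
narrows the lumen by a C¹ cosine-squared bump (configurable to rectangular)
whose minimum lumen diameter is `reference diameter × (1 − degree/100)`.

Blood is incompressible and Newtonian with density 1060 kg/m³ and dynamic
viscosity 0.004 Pa·s.  Each segment obeys the standard reduced-order
stenosis loss law

$$\Delta P = a\,Q + b\,Q\,|Q|,$$

where

* $a = \int 8\mu / (\pi r(s)^4)\, ds$ is the integrated Poiseuille
  coefficient of the lumen profile (trapezoidal over the samples), and
* $b = K_t\,\tfrac{\rho}{2}\left(\tfrac{1}{A_\mathrm{throat}} -
  \tfrac{1}{A_\mathrm{ref}}\right)^2$ is the post-stenotic expansion
  (jet) loss, booked at the lesion throat.

The $Q|Q|$ form keeps the law well defined under flow reversal; on the
acyclic trees used here converged flows are asserted non-negative rather
than assumed.  At the stenosis degrees where the 0.80 decision threshold is
crossed, the expansion term carries 50–65% of the total pressure loss, so
both coefficients matter.

Each outlet drains to zero venous pressure through a single microvascular
resistance allocated by a diameter power law and reduced by hyperemia:

$$R_i = \frac{R_\mathrm{ref}}{h}\left(\frac{d_i}{d_\mathrm{ref}}\right)^{-k}.$$

The boundary-parameter vector and its defaults are:

| parameter | meaning | default | unit |
|---|---|---|---|
| $P_a$ | mean aortic (ostium) pressure | 93 | mmHg |
| $R_\mathrm{ref}$ | resting microvascular resistance at $d_\mathrm{ref}$ | 248 | mmHg·s/mL |
| $d_\mathrm{ref}$ | reference outlet diameter | 3.0 | mm |
| $k$ | outlet-resistance diameter exponent | 2.7 | – |
| $K_t$ | expansion-loss coefficient | 1.0 | – |
| $h$ | hyperemia factor (divides resting resistance) | 4 | – |

$R_\mathrm{ref}$ is chosen so a healthy 3.0 mm outlet at 93 mmHg carries
about 1.5 mL/s of hyperemic flow; $k = 2.7$ sits between area scaling
($k=2$) and Murray's law ($k=3$); $h = 4$ quarters resting microvascular
resistance under hyperemia.  These are this package's own definitions —
production CT-FFR systems do not publish their boundary parametrizations —
and all are configuration-exposed.  $P_a$ is treated as a known per-run
input rather than a calibration target because FFR normalizes by it.
Internally the model works in SI and converts at the interfaces
(1 mmHg = 133.322 Pa).

### The solver

`solve_steady_flow()` uses damped successive substitution: the quadratic
term $b\,Q|Q|$ is folded into an effective linear resistance at the
previous flow iterate, and the resulting resistor tree is solved *exactly*
(bottom-up equivalent resistances, top-down flows).  Damping is 0.5, the
convergence tolerance is $10^{-8}$ on the maximum relative flow change, and
the iteration cap is 200; non-convergence raises an error carrying the
residual.  Because each pass solves the linearized tree exactly, mass
conservation at junctions holds to machine precision at every iterate, and
with $K_t = 0$ a single pass reproduces a dense nodal-conductance solve to
$\sim 10^{-14}$ (the test suite checks this against an independent
Laplacian oracle on 100 random trees).

CT-FFR is the pressure at any point divided by the ostium pressure.
`measure_ffr()` interpolates the pressure profile 25 mm (2–3 cm) distal to
the lesion end, mirroring the invasive measurement protocol; at a
bifurcation the branch with the larger distal reference diameter is
followed, and a probe beyond the terminal node clips there with a flag.

## Calibration

`calibrate_ffr()` minimizes the MSE between computed and measured FFR over
a retrospective training set.  The free set defaults to
$\{R_\mathrm{ref}, k, K_t\}$; $h$ is excluded because only
$R_\mathrm{ref}/h$ enters the model, making the pair unidentifiable.  The
optimizer is multi-start bounded Nelder–Mead: 8 Latin-hypercube starts in
the bound box, a logistic transform mapping the box to an unconstrained
space (the objective is smooth, but solver-in-the-loop gradients are not
available), and a polishing restart from the best start.  The fit is
deterministic for a fixed seed.  A warning is raised when the training set
spans less than 20 percentage points of stenosis degree, where the free
parameters are weakly identified.

The returned `ffr_cal` object behaves like a classic R model fit (`print`,
`summary`, `coef`, `predict`, `fitted`, `residuals`, `simulate`, `plot`);
`freeze_and_apply()` applies the fitted parameters, unchanged, to a
prospective cohort, recording per-vessel failures as missing values rather
than aborting.

### Identifiability and the designed training set

A Fisher-information analysis of the MSE estimator (Jacobian of the
per-vessel computed FFR with respect to the free parameters) shows that
$K_t$ is the weakest-identified parameter: its influence is concentrated in
severe, high-flow lesions and is partially collinear with
$R_\mathrm{ref}$ and $k$.  With 80 training vessels and measurement noise
SD 0.02, the asymptotic relative SD of $\hat K_t$ is about 11% even under
greedy optimal design — an information floor of the model class, not an
optimizer artifact (multi-start refits land on the same minimum).

`calibration_design()` therefore builds the training set used in the
package's recovery experiments as a factorial: degrees
{30, 45, 60, 70, 78, 84, 88, 90}% weighted toward the informative severe
range, crossed with short (6 mm) and long (30 mm) lesions — which separates
the flow-squared expansion loss from the integrated viscous loss — and five
vessel calibers from 2.6 to 4.2 mm, which separates the outlet power law
from the overall flow scale.  On noiseless data the free parameters are
recovered to machine precision; with noise SD 0.02 the expected recovery
error is a few percent for $R_\mathrm{ref}$ and $k$ and of order 10% for
$K_t$, with draws occasionally beyond 10% for the reason above.

## The virtual cohort

`generate_cohort()` emulates the per-vessel composition of a multicenter
CT-FFR validation cohort: 46.2% of vessels ischemic (FFR < 0.80), 13.7% of
all vessels in the 0.76–0.80 gray zone, single target lesions of 30–90%
diameter stenosis on vessels of at least 2.0 mm.  Each vessel is a
three-segment tree (proximal trunk carrying the target lesion — so the
stenosis sees the full vessel flow — plus a main continuation and a side
branch) with trunk diameters uniform on 2.4–4.4 mm.

The "invasive" measurement comes from the reference model with two noise
sources: a per-vessel log-normal perturbation of microvascular resistance
(SD 0.15, between-vessel physiology) and additive measurement noise
(SD 0.02).  Rather than sampling stenosis degree and accepting whatever FFR
distribution results, the generator draws a *target* FFR from a stratified
marginal (below-gray / gray / above-gray, with Beta-shaped tails) and
solves for the degree in [30, 90] by root-finding on the perturbed model,
clamping at the bounds.  This makes the configured stratum fractions
structural — at n = 2000 they match the targets to binomial sampling error
(±1–2 points) — instead of quantities to be tuned.  CTA readings add
Gaussian reader noise (SD 8 percentage points, truncated to [0, 100)),
chosen so CTA ≥ 50% specificity lands far below CT-FFR specificity, as
trials consistently observe.

Plaque covariates (lesion length, plaque/calcified/non-calcified volume,
and a log-normal calcium-score surrogate scaled to calcified volume) are
drawn log-normally with stratum-specific medians ranked as published
gray-zone burden tables rank them: gray-zone plaque load above
non-ischemic lesions, calcified volume highest in the gray zone.  Lumen
area, lumen diameter, and plaque burden are computed from the actual lesion
geometry, so the published pattern of larger lumen caliber in the gray zone
than in deeply ischemic vessels emerges from the lower gray-zone stenosis
degrees rather than being imposed.

### What the generator does and does not emulate

It reproduces the statistical structure the trial analysis consumes —
stratum fractions, the measured-vs-computed scatter near the threshold, the
rank ordering of plaque covariates.  It does not model imaging physics,
segmentation error correlated with calcium, multi-lesion vessels,
per-patient clustering of vessels, or serial/diffuse disease.  Passing
tests on this cohort therefore validates the *analysis machinery and the
model's internal consistency*, not clinical accuracy on real images; the
trial-reported real-data agreement numbers (r = 0.72, AUC ≈ 0.9 against
invasive FFR) are not reproducible without the trial's images and are not
targets here — on synthetic cohorts the computed-vs-measured agreement is
optimistic (r ≈ 0.98) because model error is absent by construction.

## The evaluation layer

Classification conventions follow the printed tables of CT-FFR validation
trials: ischemia is FFR < 0.80, the index test is positive at CT-FFR
≤ 0.80, CTA is positive at ≥ 50% stenosis, and the gray zone is
[0.76, 0.80] (treated as ischemic; both bounds configurable — guideline
texts also use 0.75).  Reported percentages are rounded half-up to one
decimal, as clinical tables print them, with full-precision values
alongside.

* Proportion CIs use the Wilson score interval by default (the
  normal-approximation interval is available); Wilson never leaves [0, 1]
  and always contains the point estimate.
* AUC is the rank concordance with ties counted 1/2, oriented so lower
  index values mean more disease, with a DeLong placement variance for the
  CI.
* Bland–Altman reports both the 95% limits of agreement
  (mean ± 1.96 SD) and the t-based 95% CI of the mean difference — the two
  are often confused in print, so both are emitted and labelled.
* Per-FFR-bin accuracy uses the two-decimal bin convention <0.66,
  0.66–0.70, …, >0.90; empty bins report `NA`, never a fabricated value.
* Group comparisons use the Mann–Whitney U normal approximation
  (tie-corrected, no continuity correction) with median (IQR) per group for
  continuous covariates, and chi-square — switching to Fisher's exact test
  when any expected cell is below 5 — for categorical ones.
* Misdiagnosis screening fits univariate logistic regressions of each
  covariate on the false-negative flag (ischemic strata) or false-positive
  flag (non-ischemic stratum); complete separation or a constant covariate
  is flagged non-estimable instead of reporting a divergent odds ratio.
* Paired classifier comparisons (CT-FFR vs CTA on the same vessels) use the
  exact McNemar test on discordant pairs within the relevant truth stratum.
* No multiple-testing adjustment is applied, and the report says so in a
  footer note.

## Numerical choices and degenerate inputs

* Segment resampling on lesion application inserts the lesion ends, the
  throat, and a grid of at most 0.25 mm inside the lesion, so the minimal
  lumen diameter is exact at the throat sample.
* Trapezoidal quadrature is exact for the uniform-lumen regions and
  converges quadratically elsewhere; the plaque-burden integral is tested
  against a 10× refined oracle.
* A rectangular narrowing profile has a genuine discontinuity; its
  integrated viscous coefficient then depends on the sampling grid at the
  edge (about 0.1% of the total on default sampling), which is why the
  smooth cosine profile is the default.
* Zero-length lesions, non-positive radii, lumen exceeding the reference
  wall, cyclic or disconnected trees, dead-end (non-outlet) leaves, and
  empty outlet sets are rejected with specific errors.
* Solver determinism: results are invariant to segment enumeration order to
  $10^{-10}$, and all randomness in the package flows through explicit
  seeds (the orchestrator derives per-stage substreams from the master seed
  so toggling one stage does not shift the others).

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run: the solver-vs-oracle
comparison on 100 random trees of up to 50 segments; parameter recovery on
80-vessel designed training sets (noiseless and noise SD 0.02, 8 optimizer
starts); and one end-to-end virtual trial with an 80-vessel retrospective
calibration stage and a 2000-vessel prospective cohort.  These sizes give
the stratum fractions a sampling SD well under one percentage point and
keep every experiment reproducible from a single seed.

## Known limitations

* Steady flow only — no pulsatility, no transient adenosine dynamics.
* Newtonian rheology; no non-Newtonian corrections in small vessels.
* One target lesion per vessel; serial and diffuse disease are out of
  scope, as is per-patient aggregation.
* The expansion-loss coefficient $K_t$ is weakly identified from FFR-only
  calibration data (see above); its calibrated value should be read as a
  model-internal constant, not a physiological measurement.
* The geometry is taken as given input; contour extraction from images, and
  true Agatston scoring from HU values, are explicitly not modelled.
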