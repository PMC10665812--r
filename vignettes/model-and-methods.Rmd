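---
title: "An energy-balance model of diabetes onset and remission: equations, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An energy-balance model of diabetes onset and remission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2dsim)
```

## The model

`t2dsim` implements a fasting-state, multi-timescale model of how sustained
over-eating drives obesity, insulin resistance and eventually type 2
diabetes (T2D), and of when calorie restriction can still reverse the
disease. Eight state variables evolve in months:

* body weight $W$ (kg), driven by daily energy intake:
  $dW/dt = k_w\,DE_i - DE_e\,W$, with $BMI = W/h^2$;
* fasting plasma glucose $G$ (mg/dL):
  $dG/dt = HGP - (E_{G0} + S_i I)\,G$, where hepatic glucose production
  $HGP$ is a decreasing sigmoid of the insulin action $S_i I$;
* fasting insulin $I$: $dI/dt = \beta\,ISR/V - k I$, with the
  per-unit-mass secretion rate $ISR = \sigma\,M^{2}/(M^{2}+\alpha_{ISR}^{2})$
  a sigmoid of the beta-cell metabolic rate $M(G)$;
* fasting free fatty acids $FFA$ (umol/L): appearance is maximal
  lipolysis (linear in fat mass, itself a linear-in-BMI fraction of body
  weight) suppressed by insulin action; disappearance is first-order with
  body-weight-scaled turnover;
* a systemic inflammation index $\theta \in [0,1]$ relaxing toward a steep
  sigmoid of BMI with half-max $K_\theta$ (40 kg/m^2 nominally);
* peripheral insulin sensitivity $S_i$ relaxing toward
  $S_{i,b}\,[1 - M_{FFA}\,h_{FFA}]\,[1 - h_\theta]$: FFA and inflammation
  both depress it;
* beta-cell mass $\beta$ (mg):
  $\tau_\beta\,d\beta/dt = P_{ng} + P(ISR)\,\beta - A(M)\,\beta - s\beta^2$,
  replication increasing in secretory workload, apoptosis increasing in
  metabolic rate, plus a pairwise-interaction (logistic) term that caps
  growth and creates a genuine saddle-node structure;
* beta-cell function $\sigma$ relaxing toward
  $\sigma_b\,[\sigma_{gu} - \sigma_{gd}\sigma_{FFA} - \sigma_\theta]$,
  clamped at zero: glucose up-regulates function, but the *product* of the
  glucotoxic and lipotoxic sigmoids (glucolipotoxicity) and inflammation
  tear it down. The bracket equals 1 at the healthy baseline by
  construction.

Hepatic insulin sensitivity is identified with $S_i$ (one sensitivity
state). The disease progression index
$DPI = 1 - S_i\sigma\beta/(S_{i,0}\sigma_0\beta_0)$ is zero at baseline and
grows as any of its three factors falls.

All glycemic labels use fasting glucose: below 100 mg/dL healthy,
100-125 mg/dL (both ends included) prediabetes, above 125 mg/dL T2D.
BMI 25 and 30 are classified as overweight (inclusive thresholds).

## The parameter set

The packaged nominal set (`inst/extdata/parameters_nominal.yaml`, loaded by
`t2d_parameters()`) was built in two stages.

*Anchoring.* The baseline healthy state is exact by construction: the
energy balance `k_w * DE_i_b = DE_e * 25 * h^2` makes BMI 25 an
equilibrium; `s_gu_max` is solved so the beta-cell-function bracket is 1
there, and the pairwise term `s` so that beta-cell mass is exactly
1000 mg. Baseline glucose (~91 mg/dL), insulin (~11 uU/mL) and FFA
(~400 umol/L) sit at textbook fasting values. The weight-loss rate
constant `DE_e = 0.0813`/month is derived from the observed exponential
approach of BMI to its intake-determined limit during weight-loss
interventions (a ~12-month time constant); `k_w` follows from the balance.

*Shape calibration.* The response half-maxima and amplitudes
(glucolipotoxicity, inflammation, apoptosis/replication sigmoids) were
calibrated once, before the test suite was frozen, against the behaviour
the model is meant to exhibit: a bistable interval in BMI of roughly
[25, 39.5] for the clamped subsystem; moderate over-eating (130% of
baseline intake) producing obesity without T2D; 155% producing sustained
prediabetes; 175% producing overt T2D with a non-monotonic insulin time
course; and intake-restoration interventions whose success degrades with
delay (full recovery, remission within prediabetes, failure). These are
the quantities the acceptance script recomputes; the vignette asserts
nothing beyond them.

One timing quantity resisted reconstruction: with this parameter set the
interior beta-cell-mass maximum under the 175% protocol occurs about ten
months after the trajectory exits the healthy basin, rather than
coinciding with it. Forcing an earlier collapse (stronger glucotoxic or
inflammatory amplitudes) consistently destroyed the delayed-intervention
remission outcome, so the slower collapse was kept and the timing is
checked as an ordering property (crossing before maximum) rather than a
printed value.

## Bistability, the threshold, and the remission map

`equilibria_at_bmi()` clamps $W$ (removing the weight equation) and
root-solves the remaining seven equations from a fixed lattice of 36
starting points spanning healthy and diabetic regimes; solutions are
deduplicated and classified by the eigenvalues of a finite-difference
Jacobian. Eigenvalue real parts within 1e-6 of zero are flagged
"marginal" and excluded from branch labels, because finite-difference
Jacobians are ill-conditioned near folds. `continue_branches()` scans BMI
(natural-parameter continuation with fold-aware bisection to 0.05 kg/m^2)
and labels upper-stable, unstable and lower-stable branches; the unstable
branch, interpolated monotonically by `threshold_curve()`, is the
projected separatrix.

`classify_attractor()` simulates under constant intake and compares
terminal beta-cell mass with the threshold at terminal BMI; a result
within 2% of the threshold is reported `"undetermined"`, never guessed.
The default horizon (600 months; 400-500 in the heavier map and
acceptance runs) reflects that beta-cell mass is the slowest variable;
tests check that doubling the horizon does not change labels.

`remission_map()` asks, for each (BMI, beta-cell mass) cell, the largest
constant intake that still reaches the healthy attractor. The off-plane
variables are reconstructed by a quasi-steady root-solve of the fast
subsystem conditioned on the clamped pair — the map is a projection, and
the fast variables equilibrate within weeks, so this is the natural
lift. Intake is bisected to 1% of baseline; cells that fail at baseline
intake are coded `F`, cells that converge even at the upper search bound
`NR`. The default upper bound (155% of baseline) is just below the
intake whose steady-state BMI reaches the fold, beyond which no cell can
hold the healthy attractor indefinitely.

## Virtual cohorts

`sample_cohort()` draws independent uniform perturbations (5-20%,
parameter-dependent) around the nominal values for ten parameters
governing inter-individual differences — inflammatory susceptibility
(`K_theta`, `s_th_max`), insulin sensitivity (`S_i_b`, `M_FFA`),
beta-cell turnover (`P_max`, `A_max`, `tau_beta`, `tau_sigma`) and
lipid handling (`K_sf`, `F_Ra1`) — plus protocol randomization. The
`fig6` preset (gain to U(150,180)% at month 10, baseline from month 80)
produces non-diabetic, diabetic and remission subgroups from a healthy
population. The `fig9` preset emulates a remission-trial cohort: since
such a trial recruits people who already have T2D, sampling is centred
on a diabetes-prone variant (`K_theta` scaled by 0.75) so that ~90% are
diabetic at the month-60 restriction; T2D duration at intervention then
*emerges* from each individual's own onset time. Group summaries use
paired t-tests within group across time and Welch tests between groups
(group sizes differ, so between-group pairing is undefined).

The generator emulates heterogeneity in disease susceptibility and
protocol adherence ranges. It does not emulate measurement error on
individual patients, covariates (age, sex, medication), dropout, or
non-metabolic determinants of remission — passing cohort tests therefore
says the *model population* reproduces trial-level summary statistics,
not that the model predicts individual patients.

## Calibration

`fit()` minimizes the weighted sum of squared residuals between simulated
observables and sparse observations by bounded Levenberg-Marquardt from
seeded random multi-starts. The default weighting divides squared
residuals by the *variance* (`sd^2`), which is the Gaussian
maximum-likelihood form; a `weighting = "sd"` mode divides by the SD
itself for compatibility with sum-of-squares conventions that weight by
dispersion rather than variance. Confidence intervals follow from the
Fisher information approximated as $J^TJ$ with $J$ the weighted-residual
Jacobian at the optimum: $C = F^{-1}$, half-width
$t_{1-\alpha/2,\,df}\sqrt{C_{ii}}$, $df$ = observations minus free
parameters. Zero-sensitivity parameters are flagged unidentifiable and
$F$ is pseudo-inverted. Solver failures at trial parameters return a
large finite penalty so optimizers continue.

`recovery_study()` is the module's self-validation: 50 seeded replicates
of sparse trial-like data (baseline, intervention, +5, +12, +24 months;
4 streams) with 5% proportional noise, refit for `K_theta` and `sigma_b`
from 2 starts each. The suite requires >= 90% CI coverage and
relative bias below 2%.

## Numerical choices

* Integration: LSODA via deSolve with a compiled right-hand side;
  the pure-R `rhs()` is the reference implementation and the test suite
  checks the two agree to 0.1% along trajectories. The integrator is
  restarted at every schedule switch — intake steps are genuine
  discontinuities, not smoothed.
* Tolerances: rtol 1e-8, atol 1e-10 scaled per state magnitude
  (weight ~1e2, inflammation ~1e-2, ...); halving both changes reported
  states by < 0.1%. Cohort and map runs use 1e-7/1e-9 — classification
  only needs the glucose envelope.
* Event times: sign-change bracketing on the output grid, refined by
  bisection on a natural-spline interpolant to 0.01 months; beta extrema
  use the exact right-hand side along the trajectory, with sign flips at
  schedule switches and flat-gradient wiggles (< 1e-3 mg/month) ignored.
* Root solving: a damped Newton iteration in log coordinates (positivity
  for free) with finite-difference Jacobians; the equilibrium and
  quasi-steady solvers are deliberately independent of the
  Levenberg-Marquardt library used for fitting, so fitting can call
  simulation (and its inner root solves) re-entrantly.
* Determinism: equilibrium multi-starts form a fixed lattice; cohorts and
  fits are seed-determined; repeated runs produce byte-identical CSV
  payloads (timestamps live only in run manifests).

## Problem sizes

The test suite and acceptance script use: continuation at 0.5-1 kg/m^2
base steps over BMI [23, 43] with 0.05 fold refinement; attractor
horizons of 400-600 months; remission-map probes on small grids with the
failure boundary bisected at three BMI values; cohorts of 200
individuals; and 50 recovery replicates. These sizes keep the whole
suite within a few minutes while leaving every statistic's Monte Carlo
error well inside the tolerances tested.

## Limitations

The model describes fasting-state physiology on monthly timescales:
meal-scale (postprandial) dynamics, incretin effects, gastrointestinal
adaptation and drug or surgical interventions are out of scope. Energy
expenditure per kilogram is constant within a run (no adaptive
thermogenesis or exercise modelling). The parameter set is the package's
own calibration to the anchor behaviours listed above, not a measured
table: absolute rates inherit their scales from those anchors, and two
timing quantities of the reference protocols (the month of the interior
beta-cell-mass maximum under sustained 175% intake, and the months/BMI at
which delayed interventions re-enter the healthy basin) are guaranteed
only as ordering properties, not to fixed values.
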