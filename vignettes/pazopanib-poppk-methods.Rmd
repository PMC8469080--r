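---
title: "Population pharmacokinetics of pazopanib: model, estimation and AUC-based monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of pazopanib: model, estimation and AUC-based monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pazopk)
```

## The clinical problem

Pazopanib efficacy correlates with the trough plasma concentration
(C~trough~ ≥ 20.5 mg·L^−1^), but a trough must be drawn immediately before
the next intake — hard to schedule in routine oncology care. This package
implements the alternative: a population pharmacokinetic (popPK) model from
which a patient's apparent clearance Cl/F, and hence their exposure
AUC = Dose/(Cl/F), can be estimated from a **single sample drawn at any
time**, and a target AUC (750 mg·h·L^−1^) that acts as a surrogate for the
trough criterion.

## Structural and statistical model

Concentrations follow a one-compartment model with first-order absorption
(rate ka, h^−1^) and first-order elimination from an apparent central
volume V/F (L) with apparent clearance Cl/F (L·h^−1^):

$$C(t) = \frac{D}{V/F}\,\frac{k_a}{k_a-k_e}\left(e^{-k_e t}-e^{-k_a t}\right),
\qquad k_e = \frac{Cl/F}{V/F}.$$

Under once-daily dosing the steady-state curve is the superposition of all
past doses, which closes to

$$C_{ss}(t)=\frac{D}{V/F}\,\frac{k_a}{k_a-k_e}
\left(\frac{e^{-k_e t}}{1-e^{-k_e\tau}}-\frac{e^{-k_a t}}{1-e^{-k_a\tau}}\right),$$

with $t$ the time since the last dose and $\tau$ = 24 h. Because this is an
exact sum over past doses, it remains valid for $t>\tau$ when a sample is
drawn before a delayed next intake — which is exactly what happens with
sparse monitoring samples averaging 24.6 h post-dose. When
$|k_a-k_e| < 10^{-8}k_e$ both expressions switch to their analytic
$k_a \to k_e$ limits, so the flip-flop degeneracy never produces a
cancellation blow-up; the switch is continuous well below test tolerances.

Between-patient and between-visit variability are lognormal. With subject
$i$ and occasion (visit or treatment cycle) $occ$:

$$\log V_i/F = \log V_{pop}/F + \beta_{V}\,
\log\!\frac{ASAT_i}{36.5} + \eta_{V,i} + \kappa_{V,occ},
\qquad
\log Cl_i/F = \log Cl_{pop}/F + \eta_{Cl,i} + \kappa_{Cl,occ},$$

and $\log k_{a,i} = \log k_{a,pop} + \eta_{ka,i}$. The $\eta$ terms are
inter-individual (IIV, SDs $\omega$), the $\kappa$ terms inter-occasion
(IOV, SDs $\gamma$, on V/F and Cl/F only); random-effect correlations are
fixed at zero. Aspartate transaminase (ASAT) enters as a power of the ratio
to its reference 36.5 UI·L^−1^ with exponent $\beta_V$ = −0.838 in the
reference parameter set. Residual error is combined,
$y = f + (a + b f)\,\varepsilon$ with standard-normal $\varepsilon$
("combined-1"; the quadratic "combined-2" form is available through
`err_model`). We default to combined-1 because it is the default convention
of the SAEM tooling this class of analysis is usually run in.

The reference (published) fixed effects are ka = 0.976 h^−1^,
V/F = 22.3 L, Cl/F = 0.458 L·h^−1^, $\omega_V$ = 0.248 (24.8 %CV). Values
not published — $\omega_{ka}$, $\omega_{Cl}$, both $\gamma$s and the
residual coefficients — are package assumptions chosen once for
simulation: $\omega_{ka}=\omega_{Cl}=0.30$ and $\gamma_V=\gamma_{Cl}=0.15$
(typical magnitudes for an oral kinase inhibitor with moderate
within-patient variability), err_add = 1.0 mg·L^−1^ (the assay's lower
limit of quantification, a natural scale for the additive floor) and
err_prop = 0.20. They are visible and overridable in
`reference_pop_params()`.

## The synthetic cohort

The study's raw data are not deposited, so `simulate_cohort()` reproduces
the *design*: a sparse therapeutic-drug-monitoring arm (58 patients, 126
trough samples at a mean of 24.6 h post-dose, 1–6 visits each, mean 2.17)
and a rich-profile trial arm (15 patients, 280 samples over 36 day-1
profiles in treatment cycles 1, 2 and 4, nominally at 0, 0.5, 1, 2, 4, 6,
8 and 24 h post-dose). The printed per-profile counts of the source cannot
be reconciled exactly with its totals, so the default allocation preserves
the totals — 28 eight-point and 8 seven-point profiles (0.5 h dropped),
all 15 subjects in cycles 1 and 2 and six of them in cycle 4 — giving
exactly 406 observations. Cycle-1 profiles are simulated from the
single-dose curve (treatment start); everything else is at steady state.
TDM visit counts are a fixed multiset (19×1, 22×2, 9×3, 5×4, 2×5, 1×6)
permuted by the seed so the 126-sample total is exact for every seed, and
visit times are Normal(24.6, 2²) h truncated to [20, 30] (the source gives
only the mean; the spread is an assumption).

Covariates: ASAT is lognormal with median 36.5 UI·L^−1^ (log-SD 0.4);
ALAT, albumin, creatinine, age and sex use plausible clinical
distributions; food status is drawn 52/15/6 fasted/fed/unknown. Only ASAT
affects the model, matching the final covariate structure. Daily doses are
drawn from {200, 400, 600, 800} mg with weights (0.10, 0.20, 0.20, 0.50),
reflecting that 800 mg is the registered dose and reductions are common.
Recorded covariate values are masked missing-at-random at 10% to exercise
the imputation rule (patient median, then cohort median); the generating
values are never masked. Observations below the 1 mg·L^−1^ quantification
limit are flagged and excluded from all likelihoods (simple M1-style
exclusion; censored-likelihood handling is out of scope), but retained in
the table.

What the generator does **not** emulate: non-adherence, food effects,
dose-dependent (nonlinear) absorption, drug–drug interactions,
within-profile covariate drift, or assay batch effects. Green tests
therefore demonstrate that the estimation and decision machinery is
correct under the stated design, not that real pazopanib data are this
well behaved.

## SAEM estimation

`fit_saem()` is a stochastic-approximation EM. Each iteration samples every
subject's individual log-parameters (and occasion deviations) from their
conditional posterior by Markov chain Monte Carlo, then updates the
population parameters from stochastically smoothed sufficient statistics;
fixed effects and covariate coefficients have closed-form regression
updates, variances closed-form moment updates, and the two residual
coefficients an inner numerical maximisation warm-started each iteration.

The MCMC kernel combines three moves per sweep:

* componentwise random-walk Metropolis with per-subject, per-component
  scales adapted toward ≈35% acceptance;
* an **exact Gibbs move along the IIV/IOV ridge**: adding $\delta$ to
  $\eta_V$ while subtracting it from every $\kappa_{V,occ}$ leaves the
  likelihood unchanged, so the conditional of $\delta$ is Gaussian and can
  be drawn exactly. Without it the decomposition of V- and Cl-variability
  into between-subject and between-occasion parts mixes far too slowly;
* a Haario-type adaptive joint proposal built from the running covariance
  of the subject's own draws, which handles the correlated
  $\eta_V/\eta_{Cl}$ ridge that trough-only subjects induce (a single
  trough constrains only one linear combination of the two).

Two schedule choices matter and are deliberate:

* **Annealing.** During exploration a variance component may shrink by at
  most 5% per iteration. Otherwise the very first M-step — computed from
  latents that have barely moved from their prior means — collapses the
  $\omega$s and freezes the chain.
* **Exploration step size 0.1** (not the conventional 1). With step 1 the
  variance updates form a multiplicative recursion in which the Jensen
  inequality ($E[\log \chi^2_n/n] < 0$) deflates weakly identified
  $\omega$s by roughly 1.4% per iteration; on this design that slowly
  drives $\omega_V$ toward zero, and profiling the importance-sampling
  likelihood confirms the collapsed values are *not* maxima. A constant
  step of 0.1 pools the statistics over ~10 recent draws and removes the
  drift while still tracking the data. The smoothing phase uses the
  standard $1/k^{0.7}$ steps.

Defaults are 300 exploration + 200 smoothing iterations, one chain, two
kernel sweeps per iteration. Subjects with a single occasion carry no IOV
information; their occasion deviations are absorbed at zero, and if no
subject has two occasions the $\gamma$s are fixed at zero and leave the
parameter count. Convergence is declared when the smoothed parameter path
drifts by less than 10% over the tail of the smoothing phase; a
non-converged fit is flagged, not an error.

After estimation: the objective function value (OFV = −2 log-likelihood)
comes from `log_likelihood_is()` — per-subject importance sampling with a
multivariate t proposal (5 degrees of freedom, the conventional
heavy-tailed choice; we read the source's "degree of freedom fixed at 5"
as this proposal setting) centred at the conditional mode and scaled by
the inverse Hessian, Monte Carlo size 10,000, all in log space with the
Monte Carlo standard error reported. AIC = OFV + 2·n~p~ exactly. Relative
standard errors use the empirical Fisher information (outer products of
posterior-averaged per-subject complete-data scores over 100 extra
sweeps); the bootstrap is the fallback when that matrix is ill-conditioned.
Eta-shrinkage is 100·(1 − SD(EBE)/ω).

Covariate selection (`stepwise_covariates()`) is forward-only: a candidate
is accepted only if it lowers the OFV by ≥ 3.84 (the χ²₁ 95% quantile) *and*
the AIC by ≥ 2 — the source states both rules without saying whether they
were applied jointly, so we enforce both (conservative) and expose the
cuts as arguments. Continuous candidates enter as powers of the
ratio-to-median, categorical ones as multiplicative shifts, dose as
log(dose/800).

## Individual inference from a single sample

`map_estimate()` maximises the empirical-Bayes posterior of one subject's
random effects under fixed population parameters:

$$\min_\eta \sum_{obs}\left[\frac{(y-f)^2}{sd(f)^2}+2\log sd(f)\right]
+ \eta^\top\Omega^{-1}\eta,$$

with the sampled occasion's IOV deviations estimated jointly with the IIV
effects. Optimisation restarts from $\eta=0$ plus four jittered starts and
keeps the best mode; the mode's objective is always ≤ the objective at
zero. Samples at ≥ 7 days of stable dosing are evaluated against the
steady-state curve (steady state is reached within 7–8 days);
treatment-start profiles use the single-dose curve. The clearance of the
sampled occasion then gives AUC = daily dose / (Cl/F), so AUC·Cl equals
the dose identically. One sample identifies Cl/F only partially — the
posterior trades it against V/F — so estimates from samples near the
concentration peak (within 2 h of the individual t~max~) are flagged
`near_cmax`.

## Non-compartmental reference

`nca_reference()` computes the "real" exposure of a rich profile:
linear-up/log-down trapezoids (linear while rising or when an endpoint is
zero — the log rule is undefined at zero — and the exact log trapezoid on
strictly decreasing positive segments), the terminal slope λ~z~ by best-fit
log-linear regression over all ≥3-point post-peak windows (highest
adjusted R², ties to more points), and Cl = dose/AUC. At steady state
AUC~0–τ~ needs no extrapolation and λ~z~ is reported for parity only; a
single-dose profile is extrapolated to infinity with λ~z~ before the
clearance is formed. A steady-state predose sample exceeding the 24 h
sample is flagged inconsistent rather than corrected. Eight-point
steady-state schedules carry <5% discretisation error in Cl across the
plausible parameter range (verified by property test).

## Model evaluation

* **VPC** (`vpc()`): 1000 replicates simulated on the observed design,
  observation times binned by one-dimensional least-squares (k-means)
  clustering with 8 bins by default (the source names the criterion but
  not the count), no stratification; observed 10th/50th/90th percentiles
  against their 90% simulation bands.
* **NPDE** (`npde()`): simulation-based decorrelation (Cholesky of the
  simulated covariance, ridge-stabilised if singular), rank transform,
  normal quantiles; standard normal under the correct model. The replicate
  count is unstated in the source; 1000 is shared with the VPC.
* **IWRES** (`iwres()`): individual weighted residuals at the EBE modes.
* **Bootstrap** (`bootstrap_fit()`): subjects resampled with replacement,
  100 replicates by default, each refit on a shortened 100 + 50 schedule
  to stay desk-scale; per-parameter quartiles and a check that the point
  estimates sit inside [Q1, Q3].
* **Leave-one-out** (`loo_crossvalidate()`): for each steady-state
  rich-profile subject, refit without them, estimate their Cl/F from each
  sample individually, convert to AUC, and compare with their NCA
  reference; reports the mean absolute relative deviation and how often
  the AUC < 750 classification agrees with the observed 24 h trough <
  20.5 mg·L^−1^ (the observed sample, not the model prediction, mirroring
  monitoring practice). Two floors are worth knowing: the n−1 refits
  contribute sampling error of order $\omega_{Cl}/\sqrt{n-1}$ to every
  estimate, and with mixed dose levels the AUC and trough criteria are
  structurally discordant for a band of mid-range clearances — both are
  properties of the procedure, not estimation failures.

## Target-AUC determination and exposure decisions

`sensitivity_specificity_scan()` scans candidate AUC thresholds (default
250–1500 by 50) against the trough criterion. Orientation is fixed and
documented: condition positive ⇔ C~trough~ ≥ 20.5 mg·L^−1^ (adequate
exposure), test positive ⇔ AUC ≥ threshold. The chosen threshold maximises
Youden's J by default (ties to the lower threshold); since the source does
not describe how its threshold was chosen given the printed
sensitivity/specificity pair, a fixed-sensitivity mode (lowest threshold
with sensitivity ≥ 99%) is also provided. The trough criterion defaults to
20.5 mg·L^−1^ (20.0 appears in places; it is available by argument).
`classify_exposure()` keeps the boundary AUC = 750 as adequate.
`paired_cycle_test()` is a Wilcoxon *signed-rank* test despite the
"Mann–Whitney" naming in the source, because the comparison is explicitly
paired; it is exact for ≤25 untied pairs and falls back to the corrected
normal approximation with ties.

## Numerical conventions and degenerate inputs

* ka ≈ ke switch at relative tolerance 1e-8; continuous analytic limits on
  both curves.
* Estimated random-effect SDs floored at 1e-3; residual SD floored at
  1e-10 inside likelihoods.
* BLQ boundary: a value exactly at the limit of quantification is kept.
* A zero concentration inside a decreasing NCA segment forces the linear
  trapezoid.
* All randomness flows from one seed through named substreams (simulate,
  fit, vpc, npde, bootstrap, loo, map); identical seed + design +
  parameters reproduce a dataset byte for byte.
* Empty VPC bins reduce the bin count with a warning; an IS effective
  sample size below 10 warns.

## Problem sizes used by the test suite

The tests run the full machinery at sizes chosen to finish on a laptop
while still exercising every code path: the complete 73-subject/406-sample
design for parameter recovery (one seeded fit at the default 300 + 200
schedule), 10 subjects for the leave-one-out bounds, 10–30 subjects for
VPC/NPDE self-coverage, 20 bootstrap replicates on shortened schedules,
and noise-free cohorts for exact-identity checks. The noise-free
fixed-effect identifiability check uses a rich-profile design because
sparse trough-only subjects are individually under-identified there —
with near-zero residual error their needle-shaped posteriors stall any
random-walk sampler, an extreme regime irrelevant to realistic noise
levels, where recovery on the full design is unbiased across seeds.

## Known limitations

* On the default design the decomposition of V/F variability into IIV and
  IOV is nearly flat in the likelihood (±2 OFV over a wide ridge): with
  only 15 rich subjects informing the split, $\omega_V$ estimates scatter
  low and $\gamma_V$ high relative to their generating values, while
  their total is preserved. Consistency was verified on a 150-subject
  rich design, where the split is recovered.
* BLQ handling is exclusion, not censored likelihood — at the 1 mg·L^−1^
  limit this touches mainly predose cycle-1 samples.
* Only the one-compartment structural model is implemented; two- and
  three-compartment alternatives were rejected in the source's model
  comparison and are out of scope here (the ODE-based test oracle provides
  the structural hook).
* The MAP estimator returns modes, not posterior intervals.
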