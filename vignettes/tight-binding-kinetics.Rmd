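---
title: "Tight-binding inhibition analysis with Morrison's equation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tight-binding inhibition analysis with Morrison's equation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tightbind)
```

## The problem

A potent reversible inhibitor can bind enough of the enzyme in the assay
that the free inhibitor concentration is visibly depleted: the usual
assumption \[I\]~free~ ≈ \[I\]~total~ breaks down whenever the inhibition
constant is comparable to, or below, the enzyme concentration. This is the
tight-binding regime. It is diagnosed operationally when sub-stoichiometric
inhibitor (relative to substrate, and comparable to the enzyme) already
suppresses activity — as GC7 does to bovine serum amine oxidase (BSAO)
oxidizing spermidine. In that regime classical IC50 or Lineweaver–Burk
analyses mislead: competitive and noncompetitive inhibitors produce similar
double-reciprocal patterns, and the IC50 inflates with enzyme
concentration.

`tightbind` implements the standard remedy: fit Morrison's closed-form
solution of the enzyme–inhibitor binding quadratic globally over a
substrate × inhibitor rate grid, let the substrate dependence of the
*apparent* inhibition constant discriminate the inhibition mode via AIC,
and derive IC50s that account for enzyme depletion.

## The model

The uninhibited stage is Michaelis–Menten,
$$v_0(S) = \frac{V_{max} S}{K_m + S},$$
fitted by nonlinear least squares to the zero-inhibitor rows of the grid
(`fit_michaelis_menten()`). Replicates enter as individual points so the
downstream AIC sees the true *n*.

The inhibited velocity is the uninhibited rate at the same substrate
concentration scaled by Morrison's fractional velocity,
$$\frac{v_i}{v_0} = 1 - \frac{([E]+[I]+K_i^{app}) -
  \sqrt{([E]+[I]+K_i^{app})^2 - 4[E][I]}}{2[E]},$$
with the apparent inhibition constant carrying the mode information:

| mode | $K_i^{app}(S)$ | behaviour in $S$ |
|---|---|---|
| competitive | $K_i\,(1 + S/K_m)$ | strictly increasing |
| noncompetitive (mixed) | $(S+K_m)\,/\,(K_m/K_i + S/(\alpha K_i))$ | bounded between $K_i\min(1,\alpha)$ and $K_i\max(1,\alpha)$ |
| uncompetitive | $K_i\,(1 + K_m/S)$ | strictly decreasing |

A note on naming: the $\alpha$-bearing form is labelled "noncompetitive"
here, following common usage in the inhibition literature, although with
$\alpha \neq 1$ it is formally a *mixed* model; $\alpha = 1$ is the pure
noncompetitive special case. The package never asserts $\alpha = 1$.

One modelling decision deserves emphasis. Morrison's equation is a ratio
against the *uninhibited velocity at the same substrate concentration*.
Descriptions of the method sometimes call the denominator "the maximum
reaction velocity"; taken literally (a constant $V_{max}$) the model could
not reproduce substrate saturation across a grid, so the only reading
consistent with global fitting is $v_0 = v_0(S)$, which is what
`predict_rate()` implements. The literal reading still matters for
qualitative statements: at 20 µM substrate and 2 µM inhibitor the
reference parameter set predicts $v_i/v_0(S) \approx 0.15$ but
$v_i/V_{max} \approx 0.016$ — "the reaction almost stopped" describes the
rate relative to the enzyme's maximal capacity.

## Fitting strategy and numerical choices

`fit_tight_binding()` supports two strategies.

* **two_stage** (default): $K_m$ and $V_{max}$ are assigned from the
  Michaelis–Menten stage, then $K_i$, $\alpha$ (noncompetitive only) and
  $[E]$ are fitted to the full grid. This mirrors the classical workflow.
* **joint**: all five parameters are refitted together, starting from the
  two-stage solution. On noiseless data the strategies coincide; joint
  additionally yields standard errors for all five parameters, which is
  why both are provided.

All positive parameters are optimized on the log scale with
Levenberg–Marquardt (`minpack.lm::nls.lm`) under box bounds; this keeps
them positive without penalty terms and makes the optimizer scale-free.
Generic bounds are wide (10^-9^–10^6^ µM for $K_i$, 10^-6^–10^6^ for
$\alpha$); the active enzyme concentration is bounded below at 10^-4^ µM
and a fit ending on that bound raises a warning, because $[E]$ is then not
identifiable from depletion curvature. The Morrison discriminant is
clamped at zero against floating-point underflow and predicted fractions
clipped to [0, 1]. Initialization is deterministic (no random restarts):
$V_{max}$ from the maximum observed rate, $K_m$ from the level nearest
half-maximal mean rate, $K_i$ from the inhibitor level closest to halving
the rate at the lowest substrate, $\alpha = 1$, and $[E]$ from the nominal
enzyme concentration when the grid metadata carries one (else the smallest
positive inhibitor level). Standard errors come from the Jacobian at the
optimum, mapped to the natural scale by the delta method.

Mode discrimination uses the least-squares AIC,
$$\mathrm{AIC} = n \ln(\mathrm{RSS}/n) + 2(k+1),$$
where $k$ counts free parameters only ($+1$ for the error variance). The
additive constant is a convention; since modes are compared at fixed $n$
on the same data, the argmin is convention-independent. Ties below
$|\Delta\mathrm{AIC}| < 10^{-6}$ are reported as ties rather than broken
arbitrarily.

A structural caveat, stated openly: the mixed model *nests* the other two
modes as boundary limits ($\alpha \to \infty$ recovers competitive,
$\alpha \to 0$ with $\alpha K_i$ finite recovers uncompetitive). On data
generated from a competitive or uncompetitive truth the mixed fit can
therefore always match the generating model's RSS, and AIC's +2 penalty
for the extra parameter yields a theoretical selection rate of roughly
92% for the true boundary mode (a ½·χ²₁ boundary mixture exceeds 2 about
8% of the time). Simulation with the default design reproduces this:
under 2% proportional noise the generating mode is selected 100/100 times
when the truth is mixed, but 86/100 (competitive) and 92/100
(uncompetitive) — an intrinsic property of AIC with nested alternatives,
not of the implementation. On noiseless grids selection is exact with
$\Delta\mathrm{AIC} > 10$ for the wrong modes.

## IC50

For the tight-binding isotherm the half-inhibition concentration has the
closed form
$$\mathrm{IC}_{50}(S) = K_i^{app}(S) + [E]/2,$$
reducing to the classical $\mathrm{IC}_{50} = K_i^{app}$ as $[E] \to 0$
(`ic50_tight_binding()`, verified in the tests against bisection on the
Morrison curve). Independently, `fit_loglogistic3()` fits the
three-parameter log-logistic
$$f(x) = \frac{d}{1 + \exp\{b(\ln x - \ln e)\}}$$
to each substrate level's dose–response, reporting the inflection $e$ as
the empirical IC50. The lower asymptote is fixed at zero and the curve is
decreasing ($b > 0$), matching an inhibition readout; dose zero is kept
via the $b > 0$ limit $f(0) = d$ so uninhibited controls inform the upper
asymptote, and `fix_d = 1` pins it for ratio-normalized responses. The
log-logistic is an *approximation* to the steeper Morrison isotherm; on
Morrison-generated curves the two IC50 estimates agree within 15%, which
is the cross-model consistency the tests assert — not an identity.

## Rate conversion

`estimate_initial_rate()` takes the ordinary least-squares slope of
absorbance against time over the first 10% of the trace (minimum 5
points, explicit time spans supported). The 10% default is the standard
initial-rate convention and is deliberately conservative against
progress-curve curvature; no substrate-depletion correction is applied.
`absorbance_to_rate()` applies Beer–Lambert:
rate (nmol/min) = stoichiometry × slope/(ε·l) × V~mL~ × 10⁶. The relevant
coefficients for amine-oxidase work are ε = 12,500 M⁻¹cm⁻¹ (benzaldehyde,
250 nm) and ε = 26,000 M⁻¹cm⁻¹ (the DCHBS/AAP quinonimine adduct,
515 nm). The adduct-per-H₂O₂ stoichiometry is taken as 1 by default but is
an explicit field of `extinction_spec()`, because the coupled-assay
stoichiometry is an assumption, not a measurement.

## What the synthetic generator does and does not emulate

`simulate_rate_grid()` draws replicated rates from the tight-binding
model on a 6 × 6 design spanning substrate 20–1000 µM and inhibitor
0–2 µM (interior levels log-spaced; the published endpoints are the
anchors), 3 replicates, with proportional Gaussian noise at CV = 2% by
default — chosen once as typical spectrophotometric repeatability; it is
an explicit stand-in, not a measured value.
Negative noisy rates are kept and flagged rather than clipped, so fitters
meet realistic data. All randomness flows through the design's single
seed; the global RNG stream is untouched.

What it does **not** emulate: substrate depletion over the time course,
product inhibition, slow-binding (time-dependent) onset, pipetting
covariance between wells, or heteroscedasticity beyond the proportional
model. Parameter recovery on these simulations therefore demonstrates the
estimator's correctness and conditioning on clean tight-binding data, not
robustness to every artefact of a real plate assay.

## A worked run

```{r example, eval = FALSE}
truth <- gc7_reference_params()
design <- simulation_design(seed = 1)          # 6 x 6, 3 reps, 2% CV
grid <- simulate_rate_grid(truth, "noncompetitive", design)

cmp <- compare_inhibition_modes(grid, strategy = "joint")
cmp$best_mode
summary(cmp$fits[[cmp$best_mode]])
ic50_tight_binding(cmp$fits[[cmp$best_mode]]$params, cmp$best_mode,
                   S = c(20, 100, 1000))
```

Problem sizes throughout the package's tests are desk-scale by design: a
36-point noiseless grid for exact recovery, 108-point noisy grids for the
selection study (100 seeds per generating mode), and 1,000-point oracle
sweeps for the Morrison quadratic.

## Known limitations

* The mixed-model nesting bounds AIC selection consistency for
  competitive/uncompetitive truths near 92%, as quantified above.
* Standard errors are asymptotic (Jacobian-based); no profile likelihood
  or bootstrap intervals are provided (though `simulate()` on a fitted
  model supports a manual parametric bootstrap).
* Reversibility and slow-binding kinetics are out of scope; the model
  assumes instantaneous equilibrium at each measurement.
* `[E]` is estimable only because inhibitor depletion curves the
  isotherm; when data carry no depletion signal the fit lands on the
  lower bound and is flagged, and `fix_E` should be used instead.
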