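---
title: "Methods: simultaneous serum-urine population pharmacokinetics of enalapril and enalaprilat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simultaneous serum-urine population pharmacokinetics of enalapril and enalaprilat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

Enalapril is an inactive prodrug: after an oral dose it is partly lost to
pre-systemic metabolism, absorbed into a central serum compartment,
and eliminated both by renal excretion and by hepatic conversion to the
active ACE inhibitor enalaprilat, which itself distributes into a
peripheral compartment and leaves through the urine.  Because serum
concentrations *and* cumulative urinary amounts of both species are
measured, the absolute bioavailable fraction `f1` is identifiable — with
serum data alone only ratios such as `vc/f1` could be estimated.

The structural model is a linear compartmental system:

* an oral **depot** receiving `f1 * dose` (the rest never enters the
  system),
* `n1` **absorption transit compartments** traversed at
  `ktr1 = (n1 + 1)/mtt1`, the last one emptying into the parent central
  compartment at `ka`.  A chain of identical first-order steps makes the
  arrival-time density an Erlang distribution — a flexible, smooth delay
  that reproduces the slow early rise of enalapril much better than a lag
  time.  `mtt1` is reported through the `(n1 + 1)/ktr1` convention, so its
  value is comparable across transit counts,
* a **one-compartment parent** (volume `vc`) with two first-order exits:
  renal `kren` (into a cumulative parent-urine sink) and metabolic `km`,
* `n2` **formation transits** at `ktr2 = (n2 + 1)/mtt2` delaying the
  appearance of the metabolite (default `n2 = 2`),
* a **two-compartment metabolite** (central volume `vm`, exchange rates
  `kq1`/`kq2`) with renal elimination `kme` into a metabolite-urine sink.

Amount units are micrograms of dosed salt; no molar parent-to-metabolite
correction is applied (the factor is not identifiable separately from
`vm`, which is therefore an apparent volume conditional on this
convention).  Urine observations are cumulative since dose and never
reset, matching how the assay data were processed.

`solve_amounts()` evaluates the system by the action of the matrix
exponential computed by *uniformization*: with
`lambda >= max |A_ii|`, `expm(A t) = exp(-lambda t) * sum_k (lambda t)^k / k! * (I + A/lambda)^k`.
For a compartmental generator `I + A/lambda` is entrywise non-negative, so
the series has no cancellation, works for the defective rate matrices
produced by repeated transit rates (where eigendecomposition fails), and
costs a few matrix-vector products per sampling interval.  Compartments
that have already drained are dropped from the active block on the fly;
for extremely stiff blocks explored by the optimizer the propagator
switches to squaring up an exactly computed short-interval exponential.
`deSolve::lsoda` and `Matrix::expm` serve as independent oracles in the
test-suite (relative agreement better than `1e-8`).

# Statistical layer

Between-subject variability is exponential, `P_i = TV * exp(eta_i)` with
independent normal etas (diagonal Omega, nine etas; none on the
metabolite exchange rates `kq1`/`kq2`).  Etas are subject-level and
shared across the two crossover periods: no inter-occasion variability is
modelled, since a single variance per parameter is all the published
analysis reports.  A consequence worth knowing: with the reported
`omega^2(f1) = 0.041`, an individual bioavailable fraction can exceed 1
with probability about 0.7% per subject.  We deliberately do not cap it —
capping would bias recovery of the typical value — and the constructor
only warns.

Residual error is combined proportional + additive for the two serum
streams (`y = f(1 + eps1) + eps2`) and proportional only for the two
urine streams, giving per-observation variances `f^2 s2_prop + s_add^2`
and `f^2 s2_prop`.  Covariates enter multiplicatively: body weight
normalized by the study mean (69.76 kg) on the parent central volume with
the exponent fixed at 1 (0.75 would be used for clearance-like rates),
and a formulation multiplier `theta_form^FORM` on `mtt1` distinguishing
the orodispersible mini-tablet (`FORM = 1`) from the reference tablet.
Total body water (sex-specific Watson equations) is computed and carried
as a candidate covariate for the selection interface even though the
final model does not retain it.

# Estimation

`fit_poppk()` maximizes the first-order-conditional (FOCE) approximation
of the marginal likelihood with interaction: for each subject the
conditional etas minimize

```
inner(eta) = sum[(dv - f)^2/v + log v] + eta' Omega^-1 eta + log det Omega
```

with `v` evaluated at the individual prediction, and the subject's
contribution to the objective function is
`inner(eta_hat) + n log(2 pi) + log det(H/2)` with the curvature `H`
taken from the FOCE linearization
`2(J'V^-1 J + Omega^-1) + sum v'v'^T/v^2`.  The full `2 pi` constants are
kept so the OFV is directly comparable to the exact `-2 log L` from
adaptive Gauss-Hermite quadrature; the test-suite bounds the
approximation error below 0.5 on one- and two-eta problems (and near 0.1
on well-behaved one-eta cases).

Numerical choices that matter:

* **Inner search.** Damped Newton in the Gauss-Newton metric with an
  analytic gradient; steps are capped at one log-unit per component.
  Cold starts first solve the problem under `Omega/4` and then relax —
  the joint surface can be multimodal for subjects with large random
  effects, and this prior homotopy reliably lands in the data-supported
  basin (verified against a bounded quasi-Newton oracle on every subject
  of a simulated trial).
* **Outer search.** All parameters are estimated on the log scale.  A
  BFGS pass uses the *envelope* gradient — finite differences on the
  Laplace objective with the conditional modes frozen, exact for the
  conditional-likelihood part by the envelope property — preconditioned
  by the diagonal curvature of that frozen surface.  Because the frozen
  gradient neglects how the curvature log-determinant moves with the
  modes, a short second pass repeats BFGS with the exact
  finite-difference gradient of the true objective (conditional modes
  re-optimized at every perturbed point).  Without this polish the
  volume terms settle 5-10% low.
* **Multi-start.** When the starting values are jittered, the cheap
  envelope-gradient phase is run twice — from the jittered vector and
  from the user's own starting model — and only the better basin is
  polished.  The marginal surface is multimodal in the high-variability
  absorption direction (`omega^2(KA)` near 0.7), and a single unlucky
  start can settle ~100 OFV points high; the conditional modes are reset
  before each descent so a previous basin cannot anchor the next one.
* **Warm starts.** Conditional modes are carried across outer
  iterations, across transit-selection candidates, and into bootstrap
  replicates.
* **Floors and boundaries.** Active variances are floored at `1e-10`,
  per-observation variances at `1e-12`; parameters that travel more than
  `log(50)` from their start are flagged as boundary solutions.
* **Standard errors.** Inverse observed Fisher information: the Hessian
  of OFV/2 from central differences of the envelope gradient with the
  modes re-optimized at each base point.  On the log scale the square
  roots are directly relative standard errors.

Model-building tools mirror the published procedure: `select_transits()`
adds one absorption transit at a time while the OFV drops by at least
3.8 (the printed threshold; chi-square(1, 0.05) would be 3.84), and
`covariate_step()` runs forward addition / backward elimination at the
same threshold.  Both accept a pluggable fitting backend so the decision
rules are unit-testable in isolation.

# Evaluation and comparison

`vpc()` simulates full replicates of the observed design (same subjects,
covariates, formulation flags, times, and quantification-limit rule) and
compares the observed 2.5th/50th/97.5th percentiles per nominal time with
the 95% band of the same percentile across simulations; the fixed
sampling schedule makes nominal-time binning exact, and no prediction
correction is needed with a fixed dose.  `bootstrap_poppk()` resamples
subjects with replacement and refits (starting from the final estimates,
as common bootstrap tooling does); `sir_uncertainty()` draws from a
multivariate-normal proposal on the log scale with the covariance
inflated 1.5-fold (the source analysis does not state its proposal;
mild inflation is common practice), weighs by `exp(-dOFV/2)` against the
proposal density and resamples without replacement.
`stability_check()` perturbs each starting value by ±10% and refits.

`compare_formulations()` reproduces the crossover comparison: individual
post-hoc parameters (typical values at the subject's covariates times
`exp(eta_hat)`, plus the clearances `clren = kren*vc`,
`clent = kme*vm`) from separate fits of the two formulation arms are
compared by a two-sided paired Wilcoxon signed-rank test at the 5% level
without multiplicity correction (nine tests, as in the source analysis —
a caveat worth keeping in mind).  Zero differences are dropped; the exact
null distribution is used up to 25 informative pairs, the tie-corrected
normal approximation beyond.  With 24 subjects the exact branch applies.

# The synthetic trial

No subject-level data are public, so `simulate_trial()` generates the
study: 24 healthy adults, two-period crossover, a single 10 mg
(10,000 ug) oral dose of enalapril maleate per period, 20 serum samples
between 0.17 and 48 h, urine collected over seven intervals to 48 h and
expressed as cumulative amounts, serum values below the assay limits
(0.195 ug/L parent, 0.180 ug/L metabolite; values exactly at the limit
kept) excluded as in the source analysis.  Urine censoring is off by
default because the assay limits are concentrations while the model works
on cumulative amounts — converting would require a urine-volume model we
did not want to invent.  Covariates are drawn from truncated normals
bounded by the published minima/maxima with locations solved so the
truncated means equal the published means (weight 69.76 kg, height
174.5 cm, age 28.0 yr; spreads of 11 kg, 8 cm and 6 yr — roughly a
quarter of each range); sex is Bernoulli(0.5).  Negative serum draws are
resampled rather than truncated to keep the residual distribution
near-Gaussian (counts are recorded in the dataset's `truth` attribute).
Proportional urine noise is applied to the cumulative value — the literal
reading of the residual model on the modelled observation — so simulated
cumulative urine series may occasionally decrease between collections,
as real back-calculated cumulative data can.

What passing recovery tests do *not* show: the generator shares the
estimator's structural and statistical assumptions, so recovery within
the published bootstrap intervals demonstrates internal consistency of
the whole pipeline at the study's design and published variability — not
robustness to model misspecification, censoring-mechanism errors, or
assay drift in real data.  One invariant deserves a note: the median of
simulated concentrations equals the typical profile only under a
monotone single-eta transform; under the full nine-eta model the
nonlinearity shifts the median by up to ~15% at the absorption front, so
the test-suite checks the exact property with a single volume eta and
only a loose envelope under the full Omega.

# Problem sizes

The shipped defaults follow the published analysis (1000 VPC
simulations, 200 bootstrap datasets, SIR 20,000/2,000, threshold 3.8).
The test-suite and the acceptance script run the package's own choices of
desk-scale problem sizes: one full 24-subject recovery fit, transit
selection on a 12-subject single-period trial over candidates 4-10,
ten crossover replicates for the comparison power check (post-hoc
evaluation at a common population model rather than twenty full refits),
200-replicate VPCs, and toy one/two-eta problems for the quadrature
oracle.  At the reduced selection design the Erlang shape is near the
resolution limit: neighbouring transit counts differ by a handful of OFV
points, so the selected count can land one off the generating value —
the behaviour, not a defect, of the stepwise rule on thin data.

# Known limitations

* Laplace/FOCE is an approximation; its error is bounded by quadrature
  only on low-dimensional toys.  SAEM-style exact-likelihood methods are
  out of scope.
* Observations excluded below the quantification limit are simply
  dropped (as in the source analysis); no censored-likelihood treatment.
* Omega is diagonal; no inter-occasion variability; covariate search is
  limited to multiplicative weight/body-water/formulation effects.
* The bootstrap and SIR intervals inherit the point estimator's
  approximations; they are not posterior distributions.
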