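# enapopk

Simultaneous population pharmacokinetics of the prodrug **enalapril** and
its active metabolite **enalaprilat** in serum *and* urine, for
pharmacometricians studying child-appropriate reformulations of an adult
cardiovascular drug.  The package implements, as reusable and tested R
code, the semi-mechanistic nonlinear mixed-effects analysis of a
two-period crossover trial in which 24 healthy adults received a single
10 mg oral dose of enalapril maleate as a reference tablet and as
orodispersible mini-tablets (ODMT): the structural model, FOCE-with-
interaction estimation, objective-function-driven model building, model
qualification (VPC, bootstrap, SIR, stability), and the paired crossover
comparison of the two formulations.  Because the original subject-level
data are not public, a synthetic-trial generator reproduces the study
design so every stage of the pipeline runs end to end.

## The model

One subject's kinetics are a linear compartmental system: an oral depot
charged with `F1 x dose` (the unabsorbed remainder is lost
pre-systemically), `N1` absorption transit compartments traversed at
`KTR1 = (N1 + 1)/MTT1` — an Erlang delay whose last stage empties into
the parent central compartment at `KA` — a one-compartment parent
(volume `VC`) eliminated renally (`KREN`, into a cumulative urine sink)
and by conversion to the metabolite (`KM`), `N2` formation transits, and
a two-compartment metabolite (`VM`, exchange `KQ1`/`KQ2`) with renal
elimination `KME`.  Statistically: log-normal between-subject variability
on nine parameters, combined proportional + additive residual error for
the serum streams, proportional error for the cumulative urine amounts,
body weight (normalized to 69.76 kg, exponent 1) on `VC`, and a
formulation multiplier on `MTT1`.  Estimation maximizes the Laplace
(FOCE+I) marginal-likelihood approximation; `-2 log L` differences drive
transit-number and covariate selection at the 3.8 threshold.  Having
serum and urine data for both analytes makes the absolute bioavailable
fraction `F1` identifiable.

See the methods vignette (`vignettes/poppk-methods.Rmd`) for the full
account: model assumptions, estimation internals, numerical choices, what
the simulator does and does not emulate, and known limitations.

## Worked example

Deterministic kinetics at the published pooled estimates, for a 10 mg
(10,000 ug) dose:

```r
library(enapopk)
p <- structural_params(ka = 6.010, vc = 51.10, f1 = 0.606, mtt1 = 0.558,
                       kren = 0.305, km = 0.688, vm = 46.10, kq1 = 0.060,
                       kq2 = 0.054, kme = 0.184, mtt2 = 0.910)
grid <- seq(0.05, 48, by = 0.05)
pr <- predict_profile(p, 10000, grid, c(2, 4, 8, 12, 24, 36, 48))
max(pr$serum$parent)       # 75.0 ug/L at 0.95 h  (parent peaks near 1 h)
max(pr$serum$metabolite)   # 55.9 ug/L at 3.30 h  (metabolite 3-4 h later)
pr$urine$parent_cum[7]     # 1861 ug of parent in urine by 48 h
pr$urine$metabolite_cum[7] # 3949 ug of metabolite: together ~5810 ug,
                           # i.e. ~96% of the bioavailable 6060 ug
to_clearances(p)           # clren 15.59 L/h, clent 8.48 L/h
```

A full synthetic trial and population fit:

```r
ds  <- simulate_trial(trial_design(), enalapril_popmodel(), seed = 1)
sum(ds$EVID == 0)          # 2338 observations kept of 2592 simulated
                           # (serum values below the assay limits excluded)
fit <- fit_poppk(ds, enalapril_popmodel(),
                 fit_config(jitter = 0.2, seed = 2))
fit                        # estimates, %RSE, OFV, shrinkage
vpc(fit, n_sim = 1000, seed = 3)
```

Downstream: `select_transits()` and `covariate_step()` for model
building, `bootstrap_poppk()` / `sir_uncertainty()` / `stability_check()`
for qualification, and `split_by_formulation()` +
`compare_formulations()` for the paired Wilcoxon crossover comparison.
A thin command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/enapk.R", package="enapopk"))') \
    simulate --n-subjects 24 --seed 1 --out-dir run1
```

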