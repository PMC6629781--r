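Package: enapopk
Title: Simultaneous Population Pharmacokinetics of Enalapril and
    Enalaprilat in Serum and Urine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Semi-mechanistic population pharmacokinetic analysis of the
    prodrug enalapril and its active metabolite enalaprilat measured
    simultaneously in serum and urine after a single oral dose. Implements
    the linear transit-compartment (Erlang) absorption model with dual
    renal/metabolic elimination and a two-compartment metabolite, log-normal
    between-subject variability, combined residual-error models, FOCE-with-
    interaction (Laplace) marginal-likelihood estimation, objective-function
    driven transit-number and covariate selection, model evaluation by visual
    predictive check, nonparametric bootstrap, sampling-importance-resampling
    and initial-estimate stability checks, and paired Wilcoxon comparison of
    a child-appropriate orodispersible mini-tablet against the reference
    tablet in a two-period crossover design. A synthetic-trial generator
    reproduces the study design so the whole pipeline is testable without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    ggplot2,
    jsonlite,
    Matrix,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
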