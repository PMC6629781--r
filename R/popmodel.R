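#' Population pharmacokinetic model specification
#'
#' Bundles the fixed effects (typical values of the 11 structural
#' parameters), the covariate model, the diagonal between-subject variance
#' matrix Omega, and the residual-error variances Sigma for the four
#' observation streams (serum parent/metabolite: combined proportional +
#' additive; urine parent/metabolite: proportional only).
#'
#' Between-subject variability is exponential, `P_i = TV * exp(eta_i)` with
#' `eta ~ N(0, omega^2)`; a parameter with `omega2 = 0` carries no random
#' effect.  Etas are subject-level and shared across crossover periods (no
#' inter-occasion variability).
#'
#' @param theta named numeric vector of typical values for
#'   ka, vc, f1, mtt1, kren, km, vm, kq1, kq2, kme, mtt2
#' @param omega2 named vector of BSV variances for (a subset of)
#'   ka, vc, f1, mtt1, kren, km, vm, kme, mtt2; omitted names get 0
#' @param sigma named vector of residual components: `serum_parent_prop`,
#'   `serum_metab_prop`, `urine_parent_prop`, `urine_metab_prop`
#'   (proportional variances) and `serum_parent_add`, `serum_metab_add`
#'   (additive SDs, ug/L)
#' @param n1,n2 transit counts of the structural model
#' @param covariates list of covariate effects, each created by
#'   [cov_power()] or [cov_multiplier()]
#' @param wt_ref reference body weight (kg) for allometric normalization
#' @return object of class `enapk_popmodel`
#' @export
pop_model <- function(theta, omega2 = NULL, sigma = NULL, n1 = 8L, n2 = 2L,
                      covariates = list(), wt_ref = 69.76) {
  if (is.null(names(theta)) || !all(.param_names %in% names(theta)))
    stop("`theta` must be named and include all of: ",
         paste(.param_names, collapse = ", "))
  theta <- theta[.param_names]
  if (any(theta <= 0)) stop("typical values must be strictly positive")
  om <- setNames(numeric(length(.eta_names)), .eta_names)
  if (!is.null(omega2)) {
    bad <- setdiff(names(omega2), .eta_names)
    if (length(bad)) stop("no eta is defined for: ", paste(bad, collapse = ", "))
    om[names(omega2)] <- omega2
  }
  if (any(om < 0)) stop("omega2 must be non-negative")
  sg <- setNames(numeric(length(.sigma_names)), .sigma_names)
  if (!is.null(sigma)) {
    bad <- setdiff(names(sigma), .sigma_names)
    if (length(bad)) stop("unknown sigma component: ", paste(bad, collapse = ", "))
    sg[names(sigma)] <- sigma
  }
  if (any(sg < 0)) stop("sigma components must be non-negative")
  for (cv in covariates) .check_cov(cv)
  structure(list(theta = theta, omega2 = om, sigma = sg,
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 covariates = covariates, wt_ref = wt_ref),
            class = "enapk_popmodel")
}

#' Final pooled-data population model of enalapril/enalaprilat
#'
#' The package's reference parameterization: the published final
#' simultaneous serum + urine model for a 10 mg oral enalapril maleate dose
#' in healthy adults, with 8 absorption and 2 metabolite-formation transits,
#' body weight (normalized to the study mean 69.76 kg, exponent fixed at 1)
#' on the parent central volume, and a formulation multiplier (0.730 for the
#' orodispersible mini-tablet) on the absorption mean transit time.
#'
#' @param covariates logical; include the two final-model covariate effects
#' @return `enapk_popmodel`
#' @export
enalapril_popmodel <- function(covariates = TRUE) {
  theta <- c(ka = 6.010, vc = 51.10, f1 = 0.606, mtt1 = 0.558,
             kren = 0.305, km = 0.688, vm = 46.10, kq1 = 0.060,
             kq2 = 0.054, kme = 0.184, mtt2 = 0.910)
  omega2 <- c(ka = 0.688, vc = 0.058, f1 = 0.041, mtt1 = 0.151,
              kren = 0.058, km = 0.078, vm = 0.069, kme = 0.063,
              mtt2 = 0.296)
  sigma <- c(serum_parent_prop = 0.010, serum_parent_add = 0.188,
             serum_metab_prop = 0.018, serum_metab_add = 0.220,
             urine_parent_prop = 0.019, urine_metab_prop = 0.005)
  covs <- if (covariates)
    list(cov_power("vc", "WT", exponent = 1),
         cov_multiplier("mtt1", "FORM", value = 0.730))
  else list()
  pop_model(theta, omega2, sigma, n1 = 8L, n2 = 2L,
            covariates = covs, wt_ref = 69.76)
}

#' @export
print.enapk_popmodel <- function(x, ...) {
  cat("Population PK model (n1 =", x$n1, ", n2 =", x$n2, ")\n")
  cat("theta:\n"); print(round(x$theta, 4))
  cat("omega2 (BSV variances):\n"); print(round(x$omega2, 4))
  cat("sigma (residual):\n"); print(round(x$sigma, 4))
  if (length(x$covariates)) {
    cat("covariates:\n")
    for (cv in x$covariates) cat("  ", format(cv), "\n")
  }
  invisible(x)
}

# ---- covariate effects -----------------------------------------------------

#' Covariate effects on typical values
#'
#' `cov_power()` scales a typical value by `(covariate / reference)^exponent`
#' with the exponent fixed by convention (1 for volumes, 0.75 for
#' clearance-like rates); it introduces no estimated coefficient.
#' `cov_multiplier()` multiplies the typical value by `value^covariate`
#' (for a 0/1 covariate such as formulation this is a proportional shift on
#' the covariate-positive level); `value` is an estimable fixed effect.
#'
#' @param param structural parameter name receiving the effect
#' @param cov covariate column name (`WT`, `TBW`, `FORM`, ...)
#' @param exponent fixed power exponent
#' @param ref reference value for normalization (defaults to the model's
#'   `wt_ref` when `NA`)
#' @param value multiplier fixed effect (> 0)
#' @return covariate-effect specification (list)
#' @export
cov_power <- function(param, cov, exponent = 1, ref = NA_real_) {
  structure(list(param = param, cov = cov, type = "power",
                 exponent = exponent, ref = ref),
            class = "enapk_cov")
}

#' @rdname cov_power
#' @export
cov_multiplier <- function(param, cov, value = 1) {
  if (value <= 0) stop("multiplier must be positive")
  structure(list(param = param, cov = cov, type = "multiplier",
                 value = value),
            class = "enapk_cov")
}

.check_cov <- function(cv) {
  if (!inherits(cv, "enapk_cov"))
    stop("covariate effects must be built with cov_power()/cov_multiplier()")
  if (!cv$param %in% .param_names)
    stop("unknown parameter in covariate effect: ", cv$param)
  invisible(cv)
}

#' @export
format.enapk_cov <- function(x, ...) {
  if (x$type == "power")
    sprintf("%s ~ (%s/ref)^%g", x$param, x$cov, x$exponent)
  else
    sprintf("%s ~ %g^%s", x$param, x$value, x$cov)
}

# ---- covariate equations ---------------------------------------------------

#' Watson total body water
#'
#' Sex-specific linear equations for total body water (L):
#' males `0.3625 wt + 0.2239 ht - 0.1387 age - 14.47`,
#' females `0.2363 wt + 0.1962 ht - 0.0272 age - 10.26`.
#'
#' @param weight body weight (kg)
#' @param height height (cm)
#' @param age age (years)
#' @param sex `"male"` or `"female"` (vectorized)
#' @return total body water (L)
#' @export
watson_tbw <- function(weight, height, age, sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("`sex` must be \"male\" or \"female\"")
  ifelse(sex == "male",
         0.3625 * weight + 0.2239 * height - 0.1387 * age - 14.47,
         0.2363 * weight + 0.1962 * height - 0.0272 * age - 10.26)
}

#' Covariate-adjusted typical values
#'
#' Applies the model's covariate effects multiplicatively to the population
#' typical values for one subject-period: the final model scales `vc` by
#' `(WT / wt_ref)^1` and multiplies `mtt1` by the formulation coefficient
#' when `FORM = 1`.
#'
#' @param pop [pop_model()] object
#' @param covs named list or one-row data.frame of covariate values
#'   (`WT`, `FORM`, and any covariate named by the model's effects)
#' @return named vector of the 11 covariate-adjusted typical values
#' @export
typical_values <- function(pop, covs = list()) {
  stopifnot(inherits(pop, "enapk_popmodel"))
  covs <- as.list(covs)
  tv <- pop$theta
  for (cv in pop$covariates) {
    x <- covs[[cv$cov]]
    if (is.null(x)) stop("covariate `", cv$cov, "` not supplied")
    if (cv$type == "power") {
      ref <- if (is.na(cv$ref)) pop$wt_ref else cv$ref
      tv[cv$param] <- tv[cv$param] * (x / ref)^cv$exponent
    } else {
      tv[cv$param] <- tv[cv$param] * cv$value^x
    }
  }
  tv
}

#' Individual parameters from typical values and random effects
#'
#' Exponential between-subject model `P_i = TV * exp(eta)`; parameters
#' without an eta (kq1, kq2) keep their typical values.
#'
#' @param tv named vector of 11 covariate-adjusted typical values
#' @param eta named vector of random effects (subset of
#'   ka, vc, f1, mtt1, kren, km, vm, kme, mtt2); missing names count as 0
#' @param n1,n2 transit counts for the returned parameter object
#' @return [structural_params()] object
#' @export
individual_params <- function(tv, eta = NULL, n1 = 8L, n2 = 2L) {
  if (!all(.param_names %in% names(tv)))
    stop("`tv` must contain all 11 structural parameters")
  p <- tv[.param_names]
  if (!is.null(eta) && length(eta)) {
    bad <- setdiff(names(eta), .eta_names)
    if (length(bad)) stop("no eta exists for: ", paste(bad, collapse = ", "))
    p[names(eta)] <- p[names(eta)] * exp(eta)
  }
  suppressWarnings(
    do.call(structural_params, c(as.list(p), list(n1 = n1, n2 = n2))))
}

#' Residual-error variance of one prediction
#'
#' Serum streams use a combined error `y = f (1 + eps1) + eps2`, giving
#' variance `f^2 sigma2_prop + sigma_add^2`; urine streams are proportional
#' only, `f^2 sigma2_prop`.
#'
#' @param pred non-negative model prediction (ug/L serum, ug urine)
#' @param stream one of `"serum_parent"`, `"serum_metab"`,
#'   `"urine_parent"`, `"urine_metab"`
#' @param sigma named residual components as in [pop_model()]
#' @return residual variance (vectorized over `pred`)
#' @export
residual_variance <- function(pred, stream, sigma) {
  stream <- match.arg(stream, .stream_names)
  if (any(pred < 0)) stop("`pred` must be non-negative")
  sg <- setNames(numeric(length(.sigma_names)), .sigma_names)
  sg[names(sigma)] <- sigma
  switch(stream,
    serum_parent = pred^2 * sg[["serum_parent_prop"]] + sg[["serum_parent_add"]]^2,
    serum_metab  = pred^2 * sg[["serum_metab_prop"]] + sg[["serum_metab_add"]]^2,
    urine_parent = pred^2 * sg[["urine_parent_prop"]],
    urine_metab  = pred^2 * sg[["urine_metab_prop"]])
}
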