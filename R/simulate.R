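#' Crossover trial design
#'
#' The study layout emulated by the simulator: healthy adults receiving a
#' single 10 mg (10,000 ug) oral dose of enalapril maleate in each of two
#' crossover periods (reference tablet and orodispersible mini-tablet),
#' serum sampled 0.17-48 h post dose and urine collected over seven
#' intervals to 48 h, with assay LLOQ exclusion applied to the serum
#' streams.
#'
#' @param n_subjects number of subjects
#' @param dose dose per period (ug of enalapril maleate)
#' @param serum_times serum sampling times (h)
#' @param urine_times urine collection interval ends (h); observations are
#'   cumulative amounts since dose
#' @param periods number of crossover periods (1 or 2)
#' @param lloq per-stream quantification limits (see [default_lloq()])
#' @return list of class `enapk_design`
#' @export
trial_design <- function(n_subjects = 24L, dose = 10000,
                         serum_times = c(0.17, 0.33, 0.5, 0.75, 1, 1.25,
                                         1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5, 6,
                                         8, 10, 12, 24, 48),
                         urine_times = c(2, 4, 8, 12, 24, 36, 48),
                         periods = 2L, lloq = default_lloq()) {
  stopifnot(n_subjects >= 1, dose > 0, periods %in% 1:2,
            !is.unsorted(serum_times), !is.unsorted(urine_times),
            all(serum_times > 0), all(urine_times > 0))
  structure(list(n_subjects = as.integer(n_subjects), dose = dose,
                 serum_times = serum_times, urine_times = urine_times,
                 periods = as.integer(periods), lloq = lloq),
            class = "enapk_design")
}

# mean of a normal truncated to [lo, hi]
.trunc_mean <- function(mu, sd, lo, hi) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

.rtruncnorm <- function(n, mu, sd, lo, hi) {
  qnorm(runif(n, pnorm((lo - mu) / sd), pnorm((hi - mu) / sd))) * sd + mu
}

# location solved so the truncated mean hits the published summary mean
.calibrated_truncnorm <- function(n, target_mean, sd, lo, hi) {
  mu <- uniroot(function(m) .trunc_mean(m, sd, lo, hi) - target_mean,
                interval = c(lo - 3 * sd, hi + 3 * sd))$root
  .rtruncnorm(n, mu, sd, lo, hi)
}

#' Generate biometric covariates
#'
#' Weight, height and age are drawn from truncated normal distributions
#' whose bounds are the published study minima/maxima and whose locations
#' are solved so the truncated means equal the published study means
#' (weight 69.76 kg in 51.8-95.6, height 174.5 cm in 153-189, age 28.0 yr
#' in 22.08-47.16); sex is Bernoulli(0.5).  Total body water follows from
#' the sex-specific Watson equations.
#'
#' @param n number of subjects
#' @param seed optional seed (when `NULL` the current RNG stream is used)
#' @return data.frame with ID, WT, HT, AGE, SEX and TBW
#' @export
gen_covariates <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  wt <- .calibrated_truncnorm(n, 69.76, 11, 51.8, 95.6)
  ht <- .calibrated_truncnorm(n, 174.5, 8, 153, 189)
  age <- .calibrated_truncnorm(n, 28.0, 6, 22.08, 47.16)
  sex <- ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")
  data.frame(ID = seq_len(n), WT = wt, HT = ht, AGE = age, SEX = sex,
             TBW = watson_tbw(wt, ht, age, sex))
}

#' Simulate a crossover trial dataset
#'
#' Draws one subject-level eta vector per subject (shared across the two
#' periods -- no inter-occasion variability), applies the population model's
#' covariate effects per period (the formulation flag alternates with the
#' crossover sequence), predicts the four observation streams with the
#' structural model, adds residual error (combined for serum, proportional
#' for urine; negative serum draws are resampled and counted) and applies
#' the LLOQ exclusion rule.
#'
#' @param design [trial_design()] object
#' @param pop simulation truth as a [pop_model()]
#' @param seed RNG seed
#' @param covariates optional pre-generated covariate table from
#'   [gen_covariates()]
#' @return [pk_dataset()] with attribute `"truth"` (population model, etas,
#'   covariates, pre-exclusion row count, resampled-negative count)
#' @export
simulate_trial <- function(design = trial_design(),
                           pop = enalapril_popmodel(), seed = 1L,
                           covariates = NULL) {
  stopifnot(inherits(design, "enapk_design"),
            inherits(pop, "enapk_popmodel"))
  set.seed(seed)
  n <- design$n_subjects
  covs <- if (is.null(covariates)) gen_covariates(n) else covariates
  etas <- matrix(0, n, 9, dimnames = list(NULL, .eta_names))
  for (k in seq_len(9))
    if (pop$omega2[k] > 0)
      etas[, k] <- rnorm(n, 0, sqrt(pop$omega2[k]))
  st <- design$serum_times
  ut <- design$urine_times
  dvid <- c(rep(1L, length(st)), rep(2L, length(st)),
            rep(3L, length(ut)), rep(4L, length(ut)))
  tim <- c(st, st, ut, ut)
  allt <- sort(unique(tim))
  idx0 <- as.integer(match(tim, allt) - 1L)
  n_negative <- 0L
  rows <- vector("list", n * design$periods)
  ri <- 0L
  for (i in seq_len(n)) {
    # alternate crossover sequences: odd subjects reference first
    seq_i <- if (i %% 2 == 1) c(0L, 1L) else c(1L, 0L)
    for (per in seq_len(design$periods)) {
      form <- seq_i[per]
      cv <- list(WT = covs$WT[i], HT = covs$HT[i], AGE = covs$AGE[i],
                 SEX = covs$SEX[i], TBW = covs$TBW[i], FORM = form)
      tv <- typical_values(pop, cv)
      ip <- tv
      ip[.eta_names] <- ip[.eta_names] * exp(etas[i, ])
      f <- predict_dv_cpp(unname(ip), pop$n1, pop$n2, 0, design$dose,
                          allt, idx0, dvid)
      dv <- numeric(length(f))
      for (j in seq_along(f)) {
        repeat {
          val <- switch(dvid[j],
            f[j] * (1 + rnorm(1, 0, sqrt(pop$sigma[["serum_parent_prop"]]))) +
              rnorm(1, 0, pop$sigma[["serum_parent_add"]]),
            f[j] * (1 + rnorm(1, 0, sqrt(pop$sigma[["serum_metab_prop"]]))) +
              rnorm(1, 0, pop$sigma[["serum_metab_add"]]),
            f[j] * (1 + rnorm(1, 0, sqrt(pop$sigma[["urine_parent_prop"]]))),
            f[j] * (1 + rnorm(1, 0, sqrt(pop$sigma[["urine_metab_prop"]]))))
          if (val >= 0) break
          n_negative <- n_negative + 1L
        }
        dv[j] <- val
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        ID = i, PER = per,
        TIME = c(0, tim), EVID = c(1L, rep(0L, length(tim))),
        AMT = c(design$dose, rep(NA_real_, length(tim))),
        DV = c(NA_real_, dv), DVID = c(NA_integer_, dvid),
        FORM = form, WT = covs$WT[i], HT = covs$HT[i], AGE = covs$AGE[i],
        SEX = covs$SEX[i])
    }
  }
  ds <- pk_dataset(do.call(rbind, rows))
  n_pre <- sum(ds$EVID == 0)
  ds <- apply_lloq(ds, design$lloq, quiet = TRUE)
  attr(ds, "truth") <- list(pop = pop, etas = etas, covariates = covs,
                            design = design, seed = seed,
                            n_obs_pre_lloq = n_pre,
                            n_obs = sum(ds$EVID == 0),
                            n_negative_resampled = n_negative)
  ds
}

#' Deterministic fixture datasets
#'
#' Small named datasets used throughout the test-suite and examples:
#' a noiseless single subject, a 6-subject fast-fit trial, the full
#' 24-subject trial at the reference parameterization, a trial simulated
#' without any covariate effect, and a trial whose only formulation effect
#' is the multiplier on the absorption mean transit time.
#'
#' @param seed base seed (each fixture offsets it deterministically)
#' @param dir optional directory; when given, each fixture is also written
#'   as CSV via [write_pk_dataset()]
#' @return named list of datasets (invisibly also the file paths when `dir`
#'   is used, as attribute `"paths"`)
#' @export
make_fixture_suite <- function(seed = 20260101L, dir = NULL) {
  pop <- enalapril_popmodel()
  noiseless <- pop
  noiseless$omega2[] <- 0
  noiseless$sigma[] <- 0
  no_cov <- enalapril_popmodel(covariates = FALSE)
  form_only <- enalapril_popmodel(covariates = FALSE)
  form_only$covariates <- list(cov_multiplier("mtt1", "FORM", 0.730))
  fx <- list(
    noiseless_single = simulate_trial(trial_design(n_subjects = 1),
                                      noiseless, seed = seed),
    six_subject = simulate_trial(trial_design(n_subjects = 6), pop,
                                 seed = seed + 1L),
    full_trial = simulate_trial(trial_design(), pop, seed = seed + 2L),
    null_covariate = simulate_trial(trial_design(), no_cov, seed = seed + 3L),
    formulation_effect = simulate_trial(trial_design(), form_only,
                                        seed = seed + 4L))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(names(fx), function(nm) {
      write_pk_dataset(fx[[nm]], file.path(dir, paste0(nm, ".csv")))
      file.path(dir, paste0(nm, ".csv"))
    }, character(1))
    attr(fx, "paths") <- paths
  }
  fx
}

#' Split a crossover dataset by formulation
#'
#' @param ds [pk_dataset()] object with both formulations
#' @return list with `reference` (FORM 0) and `odmt` (FORM 1) datasets
#' @export
split_by_formulation <- function(ds) {
  stopifnot(inherits(ds, "enapk_dataset"))
  out <- lapply(c(reference = 0, odmt = 1), function(f) {
    d <- ds[ds$FORM == f, ]
    rownames(d) <- NULL
    class(d) <- class(ds)
    d
  })
  out
}
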