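#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the observed design (same subjects,
#' covariates, formulation flags and sampling times; fresh etas and
#' residual errors; same LLOQ exclusion rule) from the fitted model and
#' compares the observed 2.5th/50th/97.5th percentile of each stream at
#' each nominal time against the 95% interval of the same percentile across
#' simulations.  Serum streams are binned at the nominal sampling times and
#' urine streams at the collection-interval ends (the design is a fixed
#' schedule, so no adaptive binning is needed).
#'
#' @param fit [fit_poppk()] result (or a posthoc evaluation)
#' @param ds dataset whose design is replicated (defaults to the fitted one)
#' @param n_sim number of Monte Carlo replicate trials
#' @param seed RNG seed
#' @param pi percentiles summarized per bin
#' @param ci confidence level of the simulated percentile bands
#' @return data.frame of class `enapk_vpc` with observed percentiles and
#'   simulated band limits per stream and time
#' @export
vpc <- function(fit, ds = fit$data, n_sim = 1000L, seed = 1L,
                pi = c(0.025, 0.5, 0.975), ci = 0.95) {
  stopifnot(inherits(fit, "enapk_fit") || inherits(fit, "enapk_popmodel"))
  pop <- if (inherits(fit, "enapk_fit")) fit$pop else fit
  if (n_sim < 100)
    warning("n_sim < 100: simulated percentile bands will be unstable")
  cds <- .compile_dataset(ds)
  lim <- setNames(numeric(4), .stream_names)
  tr <- attr(ds, "truth")
  if (!is.null(tr)) lim[names(tr$design$lloq)] <- tr$design$lloq
  else lim[] <- default_lloq()
  obs <- ds[ds$EVID == 0, ]
  bins <- unique(obs[, c("DVID", "TIME")])
  bins <- bins[order(bins$DVID, bins$TIME), ]
  obs_q <- t(apply(bins, 1, function(b) {
    quantile(obs$DV[obs$DVID == b[1] & obs$TIME == b[2]], pi, names = FALSE)
  }))
  act <- .active_etas(pop)
  set.seed(seed)
  sim_q <- array(NA_real_, c(nrow(bins), length(pi), n_sim))
  for (s in seq_len(n_sim)) {
    simdv <- rep(NA_real_, nrow(obs))
    pos <- 0L
    for (i in seq_len(cds$n_subjects)) {
      subj <- cds$subjects[[i]]
      eta <- numeric(9)
      eta[act] <- rnorm(length(act), 0, sqrt(pop$omega2[act]))
      for (pe in subj$periods) {
        tv <- typical_values(pop, pe$covs)
        ip <- unname(tv)
        ip[.eta_map0 + 1] <- ip[.eta_map0 + 1] * exp(eta)
        f <- predict_dv_cpp(ip, pop$n1, pop$n2, pe$dose_t, pe$dose_a,
                            pe$ut, pe$idx0, pe$dvid)
        v_prop <- unname(pop$sigma[c("serum_parent_prop", "serum_metab_prop",
                                     "urine_parent_prop",
                                     "urine_metab_prop")])[pe$dvid]
        v_add <- c(pop$sigma[["serum_parent_add"]],
                   pop$sigma[["serum_metab_add"]], 0, 0)[pe$dvid]
        dv <- f * (1 + rnorm(length(f), 0, sqrt(v_prop))) +
          rnorm(length(f), 0, v_add)
        neg <- which(dv < 0)
        for (j in neg) {
          repeat {
            dv[j] <- f[j] * (1 + rnorm(1, 0, sqrt(v_prop[j]))) +
              rnorm(1, 0, v_add[j])
            if (dv[j] >= 0) break
          }
        }
        dv[dv < lim[pe$dvid]] <- NA  # below LLOQ: excluded
        simdv[pos + seq_along(dv)] <- dv
        pos <- pos + length(dv)
      }
    }
    for (b in seq_len(nrow(bins))) {
      x <- simdv[obs$DVID == bins$DVID[b] & obs$TIME == bins$TIME[b]]
      x <- x[!is.na(x)]
      if (length(x)) sim_q[b, , s] <- quantile(x, pi, names = FALSE)
    }
  }
  alpha <- (1 - ci) / 2
  out <- data.frame(stream = .stream_names[bins$DVID], time = bins$TIME)
  for (k in seq_along(pi)) {
    lab <- format(100 * pi[k], trim = TRUE)
    out[[paste0("obs_p", lab)]] <- obs_q[, k]
    out[[paste0("sim_lo_p", lab)]] <-
      apply(sim_q[, k, , drop = FALSE], 1, quantile, alpha, na.rm = TRUE)
    out[[paste0("sim_hi_p", lab)]] <-
      apply(sim_q[, k, , drop = FALSE], 1, quantile, 1 - alpha, na.rm = TRUE)
  }
  attr(out, "n_sim") <- n_sim
  attr(out, "pi") <- pi
  class(out) <- c("enapk_vpc", "data.frame")
  out
}

#' Fraction of observed percentile points inside their simulated bands
#'
#' @param v [vpc()] result
#' @return proportion in `[0, 1]`
#' @export
vpc_coverage <- function(v) {
  stopifnot(inherits(v, "enapk_vpc"))
  labs <- format(100 * attr(v, "pi"), trim = TRUE)
  inside <- total <- 0
  for (lab in labs) {
    o <- v[[paste0("obs_p", lab)]]
    lo <- v[[paste0("sim_lo_p", lab)]]
    hi <- v[[paste0("sim_hi_p", lab)]]
    ok <- !is.na(o) & !is.na(lo) & !is.na(hi)
    inside <- inside + sum(o[ok] >= lo[ok] & o[ok] <= hi[ok])
    total <- total + sum(ok)
  }
  inside / total
}

#' @export
plot.enapk_vpc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is needed for VPC plots")
  ggplot2::ggplot(x, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo_p50,
                                      ymax = .data$sim_hi_p50),
                         alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo_p2.5,
                                      ymax = .data$sim_hi_p2.5),
                         alpha = 0.15) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$sim_lo_p97.5,
                                      ymax = .data$sim_hi_p97.5),
                         alpha = 0.15) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), colour = "red",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p2.5), colour = "red",
                       linetype = 3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p97.5), colour = "red",
                       linetype = 3) +
    ggplot2::facet_wrap(~stream, scales = "free") +
    ggplot2::labs(x = "time (h)", y = "observation")
}

#' Nonparametric bootstrap of the population fit
#'
#' Resamples subjects with replacement to the original count, refits the
#' model on each replicate (starting from the final estimates, as common
#' bootstrap tooling does) and summarizes the 2.5th/50th/97.5th percentile
#' of every estimated parameter.
#'
#' @param ds original dataset
#' @param fit fitted model providing the final estimates and configuration
#' @param n_boot number of bootstrap datasets
#' @param seed RNG seed
#' @param config fit settings for the replicates (defaults to the original
#'   configuration without the covariance step)
#' @return list of class `enapk_uncertainty`
#' @export
bootstrap_poppk <- function(ds, fit, n_boot = 200L, seed = 1L,
                            config = NULL) {
  stopifnot(inherits(fit, "enapk_fit"))
  if (length(unique(ds$ID)) < 5 && n_boot > 1)
    warning("fewer than 5 subjects: bootstrap intervals are unreliable")
  if (is.null(config)) {
    config <- fit$config
    config$hessian <- FALSE
  }
  ids <- unique(ds$ID)
  set.seed(seed)
  draws <- list()
  failed <- 0L
  for (b in seq_len(n_boot)) {
    take <- sample(ids, length(ids), replace = TRUE)
    parts <- lapply(seq_along(take), function(k) {
      d <- ds[ds$ID == take[k], ]
      d$ID <- k
      d
    })
    db <- do.call(rbind, parts)
    rownames(db) <- NULL
    class(db) <- class(ds)
    fb <- tryCatch(fit_poppk(db, fit$pop, config), error = function(e) NULL)
    if (is.null(fb) || fb$convergence$code != 0) {
      failed <- failed + 1L
      next
    }
    draws[[length(draws) + 1L]] <- .flatten_estimates(fb$pop)
  }
  if (failed > 0.2 * n_boot)
    warning(failed, " of ", n_boot, " bootstrap replicates failed")
  mat <- do.call(rbind, draws)
  .uncertainty_result(mat, "bootstrap", n_boot, nrow(mat), failed)
}

.flatten_estimates <- function(pop) {
  out <- pop$theta
  for (cv in pop$covariates)
    if (cv$type == "multiplier") out[.cov_par_name(cv)] <- cv$value
  out <- c(out, setNames(pop$omega2, paste0("om_", .eta_names)),
           setNames(pop$sigma, paste0("sig_", .sigma_names)))
  out
}

.uncertainty_result <- function(mat, method, requested, used, failed = 0L) {
  qs <- t(apply(mat, 2, quantile, c(0.025, 0.5, 0.975), names = FALSE))
  tab <- data.frame(parameter = colnames(mat), p2.5 = qs[, 1],
                    p50 = qs[, 2], p97.5 = qs[, 3], row.names = NULL)
  structure(list(table = tab, draws = mat, method = method,
                 n_requested = requested, n_used = used, n_failed = failed),
            class = "enapk_uncertainty")
}

#' @export
print.enapk_uncertainty <- function(x, ...) {
  cat("Parameter uncertainty by", x$method, "(", x$n_used, "of",
      x$n_requested, "replicates )\n")
  print(transform(x$table, p2.5 = signif(p2.5, 4), p50 = signif(p50, 4),
                  p97.5 = signif(p97.5, 4)))
  invisible(x)
}

# ---- sampling importance resampling ----------------------------------------

.dmvnorm_log <- function(x, mean, chol_up) {
  z <- backsolve(chol_up, x - mean, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(chol_up))) -
    0.5 * length(mean) * log(2 * pi)
}

# Generic SIR over an arbitrary -2 log-likelihood surface; used both by
# sir_uncertainty() and by the analytic-oracle tests.
sir_core <- function(ofv_fun, center, vcov, n_sample, n_resample, seed) {
  set.seed(seed)
  p <- length(center)
  U <- chol(vcov)
  Z <- matrix(rnorm(n_sample * p), n_sample, p) %*% U
  Z <- sweep(Z, 2, center, `+`)
  ofv0 <- ofv_fun(center)
  logw <- numeric(n_sample)
  for (s in seq_len(n_sample)) {
    logw[s] <- -0.5 * (ofv_fun(Z[s, ]) - ofv0) -
      .dmvnorm_log(Z[s, ], center, U)
  }
  logw <- logw - max(logw)
  w <- exp(logw)
  w <- w / sum(w)
  ess <- 1 / sum(w^2)
  replace <- FALSE
  if (ess < n_resample) {
    warning("effective sample size (", round(ess, 1), ") below resample ",
            "size; resampling with replacement")
    replace <- TRUE
  }
  idx <- sample.int(n_sample, n_resample, replace = replace, prob = w)
  list(draws = Z[idx, , drop = FALSE], weights = w, ess = ess,
       replace = replace)
}

#' Sampling-importance-resampling parameter uncertainty
#'
#' Draws `n_sample` parameter vectors from a multivariate-normal proposal on
#' the estimation (log) scale, centred at the estimates with covariance
#' equal to the inverse-Hessian covariance inflated by `inflation`; weights
#' each draw by `exp(-dOFV/2)` against the proposal density and resamples
#' `n_resample` vectors without replacement with probability proportional to
#' the weights.
#'
#' @param fit fitted model with a covariance step (`vcov`)
#' @param ds dataset used to re-evaluate the OFV (defaults to the fitted
#'   one)
#' @param n_sample proposal sample size
#' @param n_resample resample size
#' @param seed RNG seed
#' @param inflation proposal covariance inflation factor
#' @return list of class `enapk_uncertainty` (percentiles on the natural
#'   scale)
#' @export
sir_uncertainty <- function(fit, ds = fit$data, n_sample = 20000L,
                            n_resample = 2000L, seed = 1L,
                            inflation = 1.5) {
  stopifnot(inherits(fit, "enapk_fit"))
  if (is.null(fit$vcov))
    stop("fit has no covariance step; rerun with hessian = TRUE")
  cds <- .compile_dataset(ds)
  config <- fit$config
  q <- length(.active_etas(fit$pop))
  warm <- matrix(0, cds$n_subjects, q)
  template <- fit$start
  fixed <- fit$fixed
  ofv_fun <- function(par) {
    names(par) <- names(fit$par)
    pop <- .floor_pop(.unpack(par, template, fixed))
    tot <- 0
    for (i in seq_len(cds$n_subjects)) {
      r <- .subject_ofv(cds$subjects[[i]], pop, warm[i, ],
                        config$inner_maxit, config$inner_gtol)
      warm[i, ] <<- r$eta
      tot <- tot + r$ofv
    }
    tot
  }
  res <- sir_core(ofv_fun, fit$par, fit$vcov * inflation, n_sample,
                  n_resample, seed)
  nat <- t(apply(res$draws, 1, function(p) {
    names(p) <- names(fit$par)
    .flatten_estimates(.unpack(p, template, fixed))
  }))
  out <- .uncertainty_result(nat, "SIR", n_sample, n_resample)
  out$ess <- res$ess
  out$replace <- res$replace
  out
}

#' Stability of the estimates under perturbed initial values
#'
#' Perturbs each selected starting value by +/- `perturbation` one at a
#' time, refits, and reports the change in OFV and the largest relative
#' change of any estimate against the reference fit.  Parameters that are
#' fixed by design (for example the allometric exponents) produce a flagged
#' no-op row.
#'
#' @param ds dataset
#' @param fit reference fit (its `start` model supplies the unperturbed
#'   initial values)
#' @param perturbation relative perturbation (0.10 = 10%)
#' @param params names of starting values to perturb (default: all
#'   estimated parameters)
#' @param config fit settings for the refits
#' @return data.frame with one row per (parameter, direction)
#' @export
stability_check <- function(ds, fit, perturbation = 0.10, params = NULL,
                            config = NULL) {
  stopifnot(inherits(fit, "enapk_fit"))
  if (is.null(config)) {
    config <- fit$config
    config$hessian <- FALSE
  }
  pk <- .pack(fit$start, fit$config$fix)
  est_names <- names(pk$par)
  if (is.null(params)) params <- est_names
  ref <- .flatten_estimates(fit$pop)
  out <- list()
  for (nm in params) {
    if (!nm %in% est_names) {
      out[[length(out) + 1L]] <- data.frame(
        param = nm, direction = NA_real_, ofv = NA_real_, dofv = NA_real_,
        max_rel_change = NA_real_, status = "fixed-by-design (no-op)")
      next
    }
    for (dir in c(-1, 1)) {
      start_p <- fit$start
      par_p <- pk$par
      par_p[nm] <- par_p[nm] + log(1 + dir * perturbation)
      start_p <- .unpack(par_p, start_p, pk$fixed)
      fp <- tryCatch(fit_poppk(ds, start_p, config),
                     error = function(e) NULL)
      if (is.null(fp)) {
        out[[length(out) + 1L]] <- data.frame(
          param = nm, direction = dir, ofv = NA_real_, dofv = NA_real_,
          max_rel_change = NA_real_, status = "refit failed")
        next
      }
      est <- .flatten_estimates(fp$pop)
      mrc <- max(abs(est[names(ref)] - ref) / pmax(abs(ref), 1e-12))
      out[[length(out) + 1L]] <- data.frame(
        param = nm, direction = dir, ofv = fp$ofv,
        dofv = fp$ofv - fit$ofv, max_rel_change = mrc, status = "ok")
    }
  }
  do.call(rbind, out)
}
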