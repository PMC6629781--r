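#' Estimation settings
#'
#' @param maxit maximum outer (population) iterations
#' @param reltol relative OFV convergence tolerance of the outer optimizer
#' @param inner_maxit maximum iterations of each subject's conditional-eta
#'   search
#' @param inner_gtol gradient tolerance of the inner search
#' @param fix names of parameters held at their starting values
#'   (structural names, `om_<name>`, `sig_<name>` or `cov_<param>_<cov>`)
#' @param polish_maxit iteration cap of the exact-gradient polishing pass
#' @param polish_central use central (rather than forward) differences in
#'   the polishing gradient; twice the cost, for high-precision fits of
#'   deterministic or near-deterministic data
#' @param jitter half-width of the uniform log-scale perturbation applied to
#'   the starting values (0 = start exactly at `start`)
#' @param seed seed for the jitter
#' @param hessian compute the OFV Hessian for standard errors after the fit
#' @return list of class `enapk_config`
#' @export
fit_config <- function(maxit = 300L, reltol = 1e-9, inner_maxit = 150L,
                       inner_gtol = 1e-6, polish_maxit = 60L,
                       polish_central = FALSE,
                       fix = character(), jitter = 0,
                       seed = 1L, hessian = TRUE) {
  stopifnot(reltol > 0, inner_gtol > 0)
  structure(list(maxit = as.integer(maxit), reltol = reltol,
                 inner_maxit = as.integer(inner_maxit),
                 inner_gtol = inner_gtol,
                 polish_maxit = as.integer(polish_maxit),
                 polish_central = isTRUE(polish_central),
                 fix = fix, jitter = jitter,
                 seed = as.integer(seed), hessian = isTRUE(hessian)),
            class = "enapk_config")
}

# ---- parameter packing (everything estimated on the log scale) -------------

.cov_par_name <- function(cv) paste("cov", cv$param, cv$cov, sep = "_")

.pack <- function(pop, fix = character()) {
  par <- log(pop$theta)
  names(par) <- .param_names
  for (cv in pop$covariates)
    if (cv$type == "multiplier") par[.cov_par_name(cv)] <- log(cv$value)
  act_om <- pop$omega2 > 0
  if (any(act_om))
    par[paste0("om_", .eta_names[act_om])] <- log(pop$omega2[act_om])
  act_sg <- pop$sigma > 0
  if (any(act_sg))
    par[paste0("sig_", .sigma_names[act_sg])] <- log(pop$sigma[act_sg])
  est <- setdiff(names(par), fix)
  list(par = par[est], fixed = par[setdiff(names(par), est)])
}

.unpack <- function(par, pop, fixed = numeric()) {
  full <- c(par, fixed)
  out <- pop
  out$theta[.param_names] <- exp(full[.param_names])
  for (i in seq_along(out$covariates)) {
    cv <- out$covariates[[i]]
    if (cv$type == "multiplier")
      out$covariates[[i]]$value <- exp(full[[.cov_par_name(cv)]])
  }
  for (nm in .eta_names) {
    key <- paste0("om_", nm)
    if (key %in% names(full)) out$omega2[nm] <- exp(full[[key]])
  }
  for (nm in .sigma_names) {
    key <- paste0("sig_", nm)
    if (key %in% names(full)) out$sigma[nm] <- exp(full[[key]])
  }
  out
}

.active_etas <- function(pop) which(pop$omega2 > 0)

# variance floors guarding against boundary singularities
.floor_pop <- function(pop) {
  act <- pop$omega2 > 0
  pop$omega2[act] <- pmax(pop$omega2[act], 1e-10)
  act <- pop$sigma > 0
  pop$sigma[act] <- pmax(pop$sigma[act], 1e-10)
  pop
}

# One subject's Laplace contribution; `eta_start` is the warm start.
.subject_ofv <- function(subj, pop, eta_start, inner_maxit, inner_gtol,
                         want_jac = FALSE) {
  act <- .active_etas(pop)
  tv <- .tv_matrix(pop, subj)
  subject_laplace_cpp(subj, tv, .eta_map0[act], unname(pop$omega2[act]),
                      unname(pop$sigma), pop$n1, pop$n2,
                      eta_start, inner_maxit, inner_gtol, want_jac)
}

#' FOCE objective function value of a dataset under a population model
#'
#' Minus twice the Laplace (FOCE-with-interaction) approximation to the log
#' marginal likelihood, summed over subjects, including the full `2*pi`
#' normalizing constants so that the value is directly comparable with the
#' exact `-2 log L` obtained by quadrature.  Residual variances are
#' evaluated at the individual (conditional) predictions.
#'
#' @param ds [pk_dataset()] object
#' @param pop [pop_model()] object
#' @param config [fit_config()] settings (inner-search controls are used)
#' @return OFV (scalar) with attribute `"by_subject"`
#' @export
foce_ofv <- function(ds, pop, config = fit_config()) {
  cds <- .compile_dataset(ds)
  pop <- .floor_pop(pop)
  q <- length(.active_etas(pop))
  per <- vapply(cds$subjects, function(s) {
    .subject_ofv(s, pop, numeric(q), config$inner_maxit,
                 config$inner_gtol)$ofv
  }, numeric(1))
  structure(sum(per), by_subject = per)
}

#' Inner (conditional) objective for one subject
#'
#' The quantity minimized over the random effects at fixed population
#' parameters: `sum[(dv - f)^2 / v + log v] + eta' Omega^-1 eta +
#' log det Omega`, with the residual variance `v` evaluated at the
#' individual prediction (interaction).
#'
#' @param ds dataset
#' @param pop population model
#' @param id subject identifier
#' @param eta named (or 9-vector) random-effect value
#' @return scalar objective value
#' @export
inner_objective <- function(ds, pop, id, eta) {
  cds <- .compile_dataset(ds)
  idx <- which(vapply(cds$subjects, function(s) s$id, numeric(1)) == id)
  if (!length(idx)) stop("subject ", id, " not in dataset")
  subj <- cds$subjects[[idx]]
  pop <- .floor_pop(pop)
  act <- .active_etas(pop)
  ev <- setNames(numeric(9), .eta_names)
  if (!is.null(names(eta))) ev[names(eta)] <- eta else ev[] <- eta
  subject_inner_cpp(subj, .tv_matrix(pop, subj), .eta_map0[act],
                    unname(pop$omega2[act]), unname(pop$sigma),
                    pop$n1, pop$n2, unname(ev[act]))
}

#' Conditional (empirical Bayes) random effects
#'
#' Posterior-mode etas per subject at fixed population parameters, with the
#' curvature (Hessian of the inner objective) at the mode.
#'
#' @inheritParams foce_ofv
#' @return list with `eta` (subjects x 9 matrix, inactive etas 0),
#'   `curvature` (per-subject Hessian of the inner objective over the active
#'   etas), and `ofv` contributions
#' @export
conditional_etas <- function(ds, pop, config = fit_config()) {
  cds <- .compile_dataset(ds)
  pop <- .floor_pop(pop)
  act <- .active_etas(pop)
  q <- length(act)
  n <- cds$n_subjects
  etas <- matrix(0, n, 9, dimnames = list(
    vapply(cds$subjects, function(s) as.character(s$id), character(1)),
    .eta_names))
  curv <- vector("list", n)
  ofv <- numeric(n)
  for (i in seq_len(n)) {
    r <- .subject_ofv(cds$subjects[[i]], pop, numeric(q),
                      config$inner_maxit, config$inner_gtol, want_jac = TRUE)
    etas[i, act] <- r$eta
    curv[[i]] <- 2 * .half_hessian_r(r$jac, r$fhat,
                                     .subject_dvids(cds$subjects[[i]]),
                                     pop$sigma, pop$omega2[act])
    ofv[i] <- r$ofv
  }
  list(eta = etas, curvature = curv, ofv = ofv)
}

.subject_dvids <- function(subj)
  unlist(lapply(subj$periods, `[[`, "dvid"))

.subject_dvs <- function(subj)
  unlist(lapply(subj$periods, `[[`, "dv"))

# FOCE linearized half-Hessian (mirrors the C++ formula)
.half_hessian_r <- function(J, fhat, dvid, sigma, omega2_act) {
  q <- length(omega2_act)
  if (q == 0) return(matrix(0, 0, 0))
  fhat <- as.numeric(fhat)
  v <- .res_var_vec(fhat, dvid, sigma)
  sp2 <- unname(sigma[c("serum_parent_prop", "serum_metab_prop",
                        "urine_parent_prop", "urine_metab_prop")])[dvid]
  J <- matrix(J, ncol = q)
  vp <- 2 * fhat * sp2 * J
  t(J) %*% (J / v) + 0.5 * t(vp) %*% (vp / v^2) + diag(1 / omega2_act, q)
}

.res_var_vec <- function(f, dvid, sigma) {
  v <- numeric(length(f))
  v[dvid == 1] <- f[dvid == 1]^2 * sigma[["serum_parent_prop"]] +
    sigma[["serum_parent_add"]]^2
  v[dvid == 2] <- f[dvid == 2]^2 * sigma[["serum_metab_prop"]] +
    sigma[["serum_metab_add"]]^2
  v[dvid == 3] <- f[dvid == 3]^2 * sigma[["urine_parent_prop"]]
  v[dvid == 4] <- f[dvid == 4]^2 * sigma[["urine_metab_prop"]]
  pmax(v, 1e-12)
}

# forward-difference gradient
.num_grad <- function(fn, par, f0 = NULL, h = 1e-4) {
  if (is.null(f0)) f0 <- fn(par)
  g <- numeric(length(par))
  for (j in seq_along(par)) {
    pj <- par
    hj <- h * (1 + abs(par[j]))
    pj[j] <- pj[j] + hj
    g[j] <- (fn(pj) - f0) / hj
  }
  g
}

#' Fit the population model by FOCE with interaction
#'
#' Maximizes the Laplace/FOCE approximation of the marginal likelihood over
#' the log-transformed fixed effects, covariate coefficients, BSV variances
#' and residual variances.  Conditional etas are warm-started across outer
#' iterations.  Standard errors come from the inverse observed Fisher
#' information (Hessian of OFV/2 at the optimum).
#'
#' @param ds [pk_dataset()] object; must contain serum and urine streams of
#'   both analytes for the absorbed fraction to be identifiable
#' @param start starting [pop_model()] (also defines which covariate effects
#'   and random effects are in the model)
#' @param config [fit_config()] settings
#' @param method `"foce"` performs the full population fit; `"posthoc"`
#'   skips the outer optimization and only evaluates the OFV and conditional
#'   etas at `start` (NONMEM's MAXEVAL=0 evaluation)
#' @return object of class `enapk_fit`
#' @export
fit_poppk <- function(ds, start = enalapril_popmodel(),
                      config = fit_config(),
                      method = c("foce", "posthoc")) {
  method <- match.arg(method)
  stopifnot(inherits(start, "enapk_popmodel"))
  cds <- .compile_dataset(ds)
  start <- .floor_pop(start)
  streams <- sort(unique(ds$DVID[ds$EVID == 0]))
  ident_flag <- NULL
  if (!any(c(3, 4) %in% streams)) {
    ident_flag <- "no urine streams: f1 (and vm) not identifiable"
    warning(ident_flag)
  }
  pk <- .pack(start, config$fix)
  par <- pk$par
  if (config$jitter > 0) {
    set.seed(config$seed)
    par <- par + runif(length(par), -config$jitter, config$jitter)
  }
  q <- length(.active_etas(start))
  warm <- matrix(0, cds$n_subjects, q)
  n_eval <- 0L
  obj <- function(p, inner_maxit = config$inner_maxit, update_warm = TRUE) {
    pop <- .floor_pop(.unpack(p, start, pk$fixed))
    tot <- 0
    for (i in seq_len(cds$n_subjects)) {
      r <- .subject_ofv(cds$subjects[[i]], pop, warm[i, ],
                        inner_maxit, config$inner_gtol)
      if (update_warm) warm[i, ] <<- r$eta
      tot <- tot + r$ofv
    }
    n_eval <<- n_eval + 1L
    if (!is.finite(tot)) tot <- 1e10
    tot
  }
  # The population parameters are advanced by alternating two steps, the
  # standard FOCE scheme: (1) conditional etas are re-optimized at the
  # current population values; (2) a quasi-Newton pass minimizes the
  # *frozen-eta* objective (the Laplace OFV evaluated at the fixed
  # conditional modes).  At the conditional mode the frozen surface touches
  # the true OFV (envelope property) and shares its gradient up to the
  # dependence of the curvature log-determinant on eta-hat, which FOCE
  # implementations neglect; the frozen surface is smooth and two orders of
  # magnitude cheaper, so each BFGS pass converges cleanly.  Cycles repeat
  # until the true OFV stabilizes.
  frozen <- function(p) obj(p, 0L, update_warm = FALSE)
  last_par <- NULL
  obj_true <- function(p) {
    val <- obj(p)
    last_par <<- p
    val
  }
  grad_fun <- function(p) {
    # make sure the conditional modes belong to this point, then take the
    # envelope gradient on the frozen surface
    if (is.null(last_par) || !isTRUE(all(p == last_par))) obj_true(p)
    f0 <- frozen(p)
    .num_grad(frozen, p, f0 = f0, h = 5e-4)
  }
  grad_exact <- function(p) {
    if (isTRUE(config$polish_central)) {
      g <- numeric(length(p))
      for (j in seq_along(p)) {
        hj <- 5e-4 * (1 + abs(p[j]))
        pp <- pm <- p
        pp[j] <- pp[j] + hj
        pm[j] <- pm[j] - hj
        g[j] <- (obj(pp) - obj(pm)) / (2 * hj)
      }
      g
    } else {
      f0 <- obj(p)
      .num_grad(function(pp) obj(pp), p, f0 = f0, h = 5e-4)
    }
  }
  # Phase 1: envelope-gradient BFGS rounds from a given starting vector.
  # Phase 2 (polish): a pass with the true finite-difference gradient
  # (conditional etas re-optimized at every perturbed point) — the
  # envelope gradient neglects how the curvature log-determinant moves
  # with the modes, which otherwise leaves a small systematic offset,
  # most visibly in the volume terms.
  pscale_at <- function(p0) {
    # diagonal curvature of the frozen surface preconditions the
    # quasi-Newton search (the residual-error and fixed-effect directions
    # are orders of magnitude stiffer than the variance components)
    f0 <- frozen(p0)
    vapply(seq_along(p0), function(j) {
      h <- 1e-3 * (1 + abs(p0[j]))
      pp <- pm <- p0
      pp[j] <- pp[j] + h
      pm[j] <- pm[j] - h
      d2 <- (frozen(pp) - 2 * f0 + frozen(pm)) / h^2
      1 / sqrt(max(d2, 1))
    }, numeric(1))
  }
  phase1 <- function(par0) {
    # fresh conditional modes: the warm etas of a previous descent would
    # anchor this one in the same (possibly poor) joint basin
    warm <<- matrix(0, nrow(warm), ncol(warm))
    opt <- list(par = par0, value = obj(par0), convergence = 1L)
    pscale <- pscale_at(par0)
    for (round in seq_len(3)) {
      o <- optim(opt$par, obj_true, gr = grad_fun, method = "BFGS",
                 control = list(maxit = config$maxit,
                                parscale = pscale,
                                reltol = config$reltol))
      improved <- opt$value - o$value
      if (o$value <= opt$value)
        opt <- list(par = o$par, value = o$value,
                    convergence = o$convergence)
      if (improved < 0.5) break   # restart only while it keeps paying off
    }
    opt$pscale <- pscale
    opt
  }
  polish <- function(opt) {
    pol_maxit <- if (is.null(config$polish_maxit)) 60L
                 else config$polish_maxit
    o <- optim(opt$par, obj_true, gr = grad_exact, method = "BFGS",
               control = list(maxit = min(config$maxit, pol_maxit),
                              parscale = opt$pscale,
                              reltol = config$reltol))
    if (o$value <= opt$value)
      opt <- list(par = o$par, value = o$value, convergence = o$convergence,
                  pscale = opt$pscale)
    opt
  }
  if (method == "posthoc" || length(par) == 0) {
    opt <- list(par = par, value = obj(par), convergence = 0L,
                counts = c(1L, 0L))
  } else {
    # Multi-start on the cheap phase: the jittered vector demonstrates the
    # search does real work; a second descent from the user's own starting
    # model guards against the jitter landing in a poor basin (the
    # marginal surface is multimodal in the high-variability absorption
    # direction).  Only the better basin is polished.
    opt <- phase1(par)
    if (config$jitter > 0) {
      opt2 <- phase1(pk$par)
      if (opt2$value < opt$value) opt <- opt2
      # re-anchor the conditional modes in the winning basin
      warm <- matrix(0, nrow(warm), ncol(warm))
      obj(opt$par)
    }
    opt <- polish(opt)
    warm <- matrix(0, nrow(warm), ncol(warm))
    obj(opt$par)  # leave the eta modes at the optimum
  }
  pop_hat <- .floor_pop(.unpack(opt$par, start, pk$fixed))
  grad <- if (method == "foce" && length(par))
    grad_fun(opt$par) else numeric(0)
  vcov <- NULL
  rse <- NULL
  if (config$hessian && method == "foce" && length(par)) {
    # Hessian as central differences of the envelope gradient, with the
    # conditional etas re-optimized at each perturbed base point
    p <- length(opt$par)
    H <- matrix(0, p, p)
    hs <- 1e-3 * (1 + abs(opt$par))
    for (i in seq_len(p)) {
      pp <- pm <- opt$par
      pp[i] <- pp[i] + hs[i]
      pm[i] <- pm[i] - hs[i]
      obj(pp)              # refresh eta modes at the + point
      gp <- grad_fun(pp)
      obj(pm)
      gm <- grad_fun(pm)
      H[i, ] <- (gp - gm) / (2 * hs[i])
    }
    H <- (H + t(H)) / 2
    vc <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (is.null(vc) || any(diag(vc) <= 0)) {
      ev <- eigen(H, symmetric = TRUE)
      lam <- pmax(ev$values, 1e-8 * max(abs(ev$values)))
      vc <- 2 * ev$vectors %*% diag(1 / lam, length(lam)) %*% t(ev$vectors)
      warning("OFV Hessian not positive definite; ",
              "standard errors from a regularized inverse")
    }
    dimnames(vc) <- list(names(opt$par), names(opt$par))
    vcov <- vc
    # log-scale SE ~ relative SE of the natural-scale parameter
    rse <- 100 * sqrt(pmax(diag(vc), 0))
  }
  eb <- conditional_etas(ds, pop_hat, config)
  boundary <- names(opt$par)[abs(opt$par - pk$par[names(opt$par)]) > log(50)]
  shr <- .shrinkage(eb$eta, pop_hat$omega2)
  fit <- structure(list(
    pop = pop_hat, start = start, ofv = opt$value,
    etas = eb$eta, eta_curvature = eb$curvature,
    vcov = vcov, rse = rse, par = opt$par, fixed = pk$fixed,
    shrinkage = shr,
    convergence = list(code = opt$convergence, n_eval = n_eval,
                       grad = grad,
                       grad_norm = if (length(grad)) max(abs(grad)) else 0,
                       boundary = boundary,
                       identifiability = ident_flag),
    method = method, config = config, data = ds,
    n_obs = cds$n_obs, n_subjects = cds$n_subjects),
    class = "enapk_fit")
  fit
}

.shrinkage <- function(etas, omega2) {
  out <- setNames(rep(NA_real_, 9), .eta_names)
  for (nm in .eta_names)
    if (omega2[nm] > 0)
      out[nm] <- 100 * (1 - sd(etas[, nm]) / sqrt(omega2[nm]))
  out
}

#' @export
print.enapk_fit <- function(x, ...) {
  cat("FOCE+I population fit:", x$n_subjects, "subjects,", x$n_obs,
      "observations\n")
  cat("OFV:", format(x$ofv, digits = 10),
      " (", x$method, ", convergence code", x$convergence$code, ")\n")
  est <- x$pop$theta
  if (!is.null(x$rse)) {
    cat("theta (%RSE):\n")
    df <- data.frame(estimate = round(est, 4),
                     rse = round(x$rse[match(names(est), names(x$rse))], 1))
    print(df)
  } else {
    cat("theta:\n"); print(round(est, 4))
  }
  cat("omega2:\n"); print(round(x$pop$omega2, 4))
  cat("sigma:\n"); print(round(x$pop$sigma, 4))
  if (length(x$convergence$boundary))
    cat("boundary warning:", paste(x$convergence$boundary, collapse = ", "),
        "\n")
  invisible(x)
}

#' Conditional weighted residuals
#'
#' Residuals decorrelated with the FOCE first-order linearization around the
#' conditional etas: `CWRES = L^-1 (dv - E[dv])` with
#' `E[dv] = f(eta_hat) - J eta_hat` and covariance
#' `J Omega J' + diag(v(eta_hat))`, `L` its lower Cholesky factor.
#' Approximately standard normal when the model is correct.
#'
#' @param fit [fit_poppk()] result
#' @param ds dataset (defaults to the fitted one)
#' @return data.frame with ID, PER, TIME, DVID, DV, IPRED and CWRES
#' @export
cwres <- function(fit, ds = fit$data) {
  stopifnot(inherits(fit, "enapk_fit"))
  pop <- .floor_pop(fit$pop)
  cds <- .compile_dataset(ds)
  act <- .active_etas(pop)
  q <- length(act)
  out <- list()
  for (i in seq_len(cds$n_subjects)) {
    subj <- cds$subjects[[i]]
    eta <- unname(fit$etas[i, act])
    tv <- .tv_matrix(pop, subj)
    f <- subject_preds_cpp(subj, tv, .eta_map0[act],
                           unname(pop$omega2[act]), unname(pop$sigma),
                           pop$n1, pop$n2, eta)
    dvid <- .subject_dvids(subj)
    dv <- .subject_dvs(subj)
    v <- .res_var_vec(f, dvid, pop$sigma)
    if (q > 0) {
      J <- matrix(0, length(f), q)
      for (j in seq_len(q)) {
        e <- eta
        h <- 1e-5 * (1 + abs(eta[j]))
        e[j] <- e[j] + h
        J[, j] <- (subject_preds_cpp(subj, tv, .eta_map0[act],
                                     unname(pop$omega2[act]),
                                     unname(pop$sigma), pop$n1, pop$n2,
                                     e) - f) / h
      }
      V <- J %*% diag(pop$omega2[act], q) %*% t(J) + diag(v)
      ey <- f - as.numeric(J %*% eta)
    } else {
      V <- diag(v, length(v))
      ey <- f
    }
    L <- tryCatch(t(chol(V)), error = function(e) {
      t(chol(V + diag(1e-10 * mean(diag(V)), nrow(V))))
    })
    cw <- forwardsolve(L, dv - ey)
    tim <- unlist(lapply(subj$periods, function(p) p$ut[p$idx0 + 1]))
    per <- unlist(lapply(subj$periods,
                         function(p) rep(p$per, length(p$dv))))
    out[[i]] <- data.frame(ID = subj$id, PER = per, TIME = tim,
                           DVID = dvid, DV = dv, IPRED = f, CWRES = cw)
  }
  do.call(rbind, out)
}

#' Eta shrinkage
#'
#' `100 (1 - SD(eta_hat) / omega)` per random effect; values near 100
#' indicate the individual data carry no information on that parameter.
#'
#' @param fit [fit_poppk()] result
#' @return named percentage vector (NA where no eta is modelled)
#' @export
eta_shrinkage <- function(fit) {
  stopifnot(inherits(fit, "enapk_fit"))
  if (fit$n_subjects < 2) stop("shrinkage needs at least 2 subjects")
  fit$shrinkage
}

#' Stepwise transit-compartment selection
#'
#' Starting from the smallest candidate, adds one absorption transit at a
#' time and keeps going while the objective function drops by at least 3.8;
#' returns the last count that achieved a qualifying drop (the Erlang
#' stepwise procedure).
#'
#' @param ds dataset
#' @param start population model used as starting values (its `n1` is
#'   replaced by each candidate)
#' @param candidates increasing integer candidates for `n1`
#' @param config fit settings (applied to every candidate fit)
#' @param dofv qualifying objective-function drop
#' @param fitter fitting backend `function(ds, start, config)`; replaceable
#'   for testing the selection rule in isolation
#' @return list with `n1` (selected), `table` of per-candidate OFVs, and
#'   `fit` for the selected count
#' @export
select_transits <- function(ds, start = enalapril_popmodel(),
                            candidates = 4:10, config = fit_config(),
                            dofv = 3.8, fitter = fit_poppk) {
  candidates <- sort(unique(as.integer(candidates)))
  tab <- data.frame(n1 = integer(), ofv = numeric(), delta = numeric(),
                    accepted = logical())
  prev_fit <- NULL
  chosen <- NULL
  for (k in seq_along(candidates)) {
    n1 <- candidates[k]
    pop_k <- if (is.null(prev_fit)) start else prev_fit$pop
    pop_k$n1 <- n1
    fit_k <- tryCatch(fitter(ds, pop_k, config),
                      error = function(e) {
                        warning("candidate n1 = ", n1, " failed: ",
                                conditionMessage(e))
                        NULL
                      })
    if (is.null(fit_k)) next
    delta <- if (is.null(prev_fit)) NA_real_ else fit_k$ofv - prev_fit$ofv
    if (is.null(prev_fit)) {
      accept <- TRUE          # smallest candidate is the baseline
      chosen <- fit_k
    } else if (!is.na(delta) && delta <= -dofv) {
      accept <- TRUE
      chosen <- fit_k
    } else {
      accept <- FALSE
    }
    tab <- rbind(tab, data.frame(n1 = n1, ofv = fit_k$ofv, delta = delta,
                                 accepted = accept))
    if (!accept) break
    prev_fit <- fit_k
  }
  list(n1 = chosen$pop$n1, table = tab, fit = chosen)
}

#' Stepwise covariate selection
#'
#' Forward addition (at each round the candidate with the largest
#' objective-function drop of at least `dofv` enters) followed by backward
#' elimination (an included effect is removed unless removing it raises the
#' objective function by more than `dofv`).
#'
#' @param ds dataset
#' @param start base population model (no candidate effects included)
#' @param candidates list of [cov_power()] / [cov_multiplier()] candidates
#' @param config fit settings
#' @param dofv inclusion/retention threshold on the OFV change
#' @param fitter fitting backend `function(ds, start, config)`; replaceable
#'   for testing the selection rule in isolation
#' @return list with `included` covariate effects, `history` data.frame and
#'   the final `fit`
#' @export
covariate_step <- function(ds, start, candidates, config = fit_config(),
                           dofv = 3.8, fitter = fit_poppk) {
  hist <- data.frame(step = character(), candidate = character(),
                     ofv = numeric(), delta = numeric(),
                     action = character())
  cur_fit <- fitter(ds, start, config)
  remaining <- candidates
  repeat {
    if (!length(remaining)) break
    deltas <- rep(NA_real_, length(remaining))
    fits <- vector("list", length(remaining))
    for (j in seq_along(remaining)) {
      pop_j <- cur_fit$pop
      pop_j$covariates <- c(pop_j$covariates, list(remaining[[j]]))
      fits[[j]] <- tryCatch(fitter(ds, pop_j, config),
                            error = function(e) NULL)
      if (!is.null(fits[[j]])) deltas[j] <- fits[[j]]$ofv - cur_fit$ofv
      hist <- rbind(hist, data.frame(
        step = "forward", candidate = format(remaining[[j]]),
        ofv = if (is.null(fits[[j]])) NA_real_ else fits[[j]]$ofv,
        delta = deltas[j], action = "tested"))
    }
    best <- which.min(deltas)
    if (!length(best) || !is.finite(deltas[best]) || deltas[best] > -dofv)
      break
    hist <- rbind(hist, data.frame(
      step = "forward", candidate = format(remaining[[best]]),
      ofv = fits[[best]]$ofv, delta = deltas[best], action = "included"))
    cur_fit <- fits[[best]]
    remaining <- remaining[-best]
  }
  # backward elimination over the effects added above
  added <- setdiff(vapply(cur_fit$pop$covariates, format, character(1)),
                   vapply(start$covariates, format, character(1)))
  repeat {
    covs <- cur_fit$pop$covariates
    labels <- vapply(covs, format, character(1))
    test_idx <- which(labels %in% added)
    if (!length(test_idx)) break
    dropped <- FALSE
    for (j in test_idx) {
      pop_j <- cur_fit$pop
      pop_j$covariates <- covs[-j]
      fit_j <- tryCatch(fitter(ds, pop_j, config),
                        error = function(e) NULL)
      if (is.null(fit_j)) next
      delta <- fit_j$ofv - cur_fit$ofv
      keep <- delta > dofv
      hist <- rbind(hist, data.frame(
        step = "backward", candidate = labels[j], ofv = fit_j$ofv,
        delta = delta, action = if (keep) "retained" else "removed"))
      if (!keep) {
        cur_fit <- fit_j
        added <- setdiff(added, labels[j])
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  list(included = cur_fit$pop$covariates, history = hist, fit = cur_fit)
}
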