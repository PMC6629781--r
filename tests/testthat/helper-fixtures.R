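# Shared fixtures, built once per test run.  All stochastic fixtures carry a
# fixed seed so every run sees the same data.

pooled_params <- function(n1 = 8L, n2 = 2L) {
  structural_params(ka = 6.010, vc = 51.10, f1 = 0.606, mtt1 = 0.558,
                    kren = 0.305, km = 0.688, vm = 46.10, kq1 = 0.060,
                    kq2 = 0.054, kme = 0.184, mtt2 = 0.910,
                    n1 = n1, n2 = n2)
}

.fixture_env <- new.env()

# memoised heavy fixtures
fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

small_trial <- function() {
  fixture("small_trial", function() {
    simulate_trial(trial_design(n_subjects = 6), enalapril_popmodel(),
                   seed = 101L)
  })
}

noiseless_subject <- function() {
  fixture("noiseless_subject", function() {
    pop <- enalapril_popmodel()
    pop$omega2[] <- 0
    pop$sigma[] <- 0
    simulate_trial(trial_design(n_subjects = 1), pop, seed = 5L)
  })
}

# tiny single-stream subject used by the toy-likelihood tests: one subject,
# parent serum only, coarse grid, no urine
toy_dataset <- function(n_times = 6, seed = 11L, sd_noise = 0.5) {
  set.seed(seed)
  p <- structural_params(ka = 1.2, vc = 40, f1 = 0.6, mtt1 = 0.5,
                         kren = 0.3, km = 0.7, vm = 45, kq1 = 0.06,
                         kq2 = 0.054, kme = 0.18, mtt2 = 0.9,
                         n1 = 1L, n2 = 0L)
  times <- seq(0.5, 8, length.out = n_times)
  pr <- predict_profile(p, 10000, times, 48)
  dv <- pr$serum$parent * exp(rnorm(n_times, 0, 0.1)) + rnorm(n_times, 0, sd_noise)
  dv <- pmax(dv, 0.01)
  df <- data.frame(
    ID = 1, PER = 1,
    TIME = c(0, times), EVID = c(1, rep(0, n_times)),
    AMT = c(10000, rep(NA, n_times)),
    DV = c(NA, dv), DVID = c(NA, rep(1, n_times)),
    FORM = 0, WT = 69.76, HT = 174.5, AGE = 28, SEX = "male")
  pk_dataset(df)
}

# population model for the toy dataset with a configurable set of etas
toy_popmodel <- function(etas = c(ka = 0.2)) {
  pop_model(
    theta = c(ka = 1.2, vc = 40, f1 = 0.6, mtt1 = 0.5, kren = 0.3,
              km = 0.7, vm = 45, kq1 = 0.06, kq2 = 0.054, kme = 0.18,
              mtt2 = 0.9),
    omega2 = etas,
    sigma = c(serum_parent_prop = 0.01, serum_parent_add = 0.5,
              serum_metab_prop = 0.01, serum_metab_add = 0.5,
              urine_parent_prop = 0.02, urine_metab_prop = 0.02),
    n1 = 1L, n2 = 0L, covariates = list())
}

# adaptive Gauss-Hermite -2 log marginal likelihood for 1 or 2 active etas;
# the independent quadrature oracle for the FOCE approximation
agh_ofv <- function(ds, pop, nodes = 64) {
  gh <- pracma::gaussHermite(nodes)
  act <- which(pop$omega2 > 0)
  q <- length(act)
  stopifnot(q %in% 1:2)
  ids <- unique(ds$ID)
  total <- 0
  for (id in ids) {
    ce <- conditional_etas(ds[ds$ID == id, ], pop)
    mode <- ce$eta[1, act]
    H <- ce$curvature[[1]]  # Hessian of the inner objective (of -2 log joint)
    Sg <- solve(H / 2)      # curvature of -log joint is H/2
    n_i <- sum(ds$EVID[ds$ID == id] == 0)
    # g(eta) = inner + (n_i + q) log(2 pi) = -2 log joint
    g <- function(eta) {
      ev <- setNames(numeric(length(act)), names(pop$omega2)[act])
      ev[] <- eta
      inner_objective(ds[ds$ID == id, ], pop, id, ev) +
        (n_i + q) * log(2 * pi)
    }
    L <- t(chol(Sg))
    if (q == 1) {
      s <- sqrt(2) * L[1, 1]
      vals <- vapply(gh$x, function(z) {
        exp(-0.5 * g(mode + s * z) + z^2)
      }, numeric(1))
      lik <- s * sum(gh$w * vals)
    } else {
      lik <- 0
      for (i in seq_len(nodes)) {
        for (j in seq_len(nodes)) {
          z <- c(gh$x[i], gh$x[j])
          eta <- mode + sqrt(2) * as.numeric(L %*% z)
          lik <- lik + 2 * gh$w[i] * gh$w[j] *
            exp(-0.5 * g(eta) + sum(z^2))
        }
      }
      lik <- lik * det(L)
    }
    total <- total - 2 * log(lik)
  }
  total
}
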