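test_that("rate matrix encodes the transit-chain topology", {
  p <- pooled_params()
  A <- build_rate_matrix(p)
  lay <- compartment_layout(8, 2)
  expect_equal(dim(A), c(16, 16))
  expect_equal(colnames(A), lay$names)

  ktr1 <- 9 / 0.558
  expect_equal(A["abs_transit1", "depot"], ktr1, tolerance = 1e-12)
  expect_equal(ktr1, 16.129, tolerance = 1e-4)  # 9 / 0.558
  for (k in 1:7)
    expect_equal(A[paste0("abs_transit", k + 1), paste0("abs_transit", k)],
                 ktr1)
  # the last transit empties into the central compartment at ka
  expect_equal(A["parent_central", "abs_transit8"], 6.010)
  expect_equal(A["parent_urine", "parent_central"], 0.305)
  expect_equal(A["met_transit1", "parent_central"], 0.688)
  ktr2 <- 3 / 0.910
  expect_equal(A["met_transit2", "met_transit1"], ktr2)
  expect_equal(A["metabolite_central", "met_transit2"], ktr2)
  expect_equal(A["metabolite_peripheral", "metabolite_central"], 0.060)
  expect_equal(A["metabolite_central", "metabolite_peripheral"], 0.054)
  expect_equal(A["metabolite_urine", "metabolite_central"], 0.184)

  # closed system: every column sums to zero (urine sinks included as
  # destinations), off-diagonals non-negative
  expect_true(all(abs(colSums(A)) < 1e-10))
  offdiag <- A; diag(offdiag) <- 0
  expect_true(all(offdiag >= 0))
  # urine sinks are absorbing
  expect_true(all(A[, "parent_urine"] == 0))
  expect_true(all(A[, "metabolite_urine"] == 0))
})

test_that("degenerate chain without transits connects depot to central", {
  p <- pooled_params(n1 = 0L, n2 = 0L)
  A <- build_rate_matrix(p)
  expect_equal(dim(A), c(6, 6))
  expect_equal(A["parent_central", "depot"], 6.010)
  expect_equal(A["metabolite_central", "parent_central"], 0.688)
})

test_that("invalid parameters are rejected", {
  expect_error(structural_params(-1, 51, 0.6, 0.5, 0.3, 0.7, 46, 0.06,
                                 0.054, 0.18, 0.9), "positive")
  expect_warning(structural_params(6, 51, 1.2, 0.5, 0.3, 0.7, 46, 0.06,
                                   0.054, 0.18, 0.9), "f1")
  p <- pooled_params()
  expect_error(solve_amounts(p, 10000, c(2, 1)), "sorted")
  expect_error(solve_amounts(p, -5, 1), "positive")
})

test_that("amounts conserve mass and drain into the urine sinks", {
  p <- pooled_params()
  am <- solve_amounts(p, 10000, c(0, 0.5, 1, 2, 6, 24, 48, 500))
  # t = 0 with dose at 0: bioavailable fraction sits in the depot
  expect_equal(unname(am[1, "depot"]), 0.606 * 10000)
  expect_true(all(am[1, -1] == 0))
  # conservation at every time
  expect_true(all(abs(rowSums(am) - 6060) < 1e-9 * 6060))
  # absorbing sinks capture everything eventually
  expect_equal(unname(am[8, "parent_urine"] + am[8, "metabolite_urine"]),
               6060, tolerance = 1e-6)
  expect_true(all(am >= -1e-9))
  # cumulative urine is non-decreasing
  expect_true(all(diff(am[, "parent_urine"]) >= -1e-9))
  expect_true(all(diff(am[, "metabolite_urine"]) >= -1e-9))
})

test_that("matrix-exponential solution matches ODE and expm oracles", {
  skip_if_not_installed("deSolve")
  skip_if_not_installed("Matrix")
  p <- pooled_params()
  A <- build_rate_matrix(p)
  times <- c(0.25, 1, 4, 24)
  am <- solve_amounts(p, 10000, times)
  y0 <- setNames(numeric(16), colnames(A))
  y0["depot"] <- 6060
  ode <- deSolve::ode(y0, c(0, times),
                      function(t, y, .) list(as.numeric(A %*% y)), NULL,
                      rtol = 1e-10, atol = 1e-8)
  for (k in seq_along(times)) {
    expect_equal(am[k, ], ode[k + 1, -1], tolerance = 1e-8)
  }
  em <- as.numeric(Matrix::expm(A * 1) %*% y0)
  expect_equal(unname(am[2, ]), em, tolerance = 1e-8)

  # 20 random parameter draws against the stiff integrator
  set.seed(99)
  for (r in 1:20) {
    pr <- structural_params(
      ka = runif(1, 1, 12), vc = runif(1, 20, 80), f1 = runif(1, 0.3, 0.9),
      mtt1 = runif(1, 0.2, 1.5), kren = runif(1, 0.1, 0.6),
      km = runif(1, 0.2, 1.2), vm = runif(1, 20, 80),
      kq1 = runif(1, 0.02, 0.2), kq2 = runif(1, 0.02, 0.2),
      kme = runif(1, 0.05, 0.5), mtt2 = runif(1, 0.3, 2),
      n1 = sample(0:9, 1), n2 = sample(0:3, 1))
    Ar <- build_rate_matrix(pr)
    amr <- solve_amounts(pr, 10000, c(1, 12))
    y0r <- setNames(numeric(ncol(Ar)), colnames(Ar))
    y0r["depot"] <- pr$theta[["f1"]] * 10000
    oder <- deSolve::ode(y0r, c(0, 1, 12),
                         function(t, y, .) list(as.numeric(Ar %*% y)), NULL,
                         rtol = 1e-11, atol = 1e-9)
    expect_equal(unname(amr[1, ]), unname(oder[2, -1]), tolerance = 1e-6)
    expect_equal(unname(amr[2, ]), unname(oder[3, -1]), tolerance = 1e-6)
  }
})

test_that("chain flux reduces to the Erlang density when ka equals ktr1", {
  n1 <- 5L
  mtt1 <- 0.6
  ktr1 <- (n1 + 1) / mtt1
  p <- structural_params(ka = ktr1, vc = 50, f1 = 0.7, mtt1 = mtt1,
                         kren = 1e-8, km = 1e-8, vm = 45, kq1 = 0.06,
                         kq2 = 0.054, kme = 0.18, mtt2 = 0.9, n1 = n1)
  # with (near-)zero elimination the rate of change of the central amount
  # equals the input flux f1 * D * Erlang(n1 + 1, ktr1)
  tt <- seq(0.05, 3, by = 0.05)
  h <- 1e-4
  am_lo <- solve_amounts(p, 10000, tt - h)[, "parent_central"]
  am_hi <- solve_amounts(p, 10000, tt + h)[, "parent_central"]
  flux <- (am_hi - am_lo) / (2 * h)
  erlang <- 0.7 * 10000 * dgamma(tt, shape = n1 + 1, rate = ktr1)
  expect_equal(flux, erlang, tolerance = 1e-5)
})

test_that("profiles show the documented shape at the pooled estimates", {
  p <- pooled_params()
  grid <- seq(0.05, 12, by = 0.05)
  pr <- predict_profile(p, 10000, grid, c(2, 4, 8, 12, 24, 36, 48))
  tmax_p <- grid[which.max(pr$serum$parent)]
  tmax_m <- grid[which.max(pr$serum$metabolite)]
  expect_gte(tmax_p, 0.75)
  expect_lte(tmax_p, 1.5)
  expect_gte(tmax_m, 3)
  expect_lte(tmax_m, 4)
  # single dose: parent serum profile is unimodal
  d <- diff(pr$serum$parent)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)
  # cumulative urine non-decreasing
  expect_true(all(diff(pr$urine$parent_cum) >= 0))
  expect_true(all(diff(pr$urine$metabolite_cum) >= 0))
  # doubling vc exactly halves parent serum concentrations
  p2 <- pooled_params()
  p2$theta[["vc"]] <- 2 * 51.10
  pr2 <- predict_profile(p2, 10000, grid, 48)
  expect_equal(pr2$serum$parent, pr$serum$parent / 2, tolerance = 1e-12)
})

test_that("metabolite terminal slope equals the slow disposition eigenvalue", {
  p <- pooled_params()
  # metabolite disposition sub-matrix (central/peripheral with elimination)
  M <- matrix(c(-(0.184 + 0.060), 0.054,
                0.060, -0.054), 2, 2, byrow = TRUE)
  lam_slow <- max(eigen(M)$values)
  tt <- c(150, 170)
  cm <- solve_amounts(p, 10000, tt)[, "metabolite_central"]
  slope <- diff(log(cm)) / diff(tt)
  expect_equal(slope, lam_slow, tolerance = 1e-4)
})

test_that("multiple doses superpose linearly", {
  p <- pooled_params()
  doses <- data.frame(time = c(0, 12), amount = c(10000, 10000))
  am2 <- solve_amounts(p, doses, c(13, 24))
  one <- solve_amounts(p, 10000, c(13, 24))
  shifted <- solve_amounts(p, 10000, c(1, 12))
  expect_equal(am2[1, ], one[1, ] + shifted[1, ], tolerance = 1e-9)
  expect_equal(am2[2, ], one[2, ] + shifted[2, ], tolerance = 1e-9)
})
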