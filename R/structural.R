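#' @useDynLib enapopk, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnorm median optim pnorm qnorm quantile rbinom rnorm
#'   runif sd setNames uniroot wilcox.test
#' @importFrom utils read.csv write.csv
"_PACKAGE"

# internal ordering of the 11 structural parameters (kept in step with src/)
.param_names <- c("ka", "vc", "f1", "mtt1", "kren", "km", "vm",
                  "kq1", "kq2", "kme", "mtt2")
# parameters carrying a between-subject eta (no eta on kq1/kq2)
.eta_names <- c("ka", "vc", "f1", "mtt1", "kren", "km", "vm", "kme", "mtt2")
.eta_map0 <- c(0L, 1L, 2L, 3L, 4L, 5L, 6L, 9L, 10L)
.sigma_names <- c("serum_parent_prop", "serum_parent_add",
                  "serum_metab_prop", "serum_metab_add",
                  "urine_parent_prop", "urine_metab_prop")
.stream_names <- c("serum_parent", "serum_metab", "urine_parent", "urine_metab")

#' Structural pharmacokinetic parameters for one subject-occasion
#'
#' Deterministic kinetics of the prodrug (enalapril) and its active
#' metabolite (enalaprilat): an oral depot feeding `n1` absorption transit
#' compartments (Erlang delay), a one-compartment parent with dual
#' first-order elimination (renal `kren`, metabolic `km`), `n2` metabolite
#' formation transits, a two-compartment metabolite (central/peripheral,
#' rates `kq1`/`kq2`) with renal elimination `kme`, and two absorbing urine
#' sinks.  The fraction `f1` of each dose reaches the depot; the remainder
#' is lost pre-systemically and never enters the system.
#'
#' The chain rate constants are derived from the mean transit times as
#' `ktr1 = (n1 + 1) / mtt1` and `ktr2 = (n2 + 1) / mtt2`; the last absorption
#' transit empties into the parent central compartment at `ka`.
#'
#' @param ka first-order absorption rate from the last transit (1/h)
#' @param vc parent central volume of distribution (L)
#' @param f1 absorbed (bioavailable) fraction
#' @param mtt1 mean transit time of absorption (h)
#' @param kren parent renal elimination rate (1/h)
#' @param km metabolite formation rate (1/h)
#' @param vm metabolite central volume (L)
#' @param kq1,kq2 metabolite central to peripheral and back rates (1/h)
#' @param kme metabolite renal elimination rate (1/h)
#' @param mtt2 mean transit time of metabolite formation (h)
#' @param n1,n2 number of absorption / metabolite-formation transit
#'   compartments (non-negative integers)
#' @return an object of class `enapk_params`
#' @export
structural_params <- function(ka, vc, f1, mtt1, kren, km, vm,
                              kq1, kq2, kme, mtt2, n1 = 8L, n2 = 2L) {
  p <- c(ka = ka, vc = vc, f1 = f1, mtt1 = mtt1, kren = kren, km = km,
         vm = vm, kq1 = kq1, kq2 = kq2, kme = kme, mtt2 = mtt2)
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all structural parameters must be finite and strictly positive")
  if (f1 > 1)
    warning("f1 > 1: individual bioavailability above 1 ",
            "(possible under the exponential BSV model)")
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 0 || n2 < 0) stop("transit counts must be non-negative integers")
  structure(list(theta = p, n1 = n1, n2 = n2), class = "enapk_params")
}

#' @export
print.enapk_params <- function(x, ...) {
  cat("Structural PK parameters (", x$n1, "absorption /", x$n2,
      "formation transits)\n")
  print(round(x$theta, 4))
  cat("derived: ktr1 =", round((x$n1 + 1) / x$theta[["mtt1"]], 4),
      "1/h, ktr2 =", round((x$n2 + 1) / x$theta[["mtt2"]], 4), "1/h\n")
  invisible(x)
}

#' Compartment layout of the structural model
#'
#' Ordered compartment names: depot, absorption transits, parent central,
#' parent urine, metabolite transits, metabolite central, metabolite
#' peripheral, metabolite urine (dimension `n1 + n2 + 6`).
#'
#' @param n1,n2 transit counts
#' @return list with `names`, `dim`, and the index of each named compartment
#' @export
compartment_layout <- function(n1 = 8L, n2 = 2L) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  nm <- c("depot",
          if (n1 > 0) paste0("abs_transit", seq_len(n1)),
          "parent_central", "parent_urine",
          if (n2 > 0) paste0("met_transit", seq_len(n2)),
          "metabolite_central", "metabolite_peripheral", "metabolite_urine")
  # solver order: depot, transits, pc, met transits, mc, mp, pu, mu
  solver <- c(seq_len(n1 + 2L),            # depot .. parent_central
              n1 + n2 + 5L,                # parent_urine (solver pos)
              if (n2 > 0) (n1 + 3L):(n1 + n2 + 2L),
              n1 + n2 + 3L, n1 + n2 + 4L,  # met central, peripheral
              n1 + n2 + 6L)                # met urine
  list(names = nm, dim = n1 + n2 + 6L, solver_index = solver,
       n1 = n1, n2 = n2)
}

.check_params <- function(params) {
  if (!inherits(params, "enapk_params"))
    stop("`params` must be created by structural_params()")
  params
}

#' First-order rate matrix of the structural model
#'
#' Square matrix `A` with `d(amounts)/dt = A %*% amounts` over
#' [compartment_layout()]; off-diagonals are non-negative transfer rates and
#' each column sums to zero except the urine sinks (absorbing, zero outflow).
#'
#' @param params [structural_params()] object
#' @return rate matrix (1/h) with compartment dimnames
#' @export
build_rate_matrix <- function(params) {
  .check_params(params)
  lay <- compartment_layout(params$n1, params$n2)
  A <- rate_matrix_cpp(params$theta, params$n1, params$n2)
  A <- A[lay$solver_index, lay$solver_index, drop = FALSE]
  dimnames(A) <- list(lay$names, lay$names)
  A
}

.as_dose <- function(dose) {
  if (is.numeric(dose) && is.null(dim(dose))) {
    if (!is.null(names(dose)) && all(c("time", "amount") %in% names(dose)))
      dose <- data.frame(time = dose[["time"]], amount = dose[["amount"]])
    else
      dose <- data.frame(time = 0, amount = as.numeric(dose))
  }
  dose <- as.data.frame(dose)
  if (!all(c("time", "amount") %in% names(dose)))
    stop("dose must have `time` and `amount`")
  if (any(dose$amount <= 0) || any(dose$time < 0))
    stop("dose amounts must be positive and times non-negative")
  dose[order(dose$time), , drop = FALSE]
}

#' Compartment amounts over time
#'
#' Solves the linear constant-coefficient system by matrix exponential
#' (uniformization) for one or more oral doses.  At each dose time the
#' bioavailable fraction `f1 * amount` enters the depot; total system mass
#' is conserved thereafter.
#'
#' @param params [structural_params()] object
#' @param dose a single dose amount in micrograms (given at t = 0), or a
#'   data.frame with `time` (h) and `amount` (ug) columns
#' @param times sorted non-negative observation times (h)
#' @return matrix `length(times)` x `n1 + n2 + 6` of amounts (ug), columns
#'   named per [compartment_layout()]
#' @export
solve_amounts <- function(params, dose, times) {
  .check_params(params)
  dose <- .as_dose(dose)
  times <- as.numeric(times)
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times))
    stop("`times` must be sorted, finite and non-negative")
  lay <- compartment_layout(params$n1, params$n2)
  am <- solve_amounts_cpp(params$theta, params$n1, params$n2,
                          dose$time, dose$amount, times)
  out <- t(am[lay$solver_index, , drop = FALSE])
  dimnames(out) <- list(NULL, lay$names)
  attr(out, "times") <- times
  out
}

#' Predicted observation profiles
#'
#' Serum concentrations (amount / volume, ug/L) for parent and metabolite at
#' the serum sampling times, and cumulative-since-dose urine amounts (ug) at
#' the urine collection-interval ends.
#'
#' @inheritParams solve_amounts
#' @param serum_times serum sampling times (h)
#' @param urine_times urine collection interval ends (h)
#' @return list of class `enapk_profile` with `serum` (time, parent,
#'   metabolite) and `urine` (time, parent_cum, metabolite_cum) data frames
#' @export
predict_profile <- function(params, dose, serum_times, urine_times) {
  .check_params(params)
  ut <- sort(unique(c(serum_times, urine_times)))
  am <- solve_amounts(params, dose, ut)
  si <- match(serum_times, ut)
  ui <- match(urine_times, ut)
  out <- list(
    serum = data.frame(
      time = serum_times,
      parent = am[si, "parent_central"] / params$theta[["vc"]],
      metabolite = am[si, "metabolite_central"] / params$theta[["vm"]]),
    urine = data.frame(
      time = urine_times,
      # the exact cumulative amounts are non-decreasing; cummax removes the
      # ~1e-12 relative wiggle left by series truncation
      parent_cum = cummax(pmax(am[ui, "parent_urine"], 0)),
      metabolite_cum = cummax(pmax(am[ui, "metabolite_urine"], 0))))
  class(out) <- c("enapk_profile", class(out))
  out
}
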