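#' Renal clearances from rate constants
#'
#' Converts the parent and metabolite renal elimination rate constants to
#' clearances: `clren = kren * vc` (enalapril) and `clent = kme * vm`
#' (enalaprilat), in L/h.
#'
#' @param params [structural_params()] object or named vector containing
#'   kren, vc, kme and vm
#' @return named vector `c(clren, clent)`
#' @export
to_clearances <- function(params) {
  p <- if (inherits(params, "enapk_params")) params$theta else params
  c(clren = unname(p[["kren"]] * p[["vc"]]),
    clent = unname(p[["kme"]] * p[["vm"]]))
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Classical convention: zero differences are dropped; the exact signed-rank
#' null distribution is used for up to 25 informative untied pairs and the
#' tie-corrected normal approximation otherwise.  When every difference is
#' zero the test is degenerate and `p = 1` is returned with a flag.
#'
#' @param x,y equal-length paired measurement vectors
#' @return two-sided p-value with attributes `n_informative`, `statistic`
#'   and `degenerate`
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  d <- d[!is.na(d)]
  informative <- d[d != 0]
  if (!length(informative))
    return(structure(1.0, n_informative = 0L, statistic = NA_real_,
                     degenerate = TRUE))
  ties <- any(duplicated(abs(informative)))
  exact <- length(informative) <= 25 && !ties
  wt <- suppressWarnings(
    wilcox.test(informative, exact = exact, correct = !exact))
  structure(unname(min(wt$p.value, 1)),
            n_informative = length(informative),
            statistic = unname(wt$statistic), degenerate = FALSE)
}

#' Individual post-hoc parameters
#'
#' Empirical-Bayes individual parameter values: covariate-adjusted typical
#' values times `exp(eta_hat)`, plus the derived renal clearances of parent
#' and metabolite.  Covariates are taken from each subject's first period of
#' the fitted dataset (use [split_by_formulation()] to fit each formulation
#' separately before comparing).
#'
#' @param fit [fit_poppk()] result
#' @return data.frame with one row per subject: ID, the 11 structural
#'   parameters, clren, clent
#' @export
posthoc_params <- function(fit) {
  stopifnot(inherits(fit, "enapk_fit"))
  pop <- fit$pop
  cds <- .compile_dataset(fit$data)
  rows <- lapply(seq_len(cds$n_subjects), function(i) {
    subj <- cds$subjects[[i]]
    tv <- typical_values(pop, subj$periods[[1]]$covs)
    p <- tv
    p[.eta_names] <- p[.eta_names] * exp(fit$etas[i, ])
    cl <- to_clearances(p)
    data.frame(ID = subj$id, t(p), clren = cl[["clren"]],
               clent = cl[["clent"]])
  })
  do.call(rbind, rows)
}

#' Crossover comparison of two formulations
#'
#' Paired Wilcoxon signed-rank tests on the individual post-hoc parameters
#' of the same subjects fitted separately under the reference and the
#' orodispersible mini-tablet formulation: absorption (ka, mtt1, f1),
#' disposition (vc, km, vm, mtt2) and the renal clearances of parent
#' (clren) and metabolite (clent).  No multiplicity correction is applied
#' across the nine tests.
#'
#' @param fit_ref fit of the reference-formulation data
#' @param fit_odmt fit of the mini-tablet data (same subjects)
#' @param alpha significance level
#' @return data.frame of class `enapk_comparison`: parameter, p-value,
#'   significance flag, degenerate flag
#' @export
compare_formulations <- function(fit_ref, fit_odmt, alpha = 0.05) {
  pr <- posthoc_params(fit_ref)
  po <- posthoc_params(fit_odmt)
  if (!identical(sort(pr$ID), sort(po$ID)))
    stop("the two fits cover different subjects")
  po <- po[match(pr$ID, po$ID), ]
  pars <- c("ka", "vc", "f1", "clren", "mtt1", "km", "vm", "mtt2", "clent")
  rows <- lapply(pars, function(nm) {
    p <- paired_wilcoxon(po[[nm]], pr[[nm]])
    data.frame(parameter = nm, p_value = as.numeric(p),
               significant = as.numeric(p) < alpha,
               degenerate = attr(p, "degenerate"))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("enapk_comparison", "data.frame")
  out
}
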