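#' Event-stream pharmacokinetic dataset
#'
#' Long-format, NONMEM-style dataset: one row per dose (`EVID = 1`, `AMT` in
#' ug) or observation (`EVID = 0`, `DV`).  Observation streams are coded by
#' `DVID`: 1 serum parent (ug/L), 2 serum metabolite (ug/L), 3 cumulative
#' urine parent (ug), 4 cumulative urine metabolite (ug).  `FORM` flags the
#' formulation of each crossover period (0 reference tablet, 1
#' orodispersible mini-tablet) and the biometric covariates `WT` (kg), `HT`
#' (cm), `AGE` (yr) and `SEX` (`"male"`/`"female"`) are carried per row.
#'
#' @param df data.frame with columns ID, PER, TIME, EVID, AMT, DV, DVID,
#'   FORM, WT, HT, AGE, SEX
#' @return validated data.frame of class `enapk_dataset`, rows sorted by
#'   subject, period, time
#' @export
pk_dataset <- function(df) {
  req <- c("ID", "PER", "TIME", "EVID", "AMT", "DV", "DVID", "FORM",
           "WT", "HT", "AGE", "SEX")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df)[, req]
  for (cl in setdiff(req, "SEX")) {
    x <- df[[cl]]
    if (!is.numeric(x)) {
      xn <- suppressWarnings(as.numeric(as.character(x)))
      bad <- which(!is.na(as.character(x)) & x != "." & is.na(xn))
      if (length(bad))
        stop("non-numeric value in column ", cl, " at row ", bad[1])
      df[[cl]] <- xn
    }
  }
  df$SEX <- as.character(df$SEX)
  if (!all(df$SEX %in% c("male", "female")))
    stop("SEX must be \"male\" or \"female\"")
  if (!all(df$EVID %in% c(0, 1))) stop("EVID must be 0 or 1")
  dose <- df$EVID == 1
  if (any(is.na(df$AMT[dose])) || any(df$AMT[dose] <= 0))
    stop("dose rows must have AMT > 0")
  if (any(!is.na(df$DV[dose])))
    stop("dose rows must not carry a DV")
  obs <- !dose
  if (any(is.na(df$DV[obs]))) {
    n0 <- sum(is.na(df$DV[obs]))
    message("dropping ", n0, " observation row(s) with missing DV")
    df <- df[dose | !is.na(df$DV), ]
    obs <- df$EVID == 0
  }
  if (any(df$DV[obs] < 0)) stop("observed DV must be non-negative")
  if (!all(df$DVID[obs] %in% 1:4)) stop("DVID must be 1, 2, 3 or 4")
  if (any(df$TIME < 0)) stop("TIME must be non-negative")
  key <- interaction(df$ID, df$PER, drop = TRUE)
  ndose <- tapply(df$EVID, key, sum)
  if (any(ndose == 0)) stop("every subject-period needs a dose row")
  if (any(ndose > 1)) stop("duplicate dose rows in subject-period: ",
                           names(ndose)[which(ndose > 1)[1]])
  df <- df[order(df$ID, df$PER, df$TIME, df$EVID, df$DVID), ]
  rownames(df) <- NULL
  class(df) <- c("enapk_dataset", "data.frame")
  df
}

#' Read a NONMEM-style CSV dataset
#'
#' @param path CSV file path
#' @param sep field separator
#' @param na missing-value token
#' @return [pk_dataset()] object
#' @export
read_pk_dataset <- function(path, sep = ",", na = ".") {
  df <- utils::read.csv(path, sep = sep, na.strings = na,
                        stringsAsFactors = FALSE)
  pk_dataset(df)
}

#' Write a dataset as NONMEM-style CSV
#'
#' Numeric fields are formatted to 6 significant digits, so a write-read
#' cycle is idempotent.
#'
#' @param ds [pk_dataset()] object
#' @param path output path
#' @param na missing-value token
#' @return `path`, invisibly
#' @export
write_pk_dataset <- function(ds, path, na = ".") {
  out <- as.data.frame(ds)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.csv(out, path, row.names = FALSE, na = na, quote = FALSE)
  invisible(path)
}

#' Default assay lower limits of quantification
#'
#' Serum LLOQs (ug/L) for parent and metabolite; urine censoring is off by
#' default because the urine assay limits are concentrations while the model
#' works on cumulative amounts (converting would require urine volumes).
#'
#' @return named vector of per-stream limits
#' @export
default_lloq <- function() {
  c(serum_parent = 0.195, serum_metab = 0.180,
    urine_parent = 0, urine_metab = 0)
}

#' Exclude observations below the limit of quantification
#'
#' Removes observation rows whose DV is strictly below the stream's LLOQ
#' (values exactly at the limit are retained); dose rows are never touched.
#' Removal counts per stream are attached as attribute `"lloq_removed"`.
#'
#' @param ds [pk_dataset()] object
#' @param limits named per-stream limits as in [default_lloq()]
#' @param quiet suppress the per-stream removal message
#' @return filtered dataset
#' @export
apply_lloq <- function(ds, limits = default_lloq(), quiet = FALSE) {
  stopifnot(inherits(ds, "enapk_dataset"))
  if (any(limits < 0)) stop("LLOQ limits must be non-negative")
  lim <- setNames(numeric(4), .stream_names)
  lim[names(limits)] <- limits
  drop <- ds$EVID == 0 & ds$DV < lim[ds$DVID]
  removed <- tapply(drop[ds$EVID == 0],
                    factor(.stream_names[ds$DVID[ds$EVID == 0]],
                           levels = .stream_names), sum)
  removed[is.na(removed)] <- 0
  if (!quiet && any(drop))
    message("LLOQ exclusion removed ", sum(drop), " row(s): ",
            paste(names(removed), removed, sep = "=", collapse = ", "))
  out <- ds[!drop, ]
  rownames(out) <- NULL
  class(out) <- class(ds)
  attr(out, "lloq_removed") <- removed
  attr(out, "truth") <- attr(ds, "truth")
  out
}

# ---- internal compiled form used by the estimation engine ------------------

# Per subject: per period, unique sorted times, 0-based index of each
# observation into that grid, dvid/dv vectors, dose events, covariates.
.compile_dataset <- function(ds) {
  stopifnot(inherits(ds, "enapk_dataset"))
  subjects <- list()
  for (id in unique(ds$ID)) {
    di <- ds[ds$ID == id, ]
    pers <- sort(unique(di$PER))
    periods <- list()
    covs <- list()
    for (k in seq_along(pers)) {
      dp <- di[di$PER == pers[k], ]
      dose <- dp[dp$EVID == 1, ]
      obs <- dp[dp$EVID == 0, ]
      ut <- sort(unique(obs$TIME))
      sex <- dp$SEX[1]
      pc <- list(WT = dp$WT[1], HT = dp$HT[1], AGE = dp$AGE[1], SEX = sex,
                 TBW = watson_tbw(dp$WT[1], dp$HT[1], dp$AGE[1], sex),
                 FORM = dp$FORM[1])
      periods[[k]] <- list(
        per = pers[k],
        ut = ut,
        idx0 = as.integer(match(obs$TIME, ut) - 1L),
        dvid = as.integer(obs$DVID),
        dv = obs$DV,
        dose_t = dose$TIME,
        dose_a = dose$AMT,
        covs = pc)
      covs[[k]] <- pc
    }
    subjects[[length(subjects) + 1L]] <-
      list(id = id, periods = periods, covs = covs)
  }
  list(subjects = subjects,
       n_subjects = length(subjects),
       n_obs = sum(ds$EVID == 0))
}

# 11 x nper matrix of covariate-adjusted typical values for one compiled
# subject under a population model with structural theta overridden by
# `theta` (used inside the fit where theta moves)
.tv_matrix <- function(pop, subj) {
  nper <- length(subj$periods)
  tv <- matrix(0, 11, nper)
  for (j in seq_len(nper))
    tv[, j] <- typical_values(pop, subj$periods[[j]]$covs)
  tv
}
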