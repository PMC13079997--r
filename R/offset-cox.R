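# Sex-stratified Cox augmentations of SCORE2: added covariates are fit with
# the SCORE2 linear predictor entering as a fixed offset (coefficient 1),
# per sex, after within-sex standardization of the covariates, so hazard
# ratios are per SD in the fitting cohort.

# analytes conventionally log-transformed before standardization
default_log_transform <- c("crp", "ggt", "ast", "lpa", "alp")

#' Fit a Cox augmentation of SCORE2
#'
#' For each sex separately, fits a Cox proportional-hazards model for
#' 10-year CVD with the supplied covariates as independent variables and a
#' fixed per-participant offset (normally the SCORE2 linear predictor) in
#' the linear predictor with coefficient 1. Covariates are standardized to
#' mean 0, SD 1 within the fitting cohort per sex before fitting, so
#' `exp(beta)` is the hazard ratio per SD. Skewed analytes can be
#' natural-log transformed before standardization.
#'
#' Rows with missing covariate values are dropped (complete-case per
#' model); events after `max_time` are administratively censored.
#'
#' @param cohort Cohort data frame with `sex`, `time`, `event` and the
#'   covariate columns.
#' @param covariates Character vector of covariate column names.
#' @param offset Per-row numeric offset on the log-hazard scale.
#' @param max_time Follow-up truncation horizon (years).
#' @param log_transform Covariates to log before standardization; defaults
#'   to the conventional skewed analytes present in `covariates`.
#' @return An object of class `offset_cox_fit`: covariate names, transform
#'   set, and per-sex estimates (`beta`, `se`), standardization constants
#'   (`center`, `scale`), `n` and `n_events`.
#' @export
fit_offset_cox <- function(cohort, covariates, offset, max_time = 10,
                           log_transform = intersect(covariates,
                                                     default_log_transform)) {
  stopifnot(length(offset) == nrow(cohort))
  missing_cols <- setdiff(covariates, names(cohort))
  if (length(missing_cols))
    stop("unknown covariates: ", paste(missing_cols, collapse = ", "))
  tr <- truncate_followup(cohort$time, cohort$event, max_time)
  fit <- list(covariates = covariates, log_transform = log_transform,
              offset = "user-supplied linear predictor", max_time = max_time,
              cohort_label = unique(stats::na.omit(cohort$cohort_label)),
              by_sex = list())
  for (sx in c("male", "female")) {
    i <- which(cohort$sex == sx)
    X <- as.matrix(cohort[i, covariates, drop = FALSE])
    cc <- stats::complete.cases(X)
    i <- i[cc]; X <- X[cc, , drop = FALSE]
    if (sum(tr$event[i]) == 0)
      stop("no events in stratum '", sx, "'")
    for (v in log_transform) X[, v] <- log(X[, v])
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    if (any(scl <= 0))
      stop("constant covariate in stratum '", sx, "': ",
           paste(covariates[scl <= 0], collapse = ", "))
    Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    d <- data.frame(time = tr$time[i], event = tr$event[i], off = offset[i])
    d <- cbind(d, as.data.frame(Z))
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(sprintf("`%s`", covariates), collapse = " + "),
      "+ offset(off)"))
    cx <- survival::coxph(fml, data = d)
    if (!is.null(cx$info) && isTRUE(cx$info$flag > 0))
      stop("Cox fit did not converge in stratum '", sx, "'")
    fit$by_sex[[sx]] <- list(
      beta = stats::setNames(as.numeric(stats::coef(cx)), covariates),
      se = stats::setNames(sqrt(diag(stats::vcov(cx))), covariates),
      center = ctr, scale = scl,
      n = length(i), n_events = sum(tr$event[i]),
      iterations = cx$iter)
  }
  structure(fit, class = "offset_cox_fit")
}

#' @export
print.offset_cox_fit <- function(x, ...) {
  cat("Cox augmentation with fixed offset (", length(x$covariates),
      " covariates)\n", sep = "")
  for (sx in names(x$by_sex)) {
    b <- x$by_sex[[sx]]
    cat(sprintf("  %s: n = %d, events = %d\n", sx, b$n, b$n_events))
    tab <- data.frame(beta = b$beta, se = b$se,
                      HR_per_SD = exp(b$beta), row.names = x$covariates)
    print(round(tab, 4))
  }
  invisible(x)
}

#' Linear predictor of a fitted augmentation
#'
#' Computes `offset + sum_j beta[sex, j] * (x_j - center_j) / scale_j`
#' using the fitting cohort's per-sex standardization constants (and log
#' transforms), so models fit in a discovery cohort can be predicted in a
#' replication cohort.
#'
#' @param fit An [fit_offset_cox()] object.
#' @param cohort Cohort data frame containing the model covariates.
#' @param offset Per-row offset (same scale as used at fitting).
#' @return Numeric linear predictor per row; rows with missing covariates
#'   get `NA`.
#' @export
predict_linear_predictor <- function(fit, cohort, offset) {
  stopifnot(inherits(fit, "offset_cox_fit"),
            length(offset) == nrow(cohort))
  missing_cols <- setdiff(fit$covariates, names(cohort))
  if (length(missing_cols))
    stop("unknown covariates: ", paste(missing_cols, collapse = ", "))
  lp <- rep(NA_real_, nrow(cohort))
  for (sx in names(fit$by_sex)) {
    i <- which(cohort$sex == sx)
    if (!length(i)) next
    b <- fit$by_sex[[sx]]
    X <- as.matrix(cohort[i, fit$covariates, drop = FALSE])
    for (v in fit$log_transform) X[, v] <- log(X[, v])
    Z <- sweep(sweep(X, 2, b$center), 2, b$scale, "/")
    lp[i] <- offset[i] + drop(Z %*% b$beta)
  }
  lp
}

#' Absolute 10-year risk of an augmented model
#'
#' Extends the SCORE2 linear predictor with the fitted augmentation term,
#' mean-centered within the evaluation cohort per sex (so the augmentation
#' reshuffles ranking without shifting the average risk scale), then maps
#' through the SCORE2 risk transform.
#'
#' @param fit An [fit_offset_cox()] object.
#' @param cohort Evaluation cohort.
#' @param coefs SCORE2 coefficients.
#' @param lp_score2 Optional precomputed SCORE2 linear predictor.
#' @param calibrated Apply region calibration in the risk transform.
#' @return Data frame with columns `lp` (extended linear predictor) and
#'   `risk`.
#' @export
extended_absolute_risk <- function(fit, cohort, coefs = score2_coefficients(),
                                   lp_score2 = NULL, calibrated = TRUE) {
  if (is.null(lp_score2)) lp_score2 <- score2_linear_predictor(cohort, coefs)
  aug <- predict_linear_predictor(fit, cohort, offset = rep(0, nrow(cohort)))
  for (sx in c("male", "female")) {
    i <- which(cohort$sex == sx & !is.na(aug))
    if (length(i)) aug[i] <- aug[i] - mean(aug[i])
  }
  lp <- lp_score2 + aug
  risk <- rep(NA_real_, length(lp))
  ok <- !is.na(lp)
  risk[ok] <- score2_absolute_risk(lp[ok], cohort$sex[ok], coefs,
                                   calibrated = calibrated)
  data.frame(lp = lp, risk = risk)
}
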