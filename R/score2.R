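#' Load SCORE2 coefficients
#'
#' Reads a JSON coefficient file containing, for each sex, the SCORE2
#' log-hazard-ratio weights, the covariate transformation constants, the
#' baseline 10-year survival \eqn{S_0}, and a calibration scale pair
#' \eqn{(s_1, s_2)} for one European risk region. The package ships a file
#' transcribed from the published SCORE2 derivation (low-risk region, the
#' region appropriate for the UK).
#'
#' @param path Path to the coefficient JSON. Defaults to the file shipped
#'   with the package.
#' @return An object of class `score2_coefficients`: a list with elements
#'   `transforms`, `male`, `female` (each with `S0_10yr` and `coefficients`)
#'   and `calibration`.
#' @examples
#' coefs <- score2_coefficients()
#' coefs$male$S0_10yr
#' @export
score2_coefficients <- function(path = system.file("extdata",
                                                   "score2_coefficients.json",
                                                   package = "score2plus")) {
  stopifnot(file.exists(path))
  coefs <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (sx in c("male", "female")) {
    if (is.null(coefs[[sx]]))
      stop("coefficient file must contain a '", sx, "' block")
    s0 <- coefs[[sx]]$S0_10yr
    if (!is.numeric(s0) || s0 <= 0 || s0 >= 1)
      stop("S0_10yr for ", sx, " must lie in (0, 1)")
    w <- unlist(coefs[[sx]]$coefficients)
    if (any(!is.finite(w)))
      stop("non-finite weight in ", sx, " coefficient block")
    coefs[[sx]]$coefficients <- w
  }
  structure(coefs, class = "score2_coefficients")
}

# Design-matrix columns of the SCORE2 model, in coefficient order, from the
# raw risk factors.  cage = (age - 60)/5 etc.; interactions are products of
# the transformed terms.
score2_terms <- function(age, smoking, sbp, tchol, hdl, transforms) {
  tr <- transforms
  cage   <- (age   - tr$age_center)   / tr$age_scale
  csbp   <- (sbp   - tr$sbp_center)   / tr$sbp_scale
  ctchol <- (tchol - tr$tchol_center) / tr$tchol_scale
  chdl   <- (hdl   - tr$hdl_center)   / tr$hdl_scale
  cbind(cage         = cage,
        smoking      = as.numeric(smoking),
        csbp         = csbp,
        ctchol       = ctchol,
        chdl         = chdl,
        smoking_cage = as.numeric(smoking) * cage,
        csbp_cage    = csbp * cage,
        ctchol_cage  = ctchol * cage,
        chdl_cage    = chdl * cage)
}

#' SCORE2 linear predictor
#'
#' Computes the sex-specific SCORE2 linear predictor (log-hazard scale,
#' centered at the transformation constants) from age, smoking status,
#' systolic blood pressure, total cholesterol and HDL cholesterol.
#'
#' @param cohort A data frame with columns `sex` ("male"/"female"), `age`,
#'   `smoking` (0/1), `sbp` (mmHg), `total_chol` and `hdl_chol` (mmol/L).
#' @param coefs A [score2_coefficients()] object.
#' @return Numeric vector of linear predictors, one per row of `cohort`.
#' @export
score2_linear_predictor <- function(cohort, coefs = score2_coefficients()) {
  needed <- c("sex", "age", "smoking", "sbp", "total_chol", "hdl_chol")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!stats::complete.cases(cohort[needed]))
  if (length(bad))
    stop("missing SCORE2 inputs in rows: ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10))
  X <- score2_terms(cohort$age, cohort$smoking, cohort$sbp,
                    cohort$total_chol, cohort$hdl_chol, coefs$transforms)
  lp <- numeric(nrow(cohort))
  for (sx in c("male", "female")) {
    idx <- cohort$sex == sx
    if (!any(idx)) next
    w <- coefs[[sx]]$coefficients
    lp[idx] <- drop(X[idx, names(w), drop = FALSE] %*% w)
  }
  lp
}

#' SCORE2 absolute 10-year risk
#'
#' Transforms a linear predictor into absolute 10-year CVD risk. The
#' uncalibrated risk is \eqn{1 - S_0^{\exp(lp)}}; region calibration applies
#' \eqn{1 - \exp(-\exp(s_1 + s_2 \log(-\log(1 - r))))} on the
#' complementary-log-log scale, a strictly increasing transform.
#'
#' @param lp Numeric linear predictor(s).
#' @param sex Character vector ("male"/"female"), recycled if length 1.
#' @param coefs A [score2_coefficients()] object.
#' @param calibrated If `TRUE` (default) apply the region calibration pair.
#' @return Risk fraction(s) in (0, 1).
#' @export
score2_absolute_risk <- function(lp, sex, coefs = score2_coefficients(),
                                 calibrated = TRUE) {
  if (length(sex) == 1L) sex <- rep(sex, length(lp))
  stopifnot(length(sex) == length(lp), all(is.finite(lp)))
  risk <- numeric(length(lp))
  for (sx in c("male", "female")) {
    idx <- sex == sx
    if (!any(idx)) next
    s0 <- coefs[[sx]]$S0_10yr
    if (s0 <= 0 || s0 >= 1) stop("S0_10yr must lie in (0, 1)")
    uncal <- 1 - s0^exp(lp[idx])
    if (calibrated) {
      sc <- coefs$calibration[[sx]]
      risk[idx] <- 1 - exp(-exp(sc$scale1 + sc$scale2 * log(-log(1 - uncal))))
    } else {
      risk[idx] <- uncal
    }
  }
  risk
}

#' ESC 2021 risk thresholds
#'
#' Age-dependent cut-points defining low/medium/high 10-year CVD risk groups
#' for treatment consideration: under age 50, 2.5% and 7.5%; from age 50,
#' 5% and 10%. Intervals are half-open with exclusive upper bounds for the
#' low and medium groups, so a risk exactly at a cut-point falls in the
#' higher group.
#'
#' @param age_cut Age (years) at which the upper threshold pair applies.
#' @param under_cut,over_cut Numeric length-2 vectors `(low_upper,
#'   medium_upper)` for the younger and older age groups.
#' @return An object of class `risk_thresholds`.
#' @export
risk_thresholds <- function(age_cut = 50,
                            under_cut = c(0.025, 0.075),
                            over_cut = c(0.05, 0.10)) {
  for (cut in list(under_cut, over_cut))
    if (!(length(cut) == 2 && 0 < cut[1] && cut[1] < cut[2] && cut[2] < 1))
      stop("threshold pair must satisfy 0 < low_upper < medium_upper < 1")
  structure(list(age_cut = age_cut, under_cut = under_cut,
                 over_cut = over_cut),
            class = "risk_thresholds")
}

#' Assign ESC risk category
#'
#' @param age Integer baseline age(s); participants with `age < age_cut`
#'   use the younger threshold pair.
#' @param risk Predicted absolute 10-year risk fraction(s).
#' @param thresholds A [risk_thresholds()] object.
#' @return Ordered factor with levels `low < medium < high`.
#' @examples
#' esc_category(45, c(0.024, 0.075))
#' @export
esc_category <- function(age, risk, thresholds = risk_thresholds()) {
  if (length(age) == 1L) age <- rep(age, length(risk))
  stopifnot(length(age) == length(risk))
  if (any(risk < 0)) stop("negative risk")
  if (any(risk >= 1)) stop("risk must be < 1")
  lo <- ifelse(age < thresholds$age_cut,
               thresholds$under_cut[1], thresholds$over_cut[1])
  hi <- ifelse(age < thresholds$age_cut,
               thresholds$under_cut[2], thresholds$over_cut[2])
  cat <- ifelse(risk < lo, "low", ifelse(risk < hi, "medium", "high"))
  factor(cat, levels = c("low", "medium", "high"), ordered = TRUE)
}
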