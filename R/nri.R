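# Categorical net reclassification improvement at fixed risk thresholds,
# reported separately for cases (net % moved up) and non-cases (net %
# moved down), with closed-form multinomial standard errors.

#' Categorical net reclassification improvement
#'
#' Cross-tabulates reference-model and new-model risk categories separately
#' in cases and non-cases. Net case reclassification is
#' `100 * (cases up - cases down) / n_cases`; net non-case reclassification
#' is `100 * (non-cases down - non-cases up) / n_noncases`. Standard errors
#' come from the multinomial variance of the paired up/down difference,
#' p-values from the normal approximation.
#'
#' @param ref_cat,new_cat Ordered risk-category factors (levels
#'   `low < medium < high`) from the same threshold rule.
#' @param case_status Binary indicator of incident CVD within the horizon.
#' @return An object of class `nri_result`: components `case` and
#'   `noncase`, each with `nri_pct`, `se_pct`, `ci95_pct`, `p_value`,
#'   `transition_matrix` (3x3 reference x new counts) and `n`.
#' @examples
#' ref <- factor(c("low", "medium", "high"), levels = c("low", "medium", "high"),
#'               ordered = TRUE)
#' categorical_nri(ref, ref, c(1, 0, 1))  # identical models: both NRIs 0
#' @export
categorical_nri <- function(ref_cat, new_cat, case_status) {
  if (length(ref_cat) != length(new_cat) ||
      length(ref_cat) != length(case_status))
    stop("length mismatch between categories and case status")
  lv <- c("low", "medium", "high")
  ref_cat <- factor(as.character(ref_cat), levels = lv, ordered = TRUE)
  new_cat <- factor(as.character(new_cat), levels = lv, ordered = TRUE)
  if (any(is.na(ref_cat)) || any(is.na(new_cat)))
    stop("categories must be low/medium/high")
  if (sum(case_status == 1) == 0 || sum(case_status == 0) == 0)
    stop("need at least one case and one non-case")

  component <- function(idx, direction) {
    tm <- table(reference = ref_cat[idx], new = new_cat[idx])
    n <- sum(tm)
    up <- sum(tm[upper.tri(tm)])
    down <- sum(tm[lower.tri(tm)])
    net <- if (direction == "up") (up - down) / n else (down - up) / n
    p_up <- up / n; p_down <- down / n
    v <- (p_up + p_down - (p_up - p_down)^2) / n
    se <- sqrt(v)
    p <- if (se == 0) {
      if (net == 0) 1 else 0
    } else {
      2 * stats::pnorm(-abs(net) / se)
    }
    list(nri_pct = 100 * net, se_pct = 100 * se,
         ci95_pct = 100 * (net + c(-1, 1) * 1.96 * se), p_value = p,
         transition_matrix = tm, n = n)
  }
  structure(list(case = component(case_status == 1, "up"),
                 noncase = component(case_status == 0, "down")),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf(
    "Net reclassification, cases:     %+.2f%% (95%% CI %+.2f%%, %+.2f%%), p = %.3g, n = %d\n",
    x$case$nri_pct, x$case$ci95_pct[1], x$case$ci95_pct[2],
    x$case$p_value, x$case$n))
  cat(sprintf(
    "Net reclassification, non-cases: %+.2f%% (95%% CI %+.2f%%, %+.2f%%), p = %.3g, n = %d\n",
    x$noncase$nri_pct, x$noncase$ci95_pct[1], x$noncase$ci95_pct[2],
    x$noncase$p_value, x$noncase$n))
  invisible(x)
}
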