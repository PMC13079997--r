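# Sex-stratified Harrell's C and paired delta-C inference. Comparable pairs
# are formed within stratum only and pair counts are pooled across strata
# (the usual stratified-C convention); pairs tied on event time are not
# comparable; pairs tied on the predictor count 1/2.

#' Sex-stratified Harrell's C-index
#'
#' `C = (concordant + 0.5 * tied_on_lp) / comparable`, with comparable
#' pairs formed within stratum and counts pooled across strata. The
#' standard error is the large-sample infinitesimal-jackknife estimator of
#' `survival::concordance`.
#'
#' @param lp Predicted linear predictor or risk (higher = higher risk).
#' @param time,event Follow-up and event indicator.
#' @param stratum Stratification label per participant (e.g. sex); a single
#'   value means no stratification.
#' @param max_time Truncation horizon (years).
#' @param method `"pooled-pairs"` (default) pools pair counts across
#'   strata; `"inverse-variance"` averages per-stratum C weighted by
#'   inverse variance.
#' @return An object of class `cindex_result`: `c`, `se`, `ci95`,
#'   `n_comparable_pairs`, `counts`, plus per-observation `influence`
#'   values used for paired comparisons.
#' @export
harrell_c <- function(lp, time, event, stratum = "all", max_time = 10,
                      method = c("pooled-pairs", "inverse-variance")) {
  method <- match.arg(method)
  if (length(stratum) == 1L) stratum <- rep(stratum, length(lp))
  stopifnot(length(lp) == length(time), length(time) == length(event),
            length(stratum) == length(lp))
  tr <- truncate_followup(time, event, max_time)
  d <- data.frame(time = tr$time, event = tr$event, lp = lp,
                  stratum = stratum)
  if (method == "pooled-pairs") {
    fit <- survival::concordance(
      survival::Surv(time, event) ~ lp + survival::strata(stratum),
      data = d, reverse = TRUE, influence = 1)
    counts <- fit$count
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                               dimnames = list("all", names(fit$count)))
    comparable <- sum(counts[, "concordant"] + counts[, "discordant"] +
                        counts[, "tied.x"])
    if (comparable == 0) stop("no comparable pairs")
    cstat <- fit$concordance
    se <- sqrt(fit$var)
    infl <- fit$dfbeta
  } else {
    per <- lapply(split(d, d$stratum), function(ds) {
      survival::concordance(survival::Surv(time, event) ~ lp, data = ds,
                            reverse = TRUE)
    })
    vars <- vapply(per, function(f) f$var, 0)
    cs <- vapply(per, function(f) f$concordance, 0)
    w <- 1 / vars
    cstat <- sum(w * cs) / sum(w)
    se <- sqrt(1 / sum(w))
    counts <- do.call(rbind, lapply(per, function(f) f$count))
    comparable <- sum(counts[, "concordant"] + counts[, "discordant"] +
                        counts[, "tied.x"])
    infl <- NULL
  }
  structure(list(c = unname(cstat), se = unname(se),
                 ci95 = unname(cstat + c(-1, 1) * 1.96 * se),
                 n_comparable_pairs = unname(comparable),
                 counts = counts, method = method, influence = infl),
            class = "cindex_result")
}

#' @export
print.cindex_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.4f (95%% CI %.4f, %.4f), %s comparable pairs\n",
              x$c, x$ci95[1], x$ci95[2],
              format(x$n_comparable_pairs, big.mark = ",")))
  invisible(x)
}

#' Paired change in C-index between two models
#'
#' `delta = C(new) - C(ref)` on the identical participant subset, with a
#' paired standard error from the difference of the two models'
#' per-participant influence values (a leave-one-out jackknife-type
#' estimator), and a normal-approximation p-value.
#'
#' @param lp_ref,lp_new Linear predictors of the reference and comparison
#'   models on the same participants.
#' @param time,event,stratum,max_time As in [harrell_c()].
#' @param labels Length-2 character vector naming reference and comparison.
#' @return An object of class `delta_c_result`: `delta`, `se`, `ci95`,
#'   `p_value`, and both `cindex_result`s.
#' @export
delta_c <- function(lp_ref, lp_new, time, event, stratum = "all",
                    max_time = 10, labels = c("reference", "comparison")) {
  if (length(lp_ref) != length(lp_new))
    stop("reference and comparison must cover the identical subset")
  ok <- !is.na(lp_ref) & !is.na(lp_new)
  if (!all(ok))
    stop("reference and comparison must cover the identical subset ",
         "(missing predictions present)")
  c_ref <- harrell_c(lp_ref, time, event, stratum, max_time)
  c_new <- harrell_c(lp_new, time, event, stratum, max_time)
  delta <- c_new$c - c_ref$c
  se <- sqrt(sum((c_new$influence - c_ref$influence)^2))
  p <- if (se == 0) {
    if (delta == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta) / se)
  }
  structure(list(delta = delta, se = se,
                 ci95 = delta + c(-1, 1) * 1.96 * se, p_value = p,
                 reference = labels[1], comparison = labels[2],
                 c_reference = c_ref, c_comparison = c_new,
                 se_estimator = "paired influence (jackknife-type)"),
            class = "delta_c_result")
}

#' @export
print.delta_c_result <- function(x, ...) {
  cat(sprintf("delta C (%s vs %s) = %.4f (95%% CI %.4f, %.4f), p = %.3g\n",
              x$comparison, x$reference, x$delta, x$ci95[1], x$ci95[2],
              x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg FDR across a panel of tests
#'
#' Standard step-up adjustment (`stats::p.adjust(..., "BH")`), returning a
#' per-test table with significance flags at q < 0.05.
#'
#' @param p_values Numeric vector of raw p-values in [0, 1].
#' @param labels Optional test labels.
#' @param q_cut Significance cut on the adjusted values.
#' @return Data frame of class `fdr_table` with columns `label`, `p`, `q`,
#'   `significant`; attribute `m` records the number of tests.
#' @export
bh_fdr <- function(p_values, labels = NULL, q_cut = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]")
  if (is.null(labels)) labels <- paste0("test_", seq_along(p_values))
  q <- stats::p.adjust(p_values, method = "BH")
  out <- data.frame(label = labels, p = p_values, q = q,
                    significant = q < q_cut, stringsAsFactors = FALSE)
  attr(out, "m") <- length(p_values)
  class(out) <- c("fdr_table", "data.frame")
  out
}
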