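# Standardization of cohort risk stratification to external demographics
# and incidence rates, screening outcome metrics (events prevented, NNS,
# NNT), targeted re-screening and the size-matched SCORE2-prioritized
# comparator, with bootstrap uncertainty.

stratum_key <- function(sex, age) paste(sex, age_band(age), sep = ":")

#' Standardize risk-group allocation to an external population
#'
#' For every sex-by-age-band stratum the external population contributes
#' `100000 * share * incidence` expected cases and
#' `100000 * share * (1 - incidence)` non-cases per 100,000 screened; these
#' are allocated to the low/medium/high risk groups using the cohort's
#' observed conditional probabilities `P(category | case status, stratum)`
#' and summed over strata.
#'
#' @param category Risk category per participant (levels low/medium/high).
#' @param case_status Binary incident-CVD indicator per participant.
#' @param sex,age Participant sex and integer baseline age.
#' @param strata A [generate_strata_reference()] table.
#' @return An object of class `std_allocation`: a 3x2 matrix of
#'   standardized counts (category by case status) summing to 100,000.
#' @export
standardize_allocation <- function(category, case_status, sex, age, strata) {
  lv <- c("low", "medium", "high")
  category <- factor(as.character(category), levels = lv, ordered = TRUE)
  n <- length(category)
  stopifnot(length(case_status) == n, length(sex) == n, length(age) == n)
  key <- stratum_key(sex, age)
  skey <- paste(strata$sex, strata$age_band, sep = ":")
  unmatched <- setdiff(unique(key), skey)
  if (length(unmatched))
    stop("participants in strata absent from the reference table: ",
         paste(unmatched, collapse = ", "))
  alloc <- matrix(0, nrow = 3, ncol = 2,
                  dimnames = list(lv, c("case", "noncase")))
  for (r in seq_len(nrow(strata))) {
    share <- strata$population_share[r]
    if (share <= 0) next
    inc <- strata$incidence_10y[r]
    in_s <- key == skey[r]
    for (status in c(1, 0)) {
      i <- in_s & case_status == status
      if (!any(i))
        stop(sprintf("empty stratum cell: (%s, %s)", skey[r],
                     if (status == 1) "case" else "non-case"))
      p_cat <- table(category[i]) / sum(i)
      expected <- 1e5 * share * if (status == 1) inc else 1 - inc
      col <- if (status == 1) "case" else "noncase"
      alloc[, col] <- alloc[, col] + expected * as.numeric(p_cat)
    }
  }
  structure(alloc, class = c("std_allocation", "matrix"))
}

#' Standardized participant weights
#'
#' The per-participant weight implied by [standardize_allocation()]:
#' a participant of case status g in stratum s carries
#' `100000 * share_s * incidence-part_g / n_{g,s}` of the standardized
#' population, so weighted participant counts reproduce standardized
#' counts.
#'
#' @inheritParams standardize_allocation
#' @return Numeric weight per participant.
#' @export
standardized_weights <- function(case_status, sex, age, strata) {
  key <- stratum_key(sex, age)
  skey <- paste(strata$sex, strata$age_band, sep = ":")
  w <- numeric(length(key))
  for (r in seq_len(nrow(strata))) {
    share <- strata$population_share[r]
    inc <- strata$incidence_10y[r]
    for (status in c(1, 0)) {
      i <- key == skey[r] & case_status == status
      if (!any(i)) {
        if (share > 0)
          stop(sprintf("empty stratum cell: (%s, %s)", skey[r],
                       if (status == 1) "case" else "non-case"))
        next
      }
      w[i] <- 1e5 * share * (if (status == 1) inc else 1 - inc) / sum(i)
    }
  }
  w
}

#' Statin effect on incident events
#'
#' Fraction of incident CVD events prevented by statin initiation among
#' the treated high-risk group; the conventional modelling value is one
#' event in five.
#'
#' @param fraction Fraction in (0, 1).
#' @return Numeric scalar of class `statin_effect`.
#' @export
statin_effect <- function(fraction = 0.20) {
  if (fraction <= 0 || fraction >= 1)
    stop("statin effect must lie in (0, 1)")
  structure(fraction, class = "statin_effect")
}

#' Screening outcome metrics per 100,000
#'
#' From a standardized allocation: the number classified high risk, the
#' future CVD cases among them, the events prevented by treating the
#' high-risk group (`effect * cvd_high_risk`), the number needed to screen
#' (`100000 / cvd_prevented`) and the number of statins prescribed per
#' event prevented (`n_high_risk / cvd_prevented`). When a reference
#' allocation is supplied, deltas of every metric are included.
#'
#' @param alloc A [standardize_allocation()] matrix.
#' @param effect A [statin_effect()] (or plain fraction).
#' @param reference_alloc Optional reference allocation for deltas.
#' @return An object of class `screening_outcome` (a named list).
#' @export
screening_metrics <- function(alloc, effect = statin_effect(),
                              reference_alloc = NULL) {
  effect <- as.numeric(statin_effect(as.numeric(effect)))
  n_high <- sum(alloc["high", ])
  cvd_high <- alloc["high", "case"]
  prevented <- effect * cvd_high
  degenerate <- prevented == 0
  out <- list(n_high_risk = n_high, cvd_high_risk = cvd_high,
              cvd_prevented = prevented,
              nns = if (degenerate) Inf else 1e5 / prevented,
              nnt = if (degenerate) Inf else n_high / prevented,
              statin_effect = effect, degenerate = degenerate)
  if (!is.null(reference_alloc)) {
    ref <- screening_metrics(reference_alloc, effect)
    out$delta <- list(n_high_risk = n_high - ref$n_high_risk,
                      cvd_high_risk = cvd_high - ref$cvd_high_risk,
                      cvd_prevented = prevented - ref$cvd_prevented,
                      nns = out$nns - ref$nns,
                      nnt = out$nnt - ref$nnt)
  }
  structure(out, class = "screening_outcome")
}

#' @export
print.screening_outcome <- function(x, ...) {
  cat(sprintf(paste0(
    "Per 100,000 screened: N high-risk = %.0f, CVD in high-risk = %.0f,\n",
    "  CVD prevented = %.0f (statin effect %.0f%%), NNS = %.1f, NNT = %.1f\n"),
    x$n_high_risk, x$cvd_high_risk, x$cvd_prevented,
    100 * x$statin_effect, x$nns, x$nnt))
  if (!is.null(x$delta))
    cat(sprintf(
      "  vs reference: dN_high = %+.0f, dCVD_high = %+.0f, dPrevented = %+.0f, dNNS = %+.1f, dNNT = %+.1f\n",
      x$delta$n_high_risk, x$delta$cvd_high_risk, x$delta$cvd_prevented,
      x$delta$nns, x$delta$nnt))
  invisible(x)
}

#' Targeted re-screening category
#'
#' SCORE2-low and SCORE2-high participants keep their SCORE2 category;
#' only SCORE2-medium participants are re-assessed and receive the
#' extended model's category.
#'
#' @param score2_cat,extended_cat Risk categories from the same threshold
#'   rule.
#' @return Final risk category per participant.
#' @export
targeted_rescreen <- function(score2_cat, extended_cat) {
  if (length(score2_cat) != length(extended_cat)) stop("length mismatch")
  lv <- c("low", "medium", "high")
  s2 <- factor(as.character(score2_cat), levels = lv, ordered = TRUE)
  ext <- factor(as.character(extended_cat), levels = lv, ordered = TRUE)
  out <- s2
  out[s2 == "medium"] <- ext[s2 == "medium"]
  out
}

#' SCORE2-prioritized comparator of matched size
#'
#' Fair comparator for targeted re-screening: promotes to high risk the
#' non-high participants with the largest SCORE2 risk, in descending order
#' (ties broken by stable participant order), until the standardized
#' high-risk count has increased by `n_extra`. The achieved count matches
#' `n_extra` to within one participant's standardized weight.
#'
#' @param score2_risk SCORE2 absolute risk per participant.
#' @param score2_cat SCORE2 risk category per participant.
#' @param n_extra Standardized (per-100,000) high-risk count to add.
#' @param weights Standardized participant weights
#'   ([standardized_weights()]); equal weights if omitted.
#' @return Risk category per participant after promotion.
#' @export
prioritized_comparator <- function(score2_risk, score2_cat, n_extra,
                                   weights = rep(1, length(score2_risk))) {
  if (n_extra < 0) stop("n_extra must be nonnegative")
  lv <- c("low", "medium", "high")
  cat <- factor(as.character(score2_cat), levels = lv, ordered = TRUE)
  if (n_extra == 0) return(cat)
  pool <- which(cat != "high")
  if (sum(weights[pool]) < n_extra - 1e-9)
    stop("n_extra exceeds the standardized weight of the non-high pool")
  ord <- pool[order(-score2_risk[pool])]   # stable for ties
  cum <- cumsum(weights[ord])
  k <- which(cum >= n_extra - 1e-9)[1]
  cat[ord[seq_len(k)]] <- "high"
  cat
}

#' Bootstrap uncertainty for screening outcomes and reclassification
#'
#' Resamples participants with replacement within sex (preserving sex
#' totals), recomputes risk categories, targeted re-screening,
#' standardized allocation, screening metrics and case/non-case NRI per
#' replicate, and summarizes percentile 95% confidence intervals with
#' normal-approximation p-values from the bootstrap SE. Replicates with an
#' empty stratum cell are redrawn and counted. By default risks are held
#' fixed (coefficients frozen); pass `refit` to re-estimate per-replicate
#' risks.
#'
#' @param cohort Cohort data frame (needs `sex`, `age`, `event`).
#' @param risks Named list of absolute-risk vectors, one per model; must
#'   include `reference`.
#' @param strategies Named character vector per non-reference model:
#'   `"population"` or `"targeted"`.
#' @param strata Strata reference table.
#' @param reference Name of the reference model in `risks`.
#' @param thresholds Risk thresholds for categorization.
#' @param effect Statin effect fraction.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param refit Optional `function(cohort_b)` returning a named list of
#'   per-row risk vectors for the resampled cohort (re-estimation mode).
#' @param max_redraws Redraw budget for replicates with empty stratum
#'   cells.
#' @return An object of class `bootstrap_deltas`: per model a data frame
#'   of statistics (`delta_n_high_risk`, `delta_cvd_high_risk`,
#'   `delta_cvd_prevented`, `delta_nns`, `delta_nnt`, `case_nri_pct`,
#'   `noncase_nri_pct`) with point estimate, bootstrap SE, percentile CI
#'   and p-value; plus `n_redraws` and the resampling `mode`.
#' @export
bootstrap_deltas <- function(cohort, risks, strategies, strata,
                             reference = "score2",
                             thresholds = risk_thresholds(),
                             effect = statin_effect(), B = 1000, seed = 1,
                             refit = NULL, max_redraws = 100) {
  stopifnot(B >= 2, reference %in% names(risks))
  models <- setdiff(names(risks), reference)
  stopifnot(all(models %in% names(strategies)))

  stat_one <- function(d, rk) {
    ref_cat <- esc_category(d$age, rk[[reference]], thresholds)
    out <- list()
    alloc_ref <- standardize_allocation(ref_cat, d$event, d$sex, d$age,
                                        strata)
    for (m in models) {
      cat_m <- esc_category(d$age, rk[[m]], thresholds)
      final <- if (strategies[[m]] == "targeted") {
        targeted_rescreen(ref_cat, cat_m)
      } else {
        cat_m
      }
      alloc <- standardize_allocation(final, d$event, d$sex, d$age, strata)
      sm <- screening_metrics(alloc, effect, reference_alloc = alloc_ref)
      nri <- categorical_nri(ref_cat, final, d$event)
      out[[m]] <- c(delta_n_high_risk = sm$delta$n_high_risk,
                    delta_cvd_high_risk = sm$delta$cvd_high_risk,
                    delta_cvd_prevented = sm$delta$cvd_prevented,
                    delta_nns = sm$delta$nns,
                    delta_nnt = sm$delta$nnt,
                    case_nri_pct = nri$case$nri_pct,
                    noncase_nri_pct = nri$noncase$nri_pct)
    }
    out
  }

  point <- stat_one(cohort, risks)

  i_male <- which(cohort$sex == "male")
  i_female <- which(cohort$sex == "female")
  n_redraws <- 0L
  draws <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      for (try in seq_len(max_redraws)) {
        idx <- c(sample(i_male, length(i_male), replace = TRUE),
                 sample(i_female, length(i_female), replace = TRUE))
        d <- cohort[idx, , drop = FALSE]
        rk <- if (is.null(refit)) {
          lapply(risks, function(r) r[idx])
        } else {
          refit(d)
        }
        res <- tryCatch(stat_one(d, rk), error = function(e) e)
        if (!inherits(res, "error")) return(res)
        if (!grepl("empty stratum cell", conditionMessage(res))) stop(res)
        n_redraws <<- n_redraws + 1L
      }
      stop("bootstrap replicate redraw budget exhausted")
    })
  })

  summary_tabs <- lapply(models, function(m) {
    mat <- do.call(rbind, lapply(draws, `[[`, m))
    est <- point[[m]]
    se <- apply(mat, 2, stats::sd)
    lo <- apply(mat, 2, stats::quantile, 0.025, names = FALSE)
    hi <- apply(mat, 2, stats::quantile, 0.975, names = FALSE)
    p <- ifelse(se == 0, ifelse(est == 0, 1, 0),
                2 * stats::pnorm(-abs(est) / se))
    data.frame(statistic = names(est), estimate = unname(est),
               se = unname(se), ci_lo = unname(lo), ci_hi = unname(hi),
               p_value = unname(p), stringsAsFactors = FALSE)
  })
  names(summary_tabs) <- models
  structure(list(models = summary_tabs, B = B, seed = seed,
                 n_redraws = n_redraws,
                 mode = if (is.null(refit)) "fixed-coefficients"
                        else "refit-per-replicate"),
            class = "bootstrap_deltas")
}

#' @export
print.bootstrap_deltas <- function(x, ...) {
  cat(sprintf("Bootstrap (B = %d, %s mode, %d redraws)\n", x$B, x$mode,
              x$n_redraws))
  for (m in names(x$models)) {
    cat("model:", m, "\n")
    print(transform(x$models[[m]],
                    estimate = round(estimate, 2), se = round(se, 2),
                    ci_lo = round(ci_lo, 2), ci_hi = round(ci_hi, 2),
                    p_value = signif(p_value, 3)))
  }
  invisible(x)
}
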