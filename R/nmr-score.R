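# Metabolomic risk scores: penalized proportional-hazards weights over the
# 106 fundamental NMR measures, trained in the discovery cohort only. The
# score is a weighted sum of standardized NMR columns and is itself used as
# an added covariate in the offset-Cox machinery.

nmr_columns <- function(cohort) grep("^nmr_\\d+$", names(cohort), value = TRUE)

#' Train an NMR metabolomic risk score
#'
#' Elastic-net Cox regression (default mixing `alpha = 0.5`) over the 106
#' standardized NMR panel columns, with the penalty chosen by K-fold
#' cross-validated partial likelihood at its optimum. The `"CHD"` endpoint
#' trains against the full CVD event indicator; the `"IS"` endpoint trains
#' against the narrower endpoint subset, giving two distinct scores as in
#' a two-endpoint score panel.
#'
#' @param discovery Discovery cohort data frame (must contain the NMR
#'   columns, `time` and the endpoint column).
#' @param endpoint `"CHD"` (trains on `event`) or `"IS"` (trains on
#'   `narrow_event`).
#' @param alpha Elastic-net mixing parameter.
#' @param nfolds Cross-validation folds.
#' @param seed Integer seed for fold assignment.
#' @param max_time Follow-up truncation horizon (years).
#' @return An object of class `nmr_score_weights`: `endpoint`, named
#'   `weights` (length 106, zeros where the penalty removed a column),
#'   standardization `center`/`scale`, and training metadata.
#' @export
train_nmr_score <- function(discovery, endpoint = c("CHD", "IS"),
                            alpha = 0.5, nfolds = 5, seed = 1,
                            max_time = 10) {
  endpoint <- match.arg(endpoint)
  evcol <- if (endpoint == "CHD") "event" else "narrow_event"
  if (!evcol %in% names(discovery))
    stop("endpoint column '", evcol, "' not present")
  cols <- nmr_columns(discovery)
  if (!length(cols)) stop("no NMR panel columns (nmr_###) present")
  X <- as.matrix(discovery[, cols, drop = FALSE])
  cc <- stats::complete.cases(X)
  X <- X[cc, , drop = FALSE]
  tr <- truncate_followup(discovery$time[cc], discovery[[evcol]][cc],
                          max_time)
  if (sum(tr$event) < nfolds)
    stop("fewer events (", sum(tr$event), ") than folds (", nfolds, ")")
  scl <- apply(X, 2, stats::sd)
  dropped <- cols[scl <= 0]
  if (length(dropped)) {
    warning("dropping constant NMR columns: ",
            paste(dropped, collapse = ", "))
    X <- X[, scl > 0, drop = FALSE]
  }
  ctr <- colMeans(X)
  scl2 <- apply(X, 2, stats::sd)
  Z <- sweep(sweep(X, 2, ctr), 2, scl2, "/")
  y <- survival::Surv(tr$time, tr$event)
  foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(Z))))
  cvfit <- glmnet::cv.glmnet(Z, y, family = "cox", alpha = alpha,
                             foldid = foldid, standardize = FALSE)
  w <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  weights <- stats::setNames(rep(0, length(cols)), cols)
  weights[colnames(Z)] <- w
  center <- stats::setNames(rep(0, length(cols)), cols)
  scale_ <- stats::setNames(rep(1, length(cols)), cols)
  center[colnames(Z)] <- ctr
  scale_[colnames(Z)] <- scl2
  structure(list(endpoint = endpoint, weights = weights,
                 center = center, scale = scale_,
                 training = list(method = "elastic-net Cox",
                                 alpha = alpha, nfolds = nfolds,
                                 seed = seed,
                                 lambda_min = cvfit$lambda.min,
                                 n = nrow(Z), n_events = sum(tr$event),
                                 dropped = dropped)),
            class = "nmr_score_weights")
}

#' Evaluate an NMR score on a cohort
#'
#' Weighted sum of the NMR columns standardized with the training cohort's
#' constants.
#'
#' @param weights A [train_nmr_score()] object.
#' @param cohort Cohort data frame with the NMR columns.
#' @return Numeric score per row (`NA` where panel values are missing).
#' @export
predict_nmr_score <- function(weights, cohort) {
  stopifnot(inherits(weights, "nmr_score_weights"))
  cols <- names(weights$weights)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks NMR columns: ",
         paste(utils::head(missing_cols, 5), collapse = ", "))
  X <- as.matrix(cohort[, cols, drop = FALSE])
  Z <- sweep(sweep(X, 2, weights$center), 2, weights$scale, "/")
  drop(Z %*% weights$weights)
}

#' @export
print.nmr_score_weights <- function(x, ...) {
  cat(sprintf(
    "NMR metabolomic score (%s endpoint): %d/%d nonzero weights\n",
    x$endpoint, sum(x$weights != 0), length(x$weights)))
  cat(sprintf("  %s, alpha = %g, %d-fold CV, lambda = %.4g, n = %d (%d events)\n",
              x$training$method, x$training$alpha, x$training$nfolds,
              x$training$lambda_min, x$training$n, x$training$n_events))
  invisible(x)
}
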