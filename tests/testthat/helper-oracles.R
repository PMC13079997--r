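# Independent oracles used to check the analysis code path.

# Exhaustive O(n^2) pair enumeration for stratified Harrell's C.
# A pair is comparable when one member has an event and the other is known
# to survive longer (strictly later time, or censored at the same time).
# Pairs with events at identical times are not comparable; ties on the
# predictor count 1/2. Pair counts are pooled across strata.
brute_force_c <- function(lp, time, event, stratum = rep("all", length(lp))) {
  conc <- 0; comp <- 0
  n <- length(lp)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stratum[i] != stratum[j]) next
      if (time[i] == time[j]) {
        if (event[i] + event[j] != 1) next  # both events or both censored
        case <- if (event[i] == 1) i else j
      } else {
        first <- if (time[i] < time[j]) i else j
        if (event[first] != 1) next
        case <- first
      }
      other <- if (case == i) j else i
      comp <- comp + 1
      if (lp[case] > lp[other]) conc <- conc + 1
      else if (lp[case] == lp[other]) conc <- conc + 0.5
    }
  }
  if (comp == 0) stop("no comparable pairs")
  list(c = conc / comp, comparable = comp)
}

# Hand BH step-up: q_(i) = min_{j >= i} m * p_(j) / j, capped at 1.
bh_step_up <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    q[ord[i]] <- running
  }
  q
}

# Direct transition counting for categorical NRI.
nri_by_counting <- function(ref, new, case) {
  rk <- function(x) match(as.character(x), c("low", "medium", "high"))
  up <- rk(new) > rk(ref)
  down <- rk(new) < rk(ref)
  list(case_pct = 100 * (sum(up & case == 1) - sum(down & case == 1)) /
         sum(case == 1),
       noncase_pct = 100 * (sum(down & case == 0) - sum(up & case == 0)) /
         sum(case == 0))
}

# Small cohort-like frame with simple structure for engine-level tests.
toy_cohort <- function(n = 8, seed = 1) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    data.frame(
      participant_id = sprintf("T%03d", seq_len(n)),
      sex = rep(c("male", "female"), length.out = n),
      age = sample(40:69, n, replace = TRUE),
      smoking = rbinom(n, 1, 0.2),
      sbp = rnorm(n, 135, 15),
      total_chol = rnorm(n, 5.8, 1),
      hdl_chol = pmax(rnorm(n, 1.4, 0.3), 0.5),
      stringsAsFactors = FALSE)
  })
}
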