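lv <- c("low", "medium", "high")
as_cat <- function(x) factor(x, levels = lv, ordered = TRUE)

test_that("single-stratum allocation is direct arithmetic", {
  # cases split (50%, 30%, 20%), incidence 5%: high-risk cases per 100k
  # = 100000 * 0.05 * 0.20 = 1000
  strata <- data.frame(sex = "male", age_band = "40-44",
                       population_share = 1, incidence_10y = 0.05)
  cat <- as_cat(c(rep("low", 5), rep("medium", 3), rep("high", 2),
                  rep("low", 10)))
  case <- c(rep(1, 10), rep(0, 10))
  alloc <- standardize_allocation(cat, case, rep("male", 20), rep(42, 20),
                                  strata)
  expect_equal(alloc["high", "case"], 1000)
  expect_equal(alloc["low", "case"], 2500)
  expect_equal(sum(alloc[, "case"]), 5000)
  expect_equal(sum(alloc), 1e5, tolerance = 1e-6)
})

test_that("two-strata hand example matches the hand-computed allocation", {
  strata <- data.frame(sex = "male", age_band = c("40-44", "45-49"),
                       population_share = c(0.6, 0.4),
                       incidence_10y = c(0.1, 0.2))
  age <- c(42, 42, 42, 42, 42, 42, 47, 47, 47, 47)
  cat <- as_cat(c("low", "high",            # stratum-1 cases
                  "low", "low", "medium", "high",  # stratum-1 non-cases
                  "medium", "medium",       # stratum-2 cases
                  "high", "high"))          # stratum-2 non-cases
  case <- c(1, 1, 0, 0, 0, 0, 1, 1, 0, 0)
  alloc <- standardize_allocation(cat, case, rep("male", 10), age, strata)
  expect_equal(alloc[, "case"],
               c(low = 3000, medium = 8000, high = 3000), tolerance = 1e-9)
  expect_equal(alloc[, "noncase"],
               c(low = 27000, medium = 13500, high = 45500),
               tolerance = 1e-9)
})

test_that("standardizing to the cohort's own demographics reproduces the crude allocation", {
  coh <- generate_cohort(sim_config(n = 6000, seed = 62))
  bands <- age_band(coh$age)
  key <- paste(coh$sex, bands)
  tab <- as.data.frame(table(key))
  own <- do.call(rbind, lapply(unique(key), function(k) {
    i <- key == k
    data.frame(sex = coh$sex[i][1], age_band = bands[i][1],
               population_share = mean(key == k),
               incidence_10y = mean(coh$event[i]))
  }))
  risk <- score2_absolute_risk(score2_linear_predictor(coh), coh$sex)
  cat <- esc_category(coh$age, risk)
  alloc <- standardize_allocation(cat, coh$event, coh$sex, coh$age, own)
  crude <- 1e5 * table(cat, factor(coh$event, c(1, 0))) / nrow(coh)
  expect_equal(as.numeric(alloc), as.numeric(crude), tolerance = 1e-6)
})

test_that("allocation conserves the standardized population and expected cases", {
  coh <- generate_cohort(sim_config(n = 20000, seed = 63))
  strata <- generate_strata_reference()
  risk <- score2_absolute_risk(score2_linear_predictor(coh), coh$sex)
  cat <- esc_category(coh$age, risk)
  alloc <- standardize_allocation(cat, coh$event, coh$sex, coh$age, strata)
  expect_equal(sum(alloc), 1e5, tolerance = 1e-6)
  expected_cases <- sum(1e5 * strata$population_share * strata$incidence_10y)
  expect_equal(sum(alloc[, "case"]), expected_cases, tolerance = 1e-6)
  # weights imply the same allocation
  w <- standardized_weights(coh$event, coh$sex, coh$age, strata)
  expect_equal(sum(w), 1e5, tolerance = 1e-6)
  expect_equal(sum(w[cat == "high" & coh$event == 1]),
               alloc["high", "case"], tolerance = 1e-6)
  # empty stratum cells are named in the error
  young_male <- coh$sex == "male" & age_band(coh$age) == "40-44"
  coh2 <- coh[!(young_male & coh$event == 1), ]
  expect_error(standardize_allocation(
    esc_category(coh2$age,
                 score2_absolute_risk(score2_linear_predictor(coh2),
                                      coh2$sex)),
    coh2$event, coh2$sex, coh2$age, strata),
    "empty stratum cell.*male:40-44.*case")
})

test_that("screening metrics follow their defining identities", {
  alloc <- matrix(c(1500, 2500, 1000, 45000, 45600, 3400 + 1000 - 1000),
                  nrow = 3, dimnames = list(lv, c("case", "noncase")))
  # force n_high = 4400 with 1000 high-risk cases
  alloc["high", "noncase"] <- 3400
  sm <- screening_metrics(alloc, 0.20)
  expect_equal(sm$cvd_prevented, 200)      # one in five of 1000
  expect_equal(sm$nns, 500)                # 100000 / 200
  expect_equal(sm$nnt, 22)                 # 4400 / 200
  expect_equal(sm$nnt, sm$n_high_risk / (0.2 * sm$cvd_high_risk),
               tolerance = 1e-9)
  # monotone in the statin effect
  effects <- c(0.1, 0.2, 0.3, 0.5)
  prev <- vapply(effects, function(e) screening_metrics(alloc, e)$cvd_prevented, 0)
  nns <- vapply(effects, function(e) screening_metrics(alloc, e)$nns, 0)
  nnt <- vapply(effects, function(e) screening_metrics(alloc, e)$nnt, 0)
  expect_true(all(diff(prev) > 0))
  expect_true(all(diff(nns) < 0))
  expect_true(all(diff(nnt) < 0))
  # degenerate high-risk group reports infinities with a flag
  empty <- alloc; empty["high", ] <- 0
  sm0 <- screening_metrics(empty, 0.2)
  expect_true(sm0$degenerate)
  expect_equal(sm0$nns, Inf)
  expect_error(statin_effect(1.2), "0, 1")
})

test_that("targeted re-screening only re-assesses the medium group", {
  s2 <- as_cat(c("high", "medium", "low", "medium", "medium"))
  ext <- as_cat(c("low", "high", "high", "low", "medium"))
  out <- targeted_rescreen(s2, ext)
  expect_equal(as.character(out),
               c("high", "high", "low", "low", "medium"))
  expect_identical(targeted_rescreen(s2, s2), s2)
  expect_error(targeted_rescreen(s2, ext[1:3]), "length mismatch")
})

test_that("the prioritized comparator promotes by SCORE2 risk to a matched size", {
  risk <- c(0.02, 0.06, 0.04, 0.09, 0.12, 0.03)
  cat <- as_cat(c("low", "medium", "low", "medium", "high", "low"))
  w <- rep(10, 6)
  expect_identical(prioritized_comparator(risk, cat, 0, w), cat)
  # promote 20 units: takes the two highest-risk non-high (0.09 then 0.06)
  out <- prioritized_comparator(risk, cat, 20, w)
  expect_equal(as.character(out),
               c("low", "high", "low", "high", "high", "low"))
  # promoting the whole medium pool
  all_med <- prioritized_comparator(risk, cat, 20, w)
  expect_true(all(all_med[cat == "medium"] == "high"))
  expect_error(prioritized_comparator(risk, cat, 60, w), "exceeds")
  # achieved standardized count matches the request within one weight
  coh <- generate_cohort(sim_config(n = 10000, seed = 64))
  strata <- generate_strata_reference()
  risk2 <- score2_absolute_risk(score2_linear_predictor(coh), coh$sex)
  cat2 <- esc_category(coh$age, risk2)
  w2 <- standardized_weights(coh$event, coh$sex, coh$age, strata)
  n_extra <- 2000
  out2 <- prioritized_comparator(risk2, cat2, n_extra, w2)
  achieved <- sum(w2[out2 == "high"]) - sum(w2[cat2 == "high"])
  expect_lt(abs(achieved - n_extra), max(w2) + 1e-9)
})

test_that("bootstrap is reproducible and a model versus itself is exactly null", {
  coh <- generate_cohort(sim_config(n = 6000, seed = 65))
  strata <- generate_strata_reference()
  risk <- score2_absolute_risk(score2_linear_predictor(coh), coh$sex)
  risks <- list(score2 = risk, same = risk)
  bt1 <- bootstrap_deltas(coh, risks, c(same = "population"), strata,
                          B = 3, seed = 17)
  bt2 <- bootstrap_deltas(coh, risks, c(same = "population"), strata,
                          B = 3, seed = 17)
  expect_identical(bt1$models$same, bt2$models$same)
  tab <- bt1$models$same
  expect_true(all(tab$estimate == 0))
  expect_true(all(tab$ci_lo == 0 & tab$ci_hi == 0))
  expect_true(all(tab$p_value == 1))
  expect_equal(bt1$mode, "fixed-coefficients")
})
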