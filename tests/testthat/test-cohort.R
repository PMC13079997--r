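test_that("identical config and seed give identical tables", {
  cfg <- sim_config(n = 500, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  # and the generator leaves the caller's RNG stream untouched
  set.seed(123); x1 <- runif(3)
  set.seed(123); invisible(generate_cohort(cfg)); x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("cohort invariants hold", {
  coh <- generate_cohort(sim_config(n = 4000, seed = 5))
  expect_true(all(coh$age >= 40 & coh$age <= 69))
  expect_true(all(coh$time > 0 & coh$time <= 10))
  expect_true(all(coh$event + coh$noncvd_death <= 1))
  expect_true(all(coh$fatal <= coh$event))
  expect_true(all(coh$narrow_event <= coh$event))
  expect_false(any(duplicated(coh$participant_id)))
  expect_length(grep("^nmr_\\d+$", names(coh)), 106)
})

test_that("with all effects zero the event fraction matches the calibration target", {
  cfg <- sim_config(n = 200000, seed = 11,
                    target_event_rate = c(male = 0.03, female = 0.03),
                    noncvd_death_rate = c(male = 0, female = 0),
                    ltfu_rate = 0, score2_weight = 0,
                    biomarker_effects = stats::setNames(
                      rep(0, 11), clinical_biomarker_defs()$name),
                    nmr_effect = 0, prs_effects = c(chd = 0, is = 0))
  coh <- generate_cohort(cfg)
  se <- sqrt(0.03 * 0.97 / nrow(coh))
  expect_lt(abs(mean(coh$event) - 0.03), 3 * se)
})

test_that("sex fraction is sampled at the configured rate", {
  coh <- generate_cohort(sim_config(n = 100000, seed = 21,
                                    sex_fraction_female = 0.57))
  se <- sqrt(0.57 * 0.43 / 100000)
  expect_lt(abs(mean(coh$sex == "female") - 0.57), 3 * se)
})

test_that("impossible configurations are rejected", {
  expect_error(sim_config(ltfu_rate = 1.2), "configuration error")
  expect_error(sim_config(biomarker_loadings = c(crp = 1.5)),
               "positive semi-definite")
  expect_error(sim_config(overlap = 1.4), "overlap")
})

test_that("strata reference satisfies its invariants", {
  s <- generate_strata_reference()
  expect_equal(sum(s$population_share), 1, tolerance = 1e-9)
  expect_true(all(s$incidence_10y > 0 & s$incidence_10y < 1))
  expect_setequal(unique(s$age_band),
                  c("40-44", "45-49", "50-54", "55-59", "60-64", "65-69"))
  # male incidence at least female incidence within every band
  m <- s[s$sex == "male", ]; f <- s[s$sex == "female", ]
  expect_true(all(m$incidence_10y[match(f$age_band, m$age_band)] >=
                    f$incidence_10y))
  # uniform shares over the 12 strata
  u <- generate_strata_reference(male_fraction = 0.5)
  expect_equal(u$population_share, rep(1 / 12, 12))
  expect_error(generate_strata_reference(band_shares = rep(0.2, 6)),
               "summing to 1")
})

test_that("age bands partition 40-69", {
  expect_equal(age_band(c(40, 44, 45, 69)),
               c("40-44", "40-44", "45-49", "65-69"))
  expect_error(age_band(39), "outside")
})

test_that("split is a disjoint exhaustive partition, balanced on outcome", {
  coh <- generate_cohort(sim_config(n = 10000, seed = 9))
  sp <- split_cohort(coh, 0.5, seed = 31)
  expect_equal(nrow(sp$discovery), 5000)
  expect_equal(nrow(sp$replication), 5000)
  expect_setequal(c(sp$discovery$participant_id,
                    sp$replication$participant_id), coh$participant_id)
  expect_equal(unique(sp$discovery$cohort_label), "discovery")
  # same seed reproduces the same partition
  sp2 <- split_cohort(coh, 0.5, seed = 31)
  expect_identical(sp$discovery$participant_id,
                   sp2$discovery$participant_id)
  # event rates differ by less than 3 two-proportion SEs
  p1 <- mean(sp$discovery$event); p2 <- mean(sp$replication$event)
  pbar <- mean(coh$event)
  se <- sqrt(pbar * (1 - pbar) * (1 / 5000 + 1 / 5000))
  expect_lt(abs(p1 - p2), 3 * se)
  expect_error(split_cohort(coh, 1.2), "fraction")
})

test_that("follow-up truncation censors events beyond the horizon", {
  tr <- truncate_followup(c(2, 9, 11, 12), c(1, 0, 1, 0), 10)
  expect_equal(tr$time, c(2, 9, 10, 10))
  expect_equal(tr$event, c(1L, 0L, 0L, 0L))
})

test_that("cohort CSV round trip preserves values", {
  coh <- generate_cohort(sim_config(n = 50, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$participant_id, coh$participant_id)
  expect_equal(back$sbp, coh$sbp, tolerance = 1e-10)
  expect_equal(back$event, coh$event)
})
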