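# Synthetic cohorts with known proportional-hazards structure.
#
# The generator emulates the statistical shape of a UK screening-eligible
# cohort aged 40-69: sex-specific risk-factor distributions, a panel of 11
# clinical biomarkers correlated through a shared latent (inflammation-like)
# factor partially overlapping the SCORE2 linear predictor, a 106-column NMR
# panel driven by three latent factors (one carrying CVD signal), two
# independent standardized polygenic scores, exponential event times with
# log-hazard = baseline + linear predictor, an independent exponential
# competing non-CVD death process, administrative censoring at 10 years and
# uniform loss to follow-up.

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Clinical biomarker panel definitions
#'
#' The 11 clinical biochemistry biomarkers carried by the cohort, with the
#' raw-scale distribution used by the generator (lognormal for skewed
#' analytes), the loading on the shared latent factor, and the default
#' per-SD log-hazard effect.
#'
#' @return Data frame with columns `name`, `dist`, `p1`, `p2`, `loading`,
#'   `effect`.
#' @export
clinical_biomarker_defs <- function() {
  data.frame(
    name    = c("cystatin_c", "crp", "alp", "albumin", "ggt", "lpa",
                "ast", "hba1c", "urate", "vitamin_d", "apoa1"),
    dist    = c("normal", "lognormal", "lognormal", "normal", "lognormal",
                "lognormal", "lognormal", "normal", "normal", "normal",
                "normal"),
    p1      = c(0.90, log(1.5), log(80), 45, log(30), log(20),
                log(24), 35, 300, 50, 1.5),
    p2      = c(0.15, 1.0, 0.25, 2.5, 0.6, 1.0, 0.3, 4, 70, 20, 0.25),
    loading = c(0.6, 0.7, 0.3, -0.4, 0.4, 0.0, 0.2, 0.3, 0.35, -0.2, -0.3),
    effect  = c(0.12, 0.08, 0.05, -0.07, 0.05, 0.10, 0.03, 0.06, 0.05,
                -0.05, -0.06),
    stringsAsFactors = FALSE)
}

#' Simulation configuration for synthetic cohorts
#'
#' Collects every knob of the cohort generator: size, seed, sex split,
#' risk-factor distributions, per-covariate log-hazard effects, target
#' observed 10-year event fractions (the per-sex baseline hazards are solved
#' numerically so these are met under whatever effects are configured),
#' competing non-CVD death and loss-to-follow-up rates, biomarker factor
#' structure and its overlap with the SCORE2 linear predictor.
#'
#' Defaults emulate the published baseline characteristics of a UK
#' screening-eligible cohort: 57.2% female, observed 10-year CVD event
#' fractions 4.4% (male) and 1.9% (female), non-CVD death 3.2%/2.3%, loss to
#' follow-up 2.1%.
#'
#' @param n Number of participants.
#' @param seed Integer seed controlling all randomness.
#' @param sex_fraction_female Probability a participant is female.
#' @param age_band_weights Sampling weights over the six 5-year age bands
#'   40-44, ..., 65-69.
#' @param target_event_rate Named (male, female) observed 10-year event
#'   fractions the baseline hazards are calibrated to.
#' @param noncvd_death_rate Named (male, female) 10-year non-CVD death
#'   fractions (converted to an independent exponential hazard).
#' @param ltfu_rate Probability of a uniform loss-to-follow-up censoring
#'   time on (0, 10).
#' @param score2_weight Multiplier on the true SCORE2 linear predictor in
#'   the generating log-hazard (1 = proportional hazards on SCORE2 truth).
#' @param biomarker_effects Named per-SD log-hazard effects for the 11
#'   clinical biomarkers (on their latent standardized scale).
#' @param biomarker_loadings Named loadings of the 11 biomarkers on the
#'   shared latent factor; absolute values must be < 1.
#' @param overlap Correlation in [0, 1] between the shared biomarker factor
#'   and the (standardized, per sex) SCORE2 linear predictor.
#' @param nmr_effect Log-hazard effect per SD of the NMR signal factor.
#' @param nmr_n_signal Number of the 106 NMR columns loading on the signal
#'   factor (the rest load on two noise factors).
#' @param prs_effects Named (chd, is) log-hazard effects per SD of the two
#'   polygenic scores.
#' @param fatal_fraction Named (male, female) fraction of events that are
#'   fatal.
#' @param narrow_fraction Fraction of events meeting the narrower endpoint
#'   definition.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 10000,
                       seed = 1,
                       sex_fraction_female = 0.572,
                       age_band_weights = rep(1 / 6, 6),
                       target_event_rate = c(male = 0.044, female = 0.019),
                       noncvd_death_rate = c(male = 0.032, female = 0.023),
                       ltfu_rate = 0.021,
                       score2_weight = 1.0,
                       biomarker_effects = NULL,
                       biomarker_loadings = NULL,
                       overlap = 0.3,
                       nmr_effect = 0.25,
                       nmr_n_signal = 36,
                       prs_effects = c(chd = 0.20, is = 0.10),
                       fatal_fraction = c(male = 0.202, female = 0.156),
                       narrow_fraction = 0.5) {
  defs <- clinical_biomarker_defs()
  if (is.null(biomarker_effects)) {
    biomarker_effects <- stats::setNames(defs$effect, defs$name)
  } else {
    full <- stats::setNames(defs$effect, defs$name)
    full[names(biomarker_effects)] <- biomarker_effects
    biomarker_effects <- full
  }
  if (is.null(biomarker_loadings)) {
    biomarker_loadings <- stats::setNames(defs$loading, defs$name)
  } else {
    full <- stats::setNames(defs$loading, defs$name)
    full[names(biomarker_loadings)] <- biomarker_loadings
    biomarker_loadings <- full
  }
  cfg <- list(n = n, seed = seed,
              sex_fraction_female = sex_fraction_female,
              age_band_weights = age_band_weights,
              target_event_rate = target_event_rate,
              noncvd_death_rate = noncvd_death_rate,
              ltfu_rate = ltfu_rate,
              score2_weight = score2_weight,
              biomarker_effects = biomarker_effects,
              biomarker_loadings = biomarker_loadings,
              overlap = overlap,
              nmr_effect = nmr_effect,
              nmr_n_signal = nmr_n_signal,
              prs_effects = prs_effects,
              fatal_fraction = fatal_fraction,
              narrow_fraction = narrow_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n >= 1, length(cfg$seed) == 1)
  rates <- c(cfg$target_event_rate, cfg$noncvd_death_rate, cfg$ltfu_rate,
             cfg$sex_fraction_female, cfg$fatal_fraction,
             cfg$narrow_fraction)
  if (any(rates < 0) || any(rates >= 1))
    stop("configuration error: all rates must lie in [0, 1)")
  if (cfg$overlap < 0 || cfg$overlap > 1)
    stop("configuration error: overlap must lie in [0, 1]")
  if (any(abs(cfg$biomarker_loadings) >= 1))
    stop("configuration error: biomarker loadings must have |loading| < 1 ",
         "(implied correlation matrix not positive semi-definite)")
  if (length(cfg$age_band_weights) != 6 || any(cfg$age_band_weights < 0) ||
      sum(cfg$age_band_weights) <= 0)
    stop("configuration error: age_band_weights must be 6 nonnegative weights")
  invisible(cfg)
}

# P(event observed by 10y | event hazard h) under competing exponential
# death (rate mu), administrative censoring at 10 and uniform LTFU with
# probability p: closed form used to calibrate the baseline hazard.
prob_event_observed <- function(h, mu, p) {
  tot <- h + mu
  a10 <- h / tot * (1 - exp(-10 * tot))
  au  <- h / tot * (1 - (1 - exp(-10 * tot)) / (10 * tot))
  (1 - p) * a10 + p * au
}

solve_baseline_hazard <- function(eta, target, mu, p) {
  f <- function(loglam) {
    mean(prob_event_observed(exp(loglam + eta), mu, p)) - target
  }
  exp(stats::uniroot(f, c(-14, 0), tol = 1e-12)$root)
}

#' Generate a synthetic cohort
#'
#' Draws a participant table satisfying the cohort invariants (ages 40-69,
#' follow-up in (0, 10], mutually exclusive event and competing-death
#' indicators, fatal and narrow endpoints as subsets of events) from the
#' proportional-hazards model described in [sim_config()]. The true
#' generating log-hazard uses the real SCORE2 linear predictor computed from
#' the shipped coefficients, so downstream offset models see a correctly
#' specified offset. Identical config and seed give identical tables.
#'
#' @param config A [sim_config()] object.
#' @param coefs SCORE2 coefficients used for the generating linear
#'   predictor.
#' @return A data frame (one row per participant) with attributes
#'   `sim_config`, `true_eta` (generating log-hazard linear predictor,
#'   excluding baseline), `nmr_signal_factor` and `inflammation_factor`.
#' @export
generate_cohort <- function(config, coefs = score2_coefficients()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n
    sex <- ifelse(stats::runif(n) < config$sex_fraction_female,
                  "female", "male")
    band <- sample.int(6, n, replace = TRUE,
                       prob = config$age_band_weights / sum(config$age_band_weights))
    age <- 40L + (band - 1L) * 5L + sample.int(5, n, replace = TRUE) - 1L

    smoking <- sbp <- tchol <- hdl <- numeric(n)
    pars <- list(
      male   = list(smk = 0.122, sbp = c(140, 17), tc = c(5.8, 1.0),
                    hdl = c(1.3, 0.3)),
      female = list(smk = 0.085, sbp = c(134, 19), tc = c(6.0, 1.1),
                    hdl = c(1.6, 0.4)))
    for (sx in c("male", "female")) {
      i <- sex == sx
      m <- sum(i)
      if (!m) next
      pp <- pars[[sx]]
      smoking[i] <- stats::rbinom(m, 1, pp$smk)
      sbp[i]   <- pmax(stats::rnorm(m, pp$sbp[1], pp$sbp[2]), 80)
      tchol[i] <- pmax(stats::rnorm(m, pp$tc[1], pp$tc[2]), 2)
      hdl[i]   <- pmax(stats::rnorm(m, pp$hdl[1], pp$hdl[2]), 0.4)
    }

    cohort <- data.frame(
      participant_id = sprintf("P%07d", seq_len(n)),
      sex = sex, age = age, smoking = smoking, sbp = sbp,
      total_chol = tchol, hdl_chol = hdl,
      stringsAsFactors = FALSE)

    lp_s2 <- score2_linear_predictor(cohort, coefs)

    # shared latent factor, correlated with the (per-sex standardized)
    # SCORE2 linear predictor by `overlap`
    z_s2 <- numeric(n)
    for (sx in c("male", "female")) {
      i <- sex == sx
      if (sum(i) > 1) z_s2[i] <- as.numeric(scale(lp_s2[i]))
    }
    ov <- config$overlap
    L <- ov * z_s2 + sqrt(1 - ov^2) * stats::rnorm(n)

    defs <- clinical_biomarker_defs()
    zmat <- matrix(NA_real_, n, nrow(defs),
                   dimnames = list(NULL, defs$name))
    for (j in seq_len(nrow(defs))) {
      lam <- config$biomarker_loadings[[defs$name[j]]]
      z <- lam * L + sqrt(1 - lam^2) * stats::rnorm(n)
      zmat[, j] <- z
      raw <- if (defs$dist[j] == "lognormal") {
        exp(defs$p1[j] + defs$p2[j] * z)
      } else {
        defs$p1[j] + defs$p2[j] * z
      }
      cohort[[defs$name[j]]] <- raw
    }

    # NMR panel: three latent factors, the first carrying CVD signal
    fac <- matrix(stats::rnorm(3 * n), n, 3)
    n_nmr <- 106L
    which_fac <- rep(1:3, times = c(config$nmr_n_signal,
                                    ceiling((n_nmr - config$nmr_n_signal) / 2),
                                    floor((n_nmr - config$nmr_n_signal) / 2)))
    loadings <- stats::runif(n_nmr, 0.3, 0.7)
    nmr <- fac[, which_fac, drop = FALSE] *
      matrix(loadings, n, n_nmr, byrow = TRUE) +
      matrix(stats::rnorm(n * n_nmr), n, n_nmr) *
      matrix(sqrt(1 - loadings^2), n, n_nmr, byrow = TRUE)
    colnames(nmr) <- sprintf("nmr_%03d", seq_len(n_nmr))
    cohort <- cbind(cohort, as.data.frame(nmr))

    cohort$prs_chd <- stats::rnorm(n)
    cohort$prs_is <- stats::rnorm(n)

    eta <- config$score2_weight * lp_s2 +
      drop(zmat %*% config$biomarker_effects[defs$name]) +
      config$nmr_effect * fac[, 1] +
      config$prs_effects[["chd"]] * cohort$prs_chd +
      config$prs_effects[["is"]] * cohort$prs_is

    time <- numeric(n); event <- integer(n); noncvd <- integer(n)
    for (sx in c("male", "female")) {
      i <- which(sex == sx)
      if (!length(i)) next
      mu <- -log(1 - config$noncvd_death_rate[[sx]]) / 10
      lam0 <- solve_baseline_hazard(eta[i], config$target_event_rate[[sx]],
                                    mu, config$ltfu_rate)
      h <- lam0 * exp(eta[i])
      t_ev <- stats::rexp(length(i), h)
      t_d  <- if (mu > 0) stats::rexp(length(i), mu) else rep(Inf, length(i))
      cens <- ifelse(stats::runif(length(i)) < config$ltfu_rate,
                     stats::runif(length(i), 0, 10), 10)
      tt <- pmin(t_ev, t_d, cens)
      time[i] <- tt
      event[i] <- as.integer(t_ev <= tt & t_ev <= t_d)
      noncvd[i] <- as.integer(t_d < t_ev & t_d <= tt)
    }
    cohort$time <- time
    cohort$event <- event
    cohort$noncvd_death <- noncvd
    pf <- ifelse(sex == "male", config$fatal_fraction[["male"]],
                 config$fatal_fraction[["female"]])
    cohort$fatal <- as.integer(event == 1 & stats::runif(n) < pf)
    cohort$narrow_event <- as.integer(event == 1 &
                                        stats::runif(n) < config$narrow_fraction)
    cohort$cohort_label <- NA_character_

    attr(cohort, "sim_config") <- config
    attr(cohort, "true_eta") <- eta
    attr(cohort, "nmr_signal_factor") <- fac[, 1]
    attr(cohort, "inflammation_factor") <- L
    cohort
  })
}

#' Generate a strata reference table
#'
#' Builds the sex-by-5-year-age-band table of population shares and 10-year
#' CVD incidence rates used for standardizing cohort risk stratification to
#' an external screening population. Defaults emulate UK demographics over
#' ages 40-69 with incidence rising with age and higher in males (overall
#' roughly 6,700 expected events per 100,000 screened; about 9,000 per
#' 100,000 males and 4,450 per 100,000 females).
#'
#' @param male_fraction Population fraction male.
#' @param band_shares Within-sex shares over the six age bands (sum to 1).
#' @param incidence_male,incidence_female 10-year incidence per band.
#' @return An object of class `strata_reference`: data frame with columns
#'   `sex`, `age_band`, `population_share`, `incidence_10y`.
#' @export
generate_strata_reference <- function(male_fraction = 0.49,
                                      band_shares = rep(1 / 6, 6),
                                      incidence_male = c(0.030, 0.046, 0.066,
                                                         0.096, 0.136, 0.168),
                                      incidence_female = c(0.012, 0.019, 0.030,
                                                           0.046, 0.068, 0.092)) {
  bands <- c("40-44", "45-49", "50-54", "55-59", "60-64", "65-69")
  if (length(band_shares) != 6 || abs(sum(band_shares) - 1) > 1e-9)
    stop("band_shares must be 6 values summing to 1")
  if (male_fraction <= 0 || male_fraction >= 1)
    stop("male_fraction must lie in (0, 1)")
  inc <- c(incidence_male, incidence_female)
  if (any(inc <= 0) || any(inc >= 1))
    stop("all incidence values must lie in (0, 1)")
  out <- data.frame(
    sex = rep(c("male", "female"), each = 6),
    age_band = rep(bands, 2),
    population_share = c(male_fraction * band_shares,
                         (1 - male_fraction) * band_shares),
    incidence_10y = inc,
    stringsAsFactors = FALSE)
  stopifnot(abs(sum(out$population_share) - 1) <= 1e-9)
  structure(out, class = c("strata_reference", "data.frame"))
}

#' Age band of a baseline age
#'
#' @param age Integer age(s) in [40, 69].
#' @return Character vector of 5-year band labels ("40-44", ..., "65-69").
#' @export
age_band <- function(age) {
  if (any(age < 40 | age > 69)) stop("age outside [40, 69]")
  lo <- 40L + 5L * ((as.integer(age) - 40L) %/% 5L)
  sprintf("%d-%d", lo, lo + 4L)
}

#' Split a cohort into discovery and replication halves
#'
#' Random partition independent of all outcome and biomarker columns;
#' sets `cohort_label`.
#'
#' @param cohort A cohort data frame.
#' @param fraction_discovery Fraction allocated to discovery, in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `discovery` and `replication`.
#' @export
split_cohort <- function(cohort, fraction_discovery = 0.5, seed = 1) {
  if (fraction_discovery <= 0 || fraction_discovery >= 1)
    stop("fraction_discovery must lie in (0, 1)")
  n <- nrow(cohort)
  idx <- with_seed(seed, sample.int(n, round(fraction_discovery * n)))
  disc <- cohort[idx, , drop = FALSE]
  repl <- cohort[-idx, , drop = FALSE]
  disc$cohort_label <- "discovery"
  repl$cohort_label <- "replication"
  list(discovery = disc, replication = repl)
}

#' Truncate follow-up at a horizon
#'
#' Administrative truncation: events after `max_time` become censored at
#' `max_time`.
#'
#' @param time,event Follow-up times and event indicators.
#' @param max_time Horizon in years (default 10).
#' @return List with truncated `time` and `event`.
#' @export
truncate_followup <- function(time, event, max_time = 10) {
  over <- time > max_time
  list(time = pmin(time, max_time),
       event = as.integer(event == 1 & !over))
}

#' Read or write a cohort table as CSV
#'
#' Plain-text round trip for cohort tables; the column dictionary is the
#' one produced by [generate_cohort()].
#'
#' @param cohort Cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
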