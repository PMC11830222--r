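# ---- configuration ---------------------------------------------------------

#' Configuration for the synthetic unit-record generator
#'
#' Defines the data-generating process (DGP) for synthetic scheme
#' application and participant tables with a known-truth causal structure:
#' exposure group A affects eligibility (logit scale), plan size (the
#' mediator M, log-dollar scale) and spending (Y, via budget utilization),
#' confounded by measured covariates C.
#'
#' Two DGP families are supported. The default `"scheme"` family draws
#' annualised plan size log-normally and spending as plan times a
#' Beta-distributed utilization fraction whose mean depends on A and C, so
#' spending never exceeds the plan. The `"linear"` family uses identity
#' links with Gaussian noise for mediator and spending; it exists for
#' estimator validation, where closed-form effects (direct effect `dA`,
#' indirect effect `bM * gA`) are available.
#'
#' @param n_applications number of access requests to generate.
#' @param n_participants number of active participants to generate.
#' @param seed integer seed; identical (config, seed) gives identical tables.
#' @param exposure which inequality group the latent A flag encodes:
#'   `"women_girls"`, `"low_ses"` or `"age_55plus"`.
#' @param exposure_prevalence P(A = 1) for `women_girls` / `low_ses`
#'   (for `age_55plus` the flag follows the age-group distribution).
#' @param family `"scheme"` (log-normal plan, Beta utilization) or
#'   `"linear"` (identity links, Gaussian noise).
#' @param coef_outcome list: `intercept`, `bA` (exposure effect) and `bC`
#'   (named list of confounder effects) on the logit-eligibility scale.
#' @param coef_mediator list: `intercept`, `gA`, `gC`, `sigma` for plan size
#'   (log-dollar scale under `"scheme"`, dollar scale under `"linear"`).
#' @param coef_spend list: `intercept`, `dA` (direct exposure effect), `dC`,
#'   and either `phi` (Beta precision, `"scheme"`) or `bM` + `sigma`
#'   (`"linear"`).
#' @param confounder_dist named list of probability vectors for the
#'   categorical confounders and flag probabilities.
#' @param decision_mix named probabilities over the six access-decision
#'   types; the two decided types jointly set P(decided), within which
#'   eligibility is drawn from the logistic DGP.
#' @param disability_mix named probabilities over primary disability codes.
#' @param p_demographics_complete probability a decided record has complete
#'   socio-demographic information.
#' @param confounding_violation if `TRUE`, a shared latent term is added to
#'   both A and the outcomes (sensitivity experiments only).
#' @param u_strength magnitude of the latent term when
#'   `confounding_violation` is on.
#'
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_applications = 10000L,
                         n_participants = 5000L,
                         seed = 1L,
                         exposure = c("women_girls", "low_ses", "age_55plus"),
                         exposure_prevalence = 0.43,
                         family = c("scheme", "linear"),
                         coef_outcome = NULL,
                         coef_mediator = NULL,
                         coef_spend = NULL,
                         confounder_dist = NULL,
                         decision_mix = NULL,
                         disability_mix = NULL,
                         p_demographics_complete = 0.999,
                         confounding_violation = FALSE,
                         u_strength = 0.5) {
  exposure <- match.arg(exposure)
  family <- match.arg(family)
  defaults <- synth_defaults()
  if (is.null(coef_outcome)) coef_outcome <- defaults$coef_outcome
  if (is.null(coef_mediator)) coef_mediator <- defaults$coef_mediator
  if (is.null(coef_spend)) {
    coef_spend <- if (family == "scheme") defaults$coef_spend else defaults$coef_spend_linear
  }
  if (is.null(confounder_dist)) confounder_dist <- defaults$confounder_dist
  if (is.null(decision_mix)) decision_mix <- defaults$decision_mix
  if (is.null(disability_mix)) disability_mix <- defaults$disability_mix

  cfg <- structure(
    list(
      n_applications = as.integer(n_applications),
      n_participants = as.integer(n_participants),
      seed = as.integer(seed),
      exposure = exposure,
      exposure_prevalence = exposure_prevalence,
      family = family,
      coef_outcome = coef_outcome,
      coef_mediator = coef_mediator,
      coef_spend = coef_spend,
      confounder_dist = confounder_dist,
      decision_mix = decision_mix,
      disability_mix = disability_mix,
      p_demographics_complete = p_demographics_complete,
      confounding_violation = confounding_violation,
      u_strength = u_strength
    ),
    class = "synth_config"
  )
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.na(cfg$n_applications) || cfg$n_applications < 0) {
    stop("n_applications must be a non-negative integer", call. = FALSE)
  }
  if (is.na(cfg$n_participants) || cfg$n_participants < 0) {
    stop("n_participants must be a non-negative integer", call. = FALSE)
  }
  if (!(cfg$exposure_prevalence > 0 && cfg$exposure_prevalence < 1)) {
    stop("exposure_prevalence must lie in (0, 1)", call. = FALSE)
  }
  check_probs <- function(p, what) {
    if (any(p < 0)) stop(what, ": negative probability", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-12) {
      stop(what, ": probabilities must sum to 1 (got ", sum(p), ")",
           call. = FALSE)
    }
  }
  check_probs(cfg$decision_mix, "decision_mix")
  check_probs(cfg$disability_mix, "disability_mix")
  for (nm in c("prior_support", "age_group", "remoteness",
               "severity_band", "years_band")) {
    check_probs(cfg$confounder_dist[[nm]], nm)
  }
  if (cfg$coef_mediator$sigma <= 0) stop("mediator sigma must be > 0", call. = FALSE)
  invisible(cfg)
}

# Default study conditions. Marginal compositions follow the published
# 2016-22 national scheme access tables; causal coefficients are fixed
# plausible magnitudes (modest adverse exposure effects on eligibility and
# plan size, slightly higher utilization in the exposure group).
synth_defaults <- function() {
  age_counts <- c(`7-14` = 126268, `15-18` = 41647, `19-24` = 36463,
                  `25-34` = 50967, `35-44` = 56232, `45-54` = 73712,
                  `55-64` = 100387)
  prior_counts <- c(australian_gov = 37478, state_gov = 161822, none = 286376)
  dis_counts <- c(
    hearing_impairment = 22042, visual_impairment = 10433,
    other_sensory_speech = 3722, autism = 125916,
    developmental_delay = 337, global_developmental_delay = 155,
    trisomy_21 = 9369, intellectual_disability = 81681,
    cerebral_palsy = 13751, spinal_cord_injury = 6013,
    other_physical = 46685, psychosocial = 82525,
    acquired_brain_injury = 18248, stroke = 9916,
    multiple_sclerosis = 10929, other_neurological = 26377, other = 17577
  )
  list(
    coef_outcome = list(
      intercept = 1.05, bA = -0.45,
      bC = list(prior_support = c(australian_gov = 0.40, state_gov = 0.60))
    ),
    coef_mediator = list(
      intercept = 10.40, gA = -0.06, sigma = 0.90,
      gC = list(
        remoteness = c(regional_remote = 0.05),
        severity_band = c(`6-10` = 0.50, `11-15` = 1.00),
        years_band = c(`1-2` = 0.10, `2-3` = 0.15, `3-4` = 0.20, `>4` = 0.25),
        sil = 0.80, sda = 0.60, ypirac = 0.30, trial_plan = -0.10,
        prior_support = c(australian_gov = 0.10, state_gov = 0.15)
      )
    ),
    # "scheme" family: logit of mean utilization
    coef_spend = list(
      intercept = 0.90, dA = 0.08, phi = 10,
      dC = list(
        remoteness = c(regional_remote = -0.10),
        severity_band = c(`6-10` = 0.10, `11-15` = 0.20),
        prior_support = c(australian_gov = 0.05, state_gov = 0.05)
      )
    ),
    # "linear" family: dollar scale, mediator enters with slope bM
    coef_spend_linear = list(
      intercept = 5000, dA = -1500, bM = 0.70, sigma = 8000,
      dC = list(
        remoteness = c(regional_remote = -500),
        severity_band = c(`6-10` = 2000, `11-15` = 4000)
      )
    ),
    confounder_dist = list(
      prior_support = prior_counts / sum(prior_counts),
      age_group = age_counts / sum(age_counts),
      remoteness = c(major_city = 0.672, regional_remote = 0.328),
      severity_band = c(`1-5` = 0.150, `6-10` = 0.515, `11-15` = 0.335),
      years_band = c(`<=1` = 0.335, `1-2` = 0.233, `2-3` = 0.206,
                     `3-4` = 0.155, `>4` = 0.071),
      p_ypirac = 0.017, p_sil = 0.100, p_sda = 0.076, p_trial = 0.056,
      p_indigenous = 0.068, p_low_ses = 0.310
    ),
    decision_mix = c(access_met = 0.5572, access_not_met = 0.1320,
                     withdrawn = 0.0965, cancelled = 0.0966,
                     in_progress = 0.0745, revoked_ceased = 0.0432),
    disability_mix = dis_counts / sum(dis_counts)
  )
}

# linear predictor contribution of the confounder coefficient list;
# unnamed category levels act as the reference (effect 0)
lp_confounders <- function(coef_list, data) {
  lp <- numeric(nrow(data))
  for (nm in names(coef_list)) {
    cf <- coef_list[[nm]]
    v <- data[[nm]]
    if (is.null(v)) stop("confounder column missing: ", nm, call. = FALSE)
    if (is.logical(v) || is.numeric(v)) {
      lp <- lp + cf * as.numeric(v)
    } else {
      idx <- match(as.character(v), names(cf))
      eff <- ifelse(is.na(idx), 0, cf[idx])
      lp <- lp + as.numeric(eff)
    }
  }
  lp
}

sample_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

age_from_band <- function(band) {
  lo <- c(`7-14` = 7, `15-18` = 15, `19-24` = 19, `25-34` = 25,
          `35-44` = 35, `45-54` = 45, `55-64` = 55)
  hi <- c(`7-14` = 14, `15-18` = 18, `19-24` = 24, `25-34` = 34,
          `35-44` = 44, `45-54` = 54, `55-64` = 64)
  lo[band] + floor(stats::runif(length(band)) * (hi[band] - lo[band] + 1))
}

# shared covariate draw for both tables
draw_covariates <- function(n, cfg) {
  cd <- cfg$confounder_dist
  df <- data.frame(
    prior_support = sample_cat(n, cd$prior_support),
    age_band = sample_cat(n, cd$age_group),
    remoteness = sample_cat(n, cd$remoteness),
    severity_band = sample_cat(n, cd$severity_band),
    years_band = sample_cat(n, cd$years_band),
    ypirac = stats::runif(n) < cd$p_ypirac,
    sil = stats::runif(n) < cd$p_sil,
    sda = stats::runif(n) < cd$p_sda,
    trial_plan = stats::runif(n) < cd$p_trial,
    indigenous = stats::runif(n) < cd$p_indigenous,
    primary_disability_code = sample_cat(n, cfg$disability_mix),
    stringsAsFactors = FALSE
  )
  df$age <- as.integer(age_from_band(df$age_band))
  sev_lo <- c(`1-5` = 1, `6-10` = 6, `11-15` = 11)
  df$severity_score <- as.integer(
    sev_lo[df$severity_band] + floor(stats::runif(n) * 5)
  )

  # exposure flag and the demographic columns it pins down
  gender_p <- if (cfg$exposure == "women_girls") cfg$exposure_prevalence else 0.43
  low_ses_p <- if (cfg$exposure == "low_ses") cfg$exposure_prevalence else
    cfg$confounder_dist$p_low_ses
  df$gender <- ifelse(stats::runif(n) < gender_p, "women_girls", "other")
  low <- stats::runif(n) < low_ses_p
  df$irsd_decile <- as.integer(ifelse(low, 1 + floor(stats::runif(n) * 3),
                                      4 + floor(stats::runif(n) * 7)))
  df$A <- switch(cfg$exposure,
                 women_girls = df$gender == "women_girls",
                 low_ses = df$irsd_decile <= 3,
                 age_55plus = df$age >= 55)
  if (isTRUE(cfg$confounding_violation)) {
    u <- stats::rnorm(n)
    flip <- stats::runif(n) < stats::plogis(cfg$u_strength * u) - 0.5
    df$A <- ifelse(flip, TRUE, df$A)
    df$.u <- u
  } else {
    df$.u <- 0
  }
  df
}

# ---- applications ----------------------------------------------------------

#' Generate a synthetic table of scheme access requests
#'
#' One row per access request. Decision types are drawn from
#' `decision_mix`; for decided records the eligibility outcome is drawn
#' from the logistic DGP in `coef_outcome`.
#'
#' @param config a [synth_config()].
#' @return a `data.frame` of application records with the socio-demographic
#'   columns used by the cohort filters.
#' @export
generate_applications <- function(config) {
  validate_synth_config(config)
  n <- config$n_applications
  set.seed(config$seed)
  if (n == 0L) return(empty_applications())
  cov <- draw_covariates(n, config)

  mix <- config$decision_mix
  p_decided <- mix[["access_met"]] + mix[["access_not_met"]]
  other <- mix[c("withdrawn", "cancelled", "in_progress", "revoked_ceased")]
  kind <- sample_cat(n, c(decided = p_decided, other))

  lp <- config$coef_outcome$intercept +
    config$coef_outcome$bA * as.numeric(cov$A) +
    lp_confounders(config$coef_outcome$bC, cov) +
    config$u_strength * cov$.u * as.numeric(config$confounding_violation)
  eligible <- stats::runif(n) < stats::plogis(lp)
  decision_type <- ifelse(kind != "decided", kind,
                          ifelse(eligible, "access_met", "access_not_met"))

  start <- as.Date("2016-07-01")
  end <- as.Date("2022-08-31")
  decision_date <- start + floor(stats::runif(n) * as.numeric(end - start + 1))

  data.frame(
    applicant_id = sprintf("app%07d", seq_len(n)),
    decision_type = decision_type,
    decision_date = decision_date,
    age_at_decision = cov$age,
    gender = cov$gender,
    irsd_decile = cov$irsd_decile,
    remoteness = cov$remoteness,
    indigenous = cov$indigenous,
    primary_disability_code = cov$primary_disability_code,
    prior_support = cov$prior_support,
    demographics_complete = stats::runif(n) < config$p_demographics_complete,
    stringsAsFactors = FALSE
  )
}

empty_applications <- function() {
  data.frame(
    applicant_id = character(), decision_type = character(),
    decision_date = as.Date(character()), age_at_decision = integer(),
    gender = character(), irsd_decile = integer(), remoteness = character(),
    indigenous = logical(), primary_disability_code = character(),
    prior_support = character(), demographics_complete = logical(),
    stringsAsFactors = FALSE
  )
}

# ---- participants ----------------------------------------------------------

#' Generate a synthetic table of active participants
#'
#' One row per active participant's most recent completed plan. Under the
#' `"scheme"` family the annualised plan amount is log-normal in A and C
#' and spending is plan times a Beta-distributed utilization fraction, so
#' `spend_amount <= plan_amount` row-wise. Under the `"linear"` family both
#' are Gaussian with identity links (validation mode; the row-wise ordering
#' is not enforced there).
#'
#' @param config a [synth_config()]; exposure must be `women_girls` or
#'   `low_ses` (age-related inequality is examined for eligibility only).
#' @param n_exposed optional exact number of exposed rows; remaining rows
#'   are unexposed (used to pin stratum sizes).
#' @return a `data.frame` of participant records including raw and
#'   annualised plan and spend dollars.
#' @export
generate_participants <- function(config, n_exposed = NULL) {
  validate_synth_config(config)
  if (config$exposure == "age_55plus") {
    stop("plan/spend generation supports the women_girls and low_ses exposures only",
         call. = FALSE)
  }
  n <- config$n_participants
  set.seed(config$seed + 1L)
  if (n == 0L) {
    return(cbind(empty_participants()))
  }
  cov <- draw_covariates(n, config)
  if (!is.null(n_exposed)) {
    stopifnot(n_exposed >= 0, n_exposed <= n)
    cov$A <- seq_len(n) <= n_exposed
    if (config$exposure == "women_girls") {
      cov$gender <- ifelse(cov$A, "women_girls", "other")
    } else {
      cov$irsd_decile <- as.integer(ifelse(cov$A, 1 + floor(stats::runif(n) * 3),
                                           4 + floor(stats::runif(n) * 7)))
    }
  }

  cm <- config$coef_mediator
  cs <- config$coef_spend
  lp_m <- cm$intercept + cm$gA * as.numeric(cov$A) + lp_confounders(cm$gC, cov)
  if (config$family == "scheme") {
    plan_ann <- exp(lp_m + stats::rnorm(n, 0, cm$sigma))
    mu_u <- stats::plogis(cs$intercept + cs$dA * as.numeric(cov$A) +
                            lp_confounders(cs$dC, cov))
    util <- stats::rbeta(n, mu_u * cs$phi, (1 - mu_u) * cs$phi)
    spend_ann <- plan_ann * util
  } else {
    plan_ann <- lp_m + stats::rnorm(n, 0, cm$sigma)
    mu_y <- cs$intercept + cs$dA * as.numeric(cov$A) + cs$bM * plan_ann +
      lp_confounders(cs$dC, cov)
    spend_ann <- mu_y + stats::rnorm(n, 0, cs$sigma)
  }

  plan_days <- 200L + as.integer(floor(stats::runif(n) * 531))  # 200..730
  cutoff <- as.Date("2022-08-31")
  plan_start <- cutoff - plan_days - as.integer(floor(stats::runif(n) * 365))

  data.frame(
    participant_id = sprintf("par%07d", seq_len(n)),
    age_at_plan_start = cov$age,
    age_band = cov$age_band,
    gender = cov$gender,
    irsd_decile = cov$irsd_decile,
    remoteness = cov$remoteness,
    indigenous = cov$indigenous,
    primary_disability_code = cov$primary_disability_code,
    prior_support = cov$prior_support,
    severity_score = cov$severity_score,
    severity_band = cov$severity_band,
    years_band = cov$years_band,
    ypirac = cov$ypirac,
    sil = cov$sil,
    sda = cov$sda,
    trial_plan = cov$trial_plan,
    active = TRUE,
    plan_start = plan_start,
    plan_days = plan_days,
    plan_amount = plan_ann * plan_days / 365.25,
    spend_amount = spend_ann * plan_days / 365.25,
    plan_ann = plan_ann,
    spend_ann = spend_ann,
    stringsAsFactors = FALSE
  )
}

empty_participants <- function() {
  data.frame(
    participant_id = character(), age_at_plan_start = integer(),
    age_band = character(),
    gender = character(), irsd_decile = integer(), remoteness = character(),
    indigenous = logical(), primary_disability_code = character(),
    prior_support = character(), severity_score = integer(),
    severity_band = character(), years_band = character(),
    ypirac = logical(), sil = logical(), sda = logical(),
    trial_plan = logical(), active = logical(),
    plan_start = as.Date(character()), plan_days = integer(),
    plan_amount = numeric(), spend_amount = numeric(),
    plan_ann = numeric(), spend_ann = numeric(),
    stringsAsFactors = FALSE
  )
}

# ---- exact-count calibration ----------------------------------------------

#' Build an application table with exact cell counts
#'
#' Deterministic expansion of a targets table: each target row is repeated
#' exactly `n` times, so requested counts per decision type / demographic
#' cell are matched integer-for-integer (no sampling). Columns not named in
#' the targets are filled with fixed defaults.
#'
#' @param targets a `data.frame` with an integer column `n` plus any
#'   application-record columns (e.g. `decision_type`,
#'   `demographics_complete`, `gender`).
#' @return a `data.frame` of application records with `sum(targets$n)` rows.
#' @export
calibrate_counts <- function(targets) {
  stopifnot(is.data.frame(targets), "n" %in% names(targets))
  if (any(is.na(targets$n)) || any(targets$n < 0)) {
    stop("target counts must be non-negative", call. = FALSE)
  }
  if (any(targets$n != floor(targets$n))) {
    stop("target counts must be integers", call. = FALSE)
  }
  total <- sum(targets$n)
  out <- empty_applications()
  defaults <- list(
    decision_type = "access_met",
    decision_date = as.Date("2020-01-01"),
    age_at_decision = 30L, gender = "other", irsd_decile = 5L,
    remoteness = "major_city", indigenous = FALSE,
    primary_disability_code = "autism", prior_support = "none",
    demographics_complete = TRUE
  )
  if (total == 0) return(out)
  idx <- rep(seq_len(nrow(targets)), times = targets$n)
  cols <- lapply(names(defaults), function(nm) {
    if (nm %in% names(targets)) targets[[nm]][idx] else rep(defaults[[nm]], total)
  })
  names(cols) <- names(defaults)
  res <- data.frame(applicant_id = sprintf("app%07d", seq_len(total)),
                    cols, stringsAsFactors = FALSE)
  res$decision_date <- as.Date(res$decision_date, origin = "1970-01-01")
  res
}

#' Published 2016-22 access-decision flow counts
#'
#' The exact decision-type counts printed in the national scheme's 2016-22
#' access summary: 705 594 access requests in total, of which 136 199 were
#' cancelled or withdrawn, 52 584 in progress, 30 444 revoked or ceased,
#' 691 decided but with incomplete socio-demographic information, and
#' 485 676 decided with complete information (393 152 eligible, 92 524
#' ineligible). The cancelled/withdrawn split is printed combined; it is
#' split evenly here, which does not affect the filters (both types are
#' excluded by the same rule).
#'
#' @return a targets `data.frame` for [calibrate_counts()].
#' @export
access_flow_targets <- function() {
  data.frame(
    decision_type = c("access_met", "access_not_met", "access_met",
                      "withdrawn", "cancelled", "in_progress",
                      "revoked_ceased"),
    demographics_complete = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    n = c(393152L, 92524L, 691L, 68100L, 68099L, 52584L, 30444L),
    stringsAsFactors = FALSE
  )
}

#' Published active-participant stratum sizes
#'
#' Exact gender-stratum sizes of the 312 268 active participants with a
#' completed plan of more than 180 days at 31 August 2022: 127 125 women
#' and girls and 185 143 others (equivalently 93 341 in the three lowest
#' IRSD deciles and 218 927 elsewhere).
#'
#' @param by `"gender"` or `"ses"`.
#' @return named integer vector of stratum sizes.
#' @export
participant_strata_counts <- function(by = c("gender", "ses")) {
  by <- match.arg(by)
  if (by == "gender") c(women_girls = 127125L, other = 185143L)
  else c(low_ses = 93341L, other_areas = 218927L)
}

# ---- ground-truth effects ---------------------------------------------------

#' Exact eligibility rates and inequality implied by the DGP
#'
#' Integrates the logistic eligibility DGP over the finite confounder
#' support (no simulation): P(eligible | A = a) for each arm, the marginal
#' eligibility over the exposure distribution, and the true total causal
#' effect per 1000 applications.
#'
#' @param config a [synth_config()].
#' @return list with `p0`, `p1`, `marginal`, `tce_per_1000`.
#' @export
true_eligibility_effect <- function(config) {
  validate_synth_config(config)
  co <- config$coef_outcome
  # enumerate the joint support of the confounders used in the DGP
  grids <- lapply(names(co$bC), function(nm) {
    p <- config$confounder_dist[[nm]]
    if (is.null(p)) stop("no distribution for confounder ", nm, call. = FALSE)
    data.frame(level = names(p), p = as.numeric(p), stringsAsFactors = FALSE)
  })
  cells <- Reduce(function(a, b) merge(a, b, by = NULL), lapply(seq_along(grids),
    function(i) {
      g <- grids[[i]]
      names(g) <- c(names(co$bC)[i], paste0(".p", i))
      g
    }))
  pcols <- grep("^\\.p", names(cells))
  w <- apply(cells[, pcols, drop = FALSE], 1, prod)
  arm_p <- function(a) {
    lp <- co$intercept + co$bA * a + lp_confounders(co$bC, cells)
    sum(w * stats::plogis(lp))
  }
  p0 <- arm_p(0)
  p1 <- arm_p(1)
  prev <- if (config$exposure == "age_55plus") {
    sum(config$confounder_dist$age_group[["55-64"]])
  } else config$exposure_prevalence
  list(p0 = p0, p1 = p1,
       marginal = prev * p1 + (1 - prev) * p0,
       tce_per_1000 = 1000 * (p1 - p0))
}

#' Ground-truth spending effects by direct simulation from the DGP
#'
#' Computes the true total causal effect (TCE), interventional direct
#' effect (IDE) and interventional indirect effect (IIE) of the exposure on
#' annualised spending by simulating the three-arm target trial directly
#' from the generator's equations (no fitted models): arm 1 sets A to the
#' comparator level, arm 2 to the exposure level, and arm 3 sets A to the
#' exposure level while drawing plan size from its comparator-level
#' conditional distribution given C. Noise draws are shared across arms, so
#' TCE = IDE + IIE holds exactly.
#'
#' @param config a [synth_config()].
#' @param n_oracle simulation size (a warning below 1000: unstable oracle).
#' @param seed integer seed.
#' @return object of class `true_decomposition`: list with `tce`, `ide`,
#'   `iie`, each a list of `point` and `mc_se`, plus `n_oracle`.
#' @export
true_effects <- function(config, n_oracle = 1e6, seed = 1L) {
  validate_synth_config(config)
  if (n_oracle < 1000) {
    warning("n_oracle < 1000: oracle effects will be unstable", call. = FALSE)
  }
  n <- as.integer(n_oracle)
  set.seed(as.integer(seed))
  cov <- draw_covariates(n, config)
  cm <- config$coef_mediator
  cs <- config$coef_spend

  lp_m0 <- cm$intercept + lp_confounders(cm$gC, cov)
  lp_m1 <- lp_m0 + cm$gA
  zM <- stats::rnorm(n)

  if (config$family == "scheme") {
    m0 <- exp(lp_m0 + cm$sigma * zM)
    m1 <- exp(lp_m1 + cm$sigma * zM)
    base_u <- cs$intercept + lp_confounders(cs$dC, cov)
    qU <- stats::runif(n)
    draw_u <- function(a) {
      mu <- stats::plogis(base_u + cs$dA * a)
      stats::qbeta(qU, mu * cs$phi, (1 - mu) * cs$phi)
    }
    y1 <- m0 * draw_u(0)        # arm 1: A = comparator, M ~ comparator
    y2 <- m1 * draw_u(1)        # arm 2: A = exposure,  M ~ exposure
    y3 <- m0 * draw_u(1)        # arm 3: A = exposure,  M ~ comparator | C
  } else {
    m0 <- lp_m0 + cm$sigma * zM
    m1 <- lp_m1 + cm$sigma * zM
    base_y <- cs$intercept + lp_confounders(cs$dC, cov)
    zY <- stats::rnorm(n)
    y1 <- base_y + cs$bM * m0 + cs$sigma * zY
    y2 <- base_y + cs$dA + cs$bM * m1 + cs$sigma * zY
    y3 <- base_y + cs$dA + cs$bM * m0 + cs$sigma * zY
  }

  eff <- function(d) list(point = mean(d), mc_se = stats::sd(d) / sqrt(n))
  structure(
    list(tce = eff(y2 - y1), ide = eff(y3 - y1), iie = eff(y2 - y3),
         n_oracle = n, seed = as.integer(seed)),
    class = "true_decomposition"
  )
}

#' @export
print.true_decomposition <- function(x, ...) {
  cat("Ground-truth interventional decomposition (n =", x$n_oracle, ")\n")
  for (nm in c("tce", "ide", "iie")) {
    cat(sprintf("  %s: %.3f (MC SE %.4f)\n", toupper(nm),
                x[[nm]]$point, x[[nm]]$mc_se))
  }
  invisible(x)
}

#' Write a generator configuration as structured text
#'
#' @param config a [synth_config()].
#' @param path output file path (JSON).
#' @export
write_synth_config <- function(config, path) {
  validate_synth_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
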