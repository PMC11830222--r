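# shared fixtures: small configs and prepared analytic tables

linear_cfg <- function(n = 20000, seed = 1, gA = -3000, bM = 0.7, dA = -1500) {
  cfg <- synth_config(n_participants = n, seed = seed, family = "linear")
  cfg$coef_mediator$intercept <- 90000
  cfg$coef_mediator$gA <- gA
  cfg$coef_mediator$sigma <- 9000
  cfg$coef_mediator$gC <- list(remoteness = c(regional_remote = 2000),
                               severity_band = c(`6-10` = 5000, `11-15` = 10000))
  cfg$coef_spend$dA <- dA
  cfg$coef_spend$bM <- bM
  cfg$coef_spend$dC <- list(remoteness = c(regional_remote = -500),
                            severity_band = c(`6-10` = 2000, `11-15` = 4000))
  cfg
}

# participants -> analytic table (single stratum unless strata = TRUE)
participant_table <- function(cfg, strata = FALSE) {
  d <- generate_participants(cfg)
  d <- filter_participant_cohort(d)$data
  d <- derive_exposures(d, "age_at_plan_start")
  d$disability_group <- if (strata) {
    map_disability_group(d$primary_disability_code)
  } else "all"
  d$plan_ann <- annualize(d$plan_amount, d$plan_days)
  d$spend_ann <- annualize(d$spend_amount, d$plan_days)
  d
}

application_table <- function(cfg, strata = FALSE) {
  d <- generate_applications(cfg)
  d <- filter_eligibility_cohort(d)$data
  d <- derive_exposures(d, "age_at_decision")
  d$disability_group <- if (strata) {
    map_disability_group(d$primary_disability_code)
  } else "all"
  d$eligible <- d$decision_type == "access_met"
  d
}

# causal specs used across files (single pooled stratum)
elig_spec <- function(exposure = "women_girls") {
  causal_spec(exposure, "eligible", "binary_logistic",
              confounders = "prior_support", scale = "per_1000",
              stratifier = "disability_group")
}

spend_spec_linear <- function(interaction = TRUE) {
  causal_spec("women_girls", "spend_ann", "gaussian_dollar",
              confounders = c("remoteness", "severity_band"),
              mediator = "plan_ann", mediator_family = "gaussian_dollar",
              interaction = interaction, scale = "dollars",
              stratifier = "disability_group")
}

# 4-cell discrete toy with exactly additive empirical logits, so the
# main-effects logistic fit reproduces the cell probabilities exactly:
# odds(A,C): (0,0)=1/3, (1,0)=1, (0,1)=2/3, (1,1)=2  (n = 900 per cell)
toy_4cell <- function() {
  cells <- expand.grid(A = c(FALSE, TRUE), C = c("c0", "c1"),
                       stringsAsFactors = FALSE)
  ones <- c(225, 450, 360, 600)
  do.call(rbind, lapply(seq_len(4), function(i) {
    data.frame(A = cells$A[i], C = cells$C[i],
               eligible = rep(c(TRUE, FALSE), c(ones[i], 900 - ones[i])),
               disability_group = "all", stringsAsFactors = FALSE)
  }))
}

# brute-force standardized difference over the toy's 4 (A,C) cells
toy_brute_force <- function(d) {
  pC <- prop.table(table(d$C))
  diff <- vapply(names(pC), function(cc) {
    mean(d$eligible[d$A & d$C == cc]) - mean(d$eligible[!d$A & d$C == cc])
  }, numeric(1))
  sum(pC * diff)
}

toy_spec <- function() {
  causal_spec("A", "eligible", "binary_logistic", confounders = "C",
              scale = "per_1000", stratifier = "disability_group")
}
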