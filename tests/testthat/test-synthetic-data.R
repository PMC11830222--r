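test_that("identical config and seed give byte-identical tables", {
  cfg <- synth_config(n_applications = 2000, n_participants = 1500, seed = 42)
  expect_identical(generate_applications(cfg), generate_applications(cfg))
  expect_identical(generate_participants(cfg), generate_participants(cfg))
})

test_that("config validation rejects bad probabilities and negative n", {
  expect_error(synth_config(n_applications = -5), "non-negative")
  expect_error(synth_config(decision_mix = c(access_met = 0.5,
                                             access_not_met = 0.6)),
               "sum to 1")
  bad <- synth_config()
  bad$coef_mediator$sigma <- -1
  expect_error(ndisineq:::validate_synth_config(bad), "sigma")
  expect_error(synth_config(exposure_prevalence = 1.2), "0, 1")
})

test_that("null eligibility DGP shows no exposure gap", {
  cfg <- synth_config(n_applications = 50000, seed = 11)
  cfg$coef_outcome$bA <- 0
  d <- application_table(cfg)
  p1 <- mean(d$eligible[d$women_girls])
  p0 <- mean(d$eligible[!d$women_girls])
  se <- sqrt(p1 * (1 - p1) / sum(d$women_girls) +
               p0 * (1 - p0) / sum(!d$women_girls))
  expect_lt(abs(p1 - p0), 3 * se)
})

test_that("marginal eligibility matches integration over the confounder support", {
  cfg <- synth_config(n_applications = 100000, seed = 13)
  truth <- true_eligibility_effect(cfg)$marginal
  d <- application_table(cfg)
  p_hat <- mean(d$eligible)
  se <- sqrt(truth * (1 - truth) / nrow(d))
  expect_lt(abs(p_hat - truth), 3 * se)
})

test_that("spending never exceeds the plan under the scheme family", {
  cfg <- synth_config(n_participants = 20000, seed = 5)
  d <- generate_participants(cfg)
  expect_true(all(d$spend_amount <= d$plan_amount))
  expect_true(all(d$spend_ann <= d$plan_ann))
  expect_true(all(d$plan_days > 0))
})

test_that("null plan and spend DGP shows no exposure gap in mean spending", {
  cfg <- synth_config(n_participants = 50000, seed = 17)
  cfg$coef_mediator$gA <- 0
  cfg$coef_spend$dA <- 0
  d <- generate_participants(cfg)
  s1 <- d$spend_ann[d$gender == "women_girls"]
  s0 <- d$spend_ann[d$gender != "women_girls"]
  se <- sqrt(var(s1) / length(s1) + var(s0) / length(s0))
  expect_lt(abs(mean(s1) - mean(s0)), 3 * se)
})

test_that("plan size matches the closed-form log-normal mean over the covariate support", {
  cfg <- synth_config(n_participants = 80000, seed = 19)
  # restrict the mediator DGP to two categorical covariates so the support
  # is small enough to enumerate
  cfg$coef_mediator$gC <- list(remoteness = c(regional_remote = 0.2),
                               severity_band = c(`6-10` = 0.5, `11-15` = 1.0))
  d <- generate_participants(cfg)
  cells <- expand.grid(remoteness = names(cfg$confounder_dist$remoteness),
                       severity_band = names(cfg$confounder_dist$severity_band),
                       A = c(0, 1), stringsAsFactors = FALSE)
  w <- cfg$confounder_dist$remoteness[cells$remoteness] *
    cfg$confounder_dist$severity_band[cells$severity_band] *
    ifelse(cells$A == 1, cfg$exposure_prevalence, 1 - cfg$exposure_prevalence)
  cm <- cfg$coef_mediator
  lp <- cm$intercept + cm$gA * cells$A +
    ndisineq:::lp_confounders(cm$gC, cells)
  truth <- sum(w * exp(lp + cm$sigma^2 / 2))
  # SE of the sample mean of a log-normal mixture
  se <- sd(d$plan_ann) / sqrt(nrow(d))
  expect_lt(abs(mean(d$plan_ann) - truth), 3 * se)
})

test_that("exact-count calibration reproduces requested cells integer-for-integer", {
  apps <- calibrate_counts(access_flow_targets())
  expect_identical(nrow(apps), 705594L)
  expect_identical(sum(apps$decision_type %in% c("in_progress")), 52584L)
  expect_identical(sum(!apps$demographics_complete), 691L)

  expect_identical(nrow(calibrate_counts(data.frame(decision_type = "withdrawn",
                                                    n = 0L))), 0L)
  types <- c("access_met", "access_not_met", "withdrawn", "cancelled",
             "in_progress", "revoked_ceased")
  even <- calibrate_counts(data.frame(decision_type = types, n = 10L))
  expect_identical(nrow(even), 60L)
  expect_true(all(table(even$decision_type) == 10L))
  expect_error(calibrate_counts(data.frame(decision_type = "withdrawn",
                                           n = -1L)), "non-negative")
})

test_that("ground-truth effects are null under a null config", {
  cfg <- synth_config(seed = 3)
  cfg$coef_mediator$gA <- 0
  cfg$coef_spend$dA <- 0
  te <- true_effects(cfg, n_oracle = 200000, seed = 4)
  for (eff in c("tce", "ide", "iie")) {
    tol <- 3 * max(te[[eff]]$mc_se, 1e-9)
    expect_lt(abs(te[[eff]]$point), tol)
  }
})

test_that("linear-family ground truth equals the product-of-coefficients form", {
  cfg <- linear_cfg(seed = 7)
  te <- true_effects(cfg, n_oracle = 100000, seed = 8)
  tol <- function(eff) 3 * max(te[[eff]]$mc_se, 1e-6)
  expect_lt(abs(te$ide$point - cfg$coef_spend$dA), tol("ide"))
  expect_lt(abs(te$iie$point - cfg$coef_spend$bM * cfg$coef_mediator$gA),
            tol("iie"))
  expect_equal(te$tce$point, te$ide$point + te$iie$point, tolerance = 1e-12)
})

test_that("doubling every dollar-scale coefficient doubles the TCE", {
  cfg <- linear_cfg(seed = 9)
  cfg2 <- cfg
  cfg2$coef_spend$intercept <- 2 * cfg$coef_spend$intercept
  cfg2$coef_spend$dA <- 2 * cfg$coef_spend$dA
  cfg2$coef_spend$bM <- 2 * cfg$coef_spend$bM
  cfg2$coef_spend$dC <- lapply(cfg$coef_spend$dC, function(x) 2 * x)
  t1 <- true_effects(cfg, n_oracle = 50000, seed = 10)
  t2 <- true_effects(cfg2, n_oracle = 50000, seed = 10)
  expect_equal(t2$tce$point, 2 * t1$tce$point, tolerance = 1e-9)
})

test_that("small oracle sizes raise the instability warning", {
  expect_warning(true_effects(synth_config(seed = 1), n_oracle = 500, seed = 1),
                 "unstable")
})

test_that("empirical moments converge at the root-n rate", {
  err_at <- function(n, seeds) {
    mean(vapply(seeds, function(s) {
      cfg <- synth_config(n_participants = n, seed = s)
      cfg$coef_mediator$gC <- list(remoteness = c(regional_remote = 0.2))
      d <- generate_participants(cfg)
      cm <- cfg$coef_mediator
      pr <- cfg$confounder_dist$remoteness
      pa <- cfg$exposure_prevalence
      truth <- sum(vapply(c(0, 1), function(a) {
        (if (a == 1) pa else 1 - pa) *
          (pr[["major_city"]] * exp(cm$intercept + cm$gA * a + cm$sigma^2 / 2) +
           pr[["regional_remote"]] *
             exp(cm$intercept + cm$gA * a + 0.2 + cm$sigma^2 / 2))
      }, numeric(1)))
      abs(mean(d$plan_ann) - truth)
    }, numeric(1)))
  }
  seeds <- 1:10
  ratio <- err_at(1000, seeds) / err_at(16000, seeds)
  # 16x the sample size should shrink the error about 4-fold
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 12)
})
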