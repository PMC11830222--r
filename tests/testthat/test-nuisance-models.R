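test_that("logistic fit recovers the generating coefficients at n = 50000", {
  cfg <- synth_config(n_applications = 50000, seed = 21)
  d <- application_table(cfg)
  spec <- model_spec("eligible", "binary_logistic", "women_girls",
                     confounders = "prior_support")
  fit <- fit_outcome_model(d, spec)
  sm <- summary(fit$fit)$coefficients
  truth <- c(`(Intercept)` = cfg$coef_outcome$intercept +
               cfg$coef_outcome$bC$prior_support[["australian_gov"]],
             women_girlsTRUE = cfg$coef_outcome$bA,
             prior_supportnone = -cfg$coef_outcome$bC$prior_support[["australian_gov"]],
             prior_supportstate_gov =
               cfg$coef_outcome$bC$prior_support[["state_gov"]] -
               cfg$coef_outcome$bC$prior_support[["australian_gov"]])
  for (nm in names(truth)) {
    expect_lt(abs(sm[nm, "Estimate"] - truth[[nm]]), 3 * sm[nm, "Std. Error"])
  }
  expect_true(fit$converged)
})

test_that("log-scale mediator fit recovers the generating coefficients", {
  cfg <- synth_config(n_participants = 50000, seed = 23)
  d <- participant_table(cfg)
  spec <- model_spec("plan_ann", "gaussian_log_mediator", "women_girls",
                     confounders = c("remoteness", "severity_band",
                                     "years_band", "sil", "sda", "ypirac",
                                     "trial_plan", "prior_support"))
  fit <- fit_mediator_model(d, spec)
  sm <- summary(fit$fit)$coefficients
  expect_lt(abs(sm["women_girlsTRUE", "Estimate"] - cfg$coef_mediator$gA),
            3 * sm["women_girlsTRUE", "Std. Error"])
  expect_lt(abs(sm["silTRUE", "Estimate"] - cfg$coef_mediator$gC$sil),
            3 * sm["silTRUE", "Std. Error"])
  expect_equal(fit$sigma, cfg$coef_mediator$sigma, tolerance = 0.02)
})

test_that("null exposure effect is recovered as a null coefficient", {
  cfg <- synth_config(n_participants = 30000, seed = 29)
  cfg$coef_mediator$gA <- 0
  d <- participant_table(cfg)
  spec <- model_spec("plan_ann", "gaussian_log_mediator", "women_girls",
                     confounders = c("remoteness", "severity_band"))
  fit <- fit_mediator_model(d, spec)
  sm <- summary(fit$fit)$coefficients
  expect_lt(abs(sm["women_girlsTRUE", "Estimate"]),
            3 * sm["women_girlsTRUE", "Std. Error"])
})

test_that("degenerate outcomes are rejected", {
  d <- participant_table(synth_config(n_participants = 500, seed = 31))
  d$eligible <- TRUE
  expect_error(
    fit_outcome_model(d, model_spec("eligible", "binary_logistic",
                                    "women_girls")),
    "separation"
  )
  d$plan_ann <- 1000
  expect_error(
    fit_mediator_model(d, model_spec("plan_ann", "gaussian_log_mediator",
                                     "women_girls")),
    "degenerate"
  )
  expect_error(
    fit_outcome_model(d[1:10, ], model_spec("spend_ann", "gaussian_dollar",
                                            "women_girls")),
    "minimum"
  )
})

test_that("duplicating every row leaves point estimates unchanged", {
  cfg <- synth_config(n_applications = 4000, seed = 33)
  d <- application_table(cfg)
  spec <- model_spec("eligible", "binary_logistic", "women_girls",
                     confounders = "prior_support")
  f1 <- fit_outcome_model(d, spec)
  f2 <- fit_outcome_model(rbind(d, d), spec)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

test_that("simulated draws are mean-consistent with the fitted model", {
  cfg <- synth_config(n_participants = 10000, seed = 35)
  d <- participant_table(cfg)
  spec <- model_spec("plan_ann", "gaussian_log_mediator", "women_girls",
                     confounders = "severity_band")
  fit <- fit_mediator_model(d, spec)
  row <- d[1, , drop = FALSE]
  set.seed(1)
  draws <- simulate_from_model(fit, row, n_draws = 100000)
  mu <- predict_mean(fit, row)   # exp(mu + sigma^2/2) for the log family
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se)

  # binary family at a (near-)degenerate predicted probability
  d$eligible <- d$women_girls   # strong but non-degenerate signal
  d$eligible[1:50] <- !d$eligible[1:50]
  bfit <- fit_outcome_model(d, model_spec("eligible", "binary_logistic",
                                          "women_girls"))
  bfit$fit$coefficients[] <- c(-40, 0)  # force predicted probability ~ 0
  set.seed(2)
  expect_true(all(simulate_from_model(bfit, d[1:20, ], n_draws = 50) == 0))
})

test_that("shared noise must match the requested dimensions", {
  d <- participant_table(synth_config(n_participants = 2000, seed = 37))
  fit <- fit_mediator_model(d, model_spec("plan_ann", "gaussian_log_mediator",
                                          "women_girls"))
  expect_error(simulate_from_model(fit, d[1:5, ], n_draws = 3,
                                   noise = matrix(0, 4, 3)), "noise")
})

test_that("fitted models serialise to structured text", {
  d <- participant_table(synth_config(n_participants = 2000, seed = 39))
  fit <- fit_mediator_model(d, model_spec("plan_ann", "gaussian_log_mediator",
                                          "women_girls"))
  path <- tempfile(fileext = ".json")
  write_model(fit, path)
  audit <- jsonlite::read_json(path)
  expect_equal(audit$n, fit$n)
  expect_equal(unlist(audit$coef), fit$coef, tolerance = 1e-12)
})
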