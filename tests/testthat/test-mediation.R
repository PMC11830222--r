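test_that("no exposure-to-mediator path means a null indirect effect", {
  cfg <- linear_cfg(n = 20000, seed = 51, gA = 0)
  d <- participant_table(cfg)
  dec <- decompose(d, spend_spec_linear(), n_mc = 100, seed = 5)
  # IIE = bM-hat * (gA-hat) standardized; bound via the mediator fit's SE
  mfit <- fit_mediator_model(d, ndisineq:::mediator_model_spec(spend_spec_linear()))
  se_gA <- summary(mfit$fit)$coefficients["women_girlsTRUE", "Std. Error"]
  expect_lt(abs(dec$iie), 3 * abs(cfg$coef_spend$bM) * se_gA + 3)
})

test_that("the decomposition is exactly additive under shared draws", {
  cfg <- synth_config(n_participants = 8000, seed = 53)
  d <- participant_table(cfg, strata = TRUE)
  spec <- causal_spec("women_girls", "spend_ann", "gaussian_dollar",
                      confounders = c("remoteness", "severity_band",
                                      "prior_support"),
                      mediator = "plan_ann", scale = "dollars")
  dec <- decompose(d, spec, n_mc = 100, seed = 7)
  ok <- !is.na(dec$tce)
  expect_true(any(ok))
  expect_true(all(abs(dec$tce[ok] - (dec$ide[ok] + dec$iie[ok])) < 1e-9))
})

test_that("linear-Gaussian decomposition recovers the closed-form effects", {
  cfg <- linear_cfg(n = 50000, seed = 55)
  d <- participant_table(cfg)
  spec <- spend_spec_linear()
  dec <- decompose(d, spec, n_mc = 200, seed = 9)
  ofit <- fit_outcome_model(d, ndisineq:::outcome_model_spec(spec, TRUE))
  mfit <- fit_mediator_model(d, ndisineq:::mediator_model_spec(spec))
  so <- summary(ofit$fit)$coefficients
  sm <- summary(mfit$fit)$coefficients
  se_dA <- so["women_girlsTRUE", "Std. Error"]
  se_gA <- sm["women_girlsTRUE", "Std. Error"]
  se_bM <- so["plan_ann", "Std. Error"]
  gA <- cfg$coef_mediator$gA; bM <- cfg$coef_spend$bM
  se_iie <- sqrt(bM^2 * se_gA^2 + gA^2 * se_bM^2)
  expect_lt(abs(dec$ide - cfg$coef_spend$dA), 3 * se_dA + 3 * se_iie)
  expect_lt(abs(dec$iie - bM * gA), 3 * se_iie + 3)
})

test_that("the indirect effect carries the sign of bM x gA across the sign grid", {
  grid <- expand.grid(gA = c(-4000, 4000), bM = c(-0.7, 0.7),
                      dA = c(-2000, 2000))
  for (i in seq_len(nrow(grid))) {
    cfg <- linear_cfg(n = 8000, seed = 57 + i, gA = grid$gA[i],
                      bM = grid$bM[i], dA = grid$dA[i])
    d <- participant_table(cfg)
    dec <- decompose(d, spend_spec_linear(), n_mc = 50, seed = 11)
    expect_identical(sign(dec$iie), sign(grid$bM[i] * grid$gA[i]),
                     info = paste("grid row", i))
  }
})

test_that("single-arm simulation honours its settings", {
  cfg <- linear_cfg(n = 20000, seed = 71)
  d <- participant_table(cfg)
  spec <- spend_spec_linear()
  models <- list(
    mediator = fit_mediator_model(d, ndisineq:::mediator_model_spec(spec)),
    outcome = fit_outcome_model(d, ndisineq:::outcome_model_spec(spec, TRUE))
  )
  m1 <- simulate_arm(models, "comparator", "comparator", d, spec,
                     n_mc = 200, seed = 3)
  m2 <- simulate_arm(models, "exposure", "exposure", d, spec,
                     n_mc = 200, seed = 3)
  m3 <- simulate_arm(models, "exposure", "comparator", d, spec,
                     n_mc = 200, seed = 3)
  # monotone linear DGP with negative direct and indirect effects:
  # the intervention arm lies between the other two arm means
  expect_true((m3 - m1) * (m2 - m3) > 0 || abs(m2 - m1) < 1)
  expect_true(min(m1, m2) <= m3 && m3 <= max(m1, m2))
  # the comparator/comparator arm matches plug-in standardization at the
  # comparator level
  mu1 <- mean(predict_mean(models$outcome,
                           transform(d, women_girls = FALSE,
                                     plan_ann = predict_mean(models$mediator,
                                       transform(d, women_girls = FALSE)))))
  expect_equal(m1, mu1, tolerance = 0.02 * abs(mu1))
  expect_error(simulate_arm(models, "shifted", "comparator", d, spec),
               "arg")
})

test_that("arm-mean Monte Carlo error shrinks at the root-n_mc rate", {
  cfg <- linear_cfg(n = 4000, seed = 73)
  d <- participant_table(cfg)
  spec <- spend_spec_linear()
  models <- list(
    mediator = fit_mediator_model(d, ndisineq:::mediator_model_spec(spec)),
    outcome = fit_outcome_model(d, ndisineq:::outcome_model_spec(spec, TRUE))
  )
  arm <- function(n_mc, seed) simulate_arm(models, "exposure", "comparator",
                                           d, spec, n_mc = n_mc, seed = seed)
  sd25 <- sd(vapply(1:20, function(s) arm(25, s), numeric(1)))
  sd2500 <- sd(vapply(1:20, function(s) arm(2500, s), numeric(1)))
  ratio <- sd25 / sd2500
  expect_gt(ratio, 4)
  expect_lt(ratio, 25)
})

test_that("mediation preconditions are enforced", {
  cfg <- synth_config(n_participants = 2000, seed = 75)
  d <- participant_table(cfg)
  no_med <- causal_spec("women_girls", "spend_ann", "gaussian_dollar",
                        scale = "dollars")
  expect_error(decompose(d, no_med), "mediator")
  expect_error(
    decompose(d, causal_spec("women_girls", "eligible", "binary_logistic",
                             mediator = "plan_ann", scale = "per_1000")),
    "continuous"
  )
  spec <- spend_spec_linear()
  d$plan_ann <- 1000   # degenerate mediator
  expect_error(ndisineq:::decompose_stratum(d, spec, 10, 1), "degenerate")
})
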