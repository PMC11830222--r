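# ---- model specification -----------------------------------------------------

#' Specify a parametric nuisance model
#'
#' Declares the outcome, family and terms of one of the working models the
#' g-computation and mediation estimators simulate from. Families:
#' `binary_logistic` (eligibility), `gaussian_log_mediator` (Gaussian on
#' log dollars, for plan size), `gaussian_dollar` (Gaussian on annualised
#' dollars, for spending or for a linear mediator).
#'
#' @param outcome outcome column name.
#' @param family one of `"binary_logistic"`, `"gaussian_log_mediator"`,
#'   `"gaussian_dollar"`.
#' @param exposure exposure column name (always present).
#' @param confounders character vector of confounder column names.
#' @param mediator optional mediator column name; when supplied the model
#'   includes the mediator and, if `interaction = TRUE`, an
#'   exposure-by-mediator interaction.
#' @param interaction include the exposure x mediator interaction term.
#' @param min_n minimum stratum size for fitting (default 50).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome, family, exposure, confounders = character(),
                       mediator = NULL, interaction = FALSE, min_n = 50L) {
  family <- match.arg(family, c("binary_logistic", "gaussian_log_mediator",
                                "gaussian_dollar"))
  if (interaction && is.null(mediator)) {
    stop("interaction requires a mediator term", call. = FALSE)
  }
  structure(
    list(outcome = outcome, family = family, exposure = exposure,
         confounders = confounders, mediator = mediator,
         interaction = interaction, min_n = as.integer(min_n)),
    class = "model_spec"
  )
}

spec_formula <- function(spec) {
  rhs <- c(spec$exposure, spec$confounders)
  if (!is.null(spec$mediator)) {
    rhs <- c(rhs, spec$mediator)
    if (spec$interaction) {
      rhs <- c(rhs, paste0(spec$exposure, ":", spec$mediator))
    }
  }
  lhs <- if (spec$family == "gaussian_log_mediator") {
    paste0("log(", spec$outcome, ")")
  } else {
    spec$outcome
  }
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

# ---- fitting -----------------------------------------------------------------

#' Fit an outcome (or spending) model by maximum likelihood
#'
#' Logistic regression for the binary family; ordinary least squares for
#' the Gaussian families (on log dollars for the log-mediator family).
#' Categorical covariates enter as full dummy sets with the first level as
#' reference. The fit is deterministic given the data.
#'
#' @param data model data (one stratum).
#' @param spec a [model_spec()].
#' @return object of class `fitted_nuisance`: the spec, named coefficients,
#'   residual scale (continuous families), n, convergence flag and the
#'   underlying `lm`/`glm` fit.
#' @export
fit_outcome_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  need <- c(spec$outcome, spec$exposure, spec$confounders, spec$mediator)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing model columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(data) < spec$min_n) {
    stop("stratum has n = ", nrow(data), " < minimum ", spec$min_n,
         call. = FALSE)
  }
  f <- spec_formula(spec)

  if (spec$family == "binary_logistic") {
    y <- as.numeric(data[[spec$outcome]])
    if (length(unique(y)) < 2) {
      stop("separation: outcome '", spec$outcome,
           "' is constant in this stratum", call. = FALSE)
    }
    fit <- suppressWarnings(stats::glm(f, data = data, family = stats::binomial()))
    p <- stats::fitted(fit)
    if (!fit$converged || all(p > 1 - 1e-8) || all(p < 1e-8)) {
      stop("separation or non-convergence in logistic fit for '",
           spec$outcome, "'", call. = FALSE)
    }
    sigma <- NA_real_
    converged <- fit$converged
  } else {
    yv <- data[[spec$outcome]]
    if (spec$family == "gaussian_log_mediator") {
      if (any(yv <= 0)) stop("log-scale family requires positive '",
                             spec$outcome, "'", call. = FALSE)
      if (stats::var(log(yv)) == 0) {
        stop("degenerate (zero-variance) outcome '", spec$outcome, "'",
             call. = FALSE)
      }
    } else if (stats::var(yv) == 0) {
      stop("degenerate (zero-variance) outcome '", spec$outcome, "'",
           call. = FALSE)
    }
    fit <- stats::lm(f, data = data)
    sigma <- summary(fit)$sigma
    converged <- TRUE
  }

  structure(
    list(spec = spec, formula = f, coef = stats::coef(fit), sigma = sigma,
         n = nrow(data), converged = converged, fit = fit),
    class = "fitted_nuisance"
  )
}

#' Fit the mediator (plan size) model
#'
#' Gaussian model for plan size given exposure and confounders — on the log
#' dollar scale for the default `gaussian_log_mediator` family, matching
#' the positive right-skewed distribution of plan budgets.
#'
#' @param data model data (one stratum).
#' @param spec a [model_spec()] whose `outcome` is the mediator column; no
#'   mediator term is allowed in the spec itself.
#' @return a `fitted_nuisance`.
#' @export
fit_mediator_model <- function(data, spec) {
  if (!is.null(spec$mediator)) {
    stop("the mediator model cannot itself contain a mediator term",
         call. = FALSE)
  }
  if (spec$family == "binary_logistic") {
    stop("mediator model must be a Gaussian family", call. = FALSE)
  }
  fit_outcome_model(data, spec)
}

#' @export
print.fitted_nuisance <- function(x, ...) {
  cat("Fitted", x$spec$family, "model for", x$spec$outcome,
      "(n =", x$n, ")\n")
  print(round(x$coef, 4))
  if (!is.na(x$sigma)) cat("residual scale:", round(x$sigma, 4), "\n")
  invisible(x)
}

# ---- prediction and simulation ------------------------------------------------

#' Model-scale expected value for new covariate rows
#'
#' Binary family: predicted probability. Gaussian dollar family: predicted
#' mean. Log-mediator family: predicted mean on the *dollar* scale,
#' `exp(mu + sigma^2 / 2)`.
#'
#' @param model a `fitted_nuisance`.
#' @param newdata covariate rows matching the model terms.
#' @return numeric vector of expected outcomes.
#' @export
predict_mean <- function(model, newdata) {
  stopifnot(inherits(model, "fitted_nuisance"))
  switch(model$spec$family,
    binary_logistic = as.numeric(stats::predict(model$fit, newdata = newdata,
                                                type = "response")),
    gaussian_dollar = as.numeric(stats::predict(model$fit, newdata = newdata)),
    gaussian_log_mediator = {
      mu <- as.numeric(stats::predict(model$fit, newdata = newdata))
      exp(mu + model$sigma^2 / 2)
    }
  )
}

# linear predictor on the model's own scale (logit / log / identity)
predict_lp <- function(model, newdata) {
  as.numeric(stats::predict(model$fit, newdata = newdata))
}

#' Simulate outcome draws from a fitted model
#'
#' Monte Carlo draws at the covariate rows: Bernoulli at the predicted
#' probability for the binary family; Gaussian at the predicted mean with
#' the fitted residual scale for the dollar family; exponentiated Gaussian
#' on the log scale for the log-mediator family. Noise can be supplied
#' (uniforms for the binary family, standard normals otherwise) so that
#' draws are shared across counterfactual arms.
#'
#' @param model a `fitted_nuisance`.
#' @param newdata covariate rows.
#' @param n_draws draws per row (columns of the returned matrix).
#' @param noise optional `nrow(newdata) x n_draws` matrix of uniforms
#'   (binary family) or standard normals (Gaussian families).
#' @return numeric matrix, rows aligned with `newdata`.
#' @export
simulate_from_model <- function(model, newdata, n_draws = 1L, noise = NULL) {
  stopifnot(inherits(model, "fitted_nuisance"))
  n <- nrow(newdata)
  if (!is.null(noise)) {
    noise <- as.matrix(noise)
    if (nrow(noise) != n || ncol(noise) != n_draws) {
      stop("noise must be ", n, " x ", n_draws, call. = FALSE)
    }
  }
  if (model$spec$family == "binary_logistic") {
    p <- as.numeric(stats::predict(model$fit, newdata = newdata,
                                   type = "response"))
    u <- if (is.null(noise)) matrix(stats::runif(n * n_draws), n) else noise
    (u < p) * 1
  } else {
    mu <- as.numeric(stats::predict(model$fit, newdata = newdata))
    z <- if (is.null(noise)) matrix(stats::rnorm(n * n_draws), n) else noise
    draws <- mu + model$sigma * z
    if (model$spec$family == "gaussian_log_mediator") exp(draws) else draws
  }
}

#' Serialise a fitted model to structured text for audit
#'
#' @param model a `fitted_nuisance`.
#' @param path output file path (JSON).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_nuisance"))
  jsonlite::write_json(
    list(outcome = model$spec$outcome, family = model$spec$family,
         terms = names(model$coef), coef = as.list(model$coef),
         sigma = model$sigma, n = model$n, converged = model$converged),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
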