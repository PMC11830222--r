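# ---- causal contrast specification --------------------------------------------

#' Specify a causal contrast
#'
#' Declares the exposure contrast, adjustment set, optional mediator,
#' outcome and reporting scale for g-computation and for the interventional
#' mediation decomposition. The analysis is always run within strata of a
#' stratifier (the broad disability group by default).
#'
#' @param exposure exposure column name (e.g. `"women_girls"`).
#' @param outcome outcome column name.
#' @param outcome_family model family for the outcome (see [model_spec()]).
#' @param confounders character vector of confounder column names.
#' @param comparator,exposure_level the two exposure values contrasted
#'   (defaults `FALSE` / `TRUE` for logical flags).
#' @param mediator optional mediator column name (plan size).
#' @param mediator_family model family for the mediator
#'   (default `"gaussian_log_mediator"`).
#' @param interaction include an exposure x mediator interaction in the
#'   outcome model (default `TRUE` when a mediator is declared).
#' @param scale `"per_1000"` (binary outcomes: eligible applications per
#'   1000 access requests) or `"dollars"`.
#' @param stratifier stratifying column (default `"disability_group"`).
#' @param min_n minimum stratum size (default 50).
#' @return object of class `causal_spec`.
#' @export
causal_spec <- function(exposure, outcome, outcome_family,
                        confounders = character(),
                        comparator = FALSE, exposure_level = TRUE,
                        mediator = NULL,
                        mediator_family = "gaussian_log_mediator",
                        interaction = !is.null(mediator),
                        scale = c("per_1000", "dollars"),
                        stratifier = "disability_group",
                        min_n = 50L) {
  scale <- match.arg(scale)
  if (identical(comparator, exposure_level)) {
    stop("comparator and exposure level must differ", call. = FALSE)
  }
  if (scale == "per_1000" && outcome_family != "binary_logistic") {
    stop("per_1000 scale is only defined for binary outcomes", call. = FALSE)
  }
  structure(
    list(exposure = exposure, outcome = outcome,
         outcome_family = outcome_family, confounders = confounders,
         comparator = comparator, exposure_level = exposure_level,
         mediator = mediator, mediator_family = mediator_family,
         interaction = interaction, scale = scale, stratifier = stratifier,
         min_n = as.integer(min_n)),
    class = "causal_spec"
  )
}

spec_scale_factor <- function(spec) if (spec$scale == "per_1000") 1000 else 1

outcome_model_spec <- function(spec, with_mediator = FALSE) {
  model_spec(
    outcome = spec$outcome, family = spec$outcome_family,
    exposure = spec$exposure, confounders = spec$confounders,
    mediator = if (with_mediator) spec$mediator,
    interaction = with_mediator && spec$interaction,
    min_n = spec$min_n
  )
}

mediator_model_spec <- function(spec) {
  model_spec(
    outcome = spec$mediator, family = spec$mediator_family,
    exposure = spec$exposure, confounders = spec$confounders,
    min_n = spec$min_n
  )
}

split_strata <- function(data, spec) {
  if (is.null(spec$stratifier)) return(list(all = data))
  split(data, data[[spec$stratifier]], drop = TRUE)
}

# stratum-level seeds follow a counter scheme from the root seed, so strata
# are reproducible and mutually independent
stratum_seed <- function(root, i) as.integer(root) + i

set_exposure <- function(data, spec, value) {
  data[[spec$exposure]] <- rep(value, nrow(data))
  data
}

# ---- Monte Carlo g-computation -------------------------------------------------

#' Total causal effect by Monte Carlo simulation-based g-computation
#'
#' Within each stratum: fits the declared outcome model, replicates the
#' stratum's empirical confounder rows (the standard population — both
#' exposure groups combined) with the exposure set to the comparator and
#' the exposure level in turn, simulates `n_mc` outcome draws per row from
#' the fitted model with noise shared across arms, and reports the
#' difference in mean simulated outcome (x 1000 on the `per_1000` scale).
#'
#' Confidence-interval columns are left `NA`; attach them with
#' [bootstrap_ci()] via [tce_estimator()].
#'
#' @param data analytic cohort.
#' @param spec a [causal_spec()] without mediator.
#' @param n_mc Monte Carlo draws per row (default 200).
#' @param seed root seed.
#' @return `data.frame` with one row per stratum: `stratum`, `n`,
#'   `comparator_mean`, `exposure_mean`, `estimate`, `ci_low`, `ci_high`,
#'   `scale`, `n_mc`, `seed`, `note`.
#' @export
estimate_tce <- function(data, spec, n_mc = 200L, seed = 1L) {
  stopifnot(inherits(spec, "causal_spec"))
  if (n_mc < 1) stop("n_mc must be >= 1", call. = FALSE)
  strata <- split_strata(data, spec)
  out <- lapply(seq_along(strata), function(i) {
    d <- strata[[i]]
    nm <- names(strata)[i]
    base <- data.frame(stratum = nm, n = nrow(d), comparator_mean = NA_real_,
                       exposure_mean = NA_real_, estimate = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       scale = spec$scale, n_mc = n_mc,
                       seed = as.integer(seed), note = "",
                       stringsAsFactors = FALSE)
    lv <- unique(d[[spec$exposure]])
    if (length(lv) < 2) {
      base$note <- "not_estimable_single_exposure_level"
      return(base)
    }
    res <- tryCatch(
      tce_stratum(d, spec, n_mc, stratum_seed(seed, i)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      base$note <- "skipped_model_failure_or_small_n"
      return(base)
    }
    base$comparator_mean <- res$m0
    base$exposure_mean <- res$m1
    base$estimate <- res$est
    base
  })
  do.call(rbind, out)
}

tce_stratum <- function(d, spec, n_mc, seed) {
  model <- fit_outcome_model(d, outcome_model_spec(spec))
  n <- nrow(d)
  set.seed(seed)
  noise <- if (spec$outcome_family == "binary_logistic") {
    matrix(stats::runif(n * n_mc), n)
  } else {
    matrix(stats::rnorm(n * n_mc), n)
  }
  y0 <- simulate_from_model(model, set_exposure(d, spec, spec$comparator),
                            n_mc, noise)
  y1 <- simulate_from_model(model, set_exposure(d, spec, spec$exposure_level),
                            n_mc, noise)
  k <- spec_scale_factor(spec)
  list(m0 = mean(y0) * k, m1 = mean(y1) * k, est = (mean(y1) - mean(y0)) * k)
}

#' Deterministic plug-in standardization
#'
#' The noiseless analogue of [estimate_tce()]: averages the fitted model's
#' expected outcome (probability or mean) over the standard population with
#' the exposure set to each level, instead of simulating draws. Used as the
#' simulation-free cross-check of the Monte Carlo estimator and as a fast
#' point estimator inside the bootstrap.
#'
#' @inheritParams estimate_tce
#' @return `data.frame` as in [estimate_tce()] (with `n_mc = 0`).
#' @export
standardize_analytic <- function(data, spec) {
  stopifnot(inherits(spec, "causal_spec"))
  strata <- split_strata(data, spec)
  out <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    base <- data.frame(stratum = nm, n = nrow(d), comparator_mean = NA_real_,
                       exposure_mean = NA_real_, estimate = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       scale = spec$scale, n_mc = 0L, seed = NA_integer_,
                       note = "", stringsAsFactors = FALSE)
    if (length(unique(d[[spec$exposure]])) < 2) {
      base$note <- "not_estimable_single_exposure_level"
      return(base)
    }
    res <- tryCatch({
      model <- fit_outcome_model(d, outcome_model_spec(spec))
      m0 <- mean(predict_mean(model, set_exposure(d, spec, spec$comparator)))
      m1 <- mean(predict_mean(model, set_exposure(d, spec, spec$exposure_level)))
      k <- spec_scale_factor(spec)
      list(m0 = m0 * k, m1 = m1 * k, est = (m1 - m0) * k)
    }, error = function(e) NULL)
    if (is.null(res)) {
      base$note <- "skipped_model_failure_or_small_n"
      return(base)
    }
    base$comparator_mean <- res$m0
    base$exposure_mean <- res$m1
    base$estimate <- res$est
    base
  })
  do.call(rbind, out)
}

#' Point-estimator closure for the bootstrap
#'
#' Wraps [estimate_tce()] (or, with `analytic = TRUE`,
#' [standardize_analytic()]) as a `data -> named numeric` function suitable
#' for [bootstrap_ci()]; names are the stratum labels.
#'
#' @param spec a [causal_spec()].
#' @param n_mc Monte Carlo draws per row.
#' @param seed root seed for the simulation draws.
#' @param analytic use the plug-in standardization (no simulation noise).
#' @return function of one argument (a data.frame) returning a named
#'   numeric vector of stratum estimates.
#' @export
tce_estimator <- function(spec, n_mc = 200L, seed = 1L, analytic = FALSE) {
  force(spec); force(n_mc); force(seed); force(analytic)
  function(data) {
    tab <- if (analytic) standardize_analytic(data, spec)
           else estimate_tce(data, spec, n_mc = n_mc, seed = seed)
    stats::setNames(tab$estimate, tab$stratum)
  }
}
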