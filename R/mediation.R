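# ---- interventional mediation decomposition ------------------------------------

# mediator slope of the outcome model for a given exposure value:
# bM (+ interaction coefficient when the row is at the exposure level)
mediator_slope <- function(out_model, spec, a_is_exposed) {
  cf <- out_model$coef
  m <- spec$mediator
  bM <- cf[[m]]
  if (is.null(bM) || is.na(bM)) stop("outcome model has no mediator term",
                                     call. = FALSE)
  inter <- grep(paste0("(^|:)", m, "($|:)"), names(cf), value = TRUE)
  inter <- setdiff(inter, m)
  bAM <- if (length(inter)) sum(cf[inter]) else 0
  bM + if (a_is_exposed) bAM else 0
}

# mean outcome of one simulated arm given shared noise matrices
arm_mean <- function(d, spec, med_model, out_model, a_value, m_draws, zY,
                     clamp_to_plan = FALSE) {
  pop <- set_exposure(d, spec, a_value)
  pop[[spec$mediator]] <- 0
  mu0 <- predict_lp(out_model, pop)  # identity link for the dollar family
  slope <- mediator_slope(out_model, spec,
                          identical(a_value, spec$exposure_level))
  y <- mu0 + slope * m_draws + out_model$sigma * zY
  if (clamp_to_plan) y <- pmin(y, m_draws)
  mean(y)
}

#' Decompose the spending inequality into interventional direct and
#' indirect effects
#'
#' Emulates, within each stratum, the three-arm target trial on the
#' stratum's standard population: arm 1 sets the exposure to the comparator
#' level with plan size drawn from the fitted mediator model at that level;
#' arm 2 sets the exposure to the exposure level with plan size drawn at
#' that level; arm 3 sets the exposure to the exposure level while shifting
#' its plan-size distribution to the comparator level's conditional
#' distribution given the confounders. Then TCE = mean2 - mean1,
#' IIE = mean2 - mean3 (the spending difference attributable to plan-size
#' allocation) and IDE = mean3 - mean1. Mediator and outcome noise draws
#' are shared across arms, so TCE = IDE + IIE holds to machine precision.
#'
#' @param data analytic participant cohort.
#' @param spec a [causal_spec()] with a `mediator` and a continuous outcome
#'   family.
#' @param n_mc Monte Carlo draws per row (default 200).
#' @param seed root seed.
#' @param clamp_to_plan clamp simulated spending at the simulated plan size
#'   (off by default: the fitted spending model owns that relationship; the
#'   flag is echoed in the output).
#' @return `data.frame`, one row per stratum: `stratum`, `n`,
#'   `comparator_mean`, `tce`, `ide`, `iie`, CI columns (`NA` until
#'   bootstrapped), `scale`, `n_mc`, `seed`, `clamped`, `note`.
#' @export
decompose <- function(data, spec, n_mc = 200L, seed = 1L,
                      clamp_to_plan = FALSE) {
  stopifnot(inherits(spec, "causal_spec"))
  if (is.null(spec$mediator)) stop("spec has no mediator", call. = FALSE)
  if (spec$outcome_family == "binary_logistic") {
    stop("mediation decomposition requires a continuous outcome family",
         call. = FALSE)
  }
  if (n_mc < 1) stop("n_mc must be >= 1", call. = FALSE)
  strata <- split_strata(data, spec)
  out <- lapply(seq_along(strata), function(i) {
    d <- strata[[i]]
    nm <- names(strata)[i]
    base <- data.frame(stratum = nm, n = nrow(d), comparator_mean = NA_real_,
                       tce = NA_real_, ide = NA_real_, iie = NA_real_,
                       tce_ci_low = NA_real_, tce_ci_high = NA_real_,
                       ide_ci_low = NA_real_, ide_ci_high = NA_real_,
                       iie_ci_low = NA_real_, iie_ci_high = NA_real_,
                       scale = spec$scale, n_mc = n_mc,
                       seed = as.integer(seed), clamped = clamp_to_plan,
                       note = "", stringsAsFactors = FALSE)
    if (length(unique(d[[spec$exposure]])) < 2) {
      base$note <- "not_estimable_single_exposure_level"
      return(base)
    }
    res <- tryCatch(
      decompose_stratum(d, spec, n_mc, stratum_seed(seed, i), clamp_to_plan),
      error = function(e) NULL
    )
    if (is.null(res)) {
      base$note <- "skipped_model_failure_or_small_n"
      return(base)
    }
    base$comparator_mean <- res$m1
    base$tce <- res$tce
    base$ide <- res$ide
    base$iie <- res$iie
    base
  })
  do.call(rbind, out)
}

decompose_stratum <- function(d, spec, n_mc, seed, clamp_to_plan = FALSE) {
  med_model <- fit_mediator_model(d, mediator_model_spec(spec))
  if (!is.na(med_model$sigma) && med_model$sigma == 0) {
    stop("degenerate mediator variance", call. = FALSE)
  }
  out_model <- fit_outcome_model(d, outcome_model_spec(spec, TRUE))
  n <- nrow(d)
  set.seed(seed)
  zM <- matrix(stats::rnorm(n * n_mc), n)
  zY <- matrix(stats::rnorm(n * n_mc), n)

  m_comp <- simulate_from_model(med_model,
                                set_exposure(d, spec, spec$comparator),
                                n_mc, zM)
  m_exp <- simulate_from_model(med_model,
                               set_exposure(d, spec, spec$exposure_level),
                               n_mc, zM)

  m1 <- arm_mean(d, spec, med_model, out_model, spec$comparator, m_comp, zY,
                 clamp_to_plan)
  m2 <- arm_mean(d, spec, med_model, out_model, spec$exposure_level, m_exp, zY,
                 clamp_to_plan)
  m3 <- arm_mean(d, spec, med_model, out_model, spec$exposure_level, m_comp, zY,
                 clamp_to_plan)
  list(m1 = m1, m2 = m2, m3 = m3,
       tce = m2 - m1, ide = m3 - m1, iie = m2 - m3)
}

#' Mean outcome of one arm of the three-arm target trial
#'
#' Simulates a single arm: the exposure is set to `exposure_setting`, and
#' plan size is drawn from the fitted mediator model at
#' `mediator_source_setting` (conditional on the population's confounders).
#'
#' @param models list with elements `mediator` and `outcome`
#'   (`fitted_nuisance` objects; the outcome model must include the
#'   mediator).
#' @param exposure_setting `"comparator"` or `"exposure"`.
#' @param mediator_source_setting `"comparator"` or `"exposure"`.
#' @param population standard-population covariate rows.
#' @param spec the [causal_spec()].
#' @param n_mc draws per row.
#' @param seed integer seed (the result is deterministic given the seed).
#' @return scalar Monte Carlo mean outcome.
#' @export
simulate_arm <- function(models, exposure_setting, mediator_source_setting,
                         population, spec, n_mc = 200L, seed = 1L) {
  exposure_setting <- match.arg(exposure_setting, c("comparator", "exposure"))
  mediator_source_setting <- match.arg(mediator_source_setting,
                                       c("comparator", "exposure"))
  a_val <- function(s) if (s == "comparator") spec$comparator else spec$exposure_level
  n <- nrow(population)
  set.seed(as.integer(seed))
  zM <- matrix(stats::rnorm(n * n_mc), n)
  zY <- matrix(stats::rnorm(n * n_mc), n)
  m_draws <- simulate_from_model(
    models$mediator,
    set_exposure(population, spec, a_val(mediator_source_setting)),
    n_mc, zM
  )
  arm_mean(population, spec, models$mediator, models$outcome,
           a_val(exposure_setting), m_draws, zY)
}

#' Point-estimator closure for bootstrapping the decomposition
#'
#' Wraps [decompose()] as a `data -> named numeric` function for
#' [bootstrap_ci()]; names are `<stratum>.tce`, `<stratum>.ide`,
#' `<stratum>.iie`.
#'
#' @inheritParams decompose
#' @return function of one argument (a data.frame) returning a named
#'   numeric vector.
#' @export
decomposition_estimator <- function(spec, n_mc = 200L, seed = 1L,
                                    clamp_to_plan = FALSE) {
  force(spec); force(n_mc); force(seed); force(clamp_to_plan)
  function(data) {
    tab <- decompose(data, spec, n_mc = n_mc, seed = seed,
                     clamp_to_plan = clamp_to_plan)
    vals <- c(rbind(tab$tce, tab$ide, tab$iie))
    names(vals) <- as.vector(t(outer(tab$stratum, c("tce", "ide", "iie"),
                                     paste, sep = ".")))
    vals
  }
}
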