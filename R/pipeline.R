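# ---- run configuration -----------------------------------------------------------

#' Configuration for a full pipeline run
#'
#' Ties the stages together: synthetic generation (or externally supplied
#' tables), cohort construction, g-computation of total causal effects, the
#' interventional mediation decomposition for spending, and bootstrap
#' confidence intervals.
#'
#' Age-related inequality is examined for eligibility only (support needs
#' rise with age, so age inequality in plan allocation and use is not a
#' meaningful contrast); requesting the `age_55plus` exposure for the
#' plan/spend analysis is a validation error.
#'
#' @param analysis `"eligibility"`, `"plan_spend"` or `"both"`.
#' @param exposures exposures to run, subset of
#'   `c("women_girls", "low_ses", "age_55plus")`.
#' @param synth a [synth_config()] used to generate inputs, or `NULL` when
#'   `applications` / `participants` paths are given.
#' @param applications,participants optional CSV paths for externally
#'   supplied unit-record tables.
#' @param n_mc Monte Carlo draws per row.
#' @param boot a [bootstrap_config()], or `NULL` to skip interval
#'   estimation.
#' @param seed root seed for estimation.
#' @param cutoff_date participant-cohort cutoff date.
#' @param suppression_threshold minimum stratum cell size for disclosure
#'   (estimates for smaller cells are suppressed in written outputs).
#' @param output_dir directory for [write_results()].
#' @return object of class `run_config`.
#' @export
run_config <- function(analysis = c("both", "eligibility", "plan_spend"),
                       exposures = c("women_girls", "low_ses"),
                       synth = synth_config(),
                       applications = NULL, participants = NULL,
                       n_mc = 200L, boot = NULL, seed = 1L,
                       cutoff_date = as.Date("2022-08-31"),
                       suppression_threshold = 15L,
                       output_dir = "results") {
  analysis <- match.arg(analysis)
  exposures <- match.arg(exposures, c("women_girls", "low_ses", "age_55plus"),
                         several.ok = TRUE)
  if (analysis == "plan_spend" && "age_55plus" %in% exposures) {
    stop("the age_55plus exposure is defined for the eligibility analysis only",
         call. = FALSE)
  }
  structure(
    list(analysis = analysis, exposures = exposures, synth = synth,
         applications = applications, participants = participants,
         n_mc = as.integer(n_mc), boot = boot, seed = as.integer(seed),
         cutoff_date = as.Date(cutoff_date),
         suppression_threshold = as.integer(suppression_threshold),
         output_dir = output_dir),
    class = "run_config"
  )
}

eligibility_confounders <- function() "prior_support"

plan_spend_confounders <- function() {
  c("age_band", "remoteness", "severity_band", "years_band",
    "ypirac", "sil", "sda", "trial_plan", "prior_support")
}

# ---- pipeline ---------------------------------------------------------------------

#' Run the full inequality analysis pipeline
#'
#' For each requested exposure: the eligibility analysis estimates, per
#' disability group, the total causal effect of the exposure on eligibility
#' (eligible applications per 1000 access requests, adjusted for prior
#' source of disability support); the plan/spend analysis estimates total
#' causal effects on annualised plan size and spending in dollars (adjusted
#' for age, remoteness, disability severity, years in the scheme,
#' accommodation-program participation and prior support source) and
#' decomposes the spending effect into interventional direct and indirect
#' effects with plan size as mediator.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `eligibility`, `plan`, `spend`
#'   result tables, exclusion `logs`, and the echoed `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  logs <- list()
  result <- list(eligibility = NULL, plan = NULL, spend = NULL)

  if (config$analysis %in% c("eligibility", "both")) {
    apps <- if (!is.null(config$applications)) {
      read_records(config$applications)
    } else {
      generate_applications(config$synth)
    }
    coh <- filter_eligibility_cohort(apps)
    logs$eligibility <- coh$log
    d <- coh$data
    d$disability_group <- map_disability_group(d$primary_disability_code)
    d <- derive_exposures(d, "age_at_decision")
    d$eligible <- d$decision_type == "access_met"

    elig <- lapply(config$exposures, function(expo) {
      spec <- causal_spec(
        exposure = expo, outcome = "eligible",
        outcome_family = "binary_logistic",
        confounders = eligibility_confounders(), scale = "per_1000"
      )
      tab <- estimate_tce(d, spec, n_mc = config$n_mc, seed = config$seed)
      if (!is.null(config$boot)) {
        boot <- bootstrap_ci(tce_estimator(spec, n_mc = config$n_mc,
                                           seed = config$seed),
                             d, config$boot)
        tab <- attach_ci(tab, boot)
      }
      cbind(exposure = expo, tab, stringsAsFactors = FALSE)
    })
    result$eligibility <- do.call(rbind, elig)
  }

  if (config$analysis %in% c("plan_spend", "both")) {
    expos <- setdiff(config$exposures, "age_55plus")
    parts <- if (!is.null(config$participants)) {
      read_records(config$participants)
    } else {
      generate_participants(config$synth)
    }
    coh <- filter_participant_cohort(parts, config$cutoff_date)
    logs$plan_spend <- coh$log
    d <- coh$data
    d$disability_group <- map_disability_group(d$primary_disability_code)
    d <- derive_exposures(d, "age_at_plan_start")
    d$plan_ann <- annualize(d$plan_amount, d$plan_days)
    d$spend_ann <- annualize(d$spend_amount, d$plan_days)

    plan_rows <- list(); spend_rows <- list()
    for (expo in expos) {
      conf <- setdiff(plan_spend_confounders(), character())
      plan_spec <- causal_spec(
        exposure = expo, outcome = "plan_ann",
        outcome_family = "gaussian_log_mediator",
        confounders = conf, scale = "dollars"
      )
      tab <- estimate_tce(d, plan_spec, n_mc = config$n_mc, seed = config$seed)
      if (!is.null(config$boot)) {
        boot <- bootstrap_ci(tce_estimator(plan_spec, n_mc = config$n_mc,
                                           seed = config$seed),
                             d, config$boot)
        tab <- attach_ci(tab, boot)
      }
      plan_rows[[expo]] <- cbind(exposure = expo, tab, stringsAsFactors = FALSE)

      spend_spec <- causal_spec(
        exposure = expo, outcome = "spend_ann",
        outcome_family = "gaussian_dollar", confounders = conf,
        mediator = "plan_ann", scale = "dollars"
      )
      dec <- decompose(d, spend_spec, n_mc = config$n_mc, seed = config$seed)
      if (!is.null(config$boot)) {
        boot <- bootstrap_ci(decomposition_estimator(spend_spec,
                                                     n_mc = config$n_mc,
                                                     seed = config$seed),
                             d, config$boot)
        dec <- attach_decomposition_ci(dec, boot)
      }
      spend_rows[[expo]] <- cbind(exposure = expo, dec, stringsAsFactors = FALSE)
    }
    result$plan <- do.call(rbind, plan_rows)
    result$spend <- do.call(rbind, spend_rows)
  }

  structure(
    list(eligibility = result$eligibility, plan = result$plan,
         spend = result$spend, logs = logs, config = config),
    class = "pipeline_result"
  )
}

read_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(c("decision_date", "plan_start"), names(d))) {
    d[[col]] <- as.Date(d[[col]])
  }
  d
}

#' Write unit-record tables as delimited text
#'
#' Comma-separated, header row, UTF-8, ISO-8601 dates.
#'
#' @param data a record `data.frame`.
#' @param path output CSV path.
#' @export
write_records <- function(data, path) {
  d <- data
  for (col in names(d)) if (inherits(d[[col]], "Date")) {
    d[[col]] <- format(d[[col]], "%Y-%m-%d")
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

# ---- output -----------------------------------------------------------------------

suppress_small_cells <- function(tab, threshold) {
  if (is.null(tab)) return(NULL)
  small <- !is.na(tab$n) & tab$n < threshold
  est_cols <- intersect(
    c("comparator_mean", "exposure_mean", "estimate", "ci_low", "ci_high",
      "tce", "ide", "iie", "tce_ci_low", "tce_ci_high", "ide_ci_low",
      "ide_ci_high", "iie_ci_low", "iie_ci_high"),
    names(tab)
  )
  tab[small, est_cols] <- NA_real_
  if (any(small)) tab$note[small] <- "suppressed_small_cell"
  tab
}

#' Write pipeline results, exclusion logs and run metadata
#'
#' Writes the eligibility table (stratum, comparator rate and difference per
#' 1000 with CIs), the plan-size table and the spending decomposition table
#' (comparator spending, total effect, interventional indirect and direct
#' effects) as CSVs, plus exclusion logs and a JSON metadata file echoing
#' the configuration and seeds so results are self-describing. Small-cell
#' suppression (cells below the disclosure threshold, default 15) is
#' applied to the written tables only, after estimation. Re-running the
#' writer produces identical bytes.
#'
#' @param results a `pipeline_result` from [run_pipeline()].
#' @param directory output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, directory = results$config$output_dir) {
  stopifnot(inherits(results, "pipeline_result"))
  if (is.null(results$eligibility) && is.null(results$plan) &&
      is.null(results$spend)) {
    stop("nothing to write: empty results", call. = FALSE)
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  thr <- results$config$suppression_threshold
  paths <- character()
  tabs <- list(eligibility = results$eligibility, plan = results$plan,
               spend = results$spend)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(directory, paste0(nm, "_effects.csv"))
    utils::write.csv(suppress_small_cells(tabs[[nm]], thr), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(results$logs)) {
    p <- file.path(directory, paste0("exclusion_log_", nm, ".csv"))
    write_exclusion_log(results$logs[[nm]], p)
    paths <- c(paths, p)
  }
  cfg <- results$config
  meta <- list(
    analysis = cfg$analysis, exposures = cfg$exposures, seed = cfg$seed,
    n_mc = cfg$n_mc,
    n_boot = if (!is.null(cfg$boot)) cfg$boot$n_boot else 0L,
    boot_seed = if (!is.null(cfg$boot)) cfg$boot$seed else NA,
    cutoff_date = format(cfg$cutoff_date, "%Y-%m-%d"),
    suppression_threshold = cfg$suppression_threshold,
    synth_seed = if (!is.null(cfg$synth)) cfg$synth$seed else NA,
    package_version = as.character(utils::packageVersion("ndisineq"))
  )
  p <- file.path(directory, "run_metadata.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
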