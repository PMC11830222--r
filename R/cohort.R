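# ---- exclusion log ----------------------------------------------------------

new_exclusion_log <- function(n_input) {
  structure(
    data.frame(step = character(), n_removed = integer(),
               n_remaining = integer(), stringsAsFactors = FALSE),
    n_input = n_input, class = c("exclusion_log", "data.frame")
  )
}

log_step <- function(log, step, n_before, n_after) {
  row <- data.frame(step = step, n_removed = n_before - n_after,
                    n_remaining = n_after, stringsAsFactors = FALSE)
  out <- rbind(as.data.frame(log), row)
  attr(out, "n_input") <- attr(log, "n_input")
  class(out) <- c("exclusion_log", "data.frame")
  out
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Exclusion flow (input n =", attr(x, "n_input"), ")\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-28s removed %8d, remaining %8d\n",
                x$step[i], x$n_removed[i], x$n_remaining[i]))
  }
  invisible(x)
}

# ---- eligibility cohort ------------------------------------------------------

#' Apply the eligibility-analysis inclusion rules
#'
#' Filters an application table to the analytic eligibility cohort, in
#' order: rows with a recorded decision type; applicants aged 7 years or
#' older at the decision date; the most recent access request per applicant
#' (latest decision date, ties broken by row order); decided applications
#' only (access met / not met — cancelled, withdrawn, in-progress and
#' revoked/ceased requests are excluded); and complete socio-demographic
#' information. Each rule contributes one line to the exclusion log, whose
#' counts always conserve the input total.
#'
#' @param applications application-record `data.frame`.
#' @return list with `data` (the analytic table) and `log` (an
#'   `exclusion_log`).
#' @export
filter_eligibility_cohort <- function(applications) {
  x <- applications
  x$.seq <- seq_len(nrow(x))
  log <- new_exclusion_log(nrow(x))

  keep <- !is.na(x$decision_type)
  log <- log_step(log, "missing_decision_type", nrow(x), sum(keep))
  x <- x[keep, , drop = FALSE]

  keep <- x$age_at_decision >= 7
  log <- log_step(log, "age_under_7", nrow(x), sum(keep))
  x <- x[keep, , drop = FALSE]

  if (nrow(x) > 0) {
    # most recent request per applicant: latest date, then highest sequence
    ord <- order(x$applicant_id, x$decision_date, x$.seq)
    x <- x[ord, , drop = FALSE]
    last <- !duplicated(x$applicant_id, fromLast = TRUE)
    log <- log_step(log, "earlier_duplicate_requests", nrow(x), sum(last))
    x <- x[last, , drop = FALSE]
  } else {
    log <- log_step(log, "earlier_duplicate_requests", 0L, 0L)
  }

  keep <- x$decision_type %in% c("access_met", "access_not_met")
  log <- log_step(log, "undecided_application", nrow(x), sum(keep))
  x <- x[keep, , drop = FALSE]

  keep <- x$demographics_complete
  log <- log_step(log, "incomplete_demographics", nrow(x), sum(keep))
  x <- x[keep, , drop = FALSE]

  x <- x[order(x$.seq), , drop = FALSE]
  x$.seq <- NULL
  rownames(x) <- NULL
  list(data = x, log = log)
}

# ---- participant cohort ------------------------------------------------------

#' Apply the plan-size and spending analysis inclusion rules
#'
#' Keeps active participants' most recent plan that was completed by the
#' cutoff date and covered more than 180 days of support (strict
#' inequality), for participants aged 7 years or older at plan start.
#'
#' @param participants participant-record `data.frame`.
#' @param cutoff_date the analysis cutoff date (`Date` or string).
#' @return list with `data` and `log` (an `exclusion_log`).
#' @export
filter_participant_cohort <- function(participants,
                                      cutoff_date = as.Date("2022-08-31")) {
  cutoff_date <- as.Date(cutoff_date)
  x <- participants
  if (nrow(x) > 0 && any(is.na(x$plan_days) | x$plan_days <= 0)) {
    stop("plan_days must be positive for every plan", call. = FALSE)
  }
  x$.seq <- seq_len(nrow(x))
  log <- new_exclusion_log(nrow(x))

  keep <- x$age_at_plan_start >= 7
  log <- log_step(log, "age_under_7", nrow(x), sum(keep))
  x <- x[keep, , drop = FALSE]

  keep <- if ("active" %in% names(x)) x$active else rep(TRUE, nrow(x))
  log <- log_step(log, "not_active_at_cutoff", nrow(x), sum(keep))
  x <- x[keep, , drop = FALSE]

  keep <- as.Date(x$plan_start) + x$plan_days <= cutoff_date
  log <- log_step(log, "plan_not_completed", nrow(x), sum(keep))
  x <- x[keep, , drop = FALSE]

  keep <- x$plan_days > 180
  log <- log_step(log, "plan_180_days_or_less", nrow(x), sum(keep))
  x <- x[keep, , drop = FALSE]

  if (nrow(x) > 0) {
    ord <- order(x$participant_id, as.Date(x$plan_start), x$.seq)
    x <- x[ord, , drop = FALSE]
    last <- !duplicated(x$participant_id, fromLast = TRUE)
    log <- log_step(log, "earlier_plans", nrow(x), sum(last))
    x <- x[last, , drop = FALSE]
  } else {
    log <- log_step(log, "earlier_plans", 0L, 0L)
  }

  x <- x[order(x$.seq), , drop = FALSE]
  x$.seq <- NULL
  rownames(x) <- NULL
  list(data = x, log = log)
}

# ---- disability-group mapping ------------------------------------------------

#' Mapping from primary disability codes to the seven analysis groups
#'
#' The scheme's primary disability types grouped to match the broad
#' disability groups used by the national disability survey: sensory;
#' autism (kept separate because it is the scheme's largest primary
#' disability group); intellectual disability other than autism; physical;
#' psychosocial; brain injury or stroke; and other.
#'
#' @return `data.frame` with columns `code` and `group`.
#' @export
disability_group_map <- function() {
  data.frame(
    code = c("visual_impairment", "hearing_impairment", "other_sensory_speech",
             "autism",
             "intellectual_disability", "trisomy_21", "developmental_delay",
             "global_developmental_delay",
             "cerebral_palsy", "spinal_cord_injury", "other_physical",
             "psychosocial",
             "acquired_brain_injury", "stroke",
             "other", "multiple_sclerosis", "other_neurological"),
    group = c(rep("sensory", 3),
              "autism",
              rep("intellectual_other", 4),
              rep("physical", 3),
              "psychosocial",
              rep("brain_injury_stroke", 2),
              rep("other", 3)),
    stringsAsFactors = FALSE
  )
}

#' Map primary disability codes to broad analysis groups
#'
#' @param code character vector of primary disability codes.
#' @return character vector of groups in \{sensory, autism,
#'   intellectual_other, physical, psychosocial, brain_injury_stroke,
#'   other\}.
#' @export
map_disability_group <- function(code) {
  m <- disability_group_map()
  idx <- match(code, m$code)
  if (anyNA(idx)) {
    bad <- unique(code[is.na(idx)])
    stop("unknown primary disability code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m$group[idx]
}

# ---- exposures and annualisation --------------------------------------------

#' Derive the three inequality-group exposure flags
#'
#' Adds logical columns: `women_girls` (self-reported gender), `low_ses`
#' (residence in the three lowest deciles of the Index of Relative
#' Socioeconomic Disadvantage) and `age_55plus` (aged 55 years or older at
#' the reference date — the eligibility decision date for applicants, plan
#' start for participants).
#'
#' @param data a record `data.frame` with `gender`, `irsd_decile` and an
#'   age column.
#' @param age_col name of the age column (default `"age_at_decision"`).
#' @return `data` with the three flag columns appended.
#' @export
derive_exposures <- function(data, age_col = "age_at_decision") {
  stopifnot(all(c("gender", "irsd_decile", age_col) %in% names(data)))
  data$women_girls <- data$gender == "women_girls"
  data$low_ses <- data$irsd_decile <= 3
  data$age_55plus <- data[[age_col]] >= 55
  data
}

#' Annualise a dollar amount
#'
#' Converts a plan-period dollar amount to dollars per year using a
#' 365.25-day year: `amount * 365.25 / plan_days`.
#'
#' @param amount dollars over the plan period.
#' @param plan_days plan duration in days (> 0).
#' @return annualised dollars.
#' @export
annualize <- function(amount, plan_days) {
  if (any(is.na(plan_days) | plan_days <= 0)) {
    stop("plan_days must be positive", call. = FALSE)
  }
  amount * 365.25 / plan_days
}

#' Write an exclusion log as a machine-readable table
#'
#' @param log an `exclusion_log`.
#' @param path output CSV path.
#' @export
write_exclusion_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE)
  invisible(path)
}
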