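# ---- published composition tables ----------------------------------------------

#' Published cohort composition counts
#'
#' The socio-demographic and disability composition counts printed for the
#' 485 676 applicants in the eligibility analysis
#' (`applicant_composition()`) and for the 312 268 active participants in
#' the plan-size and spending analysis, by gender stratum and by
#' area-disadvantage stratum (`participant_composition()`). Cells the
#' source suppressed for privacy (counts below 15) or printed only as
#' "< 0.1%" are omitted.
#'
#' @return `data.frame` with columns `section`, `characteristic`, `n`,
#'   `printed_pct`, `denominator` (plus `stratum` for participants).
#' @export
applicant_composition <- function() {
  utils::read.csv(
    system.file("extdata", "applicant_composition.csv", package = "ndisineq"),
    stringsAsFactors = FALSE
  )
}

#' @rdname applicant_composition
#' @export
participant_composition <- function() {
  utils::read.csv(
    system.file("extdata", "participant_composition.csv", package = "ndisineq"),
    stringsAsFactors = FALSE
  )
}

# publication rounding: half away from zero at d decimals
round_half_up <- function(x, d = 1) floor(x * 10^d + 0.5) / 10^d

#' Recompute composition percentages from counts
#'
#' Computes each cell's percentage from its count and stratum denominator,
#' rounded (half up) to the printed precision, and flags agreement with the
#' printed percentage.
#'
#' @param tbl a composition table from [applicant_composition()] or
#'   [participant_composition()].
#' @param digits decimal places of the printed percentages (default 1).
#' @return `tbl` with `recomputed_pct` and logical `matches_printed`
#'   appended.
#' @export
recompute_percentages <- function(tbl, digits = 1) {
  stopifnot(all(c("n", "printed_pct", "denominator") %in% names(tbl)))
  tbl$recomputed_pct <- round_half_up(100 * tbl$n / tbl$denominator, digits)
  tbl$matches_printed <- abs(tbl$recomputed_pct - tbl$printed_pct) < 1e-9
  tbl
}
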