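# ---- nonparametric bootstrap ----------------------------------------------------

#' Bootstrap configuration
#'
#' @param n_boot number of bootstrap replicates (default 200; raise to 1000
#'   for production runs).
#' @param seed root seed; replicate-level seeds are derived from it.
#' @param stratified resample within strata of `stratifier` (default TRUE).
#' @param stratifier stratifying column for resampling.
#' @param keep_replicates return the replicate-level estimates for
#'   diagnostics.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_boot = 200L, seed = 1L, stratified = TRUE,
                             stratifier = "disability_group",
                             keep_replicates = FALSE) {
  if (n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  structure(
    list(n_boot = as.integer(n_boot), seed = as.integer(seed),
         stratified = stratified, stratifier = stratifier,
         keep_replicates = keep_replicates),
    class = "bootstrap_config"
  )
}

resample_within_strata <- function(data, stratifier) {
  idx <- unlist(lapply(split(seq_len(nrow(data)), data[[stratifier]]),
                       function(i) i[sample.int(length(i), length(i),
                                                replace = TRUE)]),
                use.names = FALSE)
  data[idx, , drop = FALSE]
}

#' Percentile-bootstrap confidence intervals for any pipeline estimator
#'
#' Resamples records with replacement (within disability stratum when
#' `stratified`), re-runs the full fit-and-simulate estimator on every
#' replicate — so the intervals reflect nuisance-model estimation
#' uncertainty end-to-end — and returns 2.5th/97.5th percentile bounds.
#' Replicates in which the estimator fails are dropped and counted; more
#' than 10% failures is an error.
#'
#' @param estimator a `data -> named numeric` function (see
#'   [tce_estimator()], [decomposition_estimator()]).
#' @param data the analytic cohort.
#' @param config a [bootstrap_config()].
#' @return list with `point`, `ci_low`, `ci_high` (named numeric vectors),
#'   `n_boot`, `n_failed`, and `replicates` (matrix, when requested).
#' @export
bootstrap_ci <- function(estimator, data, config = bootstrap_config()) {
  stopifnot(is.function(estimator), nrow(data) > 0)
  point <- estimator(data)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, config$n_boot)
  reps <- vector("list", config$n_boot)
  for (b in seq_len(config$n_boot)) {
    set.seed(rep_seeds[b])
    d <- if (config$stratified && config$stratifier %in% names(data)) {
      resample_within_strata(data, config$stratifier)
    } else {
      data[sample.int(nrow(data), nrow(data), replace = TRUE), , drop = FALSE]
    }
    reps[[b]] <- tryCatch(estimator(d), error = function(e) NULL)
  }
  ok <- !vapply(reps, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.10 * config$n_boot) {
    stop("estimator failed in ", n_failed, " of ", config$n_boot,
         " bootstrap replicates", call. = FALSE)
  }
  mat <- do.call(rbind, reps[ok])
  # align on the point estimate's names; replicates may drop strata
  if (!is.null(names(point))) mat <- mat[, names(point), drop = FALSE]
  ci <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE, names = FALSE)
  out <- list(point = point,
              ci_low = stats::setNames(ci[1, ], names(point)),
              ci_high = stats::setNames(ci[2, ], names(point)),
              n_boot = config$n_boot, n_failed = n_failed)
  if (config$keep_replicates) out$replicates <- mat
  out
}

#' Write replicate-level bootstrap estimates for diagnostics
#'
#' @param boot result of [bootstrap_ci()] run with `keep_replicates = TRUE`.
#' @param path output CSV path.
#' @export
write_replicates <- function(boot, path) {
  if (is.null(boot$replicates)) {
    stop("bootstrap was run without keep_replicates = TRUE", call. = FALSE)
  }
  utils::write.csv(as.data.frame(boot$replicates), path, row.names = FALSE)
  invisible(path)
}

# attach bootstrap bounds to an estimate table produced by estimate_tce()
attach_ci <- function(tab, boot) {
  idx <- match(tab$stratum, names(boot$point))
  tab$ci_low <- boot$ci_low[idx]
  tab$ci_high <- boot$ci_high[idx]
  tab
}

attach_decomposition_ci <- function(tab, boot) {
  for (eff in c("tce", "ide", "iie")) {
    idx <- match(paste(tab$stratum, eff, sep = "."), names(boot$point))
    tab[[paste0(eff, "_ci_low")]] <- boot$ci_low[idx]
    tab[[paste0(eff, "_ci_high")]] <- boot$ci_high[idx]
  }
  tab
}
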