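#!/usr/bin/env Rscript
# Stage 4: plan-size and spending inequality, with the interventional
# mediation decomposition.
#
# For women/girls and low-SES participants: the total causal effect on
# annualised plan size and on spending (dollars), adjusted for age,
# remoteness, severity, years in the scheme, accommodation-program flags
# and prior support; and the decomposition of the spending effect into the
# interventional indirect effect (the part attributable to plan-size
# allocation) and the interventional direct effect (spending differences at
# matched plan-size distributions). Age-related inequality is examined for
# eligibility only.

library(ndisineq)

seed <- 20220831L
d <- ndisineq:::read_records("results/cohort/participant_cohort.csv")
for (col in c("women_girls", "low_ses", "ypirac", "sil", "sda", "trial_plan"))
  d[[col]] <- as.logical(d[[col]])

conf <- c("age_band", "remoteness", "severity_band", "years_band",
          "ypirac", "sil", "sda", "trial_plan", "prior_support")
plan_rows <- list(); spend_rows <- list()
for (expo in c("women_girls", "low_ses")) {
  pspec <- causal_spec(expo, "plan_ann", "gaussian_log_mediator",
                       confounders = conf, scale = "dollars")
  ptab <- estimate_tce(d, pspec, n_mc = 100, seed = seed)
  plan_rows[[expo]] <- cbind(exposure = expo, ptab, stringsAsFactors = FALSE)

  sspec <- causal_spec(expo, "spend_ann", "gaussian_dollar",
                       confounders = conf, mediator = "plan_ann",
                       scale = "dollars")
  dec <- decompose(d, sspec, n_mc = 100, seed = seed)
  spend_rows[[expo]] <- cbind(exposure = expo, dec, stringsAsFactors = FALSE)
  worst <- which.max(abs(dec$tce))
  cat(sprintf(
    "%s, %s: spending TCE $%.0f = IDE $%.0f + IIE $%.0f (comparator $%.0f)\n",
    expo, dec$stratum[worst], dec$tce[worst], dec$ide[worst],
    dec$iie[worst], dec$comparator_mean[worst]))
}

dir.create("results/effects", recursive = TRUE, showWarnings = FALSE)
utils::write.csv(do.call(rbind, plan_rows),
                 "results/effects/plan_effects.csv", row.names = FALSE)
utils::write.csv(do.call(rbind, spend_rows),
                 "results/effects/spend_decomposition.csv", row.names = FALSE)

gap <- max(abs(do.call(rbind, spend_rows)$tce -
                 (do.call(rbind, spend_rows)$ide +
                    do.call(rbind, spend_rows)$iie)), na.rm = TRUE)
cat("max additivity gap across strata:", gap, "(exact by construction)\n")
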