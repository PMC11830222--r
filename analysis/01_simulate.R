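#!/usr/bin/env Rscript
# Stage 1: generate the synthetic unit-record tables the analysis runs on.
#
# Two tables are written under results/data/: access requests (with decision
# types and the socio-demographic columns used by the eligibility analysis)
# and active participants (with plan and spending dollars generated from a
# known-truth causal structure: the exposure lowers eligibility and plan
# size, and raises budget utilization slightly).

library(ndisineq)

seed <- 20220831L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(n_applications = 100000, n_participants = 60000,
                    seed = seed)
write_synth_config(cfg, "results/data/synth_config.json")

apps <- generate_applications(cfg)
parts <- generate_participants(cfg)
write_records(apps, "results/data/applications.csv")
write_records(parts, "results/data/participants.csv")

cat("applications:", nrow(apps), "rows;",
    sprintf("%.1f%%", 100 * mean(apps$decision_type %in%
                                   c("access_met", "access_not_met"))),
    "decided\n")
cat("participants:", nrow(parts), "rows; spend <= plan in all rows:",
    all(parts$spend_amount <= parts$plan_amount), "\n")

truth <- true_eligibility_effect(cfg)
cat(sprintf("true eligibility inequality: %.1f per 1000 (marginal rate %.3f)\n",
            truth$tce_per_1000, truth$marginal))
te <- true_effects(cfg, n_oracle = 500000, seed = seed)
print(te)
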