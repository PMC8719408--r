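#!/usr/bin/env Rscript
# Step 1: simulate the study-scale space-time cube.
#
# Generates a synthetic dataset at the scale of the real application — a
# 29 x 10 rook lattice standing in for 290 sub-counties, 4 annual periods,
# 4 outcomes sharing a live-birth denominator of 500-5000 per area-period —
# from the shared-component model itself, and writes the long-format counts,
# covariates, adjacency and the generating truth to results/sim/.

suppressPackageStartupMessages(library(apomap))

seed <- 2016L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- apo_sim_config()  # study-scale defaults
sim <- generate_dataset(cfg, seed = seed)

write_panel_csv(sim$panel, file.path(out_dir, "counts.csv"),
                file.path(out_dir, "covariates.csv"))
write_edge_list(sim$graph, file.path(out_dir, "adjacency.csv"))

truth <- sim$truth$params
truth_df <- data.frame(
  parameter = c(sprintf("alpha[%d]", seq_along(truth$alpha)),
                sprintf("beta_s[%d]", seq_along(truth$beta_s)),
                sprintf("beta_st[%d]", seq_along(truth$beta_st)),
                sprintf("gamma_s[%d]", seq_along(truth$gamma_s)),
                sprintf("gamma_t[%d]", seq_along(truth$gamma_t))),
  value = c(truth$alpha, truth$beta_s, truth$beta_st, truth$gamma_s,
            truth$gamma_t))
write.csv(truth_df, file.path(out_dir, "truth_scalars.csv"),
          row.names = FALSE)
write.csv(data.frame(area_id = sim$panel$area_ids, u_s = truth$u_s),
          file.path(out_dir, "truth_shared_field.csv"), row.names = FALSE)

tot <- yearly_totals(sim$panel)
cat("Simulated", sim$graph$n_areas, "areas x", length(sim$panel$periods),
    "periods x", length(sim$panel$outcomes), "outcomes (seed", seed, ")\n")
cat("Total events by outcome:\n")
print(tot$outcome_totals)
cat("Overall event rate (all outcomes) per 1000 live births:",
    round(rate_per(tot$grand_total, sum(sim$panel$n), 1000), 1), "\n")
cat("Wrote counts/covariates/adjacency/truth under", out_dir, "\n")
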