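#!/usr/bin/env Rscript
# Step 5: burden summaries and the shared-component surface.
#
# Produces the reporting tables: yearly burden totals and percent changes
# for the simulated cube, the published national yearly counts with their
# derived changes for reference, per-area absolute rate differences between
# the first and last period, and the posterior shared-component surface
# keyed by area id (joinable to a boundary file).

suppressPackageStartupMessages(library(apomap))

out_dir <- "results/summaries"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

panel <- read_panel_csv("results/sim/counts.csv", "results/sim/covariates.csv")

## simulated-cube burden table
tot <- yearly_totals(panel)
by_df <- as.data.frame.table(tot$by, responseName = "count")
names(by_df) <- c("outcome", "period", "count")
write.csv(by_df, file.path(out_dir, "burden_by_year.csv"), row.names = FALSE)
first <- colnames(tot$by)[1]; last <- colnames(tot$by)[ncol(tot$by)]
chg <- data.frame(
  outcome = rownames(tot$by),
  first = tot$by[, first], last = tot$by[, last],
  percent_change = round(percent_change(tot$by[, first], tot$by[, last]), 1))
write.csv(chg, file.path(out_dir, "burden_percent_change.csv"),
          row.names = FALSE)
cat("Simulated burden totals", first, "->", last, ":\n")
print(chg, row.names = FALSE)

## published national reference table and its derived changes
ref <- yearly_totals(apo_reference_counts())
ref_chg <- data.frame(
  outcome = c(rownames(ref$by), "all_outcomes"),
  percent_change = round(c(percent_change(ref$by[, "2016"],
                                          ref$by[, "2019"]),
                           percent_change(ref$period_totals[["2016"]],
                                          ref$period_totals[["2019"]])), 1))
write.csv(ref_chg, file.path(out_dir, "reference_percent_change.csv"),
          row.names = FALSE)
cat("\nPublished national changes 2016 -> 2019 (reference):\n")
print(ref_chg, row.names = FALSE)
cat("Crude national low-birth-weight rate per 100 live births:",
    round(rate_per(ref$outcome_totals[["low_birth_weight"]],
                   apo_reference_live_births(), 100), 1),
    "(crude; the model-based figure is lower)\n")

## per-area rate differences and shared surface from the fitted model
rt_path <- "results/fit/rate_table.csv"
if (file.exists(rt_path)) {
  rt <- read.csv(rt_path)
  for (oc in unique(rt$outcome)) {
    sub <- rt[rt$outcome == oc, c("area_id", "period", "median")]
    names(sub)[3] <- "rate"
    ad <- area_absolute_difference(sub, min(sub$period), max(sub$period))
    write.csv(ad$table,
              file.path(out_dir, paste0("area_difference_", oc, ".csv")),
              row.names = FALSE)
    cat(sprintf(
      "\n%s: %d areas declining, %d increasing, %d unchanged\n", oc,
      ad$n_decline, ad$n_increase, ad$n_zero))
    if (!is.null(ad$extremes$largest_increase)) {
      cat("  largest increase:", ad$extremes$largest_increase$area_id,
          sprintf("(%+.2f)", ad$extremes$largest_increase$difference), "\n")
    }
  }
} else {
  cat("\n(no results/fit/rate_table.csv yet; run analysis/03_fit.R first)\n")
}

fit_sum <- "results/fit/posterior_summary.csv"
if (file.exists(fit_sum)) {
  sm <- read.csv(fit_sum, check.names = FALSE)
  us_rows <- grep("^u_s\\[", sm$parameter)
  surf <- data.frame(area_id = panel$area_ids,
                     median = sm[us_rows, "50%"],
                     lower = sm[us_rows, "2.5%"],
                     upper = sm[us_rows, "97.5%"])
  write.csv(surf, file.path(out_dir, "shared_component_surface.csv"),
            row.names = FALSE)
  cat("\nShared-component surface written (keyed by area_id, joinable to a",
      "boundary file's id property)\n")
}
cat("\nWrote summary tables under", out_dir, "\n")
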