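#!/usr/bin/env Rscript
# Stage 1: generate the synthetic longitudinal cohort.
#
# Produces the three-sensor epoch CSVs, the generator ground truth and the
# resolved configuration under scratch/sim/ (bulky run products), plus a
# short summary of what was emitted. Downstream stages read those files.
#
# Usage: Rscript analysis/01_simulate.R [--seed <int>] [--out <dir>]

suppressPackageStartupMessages(library(armuse))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(get_arg("--seed", "42"))
out_dir <- get_arg("--out", "scratch/sim")

cfg <- fixture_config(seed = seed)
message("Simulating ", cfg$n_subjects, " subjects x weeks {",
        paste(cfg$weeks, collapse = ", "), "} x ", cfg$days_per_week,
        " days (seed ", seed, ") ...")
cohort <- simulate_cohort(cfg)
write_cohort_csv(cohort, out_dir)

n_weeks <- length(cohort$recordings)
n_days <- nrow(cohort$truth)
message("Emitted ", n_weeks, " subject-weeks (",
        cfg$n_subjects * length(cfg$weeks) - n_weeks,
        " lost to week-level missingness), ", n_days, " subject-days.")
message("Mean scheduled walking minutes by week:")
print(tapply(cohort$truth$walk_min, cohort$truth$week, mean))
message("Files written to ", out_dir)
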