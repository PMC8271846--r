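#!/usr/bin/env Rscript
# Stage 2: run the processing pipeline on the simulated epoch CSVs.
#
# Synchronizes the three streams, restricts to the 07:00-22:00 waking window,
# excludes >= 1 h zero-count non-wear, applies the >= 10 h valid-day and
# >= 2-day valid-week rules, and computes the daily and weekly arm-use
# outcomes of both methods. Tables land in results/tables/.
#
# Usage: Rscript analysis/02_process.R [--in <dir>] [--out <dir>]

suppressPackageStartupMessages(library(armuse))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
in_dir <- get_arg("--in", "scratch/sim")
out_dir <- get_arg("--out", "results/tables")

message("Reading epoch streams from ", in_dir, " ...")
recordings <- read_cohort_csv(in_dir)
message("Processing ", length(recordings), " subject-weeks ...")
processed <- process_cohort(recordings)

if (nrow(processed$weekly) == 0) {
  stop("no valid subject-weeks after wear validation", call. = FALSE)
}
write_outcome_csvs(processed, out_dir)

n_days <- nrow(processed$daily)
n_valid <- sum(processed$daily$valid_day)
message("Retained ", n_valid, "/", n_days, " valid days across ",
        nrow(processed$weekly), " valid subject-weeks.")
message("Mean daily walking minutes by week (valid days):")
valid <- processed$daily[processed$daily$valid_day, ]
print(tapply(valid$walk_min, valid$week, mean))
message("Tables written to ", out_dir)
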