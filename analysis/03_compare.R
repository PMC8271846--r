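#!/usr/bin/env Rscript
# Stage 3: quantify the whole-body-movement effect.
#
# Bland-Altman comparison of the P&M and sit/stand methods per outcome and
# week, Spearman correlations of the method difference with daily walking
# time (cross-sectional and change scores), and the longitudinal GEE with
# Bonferroni post-hoc contrasts. Writes CSVs, a plain-text summary and
# (optionally) figures under results/.
#
# Usage: Rscript analysis/03_compare.R [--in <dir>] [--out <dir>] [--plots]

suppressPackageStartupMessages(library(armuse))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
in_dir <- get_arg("--in", "results/tables")
out_dir <- get_arg("--out", "results/comparison")
do_plots <- "--plots" %in% args

weekly <- tibble::as_tibble(data.table::fread(
  file.path(in_dir, "weekly_outcomes.csv"),
  colClasses = list(character = "subject_id")))
message("Comparing methods over ", nrow(weekly), " subject-weeks ...")
res <- compare_methods(weekly, dir = out_dir)

cat(summary_report(res$comparison, res$correlations, res$gee, res$posthoc),
    sep = "\n")

if (do_plots) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    warning("ggplot2 not available; skipping figures")
  } else {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
    for (w in sort(unique(weekly$week))) {
      for (oc in c("paretic", "nonparetic", "ratio")) {
        ggplot2::ggsave(
          file.path(fig_dir, sprintf("bland_altman_%s_week%d.pdf", oc, w)),
          plot_bland_altman(weekly, oc, w), width = 5, height = 4)
        ggplot2::ggsave(
          file.path(fig_dir, sprintf("walking_diff_%s_week%d.pdf", oc, w)),
          plot_walking_difference(weekly, oc, w), width = 5, height = 4)
      }
    }
    message("Figures written to ", fig_dir)
  }
}
message("Comparison outputs written to ", out_dir)
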