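# Report generation: tidy CSV exports, a human-readable summary of the
# method comparison, and optional Bland-Altman / walking-time figures.

#' Write the tabular outputs of a processed cohort
#'
#' Emits `daily_outcomes.csv`, `weekly_outcomes.csv` and `wear_summary.csv`
#' under `dir`.
#'
#' @param processed result of [process_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_outcome_csvs <- function(processed, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(processed$daily, file.path(dir, "daily_outcomes.csv"))
  data.table::fwrite(processed$weekly, file.path(dir, "weekly_outcomes.csv"))
  wear <- dplyr::bind_rows(lapply(processed$wear, `[[`, "days"))
  wear <- dplyr::left_join(
    wear,
    processed$daily[, c("subject_id", "week", "date", "sit_stand_min", "walk_min")],
    by = c("subject_id", "week", "date"))
  data.table::fwrite(wear, file.path(dir, "wear_summary.csv"))
  invisible(dir)
}

#' Run and export the full method-comparison analysis
#'
#' Computes the Bland-Altman table, the walking-time correlation table
#' (cross-sectional and change scores) and the GEE fit per outcome, writes
#' them as CSVs plus a plain-text summary, and returns them.
#'
#' @param weekly weekly outcome tibble.
#' @param dir output directory, or `NULL` to skip writing.
#' @param outcomes outcomes analysed.
#' @return List with `comparison`, `correlations`, `gee` (named list of
#'   `arm_gee`), `posthoc` (named list of contrast tables).
#' @export
compare_methods <- function(weekly, dir = NULL, outcomes = OUTCOMES) {
  if (length(unique(weekly$week)) < 1 || nrow(weekly) < 2) {
    stop("method comparison needs weekly outcomes for at least 2 subject-weeks",
         call. = FALSE)
  }
  comparison <- method_comparison_table(weekly, outcomes)
  correlations <- walking_correlation_table(weekly, outcomes)
  gee <- list(); posthoc <- list()
  for (oc in outcomes) {
    long <- weekly_to_long(weekly, oc)
    fit <- tryCatch(fit_gee(long), error = function(e) {
      warning("GEE skipped for ", oc, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(fit)) {
      gee[[oc]] <- fit
      posthoc[[oc]] <- posthoc_contrasts(fit)
    }
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(comparison, file.path(dir, "method_comparison.csv"))
    data.table::fwrite(correlations, file.path(dir, "correlations.csv"))
    if (length(gee)) {
      data.table::fwrite(
        dplyr::bind_rows(lapply(gee, `[[`, "coefficients"), .id = "outcome"),
        file.path(dir, "gee_coefficients.csv"))
      data.table::fwrite(
        dplyr::bind_rows(posthoc, .id = "outcome"),
        file.path(dir, "gee_posthoc.csv"))
    }
    writeLines(summary_report(comparison, correlations, gee, posthoc),
               file.path(dir, "summary.txt"))
  }
  list(comparison = comparison, correlations = correlations,
       gee = gee, posthoc = posthoc)
}

#' Plain-text summary of the method comparison
#'
#' Lists, per outcome and week, the mean difference as a percentage of the
#' cohort-mean P&M value, the walking-time correlation with its
#' interpretation label, and the GEE Wald tests. The Bonferroni family size
#' of the post-hoc contrasts is stated in the header.
#'
#' @param comparison,correlations,gee,posthoc components as returned by
#'   [compare_methods()].
#' @return Character vector of report lines.
#' @export
summary_report <- function(comparison, correlations, gee = list(),
                           posthoc = list()) {
  lines <- c("Arm-use method comparison: P&M vs sit/stand",
             strrep("=", 44), "")
  m <- if (length(posthoc)) attr(posthoc[[1]], "m") else NA
  if (!is.na(m)) {
    lines <- c(lines, sprintf(
      "Post-hoc family: method within week + week pairs within method (m = %d, Bonferroni).", m), "")
  }
  for (oc in unique(comparison$outcome)) {
    lines <- c(lines, sprintf("Outcome: %s arm use", oc))
    sub <- comparison[comparison$outcome == oc, ]
    for (i in seq_len(nrow(sub))) {
      lines <- c(lines, sprintf(
        "  week %2d: D = %.4g (%.1f%% of P&M mean), LOA [%.4g, %.4g], n = %d",
        sub$week[i], sub$d[i], sub$d_pct[i], sub$loa_low[i], sub$loa_high[i],
        sub$n[i]))
    }
    csub <- correlations[correlations$outcome == oc, ]
    for (i in seq_len(nrow(csub))) {
      lab <- if (csub$kind[i] == "change-score") "change wk3->wk26" else
        sprintf("week %2d", csub$week[i])
      lines <- c(lines, sprintf("  r(walking, difference) %s: %.2f (%s, n = %d)",
                                lab, csub$r[i], csub$label[i], csub$n[i]))
    }
    if (!is.null(gee[[oc]])) {
      w <- gee[[oc]]$wald
      lines <- c(lines, sprintf(
        "  GEE Wald: %s",
        paste(sprintf("%s p = %.3g", w$factor, w$p), collapse = "; ")))
    }
    lines <- c(lines, "")
  }
  lines
}

#' Bland-Altman plot for one outcome and week
#'
#' Mean of the two methods against their difference, with the mean difference
#' and limits of agreement as horizontal lines.
#'
#' @param weekly weekly outcome tibble.
#' @param outcome outcome name.
#' @param week measurement week.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(weekly, outcome = "paretic", week = 3) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  sub <- weekly[weekly$week == week, ]
  pm <- sub[[paste0(outcome, "_pm")]]
  ss <- sub[[paste0(outcome, "_ss")]]
  ba <- bland_altman(pm, ss)
  df <- data.frame(mean = (pm + ss) / 2, diff = pm - ss)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$d) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("Mean of methods (%s arm use)", outcome),
      y = "P&M - sit/stand",
      title = sprintf("Week %d: D = %.3g (%.1f%% of P&M mean)",
                      week, ba$d, ba$d_pct))
}

#' Walking time versus method difference scatterplot
#'
#' @param weekly weekly outcome tibble.
#' @param outcome outcome name.
#' @param week measurement week.
#' @return A ggplot object.
#' @export
plot_walking_difference <- function(weekly, outcome = "paretic", week = 3) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  sub <- weekly[weekly$week == week, ]
  diff <- sub[[paste0(outcome, "_pm")]] - sub[[paste0(outcome, "_ss")]]
  cr <- correlate_walking_difference(sub$walk_min, diff)
  ggplot2::ggplot(data.frame(walk = sub$walk_min, diff = diff),
                  ggplot2::aes(x = walk, y = diff)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Daily walking time (min)",
                  y = sprintf("P&M - sit/stand (%s)", outcome),
                  title = sprintf("Week %d: Spearman r = %.2f (%s)",
                                  week, cr$r, cr$label))
}
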