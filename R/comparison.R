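# Method-comparison statistics: Bland-Altman agreement between the P&M and
# sit/stand methods, percent differences relative to the cohort-mean P&M
# outcome, and Spearman correlations of the method difference with daily
# walking time (cross-sectional and change scores).

OUTCOMES <- c("paretic", "nonparetic", "ratio")

#' Bland-Altman comparison of the two arm-use methods
#'
#' For paired per-subject values of one outcome at one week: the mean
#' difference `D = mean(pm - ss)`, the sample SD of the differences
#' (`n - 1` denominator), the limits of agreement `D +/- 1.96 * SDdiff`, and
#' `d_pct`, `D` expressed as a percentage of the cohort-mean P&M value
#' (undefined when that mean is zero).
#'
#' @param pm,ss numeric vectors of P&M and sit/stand values, paired by
#'   subject; `n >= 2` required.
#' @return Tibble row: `d, sd_diff, loa_low, loa_high, d_pct, n`.
#' @export
bland_altman <- function(pm, ss) {
  if (length(pm) != length(ss)) stop("pm and ss must be paired", call. = FALSE)
  ok <- !is.na(pm) & !is.na(ss)
  pm <- pm[ok]; ss <- ss[ok]
  n <- length(pm)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs (SD undefined)", call. = FALSE)
  d <- pm - ss
  D <- mean(d)
  sd_diff <- stats::sd(d)
  mean_pm <- mean(pm)
  tibble::tibble(
    d = D, sd_diff = sd_diff,
    loa_low = D - 1.96 * sd_diff, loa_high = D + 1.96 * sd_diff,
    d_pct = if (mean_pm != 0) 100 * D / mean_pm else NA_real_,
    n = n)
}

#' Interpretation band for a Spearman correlation
#'
#' Bands on `|r|`: < 0.25 very weak; 0.25-0.49 weak; 0.50-0.69 moderate;
#' 0.70-0.89 strong; 0.90-1.00 very strong.
#'
#' @param r correlation coefficient (may be `NA`).
#' @return Character label.
#' @export
correlation_label <- function(r) {
  if (is.na(r)) return("undefined")
  a <- abs(r)
  if (a < 0.25) "very weak"
  else if (a < 0.50) "weak"
  else if (a < 0.70) "moderate"
  else if (a < 0.90) "strong"
  else "very strong"
}

spearman <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("Spearman correlation needs at least 3 complete pairs", call. = FALSE)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y, method = "spearman")
  tibble::tibble(r = r, n = n, label = correlation_label(r))
}

#' Correlate daily walking time with the between-method difference
#'
#' Spearman rank correlation (average ranks for ties) between per-subject
#' daily walking minutes and the per-subject difference in an arm-use outcome
#' between the P&M and sit/stand methods. A constant vector makes the
#' correlation undefined (`r = NA`, label `"undefined"`).
#'
#' @param walk_min per-subject mean daily walking minutes.
#' @param difference per-subject method difference (P&M minus sit/stand).
#' @return Tibble row: `r, n, label`.
#' @export
correlate_walking_difference <- function(walk_min, difference) {
  spearman(walk_min, difference)
}

#' Change-score correlation between two weeks
#'
#' Forms per-subject changes (late minus early week) in daily walking time
#' and in the between-method outcome difference over subjects present at both
#' weeks, then correlates the changes by Spearman rank.
#'
#' @param weekly weekly outcome tibble (see [aggregate_weekly()]).
#' @param outcome one of `"paretic"`, `"nonparetic"`, `"ratio"`.
#' @param from,to the two weeks compared (default 3 and 26).
#' @return Tibble row: `r, n, label`.
#' @export
change_score_correlation <- function(weekly, outcome = "paretic",
                                     from = 3, to = 26) {
  outcome <- match.arg(outcome, OUTCOMES)
  diff_col <- function(tbl) tbl[[paste0(outcome, "_pm")]] - tbl[[paste0(outcome, "_ss")]]
  a <- weekly[weekly$week == from, ]
  b <- weekly[weekly$week == to, ]
  common <- intersect(a$subject_id, b$subject_id)
  if (length(common) < 3) {
    stop("change-score correlation needs at least 3 subjects present at weeks ",
         from, " and ", to, call. = FALSE)
  }
  a <- a[match(common, a$subject_id), ]
  b <- b[match(common, b$subject_id), ]
  spearman(b$walk_min - a$walk_min, diff_col(b) - diff_col(a))
}

#' Bland-Altman table for every outcome and week
#'
#' @param weekly weekly outcome tibble.
#' @param outcomes outcomes to compare.
#' @return Tibble with one row per outcome x week (weeks with fewer than two
#'   subjects are skipped with a warning).
#' @export
method_comparison_table <- function(weekly, outcomes = OUTCOMES) {
  rows <- list()
  for (w in sort(unique(weekly$week))) {
    sub <- weekly[weekly$week == w, ]
    for (oc in outcomes) {
      pm <- sub[[paste0(oc, "_pm")]]
      ss <- sub[[paste0(oc, "_ss")]]
      if (sum(!is.na(pm) & !is.na(ss)) < 2) {
        warning("skipping Bland-Altman for ", oc, " at week ", w,
                ": fewer than 2 subjects", call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(outcome = oc, week = w), bland_altman(pm, ss))
    }
  }
  dplyr::bind_rows(rows)
}

#' Walking-time correlation table for every outcome and week
#'
#' @param weekly weekly outcome tibble.
#' @param outcomes outcomes to correlate.
#' @param change_from,change_to weeks used for the change-score rows.
#' @return Tibble with one row per outcome x week plus change-score rows
#'   (`week = NA`).
#' @export
walking_correlation_table <- function(weekly, outcomes = OUTCOMES,
                                      change_from = 3, change_to = 26) {
  rows <- list()
  for (w in sort(unique(weekly$week))) {
    sub <- weekly[weekly$week == w, ]
    for (oc in outcomes) {
      diff <- sub[[paste0(oc, "_pm")]] - sub[[paste0(oc, "_ss")]]
      if (sum(stats::complete.cases(sub$walk_min, diff)) < 3) next
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(outcome = oc, week = w, kind = "cross-sectional"),
        correlate_walking_difference(sub$walk_min, diff))
    }
  }
  both <- intersect(weekly$subject_id[weekly$week == change_from],
                    weekly$subject_id[weekly$week == change_to])
  if (length(both) >= 3) {
    for (oc in outcomes) {
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(outcome = oc, week = NA_real_, kind = "change-score"),
        change_score_correlation(weekly, oc, change_from, change_to))
    }
  } else {
    warning("change-score correlations skipped: fewer than 3 subjects ",
            "present at both weeks ", change_from, " and ", change_to,
            call. = FALSE)
  }
  dplyr::bind_rows(rows)
}
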