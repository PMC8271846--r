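# Arm-use quantification: the P&M method sums wrist movement counts over all
# retained 30 s epochs (all whole-body postures and movements); the sit/stand
# method sums only over epochs in which at least 90% of the 48 thigh samples
# are labelled sitting or standing. The difference between the two is the
# contribution of whole-body movements (mostly walking) to the arm-use
# outcome. Ratios are paretic/nonparetic on daily totals (ratio of sums).

#' Classify an epoch as sitting/standing
#'
#' An epoch counts as sitting/standing when at least 90% of its 48 thigh
#' samples are labelled `SIT` or `STA` (inclusive threshold: 44/48 = 91.7%
#' passes, 43/48 = 89.6% does not).
#'
#' @param labels character vector of 48 posture labels, or an `n x 48` matrix
#'   (one epoch per row).
#' @param threshold minimum sitting/standing fraction (default 0.90).
#' @return Logical scalar (vector input) or logical vector (matrix input).
#' @export
classify_epoch_sitstand <- function(labels, threshold = 0.90) {
  if (is.null(labels)) stop("posture labels are missing", call. = FALSE)
  m <- if (is.matrix(labels)) labels else matrix(labels, nrow = 1)
  if (ncol(m) != SAMPLES_PER_EPOCH) {
    stop("an epoch must have exactly ", SAMPLES_PER_EPOCH, " posture labels",
         call. = FALSE)
  }
  frac <- rowMeans(m == "SIT" | m == "STA")
  out <- frac >= threshold
  if (!is.matrix(labels)) out[[1]] else out
}

#' Compute per-day posture durations and arm-use outcomes
#'
#' For every calendar day of a synchronized, window-restricted,
#' wear-validated recording: wear time, sitting+standing and walking minutes
#' (at 1.6 Hz sample resolution from the thigh labels of retained epochs),
#' and the six arm-use outcomes — paretic, nonparetic and their ratio, each
#' under the P&M method (all retained epochs) and the sit/stand method
#' (retained epochs passing [classify_epoch_sitstand()]).
#'
#' A ratio with a zero denominator is undefined and reported as `NA` (never 0
#' or infinity).
#'
#' @param recording an [arm_recording()], synchronized and restricted to
#'   waking hours.
#' @param wear a `wear_summary` from [validate_days()] for the same epochs.
#' @return Tibble with one row per day: `subject_id, week, date, wear_min,
#'   sit_stand_min, walk_min, paretic_pm, nonparetic_pm, ratio_pm,
#'   paretic_ss, nonparetic_ss, ratio_ss, n_epochs, n_ss_epochs, valid_day`.
#' @export
compute_daily_outcomes <- function(recording, wear) {
  th <- recording$streams$thigh
  if (length(wear$retained) != n_epochs(th)) {
    stop("wear summary does not match the recording's epochs", call. = FALSE)
  }
  pw <- recording$streams$paretic_wrist
  npw <- recording$streams$nonparetic_wrist
  keep <- wear$retained
  date <- epoch_date(th$start_time)
  ss_flag <- classify_epoch_sitstand(th$labels)
  p_sum <- rowSums(pw$counts)
  n_sum <- rowSums(npw$counts)
  ss_min_ep <- rowSums(th$labels == "SIT" | th$labels == "STA") / SAMPLES_PER_MINUTE
  wal_min_ep <- rowSums(th$labels == "WAL") / SAMPLES_PER_MINUTE

  ratio_or_na <- function(num, den) if (den > 0) num / den else NA_real_

  per_day <- lapply(split(seq_along(date), date), function(idx) {
    r <- idx[keep[idx]]
    ss <- r[ss_flag[r]]
    paretic_pm <- sum(p_sum[r]); nonparetic_pm <- sum(n_sum[r])
    paretic_ss <- sum(p_sum[ss]); nonparetic_ss <- sum(n_sum[ss])
    tibble::tibble(
      subject_id = recording$subject_id, week = recording$week,
      date = date[idx[1]],
      wear_min = length(r) * EPOCH_SECONDS / 60,
      sit_stand_min = sum(ss_min_ep[r]),
      walk_min = sum(wal_min_ep[r]),
      paretic_pm = paretic_pm, nonparetic_pm = nonparetic_pm,
      ratio_pm = ratio_or_na(paretic_pm, nonparetic_pm),
      paretic_ss = paretic_ss, nonparetic_ss = nonparetic_ss,
      ratio_ss = ratio_or_na(paretic_ss, nonparetic_ss),
      n_epochs = length(r), n_ss_epochs = length(ss))
  })
  daily <- dplyr::bind_rows(per_day)
  dplyr::left_join(daily,
                   dplyr::select(wear$days, date, valid_day),
                   by = "date")
}

#' Aggregate daily outcomes to weekly mean daily values
#'
#' Averages each outcome over the valid measurement days of a subject-week.
#' Weeks with fewer than `min_valid_days` valid days are excluded (no row
#' emitted). Undefined (NA) ratios are excluded from that outcome's mean,
#' with the contributing day count reported.
#'
#' @param daily tibble from [compute_daily_outcomes()], possibly covering
#'   several subject-weeks.
#' @param min_valid_days valid-week threshold (default 2).
#' @return Tibble with one row per valid subject-week: mean daily outcomes,
#'   `n_valid_days`, `n_ratio_pm`, `n_ratio_ss`.
#' @export
aggregate_weekly <- function(daily, min_valid_days = 2) {
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  daily |>
    dplyr::filter(valid_day) |>
    dplyr::group_by(subject_id, week) |>
    dplyr::summarise(
      wear_min = mean(wear_min), sit_stand_min = mean(sit_stand_min),
      walk_min = mean(walk_min),
      n_valid_days = dplyr::n(),
      n_ratio_pm = sum(!is.na(ratio_pm)), n_ratio_ss = sum(!is.na(ratio_ss)),
      paretic_pm = mean(paretic_pm), nonparetic_pm = mean(nonparetic_pm),
      ratio_pm = mean_or_na(ratio_pm),
      paretic_ss = mean(paretic_ss), nonparetic_ss = mean(nonparetic_ss),
      ratio_ss = mean_or_na(ratio_ss),
      .groups = "drop") |>
    dplyr::filter(n_valid_days >= min_valid_days)
}

#' Run the full processing pipeline on one recording
#'
#' Synchronize the three streams, restrict to waking hours, detect per-sensor
#' non-wear, apply the valid-day/valid-week rules and compute daily and
#' weekly outcomes.
#'
#' @param recording an [arm_recording()].
#' @param waking_window clock-time pair, default 07:00-22:00.
#' @param nonwear_min non-wear run threshold in minutes.
#' @param min_wear_min valid-day threshold in minutes (600 = 10 h).
#' @param min_valid_days valid-week threshold.
#' @return List with `daily`, `weekly` (zero rows if the week is invalid),
#'   `wear` (the `wear_summary`).
#' @export
process_recording <- function(recording, waking_window = c("07:00", "22:00"),
                              nonwear_min = 60, min_wear_min = 600,
                              min_valid_days = 2) {
  rec <- synchronize_streams(recording)
  rec <- restrict_waking_hours(rec, waking_window)
  nonwear <- lapply(rec$streams, detect_nonwear, min_duration_min = nonwear_min)
  wear <- validate_days(rec, nonwear, min_wear_min, min_valid_days)
  daily <- compute_daily_outcomes(rec, wear)
  weekly <- aggregate_weekly(daily, min_valid_days)
  list(daily = daily, weekly = weekly, wear = wear)
}

#' Process every recording of a cohort
#'
#' @param recordings list of [arm_recording()] (e.g. `cohort$recordings`).
#' @param ... forwarded to [process_recording()].
#' @return List with bound `daily` and `weekly` tibbles and per-recording
#'   `wear` summaries.
#' @export
process_cohort <- function(recordings, ...) {
  res <- lapply(recordings, process_recording, ...)
  list(daily = dplyr::bind_rows(lapply(res, `[[`, "daily")),
       weekly = dplyr::bind_rows(lapply(res, `[[`, "weekly")),
       wear = lapply(res, `[[`, "wear"))
}
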