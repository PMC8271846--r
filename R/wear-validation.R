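# Waking-hours window, non-wear exclusion, valid-day and valid-week rules.
#
# Analysis is restricted to waking hours (07:00-22:00 by default). Non-wear
# is a run of zero movement counts lasting at least one hour, detected per
# sensor on the 1.6 Hz sample sequence (a run may start mid-epoch); an epoch
# is excluded when any part of it falls in any sensor's non-wear interval. A
# valid day has >= 10 h of simultaneous data from the whole three-sensor
# configuration; a valid week has >= 2 valid days. All thresholds are
# inclusive (>=).

#' Restrict a recording to waking hours
#'
#' Keeps epochs whose start time lies in the half-open clock window
#' `[from, to)`; with the default window an epoch starting 06:59:30 is
#' excluded and one starting 21:59:30 retained.
#'
#' @param recording an [arm_recording()].
#' @param window clock-time pair, default `c("07:00", "22:00")`.
#' @return The restricted `arm_recording`.
#' @export
restrict_waking_hours <- function(recording, window = c("07:00", "22:00")) {
  lo <- parse_clock(window[[1]])
  hi <- parse_clock(window[[2]])
  for (role in names(recording$streams)) {
    s <- recording$streams[[role]]
    sod <- seconds_of_day(s$start_time)
    recording$streams[[role]] <- subset_stream(s, sod >= lo & sod < hi)
  }
  recording
}

#' Detect non-wear intervals in one sensor stream
#'
#' Scans the concatenated 1.6 Hz sample sequence for maximal runs of zero
#' counts lasting at least `min_duration_min` minutes. Runs are sought within
#' contiguous stretches of epochs (a gap in the epoch sequence ends the run),
#' and may start or end mid-epoch; shorter zero runs are not non-wear.
#'
#' @param stream an [epoch_stream()] after waking-hours restriction.
#' @param min_duration_min minimum run duration in minutes (inclusive).
#' @return Tibble of intervals with columns `start`, `end` (POSIXct,
#'   half-open) and `duration_min`.
#' @export
detect_nonwear <- function(stream, min_duration_min = 60) {
  min_samples <- as.integer(round(min_duration_min * SAMPLES_PER_MINUTE))
  n <- n_epochs(stream)
  out <- list()
  if (n == 0) {
    return(tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                          end = as.POSIXct(character(), tz = "UTC"),
                          duration_min = numeric()))
  }
  # contiguous chunks of 30 s-spaced epochs
  brk <- c(0L, which(diff(as.numeric(stream$start_time)) != EPOCH_SECONDS), n)
  for (ci in seq_len(length(brk) - 1L)) {
    ep <- (brk[ci] + 1L):brk[ci + 1L]
    x <- as.vector(t(stream$counts[ep, , drop = FALSE]))
    r <- rle(x == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    hit <- which(r$values & r$lengths >= min_samples)
    t0 <- stream$start_time[ep[1]]
    for (h in hit) {
      out[[length(out) + 1L]] <- tibble::tibble(
        start = t0 + (starts[h] - 1L) / SAMPLE_HZ,
        end = t0 + ends[h] / SAMPLE_HZ,
        duration_min = r$lengths[h] / SAMPLES_PER_MINUTE)
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(start = as.POSIXct(character(), tz = "UTC"),
                   end = as.POSIXct(character(), tz = "UTC"),
                   duration_min = numeric())
}

# Logical per-epoch flag: does any part of the epoch overlap any interval?
epoch_in_intervals <- function(start_time, intervals) {
  flag <- logical(length(start_time))
  if (nrow(intervals) == 0) return(flag)
  ep_lo <- as.numeric(start_time)
  ep_hi <- ep_lo + EPOCH_SECONDS
  for (i in seq_len(nrow(intervals))) {
    flag <- flag | (ep_lo < as.numeric(intervals$end[i]) &
                      ep_hi > as.numeric(intervals$start[i]))
  }
  flag
}

#' Apply the valid-day and valid-week rules
#'
#' Computes, per calendar day, the wear time of the whole sensor
#' configuration (epochs outside every sensor's non-wear intervals), flags
#' valid days (wear >= `min_wear_min`) and the valid week (>=
#' `min_valid_days` valid days).
#'
#' @param recording a synchronized, waking-hours-restricted [arm_recording()].
#' @param nonwear named list of non-wear interval tables per sensor role, as
#'   returned by [detect_nonwear()]; computed here when `NULL`.
#' @param min_wear_min valid-day wear threshold in minutes (default 600 =
#'   10 h, inclusive).
#' @param min_valid_days valid-week threshold (default 2, inclusive).
#' @return An object of class `wear_summary`: list with `days` (tibble:
#'   `subject_id, week, date, wear_min, valid_day`), `valid_week`,
#'   `valid_days` (dates), `nonwear` (the interval tables) and `retained`
#'   (logical per synchronized epoch, outside all non-wear).
#' @export
validate_days <- function(recording, nonwear = NULL, min_wear_min = 600,
                          min_valid_days = 2) {
  if (is.null(nonwear)) {
    nonwear <- lapply(recording$streams, detect_nonwear)
  }
  st <- recording$streams$thigh$start_time
  in_nw <- Reduce(`|`, lapply(nonwear[names(recording$streams)], function(iv)
    epoch_in_intervals(st, iv)))
  if (is.null(in_nw)) in_nw <- logical(length(st))
  retained <- !in_nw
  date <- epoch_date(st)
  days <- tibble::tibble(date = date, retained = retained) |>
    dplyr::group_by(date) |>
    dplyr::summarise(wear_min = sum(retained) * EPOCH_SECONDS / 60,
                     .groups = "drop") |>
    dplyr::mutate(subject_id = recording$subject_id, week = recording$week,
                  valid_day = wear_min >= min_wear_min) |>
    dplyr::select(subject_id, week, date, wear_min, valid_day)
  valid_days <- days$date[days$valid_day]
  structure(list(days = days, valid_week = length(valid_days) >= min_valid_days,
                 valid_days = valid_days, nonwear = nonwear,
                 retained = retained),
            class = "wear_summary")
}

#' @export
print.wear_summary <- function(x, ...) {
  cat(sprintf("<wear_summary> %d day(s), %d valid; valid week: %s\n",
              nrow(x$days), length(x$valid_days), x$valid_week))
  invisible(x)
}
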