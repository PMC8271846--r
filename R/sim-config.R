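# Configuration of the synthetic longitudinal cohort. Defaults encode the
# study design the analysis targets: ~33 stroke patients wearing the
# three-sensor configuration for 7 consecutive days at weeks 3, 12 and 26
# post-stroke, measured over a 07:00-22:00 waking window, with walking time
# increasing and the paretic deficit shrinking over the follow-up.

#' Configuration for the synthetic cohort generator
#'
#' All count/bout distributions are generator choices (the device's own
#' count algorithm is proprietary); their defaults are set so that the
#' simulated cohort reproduces the qualitative structure the analysis
#' assumes: functional arm-use bursts during sitting/standing with a paretic
#' deficit that recovers over weeks, non-functional arm sway during walking
#' (larger on the nonparetic arm), daily walking time increasing from week 3
#' to week 26, night/water non-wear gaps and missing weeks/days.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param weeks measurement weeks post-stroke, an ordered subset of
#'   `c(3, 12, 26)`.
#' @param days_per_week consecutive measurement days per week.
#' @param waking_window clock-time pair (`"HH:MM"`) delimiting the analysed
#'   waking hours; the default 07:00-22:00 window is 15 h = 1800 epochs.
#' @param schedule_params per-week means/SDs (minutes/day) of walking,
#'   sitting, standing and lying within the waking window, plus
#'   `subject_walk_sdlog`, the SD of the log-normal subject-level walking
#'   multiplier that creates persistent between-subject walking differences.
#' @param burst_params functional arm-use bursts injected on sitting/standing
#'   samples: per-sample probability `rate`, gamma `shape` and `mean` of the
#'   burst magnitude (counts per 1.6 Hz sample).
#' @param paretic_deficit per-week mean multiplier in `[0, 1]` applied to
#'   paretic burst magnitudes, plus `subject_sd` (logit scale) for
#'   between-subject variation. The per-week means rise toward 1 to emulate
#'   motor recovery.
#' @param sway_params arm sway during walking samples: per-sample mean count
#'   added to each wrist (`nonparetic_mean >= paretic_mean`) with Gaussian
#'   jitter `sd`, truncated at 0.
#' @param noise_params baseline wear noise on every worn sample: per-sample
#'   probability `rate` of a nonzero count with exponential `mean`. Keeps
#'   genuinely worn periods from ever looking like non-wear.
#' @param nonwear_params daytime non-wear gaps per sensor-day: probability
#'   `prob` of a long gap with duration uniform in `dur_range_min` (>= 60 so
#'   it triggers the non-wear rule), and probability `short_gap_prob` of a
#'   short zero gap in `short_dur_range_min` that must *not* be flagged.
#' @param missingness `week_absent`: per-week probability a subject-week is
#'   missing entirely; `day_truncated`: probability a day is cut short.
#' @param bout_mean_min mean posture bout lengths (minutes) of the
#'   alternating-bout day schedule.
#' @param start_date calendar date anchoring the simulated measurements.
#' @param seed integer master seed; per subject/week/day substreams are
#'   derived deterministically so changing the cohort size does not reshuffle
#'   unrelated subjects.
#' @return A validated object of class `sim_config`.
#' @seealso [simulate_cohort()], [fixture_config()]
#' @export
sim_config <- function(n_subjects = 33,
                       weeks = c(3, 12, 26),
                       days_per_week = 7,
                       waking_window = c("07:00", "22:00"),
                       schedule_params = list(
                         walk_mean = c(`3` = 30, `12` = 60, `26` = 85),
                         walk_sd = c(`3` = 10, `12` = 15, `26` = 18),
                         sit_mean = c(`3` = 480, `12` = 460, `26` = 440),
                         sit_sd = c(`3` = 60, `12` = 60, `26` = 60),
                         stand_mean = c(`3` = 170, `12` = 180, `26` = 190),
                         stand_sd = c(`3` = 40, `12` = 40, `26` = 40),
                         lie_mean = c(`3` = 250, `12` = 230, `26` = 220),
                         lie_sd = c(`3` = 50, `12` = 50, `26` = 50),
                         subject_walk_sdlog = 0.35
                       ),
                       burst_params = list(rate = 0.10, shape = 2, mean = 3),
                       paretic_deficit = list(
                         mean = c(`3` = 0.35, `12` = 0.50, `26` = 0.60),
                         subject_sd = 0.4
                       ),
                       sway_params = list(paretic_mean = 1.0,
                                          nonparetic_mean = 1.25, sd = 0.3),
                       noise_params = list(rate = 0.05, mean = 0.3),
                       nonwear_params = list(prob = 0.12,
                                             dur_range_min = c(60, 150),
                                             short_gap_prob = 0.15,
                                             short_dur_range_min = c(10, 45)),
                       missingness = list(
                         week_absent = c(`3` = 0.09, `12` = 0.15, `26` = 0.21),
                         day_truncated = 0.08
                       ),
                       bout_mean_min = c(LIE = 30, SIT = 12, STA = 5, WAL = 2.5),
                       start_date = "2023-03-06",
                       seed = 1L) {
  cfg <- structure(
    list(n_subjects = n_subjects, weeks = weeks, days_per_week = days_per_week,
         waking_window = waking_window, schedule_params = schedule_params,
         burst_params = burst_params, paretic_deficit = paretic_deficit,
         sway_params = sway_params, noise_params = noise_params,
         nonwear_params = nonwear_params, missingness = missingness,
         bout_mean_min = bout_mean_min, start_date = as.Date(start_date),
         seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks every field and raises an error naming the offending field.
#' @param cfg a `sim_config`.
#' @return `cfg`, invisibly validated.
#' @export
validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop("invalid sim_config: field '", field, "' ", msg, call. = FALSE)
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 1 ||
      cfg$n_subjects != round(cfg$n_subjects)) {
    fail("n_subjects", "must be a positive integer")
  }
  if (!all(cfg$weeks %in% c(3, 12, 26)) || length(cfg$weeks) < 1 ||
      is.unsorted(cfg$weeks, strictly = TRUE)) {
    fail("weeks", "must be an ordered subset of {3, 12, 26}")
  }
  if (cfg$days_per_week < 1 || cfg$days_per_week != round(cfg$days_per_week)) {
    fail("days_per_week", "must be a positive integer")
  }
  win <- vapply(cfg$waking_window, parse_clock, 0)
  if (length(win) != 2 || win[2] <= win[1]) {
    fail("waking_window", "must be an increasing pair of clock times")
  }
  window_min <- (win[2] - win[1]) / 60
  sp <- cfg$schedule_params
  for (f in c("walk_mean", "walk_sd", "sit_mean", "sit_sd", "stand_mean",
              "stand_sd", "lie_mean", "lie_sd")) {
    v <- sp[[f]]
    if (is.null(v) || any(v < 0) || !all(as.character(cfg$weeks) %in% names(v))) {
      fail(paste0("schedule_params$", f),
           "must be non-negative and named for every simulated week")
    }
  }
  for (w in as.character(cfg$weeks)) {
    # walking alone may not exceed the window; the sedentary budget is
    # rescaled to the remainder, so the total always fits exactly.
    if (sp$walk_mean[[w]] > window_min) {
      fail("schedule_params$walk_mean",
           sprintf("exceeds the %g-minute waking window at week %s", window_min, w))
    }
  }
  if (is.null(sp$subject_walk_sdlog) || sp$subject_walk_sdlog < 0) {
    fail("schedule_params$subject_walk_sdlog", "must be >= 0")
  }
  bp <- cfg$burst_params
  if (bp$rate < 0 || bp$rate > 1) fail("burst_params$rate", "must be in [0, 1]")
  if (bp$mean < 0 || bp$shape <= 0) {
    fail("burst_params", "must have mean >= 0 and shape > 0")
  }
  pd <- cfg$paretic_deficit
  if (any(pd$mean < 0) || any(pd$mean > 1) ||
      !all(as.character(cfg$weeks) %in% names(pd$mean))) {
    fail("paretic_deficit$mean", "must be in [0, 1] and named for every week")
  }
  if (pd$subject_sd < 0) fail("paretic_deficit$subject_sd", "must be >= 0")
  sw <- cfg$sway_params
  if (sw$paretic_mean < 0 || sw$nonparetic_mean < 0 || sw$sd < 0) {
    fail("sway_params", "magnitudes must be non-negative")
  }
  if (sw$nonparetic_mean < sw$paretic_mean) {
    fail("sway_params$nonparetic_mean", "must be >= paretic_mean")
  }
  np <- cfg$noise_params
  if (np$rate < 0 || np$rate > 1 || np$mean < 0) {
    fail("noise_params", "must have rate in [0, 1] and mean >= 0")
  }
  nw <- cfg$nonwear_params
  if (nw$prob < 0 || nw$prob > 1 || nw$short_gap_prob < 0 || nw$short_gap_prob > 1) {
    fail("nonwear_params", "probabilities must be in [0, 1]")
  }
  if (nw$dur_range_min[1] < 60) {
    fail("nonwear_params$dur_range_min", "long gaps must be >= 60 min")
  }
  if (nw$short_dur_range_min[2] >= 60) {
    fail("nonwear_params$short_dur_range_min", "short gaps must stay < 60 min")
  }
  ms <- cfg$missingness
  if (any(ms$week_absent < 0) || any(ms$week_absent > 1) ||
      !all(as.character(cfg$weeks) %in% names(ms$week_absent))) {
    fail("missingness$week_absent", "must be probabilities named for every week")
  }
  if (ms$day_truncated < 0 || ms$day_truncated > 1) {
    fail("missingness$day_truncated", "must be a probability")
  }
  if (!all(c("LIE", "SIT", "STA", "WAL") %in% names(cfg$bout_mean_min)) ||
      any(cfg$bout_mean_min <= 0)) {
    fail("bout_mean_min", "must be positive and name LIE, SIT, STA, WAL")
  }
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' Packaged demonstration cohort configuration
#'
#' A scaled-down cohort (12 subjects, 3 days per week, all three weeks) with
#' the default effect structure: sway present on both arms, walking time
#' increasing over weeks. Small enough for interactive runs and tests while
#' keeping every rule of the pipeline exercised.
#'
#' @param seed master seed.
#' @param ... overrides forwarded to [sim_config()].
#' @return A `sim_config`.
#' @export
fixture_config <- function(seed = 1L, ...) {
  sim_config(n_subjects = 12, days_per_week = 3, seed = seed, ...)
}

#' Turn off non-wear gaps and missingness
#'
#' Convenience for parameter-recovery runs: the generator then emits every
#' scheduled epoch of every subject-week.
#' @param cfg a `sim_config`.
#' @return The modified `sim_config`.
#' @export
disable_dropout <- function(cfg) {
  cfg$nonwear_params$prob <- 0
  cfg$nonwear_params$short_gap_prob <- 0
  cfg$missingness$week_absent[] <- 0
  cfg$missingness$day_truncated <- 0
  validate_sim_config(cfg)
}

#' Write / read a simulation configuration as YAML
#'
#' The YAML round-trip preserves every field, so a cohort can be regenerated
#' from the file alone.
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `read_sim_config` returns a validated `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$start_date <- as.character(x$start_date)
  # named atomic vectors must become maps, or YAML drops their names
  mapify <- function(v) {
    if (is.list(v)) lapply(v, mapify)
    else if (!is.null(names(v))) as.list(v)
    else v
  }
  yaml::write_yaml(lapply(x, mapify), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  relist_named <- function(v) if (is.list(v)) unlist(v) else v
  for (f in c("schedule_params", "paretic_deficit", "missingness")) {
    x[[f]] <- lapply(x[[f]], relist_named)
  }
  x$bout_mean_min <- unlist(x$bout_mean_min)
  do.call(sim_config, x)
}
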