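# Synthetic longitudinal cohort generator. Counts are generated directly at
# the device's 1.6 Hz count resolution; the optional raw 12.5 Hz mode exists
# only to exercise the posture-classifier emulation (see
# emulate_posture_classifier), because the device's own acceleration-to-count
# firmware is proprietary and is emulated, not reverse-engineered.

# Deterministic substream seed for (subject, week, day): counter-based
# splitting from the master seed, so adding subjects or weeks never
# reshuffles the streams of unrelated subject-days. All arithmetic stays
# below 2^53, and the result below 2^31.
substream_seed <- function(seed, subject = 0L, week = 0L, day = 0L) {
  h <- (as.numeric(seed) %% 2147483647) + 1
  for (k in c(subject, week, day)) {
    h <- (h * 69069 + (k + 1) * 104729) %% 2147483647
  }
  as.integer(h)
}

# Draw one day's posture schedule in 1.6 Hz sample units. Walking is drawn
# first (subject multiplier times the week mean); the sedentary postures are
# rescaled to fill the remaining window exactly, so the daily budget always
# sums to the full waking window.
draw_schedule <- function(cfg, week, walk_mult) {
  sp <- cfg$schedule_params
  w <- as.character(week)
  win <- unname(vapply(cfg$waking_window, parse_clock, 0))
  window_samples <- as.integer(round((win[2] - win[1]) * SAMPLE_HZ))
  window_min <- (win[2] - win[1]) / 60

  rtnorm <- function(mean, sd, lo = 0, hi = Inf) {
    min(max(stats::rnorm(1, mean, sd), lo), hi)
  }
  walk <- rtnorm(sp$walk_mean[[w]] * walk_mult, sp$walk_sd[[w]],
                 lo = 0, hi = 0.5 * window_min)
  sit <- rtnorm(sp$sit_mean[[w]], sp$sit_sd[[w]], lo = 1)
  sta <- rtnorm(sp$stand_mean[[w]], sp$stand_sd[[w]], lo = 1)
  lie <- rtnorm(sp$lie_mean[[w]], sp$lie_sd[[w]], lo = 1)
  rest <- window_min - walk
  scale <- rest / (sit + sta + lie)
  mins <- c(LIE = lie * scale, SIT = sit * scale, STA = sta * scale, WAL = walk)

  samples <- round(mins * SAMPLES_PER_MINUTE)
  # force the sample budget to cover the window exactly
  samples[["SIT"]] <- samples[["SIT"]] + (window_samples - sum(samples))
  storage.mode(samples) <- "integer"
  samples
}

# Lay out one day's per-sample posture labels as alternating bouts with
# exponential lengths, consuming the sample budget of each posture exactly.
make_bout_labels <- function(budget_samples, bout_mean_min) {
  budget <- budget_samples[budget_samples > 0]
  mean_samples <- bout_mean_min[names(budget)] * SAMPLES_PER_MINUTE
  pieces <- vector("list", 256)
  i <- 0L
  prev <- ""
  while (sum(budget) > 0) {
    cand <- names(budget)[budget > 0 & names(budget) != prev]
    if (length(cand) == 0) cand <- names(budget)[budget > 0]
    pick <- if (length(cand) == 1) cand else
      sample(cand, 1L, prob = budget[cand])
    len <- min(budget[[pick]],
               max(1L, as.integer(round(stats::rexp(1, 1 / mean_samples[[pick]])))))
    i <- i + 1L
    if (i > length(pieces)) pieces <- c(pieces, vector("list", length(pieces)))
    pieces[[i]] <- rep(pick, len)
    budget[[pick]] <- budget[[pick]] - len
    prev <- pick
  }
  unlist(pieces[seq_len(i)], use.names = FALSE)
}

#' Simulate one day of three-sensor count streams
#'
#' Generates the per-sample (1.6 Hz) posture labels and movement counts for
#' one waking day. Wrist counts are the sum of three non-negative components:
#' functional arm-use bursts on sitting/standing samples (zero-inflated
#' gamma, paretic magnitude shrunk by the deficit multiplier), arm sway on
#' walking samples (truncated-Gaussian per-sample count, nonparetic >=
#' paretic), and sparse baseline wear noise on all samples.
#'
#' The caller owns the RNG state; seed it (e.g. via `set.seed`) for
#' reproducibility.
#'
#' @param schedule_samples named integer vector of per-posture sample budgets
#'   (names from [POSTURE_LABELS]); must sum to the waking-window length in
#'   samples.
#' @param cfg a [sim_config()] supplying burst/sway/noise/bout parameters.
#' @param deficit paretic burst-magnitude multiplier in `[0, 1]` for this
#'   subject-week.
#' @param func_mult subject-level multiplier on functional burst magnitude.
#' @return A list with per-sample vectors `labels`, `thigh`, `paretic`,
#'   `nonparetic`, and `truth` (injected component sums for recovery tests).
#' @export
simulate_day <- function(schedule_samples, cfg, deficit = 1, func_mult = 1) {
  labels <- make_bout_labels(schedule_samples, cfg$bout_mean_min)
  n <- length(labels)
  ss <- labels == "SIT" | labels == "STA"
  wal <- labels == "WAL"
  np <- cfg$noise_params
  bp <- cfg$burst_params
  sw <- cfg$sway_params

  base_noise <- function() {
    stats::rbinom(n, 1L, np$rate) * stats::rexp(n, rate = 1 / max(np$mean, 1e-12)) *
      (np$mean > 0)
  }
  bursts <- function(mult) {
    nss <- sum(ss)
    v <- numeric(n)
    if (nss > 0 && bp$rate > 0 && bp$mean > 0) {
      hit <- stats::rbinom(nss, 1L, bp$rate)
      mag <- stats::rgamma(nss, shape = bp$shape, scale = bp$mean / bp$shape)
      v[ss] <- hit * mag * mult
    }
    v
  }
  sway <- function(mean) {
    nw <- sum(wal)
    v <- numeric(n)
    if (nw > 0 && mean > 0) v[wal] <- pmax(0, stats::rnorm(nw, mean, sw$sd))
    v
  }

  paretic_func <- bursts(deficit * func_mult)
  nonparetic_func <- bursts(func_mult)
  paretic_sway <- sway(sw$paretic_mean)
  nonparetic_sway <- sway(sw$nonparetic_mean)
  paretic <- round(paretic_func + paretic_sway + base_noise(), 3)
  nonparetic <- round(nonparetic_func + nonparetic_sway + base_noise(), 3)

  # thigh: gait counts while walking plus the same sparse baseline noise
  gait <- numeric(n)
  if (any(wal)) gait[wal] <- pmax(0, stats::rnorm(sum(wal), 2.5, 0.8))
  thigh <- round(gait + base_noise(), 3)

  list(labels = labels, thigh = thigh, paretic = paretic,
       nonparetic = nonparetic,
       truth = list(
         func_paretic = sum(paretic_func), func_nonparetic = sum(nonparetic_func),
         sway_paretic = sum(paretic_sway), sway_nonparetic = sum(nonparetic_sway)))
}

# Zero out an injected gap in a per-sample count vector; returns the modified
# vector plus interval bookkeeping (sample indices, 1-based inclusive).
inject_gap <- function(counts, dur_min, n) {
  len <- as.integer(round(dur_min * SAMPLES_PER_MINUTE))
  len <- min(len, n)
  start <- sample.int(n - len + 1L, 1L)
  counts[start:(start + len - 1L)] <- 0
  list(counts = counts, start = start, end = start + len - 1L)
}

#' Simulate a longitudinal three-sensor cohort
#'
#' Generates one [arm_recording()] per retained subject-week under the
#' configured study design, together with the generator's ground truth
#' (scheduled per-day posture minutes, injected functional and sway counts,
#' injected non-wear intervals) for parameter-recovery tests.
#'
#' Determinism contract: the same configuration (including `seed`) always
#' reproduces byte-identical output.
#'
#' @param cfg a validated [sim_config()].
#' @return An object of class `sim_cohort`: list with `recordings` (list of
#'   `arm_recording`), `truth` (tibble, one row per emitted subject-week-day),
#'   `nonwear_truth` (tibble of injected gaps) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  validate_sim_config(cfg)
  win_start <- unname(parse_clock(cfg$waking_window[[1]]))
  recordings <- list()
  truth_rows <- list()
  gap_rows <- list()

  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", s)
    set.seed(substream_seed(cfg$seed, s))
    walk_mult <- stats::rlnorm(1, 0, cfg$schedule_params$subject_walk_sdlog)
    deficit_shift <- stats::rnorm(1, 0, cfg$paretic_deficit$subject_sd)
    func_mult <- stats::rlnorm(1, 0, 0.3)

    for (wi in seq_along(cfg$weeks)) {
      week <- cfg$weeks[wi]
      wk <- as.character(week)
      set.seed(substream_seed(cfg$seed, s, week, 9999L))
      if (stats::runif(1) < cfg$missingness$week_absent[[wk]]) next
      base_mean <- cfg$paretic_deficit$mean[[wk]]
      deficit <- stats::plogis(stats::qlogis(min(max(base_mean, 1e-6), 1 - 1e-6)) +
                                 deficit_shift)
      week_date0 <- cfg$start_date + week * 7L

      day_parts <- vector("list", cfg$days_per_week)
      for (d in seq_len(cfg$days_per_week)) {
        set.seed(substream_seed(cfg$seed, s, week, d))
        sched <- draw_schedule(cfg, week, walk_mult)
        day <- simulate_day(sched, cfg, deficit = deficit, func_mult = func_mult)
        n <- length(day$labels)
        date <- week_date0 + (d - 1L)
        t0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") + win_start

        # inject non-wear and short zero gaps per sensor
        sensors <- list(paretic_wrist = day$paretic,
                        nonparetic_wrist = day$nonparetic, thigh = day$thigh)
        nwp <- cfg$nonwear_params
        for (role in names(sensors)) {
          if (stats::runif(1) < nwp$prob) {
            g <- inject_gap(sensors[[role]],
                            stats::runif(1, nwp$dur_range_min[1], nwp$dur_range_min[2]), n)
            sensors[[role]] <- g$counts
            gap_rows[[length(gap_rows) + 1L]] <- tibble::tibble(
              subject_id = sid, week = week, date = date, sensor_role = role,
              kind = "nonwear", start = t0 + (g$start - 1) / SAMPLE_HZ,
              end = t0 + g$end / SAMPLE_HZ)
          }
          if (stats::runif(1) < nwp$short_gap_prob) {
            g <- inject_gap(sensors[[role]],
                            stats::runif(1, nwp$short_dur_range_min[1],
                                         nwp$short_dur_range_min[2]), n)
            sensors[[role]] <- g$counts
            gap_rows[[length(gap_rows) + 1L]] <- tibble::tibble(
              subject_id = sid, week = week, date = date, sensor_role = role,
              kind = "short_gap", start = t0 + (g$start - 1) / SAMPLE_HZ,
              end = t0 + g$end / SAMPLE_HZ)
          }
        }

        n_ep <- n %/% SAMPLES_PER_EPOCH
        if (stats::runif(1) < cfg$missingness$day_truncated) {
          n_ep <- max(1L, as.integer(floor(n_ep * stats::runif(1, 0.3, 0.8))))
        }
        keep <- seq_len(n_ep * SAMPLES_PER_EPOCH)
        start_time <- t0 + (seq_len(n_ep) - 1L) * EPOCH_SECONDS
        to_epochs <- function(x) matrix(x[keep], ncol = SAMPLES_PER_EPOCH, byrow = TRUE)

        day_parts[[d]] <- list(
          start_time = start_time,
          paretic = to_epochs(sensors$paretic_wrist),
          nonparetic = to_epochs(sensors$nonparetic_wrist),
          thigh = to_epochs(sensors$thigh),
          labels = to_epochs(day$labels))

        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          subject_id = sid, week = week, date = date,
          lie_min = sched[["LIE"]] / SAMPLES_PER_MINUTE,
          sit_min = sched[["SIT"]] / SAMPLES_PER_MINUTE,
          stand_min = sched[["STA"]] / SAMPLES_PER_MINUTE,
          walk_min = sched[["WAL"]] / SAMPLES_PER_MINUTE,
          func_paretic = day$truth$func_paretic,
          func_nonparetic = day$truth$func_nonparetic,
          sway_paretic = day$truth$sway_paretic,
          sway_nonparetic = day$truth$sway_nonparetic,
          deficit = deficit, n_epochs = n_ep,
          truncated = n_ep < n %/% SAMPLES_PER_EPOCH)
      }

      bind_days <- function(field) do.call(rbind, lapply(day_parts, `[[`, field))
      start_time <- do.call(c, lapply(day_parts, `[[`, "start_time"))
      rec <- arm_recording(list(
        paretic_wrist = epoch_stream(sid, week, "paretic_wrist", start_time,
                                     bind_days("paretic")),
        nonparetic_wrist = epoch_stream(sid, week, "nonparetic_wrist", start_time,
                                        bind_days("nonparetic")),
        thigh = epoch_stream(sid, week, "thigh", start_time, bind_days("thigh"),
                             labels = bind_days("labels"))))
      recordings[[length(recordings) + 1L]] <- rec
    }
  }

  structure(list(
    recordings = recordings,
    truth = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else tibble::tibble(),
    nonwear_truth = if (length(gap_rows)) dplyr::bind_rows(gap_rows) else tibble::tibble(),
    config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d subject-weeks (%d subjects configured), seed %d\n",
              length(x$recordings), x$config$n_subjects, x$config$seed))
  invisible(x)
}
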