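# Synthetic-cohort generator: determinism, schedule conservation, injected
# effect structure, config validation, posture-classifier emulation.

test_that("identical config and seed reproduce byte-identical cohorts", {
  cfg <- sim_config(n_subjects = 2, weeks = c(3), days_per_week = 1, seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$recordings, b$recordings)
  expect_identical(a$truth, b$truth)
  expect_identical(a$nonwear_truth, b$nonwear_truth)
})

test_that("cohort composition changes do not reshuffle unrelated subjects", {
  small <- simulate_cohort(disable_dropout(sim_config(n_subjects = 2, weeks = c(3),
                                                      days_per_week = 1, seed = 5)))
  large <- simulate_cohort(disable_dropout(sim_config(n_subjects = 4, weeks = c(3),
                                                      days_per_week = 1, seed = 5)))
  expect_identical(small$recordings[[1]], large$recordings[[1]])
  expect_identical(small$recordings[[2]], large$recordings[[2]])
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(weeks = c(3, 5)), "weeks")
  expect_error(sim_config(sway_params = list(paretic_mean = 2,
                                             nonparetic_mean = 1, sd = 0.3)),
               "nonparetic_mean")
  expect_error(sim_config(burst_params = list(rate = 1.5, shape = 2, mean = 3)),
               "burst_params")
  sp <- sim_config()$schedule_params
  sp$walk_mean[] <- 2000
  expect_error(sim_config(schedule_params = sp), "walk_mean")
})

test_that("a zero-walking schedule emits no walking-labelled samples", {
  sp <- sim_config()$schedule_params
  sp$walk_mean[] <- 0
  sp$walk_sd[] <- 0
  cfg <- sim_config(n_subjects = 1, weeks = c(3), days_per_week = 1,
                    schedule_params = sp, seed = 3)
  co <- simulate_cohort(cfg)
  labs <- co$recordings[[1]]$streams$thigh$labels
  expect_true(all(labs %in% c("LIE", "SIT", "STA")))
  expect_equal(co$truth$walk_min, 0)
})

test_that("certain week-level missingness removes those subject-weeks", {
  cfg <- sim_config(n_subjects = 5, weeks = c(3, 26), days_per_week = 1, seed = 2,
                    missingness = list(week_absent = c(`3` = 0, `12` = 0, `26` = 1),
                                       day_truncated = 0))
  co <- simulate_cohort(cfg)
  wks <- vapply(co$recordings, `[[`, 1L, "week")
  expect_true(all(wks == 3))
  expect_length(co$recordings, 5)
})

test_that("scheduled minutes are conserved in the emitted label stream", {
  co <- clean_cohort(n_subjects = 2, days = 2)
  for (rec in co$recordings) {
    labs <- rec$streams$thigh$labels
    dates <- as.Date(rec$streams$thigh$start_time, tz = "UTC")
    for (d in unique(dates)) {
      day_truth <- co$truth[co$truth$subject_id == rec$subject_id &
                              co$truth$week == rec$week & co$truth$date == d, ]
      day_labs <- labs[dates == d, , drop = FALSE]
      # full waking window emitted: 1800 epochs x 48 samples
      expect_identical(nrow(day_labs), 1800L)
      expect_equal(sum(day_labs == "WAL") / 96, day_truth$walk_min)
      expect_equal(sum(day_labs == "SIT") / 96, day_truth$sit_min)
      # budgets fill the window exactly
      expect_equal(day_truth$lie_min + day_truth$sit_min +
                     day_truth$stand_min + day_truth$walk_min, 900)
    }
  }
})

test_that("wrist counts decompose additively into the injected components", {
  base <- sim_config(n_subjects = 1, weeks = c(3), days_per_week = 1, seed = 9,
                     noise_params = list(rate = 0, mean = 0))
  base <- disable_dropout(base)

  # burst 0, sway 0, noise 0 -> all wrist counts zero
  cfg0 <- base
  cfg0$burst_params$rate <- 0
  cfg0$sway_params$paretic_mean <- 0
  cfg0$sway_params$nonparetic_mean <- 0
  co0 <- simulate_cohort(cfg0)
  expect_true(all(co0$recordings[[1]]$streams$paretic_wrist$counts == 0))
  expect_true(all(co0$recordings[[1]]$streams$nonparetic_wrist$counts == 0))

  # sway 0, noise 0 -> walking samples carry zero wrist counts
  cfg1 <- base
  cfg1$sway_params$paretic_mean <- 0
  cfg1$sway_params$nonparetic_mean <- 0
  co1 <- simulate_cohort(cfg1)
  rec <- co1$recordings[[1]]
  wal <- rec$streams$thigh$labels == "WAL"
  expect_gt(sum(wal), 0)
  expect_true(all(rec$streams$paretic_wrist$counts[wal] == 0))
  expect_true(all(rec$streams$nonparetic_wrist$counts[wal] == 0))
})

test_that("no deficit and symmetric sway give symmetric expected arm use", {
  cfg <- disable_dropout(sim_config(
    n_subjects = 1, weeks = c(3), days_per_week = 1, seed = 21,
    paretic_deficit = list(mean = c(`3` = 1, `12` = 1, `26` = 1), subject_sd = 0),
    sway_params = list(paretic_mean = 1.25, nonparetic_mean = 1.25, sd = 0.3)))
  co <- simulate_cohort(cfg)
  p <- sum(co$recordings[[1]]$streams$paretic_wrist$counts)
  np <- sum(co$recordings[[1]]$streams$nonparetic_wrist$counts)
  expect_lt(abs(p - np) / np, 0.05)
})

test_that("increasing sway magnitude never decreases walking-sample counts", {
  mk <- function(sway_p, sway_np) {
    cfg <- disable_dropout(sim_config(
      n_subjects = 2, weeks = c(3), days_per_week = 1, seed = 31,
      sway_params = list(paretic_mean = sway_p, nonparetic_mean = sway_np,
                         sd = 0.3)))
    simulate_cohort(cfg)
  }
  lo <- mk(0.5, 0.75)
  hi <- mk(1.5, 2.0)
  for (i in seq_along(lo$recordings)) {
    wal <- lo$recordings[[i]]$streams$thigh$labels == "WAL"
    expect_identical(wal, hi$recordings[[i]]$streams$thigh$labels == "WAL")
    for (role in c("paretic_wrist", "nonparetic_wrist")) {
      expect_gte(sum(hi$recordings[[i]]$streams[[role]]$counts[wal]),
                 sum(lo$recordings[[i]]$streams[[role]]$counts[wal]))
    }
  }
})

test_that("simulate_day rejects nothing but produces non-negative counts", {
  cfg <- sim_config()
  set.seed(1)
  sched <- c(LIE = 100L, SIT = 400L, STA = 200L, WAL = 100L) * 96L
  # pad to a small window: budgets are arbitrary here
  day <- simulate_day(sched, cfg, deficit = 0.5)
  expect_length(day$labels, sum(sched))
  expect_true(all(day$paretic >= 0))
  expect_true(all(day$nonparetic >= 0))
  expect_true(all(day$thigh >= 0))
  expect_equal(sum(day$labels == "WAL"), sched[["WAL"]])
})

test_that("posture classifier follows the orientation and intensity rules", {
  # upright static -> standing
  expect_true(all(emulate_posture_classifier(synth_raw_segment("upright")) == "STA"))
  # horizontal static -> sitting (tie-break: anterior surface up) or lying
  expect_true(all(emulate_posture_classifier(synth_raw_segment("sitting")) == "SIT"))
  expect_true(all(emulate_posture_classifier(synth_raw_segment("lying_side")) == "LIE"))
  # empty signal -> empty labels
  expect_identical(emulate_posture_classifier(matrix(numeric(0), ncol = 3)),
                   character(0))

  # upright + dynamic component above the walking threshold -> walking.
  # The expected intensity is computed with the classifier's own statistic
  # (SD of the magnitude within each 1.6 Hz window) on this very signal.
  raw <- synth_raw_segment("upright", duration_s = 10, dynamic_amp = 0.4,
                           dynamic_hz = 2)
  mag <- sqrt(rowSums(raw^2))
  win_sd <- vapply(seq_len(16), function(k) {
    idx <- (floor((k - 1) * 12.5 / 1.6) + 1):floor(k * 12.5 / 1.6)
    sd(mag[idx])
  }, 0)
  expect_true(all(win_sd > 0.08))      # above walk_thresh
  expect_true(all(win_sd < 0.8))       # below run_thresh
  expect_true(all(emulate_posture_classifier(raw) == "WAL"))
})

test_that("sim config YAML round-trips", {
  cfg <- fixture_config(seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2, cfg)
})
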