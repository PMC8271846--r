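# Waking-hours window, non-wear detection, valid-day and valid-week rules.

test_that("waking-hours restriction is the half-open clock window [07:00, 22:00)", {
  t0 <- as.POSIXct("2023-05-01 00:00:00", tz = "UTC")
  clocks <- c("06:59:30", "07:00:00", "14:00:00", "21:59:30", "22:00:00")
  st <- t0 + sapply(strsplit(clocks, ":"), function(p)
    as.numeric(p[1]) * 3600 + as.numeric(p[2]) * 60 + as.numeric(p[3]))
  mk <- function(role) epoch_stream("S01", 3, role, st, matrix(1, 5, 48),
                                    labels = if (role == "thigh")
                                      matrix("SIT", 5, 48) else NULL)
  rec <- arm_recording(list(paretic_wrist = mk("paretic_wrist"),
                            nonparetic_wrist = mk("nonparetic_wrist"),
                            thigh = mk("thigh")))
  out <- restrict_waking_hours(rec)
  kept <- format(out$streams$thigh$start_time, "%H:%M:%S", tz = "UTC")
  expect_identical(kept, c("07:00:00", "14:00:00", "21:59:30"))
})

test_that("the one-hour zero-run rule is inclusive at exactly 60 minutes", {
  t0 <- as.POSIXct("2023-05-01 07:00:00", tz = "UTC")
  zero_run <- function(n_zero) {
    counts <- rbind(matrix(1, 2, 48), matrix(0, n_zero, 48), matrix(1, 2, 48))
    epoch_stream("S01", 3, "paretic_wrist",
                 t0 + (seq_len(nrow(counts)) - 1) * 30, counts)
  }
  # 120 all-zero epochs = exactly 60 min -> one non-wear interval
  nw <- detect_nonwear(zero_run(120))
  expect_identical(nrow(nw), 1L)
  expect_equal(nw$duration_min, 60)
  # 119 epochs = 59.5 min -> none
  expect_identical(nrow(detect_nonwear(zero_run(119))), 0L)
})

test_that("a single nonzero count splits a zero run below threshold", {
  t0 <- as.POSIXct("2023-05-01 07:00:00", tz = "UTC")
  counts <- matrix(0, 121, 48)
  counts[61, 24] <- 2  # one nonzero sample at ~minute 30
  s <- epoch_stream("S01", 3, "paretic_wrist", t0 + (0:120) * 30, counts)
  expect_identical(nrow(detect_nonwear(s)), 0L)
})

test_that("non-wear detection works at sample resolution across epoch boundaries", {
  t0 <- as.POSIXct("2023-05-01 07:00:00", tz = "UTC")
  # 60 min of zeros starting mid-epoch: 24 zero samples at the end of epoch 1,
  # 119 all-zero epochs, 24 zero samples at the start of the last epoch
  first <- c(rep(1, 24), rep(0, 24))
  last <- c(rep(0, 24), rep(1, 24))
  counts <- rbind(first, matrix(0, 119, 48), last)
  s <- epoch_stream("S01", 3, "paretic_wrist", t0 + (0:120) * 30, counts)
  nw <- detect_nonwear(s)
  expect_identical(nrow(nw), 1L)
  expect_equal(nw$duration_min, 60)
  # the same samples re-chunked with the run starting on an epoch boundary
  counts2 <- rbind(matrix(1, 1, 48), matrix(0, 120, 48), matrix(1, 1, 48))
  nw2 <- detect_nonwear(epoch_stream("S01", 3, "paretic_wrist",
                                     t0 + (0:121) * 30, counts2))
  expect_equal(nw2$duration_min, nw$duration_min)
})

test_that("valid-day (>= 10 h) and valid-week (>= 2 days) rules are inclusive", {
  # day of exactly 1200 retained epochs = 600 min -> valid
  rec <- full_sit_day(n_epochs = 1200)
  ws <- validate_days(rec)
  expect_identical(nrow(ws$days), 1L)
  expect_equal(ws$days$wear_min, 600)
  expect_true(ws$days$valid_day)

  # 9 h -> invalid
  ws9 <- validate_days(full_sit_day(n_epochs = 1080))
  expect_false(ws9$days$valid_day)

  # two valid days -> valid week; one -> invalid
  two <- clean_cohort(n_subjects = 1, days = 2, seed = 4)
  rec2 <- synchronize_streams(two$recordings[[1]])
  rec2 <- restrict_waking_hours(rec2)
  ws2 <- validate_days(rec2)
  expect_identical(nrow(ws2$days), 2L)
  expect_true(ws2$valid_week)

  one <- clean_cohort(n_subjects = 1, days = 1, seed = 4)
  ws1 <- validate_days(restrict_waking_hours(synchronize_streams(one$recordings[[1]])))
  expect_false(ws1$valid_week)
})

test_that("an epoch is excluded when any sensor is in non-wear there", {
  # 1320 epochs (11 h); zero out 120 epochs on one wrist only
  n <- 1320L
  counts_nw <- matrix(1, n, 48)
  counts_nw[101:220, ] <- 0
  rec <- make_recording(labels = rep("SIT", n), paretic = 1, nonparetic = 1,
                        thigh = 1)
  rec$streams$paretic_wrist$counts <- counts_nw
  ws <- validate_days(rec)
  expect_identical(nrow(ws$nonwear$paretic_wrist), 1L)
  expect_identical(sum(ws$retained), n - 120L)
  # whole-configuration wear drops by the non-wear hour
  expect_equal(ws$days$wear_min, (n - 120) * 0.5)
  # still a valid day (11 h - 1 h = 10 h, inclusive)
  expect_true(ws$days$valid_day)
})

test_that("validate_days is deterministic given its inputs", {
  co <- demo_cohort()
  rec <- restrict_waking_hours(synchronize_streams(co$recordings[[1]]))
  a <- validate_days(rec)
  b <- validate_days(rec)
  expect_identical(a$days, b$days)
  expect_identical(a$retained, b$retained)
})

test_that("injected long gaps are detected, short gaps are not", {
  cfg <- sim_config(n_subjects = 4, weeks = c(3), days_per_week = 2, seed = 13,
                    missingness = list(week_absent = c(`3` = 0, `12` = 0, `26` = 0),
                                       day_truncated = 0))
  co <- simulate_cohort(cfg)
  truth <- co$nonwear_truth
  expect_gt(nrow(truth), 0)
  for (i in seq_along(co$recordings)) {
    rec <- restrict_waking_hours(synchronize_streams(co$recordings[[i]]))
    for (role in SENSOR_ROLES) {
      nw <- detect_nonwear(rec$streams[[role]])
      tr <- truth[truth$subject_id == rec$subject_id & truth$week == rec$week &
                    truth$sensor_role == role, ]
      for (j in seq_len(nrow(tr))) {
        covered <- nrow(nw) > 0 &&
          any(nw$start <= tr$start[j] & nw$end >= tr$end[j])
        if (tr$kind[j] == "nonwear") {
          expect_true(covered, info = sprintf("%s %s gap %d not detected",
                                              rec$subject_id, role, j))
        }
      }
      # every detected interval is >= 60 min
      if (nrow(nw)) expect_true(all(nw$duration_min >= 60))
    }
  }
})
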