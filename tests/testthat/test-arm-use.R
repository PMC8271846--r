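# Epoch classification, daily outcomes, weekly aggregation.

test_that("the 90% sitting/standing epoch rule is inclusive", {
  expect_true(classify_epoch_sitstand(rep("SIT", 48)))
  expect_true(classify_epoch_sitstand(c(rep("SIT", 44), rep("WAL", 4))))   # 91.7%
  expect_false(classify_epoch_sitstand(c(rep("SIT", 43), rep("WAL", 5))))  # 89.6%
  expect_true(classify_epoch_sitstand(c(rep("SIT", 20), rep("STA", 24),
                                        rep("LIE", 4))))
  expect_error(classify_epoch_sitstand(NULL), "missing")
  expect_error(classify_epoch_sitstand(rep("SIT", 47)), "48")
})

test_that("P&M sums all retained epochs, sit/stand only the gated subset", {
  # one sitting epoch (paretic counts sum 5) + one walking epoch (sum 7)
  labels <- rbind(matrix("SIT", 1, 48), matrix("WAL", 1, 48))
  paretic <- rbind(c(5, rep(0, 47)), c(7, rep(0, 47)))
  nonparetic <- rbind(c(10, rep(0, 47)), c(14, rep(0, 47)))
  rec <- make_recording(labels = labels, paretic = paretic,
                        nonparetic = nonparetic, thigh = 0)
  ws <- validate_days(rec, min_wear_min = 0)
  out <- compute_daily_outcomes(rec, ws)
  expect_equal(out$paretic_pm, 12)
  expect_equal(out$paretic_ss, 5)
  expect_equal(out$nonparetic_pm, 24)
  expect_equal(out$nonparetic_ss, 10)
  expect_equal(out$ratio_pm, 0.5)
  expect_equal(out$ratio_ss, 0.5)
  expect_equal(out$walk_min, 0.5)
  expect_equal(out$sit_stand_min, 0.5)
})

test_that("identical count streams on both wrists give ratios of exactly 1", {
  co <- clean_cohort(n_subjects = 1, days = 1, seed = 8)
  rec <- co$recordings[[1]]
  rec$streams$nonparetic_wrist$counts <- rec$streams$paretic_wrist$counts
  res <- process_recording(rec, min_valid_days = 1)
  expect_equal(res$daily$ratio_pm, 1)
  expect_equal(res$daily$ratio_ss, 1)
})

test_that("a zero nonparetic denominator flags the ratio as undefined", {
  labels <- matrix("SIT", 2, 48)
  rec <- make_recording(labels = labels, paretic = 1, nonparetic = 0, thigh = 1)
  ws <- validate_days(rec, min_wear_min = 0)
  out <- compute_daily_outcomes(rec, ws)
  expect_true(is.na(out$ratio_pm))
  expect_true(is.na(out$ratio_ss))
  expect_false(is.infinite(out$ratio_pm))
})

test_that("conservation: P&M minus sit/stand equals the non-sit/stand sum", {
  co <- demo_cohort()
  rec <- co$recordings[[1]]
  res <- process_recording(rec)
  # independent recomputation from the raw epochs
  sync <- restrict_waking_hours(synchronize_streams(rec))
  ws <- validate_days(sync)
  dates <- as.Date(sync$streams$thigh$start_time, tz = "UTC")
  for (i in seq_len(nrow(res$daily))) {
    d <- res$daily$date[i]
    idx <- which(dates == d & ws$retained)
    ss <- classify_epoch_sitstand(sync$streams$thigh$labels[idx, , drop = FALSE])
    non_ss_sum <- sum(sync$streams$paretic_wrist$counts[idx[!ss], , drop = FALSE])
    expect_equal(res$daily$paretic_pm[i] - res$daily$paretic_ss[i], non_ss_sum)
    non_ss_np <- sum(sync$streams$nonparetic_wrist$counts[idx[!ss], , drop = FALSE])
    expect_equal(res$daily$nonparetic_pm[i] - res$daily$nonparetic_ss[i], non_ss_np)
    # subset property
    expect_lte(res$daily$paretic_ss[i], res$daily$paretic_pm[i])
    expect_lte(res$daily$nonparetic_ss[i], res$daily$nonparetic_pm[i])
  }
})

test_that("scaling all wrist counts scales count outcomes and fixes ratios", {
  co <- clean_cohort(n_subjects = 1, days = 1, seed = 15)
  rec <- co$recordings[[1]]
  base <- process_recording(rec, min_valid_days = 1)$daily
  rec2 <- rec
  rec2$streams$paretic_wrist$counts <- rec$streams$paretic_wrist$counts * 3
  rec2$streams$nonparetic_wrist$counts <- rec$streams$nonparetic_wrist$counts * 3
  scaled <- process_recording(rec2, min_valid_days = 1)$daily
  for (col in c("paretic_pm", "nonparetic_pm", "paretic_ss", "nonparetic_ss")) {
    expect_equal(scaled[[col]], 3 * base[[col]])
  }
  expect_equal(scaled$ratio_pm, base$ratio_pm)
  expect_equal(scaled$ratio_ss, base$ratio_ss)
})

test_that("on an all-sit/stand day the two methods coincide", {
  rec <- full_sit_day(n_epochs = 1300)
  res <- process_recording(rec, min_valid_days = 1)
  expect_equal(res$daily$paretic_pm, res$daily$paretic_ss)
  expect_equal(res$daily$nonparetic_pm, res$daily$nonparetic_ss)
  expect_equal(res$daily$ratio_pm, res$daily$ratio_ss)
})

test_that("weekly aggregation averages over valid days only", {
  daily <- tibble::tibble(
    subject_id = "S01", week = 3,
    date = as.Date("2023-05-01") + 0:2,
    wear_min = c(700, 700, 400), sit_stand_min = c(600, 600, 300),
    walk_min = c(30, 50, 10),
    paretic_pm = c(100, 200, 999), nonparetic_pm = c(200, 400, 999),
    ratio_pm = c(0.5, 0.5, 0.5),
    paretic_ss = c(80, 160, 999), nonparetic_ss = c(160, 320, 999),
    ratio_ss = c(0.5, 0.5, 0.5),
    n_epochs = 1, n_ss_epochs = 1,
    valid_day = c(TRUE, TRUE, FALSE))
  wk <- aggregate_weekly(daily)
  expect_identical(nrow(wk), 1L)
  expect_equal(wk$paretic_pm, 150)
  expect_equal(wk$n_valid_days, 2L)

  # one valid day -> no weekly row
  daily1 <- daily
  daily1$valid_day <- c(TRUE, FALSE, FALSE)
  expect_identical(nrow(aggregate_weekly(daily1)), 0L)

  # all days invalid -> nothing
  daily0 <- daily
  daily0$valid_day <- FALSE
  expect_identical(nrow(aggregate_weekly(daily0)), 0L)

  # undefined ratios excluded from the ratio mean with n reported
  daily2 <- daily
  daily2$ratio_pm <- c(0.4, NA, 0.6)
  wk2 <- aggregate_weekly(daily2)
  expect_equal(wk2$ratio_pm, 0.4)
  expect_identical(wk2$n_ratio_pm, 1L)
})

test_that("pipeline recovers scheduled walking minutes when dropout is off", {
  co <- clean_cohort(n_subjects = 3, days = 2, seed = 19)
  res <- process_cohort(co$recordings)
  merged <- dplyr::inner_join(
    res$daily, co$truth[, c("subject_id", "week", "date", "walk_min")],
    by = c("subject_id", "week", "date"), suffix = c("", "_truth"))
  expect_identical(nrow(merged), nrow(co$truth))
  expect_equal(merged$walk_min, merged$walk_min_truth, tolerance = 1e-10)
})
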