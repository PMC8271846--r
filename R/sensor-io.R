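# Epoch CSV dialect and stream synchronization.
#
# One row per epoch: subject_id, week, sensor_role, start_time (ISO-8601 with
# offset), c01..c48 (counts); thigh files add l01..l48 (posture labels from
# the fixed vocabulary). Flat and diff-able; loads with any table reader.

count_cols <- sprintf("c%02d", seq_len(SAMPLES_PER_EPOCH))
label_cols <- sprintf("l%02d", seq_len(SAMPLES_PER_EPOCH))

fmt_iso8601 <- function(t) format(t, "%Y-%m-%dT%H:%M:%S+00:00", tz = "UTC")

parse_iso8601 <- function(x) {
  # clock times are stored with their stated offset; we keep them in UTC
  t <- as.POSIXct(sub("([+-]\\d{2}):?(\\d{2})$", "", x),
                  format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  t
}

#' Write epoch streams to the flat CSV format
#'
#' @param streams an [epoch_stream()] or a list of them (all the same
#'   `sensor_role`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(streams, path) {
  if (inherits(streams, "epoch_stream")) streams <- list(streams)
  roles <- unique(vapply(streams, `[[`, "", "sensor_role"))
  if (length(roles) != 1) stop("all streams in one file must share a sensor_role",
                               call. = FALSE)
  tabs <- lapply(streams, function(s) {
    dt <- data.table::data.table(
      subject_id = s$subject_id, week = s$week, sensor_role = s$sensor_role,
      start_time = fmt_iso8601(s$start_time))
    cm <- data.table::as.data.table(s$counts)
    data.table::setnames(cm, count_cols)
    dt <- cbind(dt, cm)
    if (!is.null(s$labels)) {
      lm <- data.table::as.data.table(s$labels)
      data.table::setnames(lm, label_cols)
      dt <- cbind(dt, lm)
    }
    dt
  })
  data.table::fwrite(data.table::rbindlist(tabs), path)
  invisible(path)
}

#' Read epoch streams from the flat CSV format
#'
#' Validates structure row by row: 48 numeric non-negative counts per epoch,
#' strictly increasing 30 s-aligned timestamps within each subject-week,
#' labels present on thigh streams and absent on wrist streams. Malformed
#' input raises an error naming the violation and the offending line.
#'
#' @param path CSV path in the dialect written by [write_epoch_csv()].
#' @param sensor_role expected sensor role of the file.
#' @return A list of [epoch_stream()], one per subject-week in the file.
#' @export
read_epoch_csv <- function(path, sensor_role) {
  sensor_role <- match.arg(sensor_role, SENSOR_ROLES)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", blank.lines.skip = TRUE)
  if (length(unique(nf)) > 1) {
    bad <- which(nf != nf[1])
    stop("malformed epoch CSV: expected ", nf[1], " fields per row (",
         SAMPLES_PER_EPOCH, " count fields c01..c48) but line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), " have a different count",
         call. = FALSE)
  }
  dt <- data.table::fread(path, colClasses = list(character = c("subject_id",
                                                                "start_time")))
  need <- c("subject_id", "week", "sensor_role", "start_time", count_cols)
  if (sensor_role == "thigh") need <- c(need, label_cols)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("epoch CSV is missing expected column(s) (", length(need),
         " required, e.g. 48 count fields c01..c48): ",
         paste(utils::head(missing_cols, 4), collapse = ", "), call. = FALSE)
  }
  if (sensor_role != "thigh" && any(label_cols %in% names(dt))) {
    stop("posture label columns found in a ", sensor_role,
         " file; labels are only valid on the thigh stream", call. = FALSE)
  }
  if (!all(dt$sensor_role == sensor_role)) {
    stop("sensor_role column disagrees with expected role '", sensor_role, "'",
         call. = FALSE)
  }
  cm <- as.matrix(dt[, count_cols, with = FALSE])
  if (!is.numeric(cm)) stop("non-numeric movement counts in ", path, call. = FALSE)
  partial <- which(rowSums(is.na(cm)) > 0)
  if (length(partial)) {
    warning(length(partial), " partial epoch(s) (<48 samples) discarded at lines ",
            paste(utils::head(partial + 1L, 5), collapse = ", "), call. = FALSE)
    dt <- dt[-partial]
    cm <- cm[-partial, , drop = FALSE]
  }
  neg <- which(rowSums(cm < 0) > 0)
  if (length(neg)) {
    stop("negative movement counts at line(s) ",
         paste(utils::head(neg + 1L, 5), collapse = ", "), call. = FALSE)
  }
  tt <- parse_iso8601(dt$start_time)
  if (anyNA(tt)) {
    stop("unparseable start_time at line(s) ",
         paste(utils::head(which(is.na(tt)) + 1L, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(dt$subject_id, dt$week)
  out <- lapply(split(seq_len(nrow(dt)), key), function(idx) {
    if (length(idx) > 1 && any(diff(as.numeric(tt[idx])) <= 0)) {
      stop("non-monotone or duplicated start_time within subject-week ",
           key[idx[1]], call. = FALSE)
    }
    labels <- NULL
    if (sensor_role == "thigh") {
      labels <- as.matrix(dt[idx, label_cols, with = FALSE])
      bad <- which(!(labels %in% POSTURE_LABELS))
      if (length(bad)) {
        stop("unknown posture label(s) in subject-week ", key[idx[1]], ": ",
             paste(utils::head(unique(labels[bad]), 5), collapse = ", "),
             call. = FALSE)
      }
    }
    epoch_stream(dt$subject_id[idx[1]], dt$week[idx[1]], sensor_role,
                 tt[idx], cm[idx, , drop = FALSE], labels)
  })
  unname(out)
}

#' Write a simulated cohort to disk
#'
#' Emits one epoch CSV per sensor role, the ground-truth CSVs and the
#' resolved configuration as YAML.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (role in SENSOR_ROLES) {
    streams <- lapply(cohort$recordings, function(r) r$streams[[role]])
    write_epoch_csv(streams, file.path(dir, paste0("epochs_", role, ".csv")))
  }
  data.table::fwrite(cohort$truth, file.path(dir, "ground_truth.csv"))
  if (nrow(cohort$nonwear_truth)) {
    nw <- cohort$nonwear_truth
    nw$start <- fmt_iso8601(nw$start)
    nw$end <- fmt_iso8601(nw$end)
    data.table::fwrite(nw, file.path(dir, "nonwear_truth.csv"))
  }
  write_sim_config(cohort$config, file.path(dir, "sim_config.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param dir directory containing the three epoch CSVs.
#' @return A list of [arm_recording()], one per subject-week.
#' @export
read_cohort_csv <- function(dir) {
  by_role <- lapply(stats::setNames(SENSOR_ROLES, SENSOR_ROLES), function(role) {
    read_epoch_csv(file.path(dir, paste0("epochs_", role, ".csv")), role)
  })
  keys <- lapply(by_role, function(streams)
    vapply(streams, function(s) paste(s$subject_id, s$week), ""))
  common <- Reduce(intersect, keys)
  lapply(common, function(k) {
    arm_recording(lapply(by_role, function(streams) {
      streams[[match(k, vapply(streams, function(s) paste(s$subject_id, s$week), ""))]]
    }))
  })
}

#' Time-synchronize the three sensor streams of a recording
#'
#' Retains only epochs whose start time occurs in all three streams; the
#' number of epochs dropped from each stream is attached as the `"dropped"`
#' attribute and logged.
#'
#' @param recording an [arm_recording()].
#' @param quiet suppress the per-stream drop log.
#' @return The synchronized `arm_recording`.
#' @export
synchronize_streams <- function(recording, quiet = TRUE) {
  times <- lapply(recording$streams, function(s) as.numeric(s$start_time))
  common <- Reduce(intersect, times)
  if (length(common) == 0) {
    stop("no co-registered data: the three streams share no epoch start times",
         call. = FALSE)
  }
  dropped <- integer(0)
  for (role in names(recording$streams)) {
    keep <- times[[role]] %in% common
    dropped[role] <- sum(!keep)
    recording$streams[[role]] <- subset_stream(recording$streams[[role]], keep)
  }
  if (!quiet && any(dropped > 0)) {
    message("synchronize_streams: dropped ",
            paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "))
  }
  attr(recording, "dropped") <- dropped
  recording
}
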