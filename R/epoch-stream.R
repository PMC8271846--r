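# Core data model: 30 s epochs of 48 movement-count samples (1.6 Hz) per
# sensor, three sensors per subject-week (paretic wrist, nonparetic wrist,
# thigh). The thigh stream additionally carries a posture label per sample.

#' Constants of the epoch data model
#'
#' The devices emit movement counts at 1.6 Hz and store them in 30 s epochs of
#' 48 samples. The thigh sensor labels every sample with one of six body
#' postures/movements.
#'
#' @name epoch-model
#' @keywords internal
NULL

SAMPLES_PER_EPOCH <- 48L
EPOCH_SECONDS <- 30
SAMPLE_HZ <- 1.6
SAMPLES_PER_MINUTE <- 96L # 1.6 Hz * 60 s

#' Posture label vocabulary of the thigh sensor
#' @export
POSTURE_LABELS <- c("LIE", "SIT", "STA", "WAL", "CYC", "RUN")

#' Sensor roles of the three-accelerometer configuration
#' @export
SENSOR_ROLES <- c("paretic_wrist", "nonparetic_wrist", "thigh")

#' Build an epoch stream for one sensor of one subject-week
#'
#' An epoch stream is the ordered sequence of 30 s epochs recorded by one
#' sensor. Counts are stored as an `n x 48` matrix (one row per epoch); the
#' thigh stream carries an `n x 48` character matrix of posture labels.
#'
#' @param subject_id character scalar.
#' @param week measurement week post-stroke (3, 12 or 26).
#' @param sensor_role one of `r paste(SENSOR_ROLES, collapse = ", ")`.
#' @param start_time `POSIXct` vector of epoch start times (UTC-stored local
#'   clock time), strictly increasing and aligned to 30 s.
#' @param counts numeric matrix with 48 columns, non-negative.
#' @param labels character matrix with 48 columns (thigh only), values from
#'   [POSTURE_LABELS].
#' @return An object of class `epoch_stream`.
#' @export
epoch_stream <- function(subject_id, week, sensor_role, start_time, counts,
                         labels = NULL) {
  sensor_role <- match.arg(sensor_role, SENSOR_ROLES)
  counts <- as.matrix(counts)
  if (ncol(counts) != SAMPLES_PER_EPOCH) {
    stop("counts must have exactly ", SAMPLES_PER_EPOCH, " columns, got ",
         ncol(counts), call. = FALSE)
  }
  if (any(counts < 0)) stop("negative movement counts are not allowed", call. = FALSE)
  if (!inherits(start_time, "POSIXct")) stop("start_time must be POSIXct", call. = FALSE)
  if (length(start_time) != nrow(counts)) {
    stop("start_time length must match number of epochs", call. = FALSE)
  }
  if (nrow(counts) > 1 && any(diff(as.numeric(start_time)) <= 0)) {
    stop("epoch start_times must be strictly increasing", call. = FALSE)
  }
  if (any(as.numeric(start_time) %% EPOCH_SECONDS != 0)) {
    stop("epoch start_times must be aligned to 30 s", call. = FALSE)
  }
  if (sensor_role == "thigh") {
    if (is.null(labels)) stop("thigh stream requires posture labels", call. = FALSE)
    labels <- as.matrix(labels)
    if (!identical(dim(labels), dim(counts))) {
      stop("labels must have the same dimensions as counts", call. = FALSE)
    }
    bad <- !(labels %in% POSTURE_LABELS)
    if (any(bad)) {
      stop("unknown posture label(s): ",
           paste(unique(labels[bad]), collapse = ", "), call. = FALSE)
    }
  } else if (!is.null(labels)) {
    stop("posture labels are only valid on the thigh stream", call. = FALSE)
  }
  structure(
    list(subject_id = as.character(subject_id), week = as.integer(week),
         sensor_role = sensor_role, start_time = start_time,
         counts = unname(counts), labels = if (is.null(labels)) NULL else unname(labels)),
    class = "epoch_stream"
  )
}

#' @export
print.epoch_stream <- function(x, ...) {
  cat(sprintf("<epoch_stream> %s week %d, %s: %d epochs (%s .. %s)\n",
              x$subject_id, x$week, x$sensor_role, nrow(x$counts),
              format(min(x$start_time)), format(max(x$start_time))))
  invisible(x)
}

n_epochs <- function(stream) nrow(stream$counts)

# Subset a stream to a logical/integer epoch index, keeping metadata.
subset_stream <- function(stream, idx) {
  stream$start_time <- stream$start_time[idx]
  stream$counts <- stream$counts[idx, , drop = FALSE]
  if (!is.null(stream$labels)) stream$labels <- stream$labels[idx, , drop = FALSE]
  stream
}

#' Bundle the three synchronized sensor streams of one subject-week
#'
#' @param streams named list with elements `paretic_wrist`, `nonparetic_wrist`
#'   and `thigh`, each an [epoch_stream()] for the same subject and week.
#' @return An object of class `arm_recording`.
#' @export
arm_recording <- function(streams) {
  if (!all(SENSOR_ROLES %in% names(streams))) {
    stop("streams must contain all of: ", paste(SENSOR_ROLES, collapse = ", "),
         call. = FALSE)
  }
  streams <- streams[SENSOR_ROLES]
  ids <- unique(vapply(streams, `[[`, "", "subject_id"))
  wks <- unique(vapply(streams, `[[`, 1L, "week"))
  if (length(ids) != 1L || length(wks) != 1L) {
    stop("all three streams must belong to the same subject and week", call. = FALSE)
  }
  structure(list(subject_id = ids, week = wks, streams = streams),
            class = "arm_recording")
}

#' @export
print.arm_recording <- function(x, ...) {
  cat(sprintf("<arm_recording> %s week %d\n", x$subject_id, x$week))
  for (s in x$streams) {
    cat(sprintf("  %-17s %d epochs\n", s$sensor_role, n_epochs(s)))
  }
  invisible(x)
}

# Seconds since local midnight for each epoch start.
seconds_of_day <- function(start_time) {
  as.numeric(start_time) %% 86400
}

# Calendar date of each epoch (clock time is stored in UTC).
epoch_date <- function(start_time) {
  as.Date(start_time, tz = "UTC")
}

parse_clock <- function(x) {
  # "HH:MM" -> seconds since midnight
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.numeric(parts[1]) * 3600 + as.numeric(parts[2]) * 60
}
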