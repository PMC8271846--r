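# Device-emulation posture classifier. The thigh-worn device derives posture
# labels from (1) the orientation of the sensor relative to gravity and
# (2) the intensity of movement. Its firmware is proprietary; this emulation
# implements those two ingredients with explicit, configurable thresholds.

#' Emulate the thigh sensor's posture classifier
#'
#' Converts a tri-axial acceleration signal (g units, 12.5 Hz) into posture
#' labels at the device's 1.6 Hz output rate. Axis convention (thigh-mounted):
#' `x` is the thigh's longitudinal axis (distal positive, so `x` aligns with
#' gravity when upright), `y` mediolateral, `z` the outward normal of the
#' anterior thigh surface (pointing up when seated).
#'
#' Each 1.6 Hz output sample summarises the raw samples of its window: the
#' mean acceleration vector gives the inclination of the longitudinal axis to
#' gravity, and the standard deviation of the vector magnitude gives the
#' movement intensity. Labels:
#' \itemize{
#'   \item upright (inclination < `incl_thresh`): `STA` below `walk_thresh`,
#'     `WAL` between `walk_thresh` and `run_thresh`, `RUN` above;
#'   \item horizontal thigh: `CYC` above `cycle_thresh`; otherwise `SIT` when
#'     the anterior surface faces up (|z| component of gravity dominates |y|),
#'     else `LIE` (tie-break convention for a horizontal thigh).
#' }
#'
#' @param raw numeric matrix `n x 3` of accelerations in g (columns x, y, z).
#' @param fs raw sampling frequency (Hz).
#' @param out_hz output label rate (Hz).
#' @param incl_thresh inclination threshold (degrees) separating upright from
#'   horizontal; default 45.
#' @param walk_thresh,run_thresh,cycle_thresh intensity thresholds (g) on the
#'   within-window SD of the acceleration magnitude.
#' @return Character vector of labels from [POSTURE_LABELS], one per 1.6 Hz
#'   output sample; empty input gives an empty vector.
#' @export
emulate_posture_classifier <- function(raw, fs = 12.5, out_hz = SAMPLE_HZ,
                                       incl_thresh = 45,
                                       walk_thresh = 0.08, run_thresh = 0.8,
                                       cycle_thresh = 0.3) {
  raw <- as.matrix(raw)
  if (nrow(raw) == 0) return(character(0))
  if (ncol(raw) != 3) stop("raw must have 3 columns (x, y, z)", call. = FALSE)
  n_out <- floor(nrow(raw) * out_hz / fs)
  if (n_out == 0) return(character(0))
  # window k covers raw samples (floor((k-1)*fs/out_hz), floor(k*fs/out_hz)]
  bounds <- floor((0:n_out) * fs / out_hz)
  labels <- character(n_out)
  for (k in seq_len(n_out)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    win <- raw[idx, , drop = FALSE]
    g <- colMeans(win)
    gn <- sqrt(sum(g^2))
    incl <- if (gn > 0) acos(pmin(pmax(g[1] / gn, -1), 1)) * 180 / pi else 90
    mag <- sqrt(rowSums(win^2))
    intensity <- if (length(mag) > 1) stats::sd(mag) else 0
    labels[k] <- if (incl < incl_thresh) {
      if (intensity >= run_thresh) "RUN"
      else if (intensity >= walk_thresh) "WAL"
      else "STA"
    } else {
      if (intensity >= cycle_thresh) "CYC"
      else if (abs(g[3]) >= abs(g[2])) "SIT"
      else "LIE"
    }
  }
  labels
}

#' Synthesise a raw tri-axial acceleration segment
#'
#' Test signal generator for [emulate_posture_classifier()]: a static gravity
#' vector for a given device orientation plus an optional sinusoidal dynamic
#' component along the longitudinal axis.
#'
#' @param posture one of `"upright"`, `"sitting"` (thigh horizontal, anterior
#'   surface up) or `"lying_side"` (thigh horizontal, mediolateral axis
#'   vertical).
#' @param duration_s segment duration in seconds.
#' @param fs sampling frequency (Hz).
#' @param dynamic_amp amplitude (g) of the sinusoidal dynamic component.
#' @param dynamic_hz frequency of the dynamic component.
#' @return Numeric matrix `n x 3` in g.
#' @export
synth_raw_segment <- function(posture = c("upright", "sitting", "lying_side"),
                              duration_s = 10, fs = 12.5,
                              dynamic_amp = 0, dynamic_hz = 2) {
  posture <- match.arg(posture)
  n <- round(duration_s * fs)
  gvec <- switch(posture,
                 upright = c(1, 0, 0),
                 sitting = c(0, 0, 1),
                 lying_side = c(0, 1, 0))
  raw <- matrix(rep(gvec, each = n), ncol = 3)
  if (dynamic_amp > 0) {
    t <- seq_len(n) / fs
    raw[, 1] <- raw[, 1] + dynamic_amp * sin(2 * pi * dynamic_hz * t)
  }
  raw
}
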