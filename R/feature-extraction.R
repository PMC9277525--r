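## Feature extraction: one scalar readout per active-test session.
##
## Each extractor implements the feature definition for one test; failures of
## the minimum-evidence gates (too few taps / turns / steps, empty traces) are
## signalled as classed conditions and surfaced by extract_features() as
## qc_status = "fail" rather than hard errors, because an unevaluable session
## is a QC outcome, not a programming error.

extraction_error <- function(msg, reason) {
  stop(structure(class = c("hd_extraction_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), reason = reason)))
}

#' Sensor recording container
#'
#' Bundles a time base with tri-axial accelerometer (m/s^2) and, optionally,
#' gyroscope (rad/s) streams for a single test session. Streams are stored
#' as-is; IMU extractors resample to a uniform grid (50 Hz) internally.
#'
#' @param t Numeric vector of sample times in seconds, strictly increasing.
#' @param acc n x 3 matrix of accelerations (m/s^2), or NULL.
#' @param gyro n x 3 matrix of angular rates (rad/s), or NULL.
#' @return Object of class `sensor_recording`.
#' @export
sensor_recording <- function(t, acc = NULL, gyro = NULL) {
  stopifnot(is.numeric(t), length(t) >= 2L, all(diff(t) > 0))
  for (m in list(acc, gyro)) {
    if (!is.null(m)) {
      stopifnot(is.matrix(m), ncol(m) == 3L, nrow(m) == length(t),
                all(is.finite(m)))
    }
  }
  structure(list(t = as.numeric(t), acc = acc, gyro = gyro),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d samples over %.2f s (acc: %s, gyro: %s)\n",
              length(x$t), diff(range(x$t)),
              if (is.null(x$acc)) "no" else "yes",
              if (is.null(x$gyro)) "no" else "yes"))
  invisible(x)
}

#' Number of correct digital SDMT answers
#'
#' A response is correct when the digit entered equals the key's digit for the
#' displayed symbol. An empty response list is a valid session with 0 correct
#' answers (the participant answered nothing).
#'
#' @param responses Data frame with columns `symbol` and `digit` in
#'   presentation order.
#' @param key Named integer vector mapping symbol to digit (1-9).
#' @return Integer count of matching events.
#' @export
sdmt_correct_answers <- function(responses, key) {
  stopifnot(is.data.frame(responses),
            all(c("symbol", "digit") %in% names(responses)))
  if (nrow(responses) == 0L) return(0L)
  stopifnot(all(responses$digit %in% 1:9),
            all(responses$symbol %in% names(key)))
  sum(as.integer(key[as.character(responses$symbol)]) ==
        as.integer(responses$digit))
}

#' Number of correctly read Stroop words
#'
#' Matches the recognizer's token stream against the displayed word sequence
#' using the longest common subsequence, so that skipped or misread words are
#' tolerated without double counting. Capped at the display length (60 words).
#'
#' @param displayed Character vector of displayed colour names.
#' @param recognized Character vector of recognized tokens, in spoken order.
#' @return Integer count of matched words.
#' @export
swr_correct_words <- function(displayed, recognized) {
  if (length(recognized) == 0L || length(displayed) == 0L) return(0L)
  min(lcs_length(displayed, recognized), HD_SWR_WORDS)
}

## Classic O(n*m) dynamic-programming LCS length.
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  prev <- integer(m + 1L)
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    for (j in seq_len(m)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Mean intertap interval (speeded tapping)
#'
#' The intertap interval is the time the finger spends in the air: from each
#' lift-off (`up`) to the next touch-down (`down`). Requires at least two
#' completed taps, i.e. one air interval.
#'
#' @param touches Data frame with columns `t_s` and `phase`
#'   (`"down"`/`"up"`, alternating starting with `"down"`).
#' @return Mean finger-in-air time in milliseconds.
#' @export
mean_intertap_interval <- function(touches) {
  stopifnot(is.data.frame(touches), all(c("t_s", "phase") %in% names(touches)))
  ev <- touches[touches$phase %in% c("down", "up"), , drop = FALSE]
  ev <- ev[order(ev$t_s), , drop = FALSE]
  downs <- ev$t_s[ev$phase == "down"]
  ups <- ev$t_s[ev$phase == "up"]
  k <- min(length(downs) - 1L, length(ups))
  if (length(downs) < 2L || k < 1L)
    extraction_error("fewer than 2 completed taps", "too_few_taps")
  1000 * mean(downs[1L + seq_len(k)] - ups[seq_len(k)])
}

#' Spiral drawing speed variability
#'
#' Coefficient of variation of the instantaneous drawing speed along the
#' spiral trace: speeds are finite differences of position over time between
#' consecutive move samples; CV = sd(v)/mean(v).
#'
#' @param trace Data frame with columns `t_s`, `x_mm`, `y_mm` ordered in time
#'   (only samples while the finger is on the glass).
#' @return Unitless coefficient of variation (>= 0).
#' @export
spiral_speed_variability <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("t_s", "x_mm", "y_mm") %in% names(trace)))
  tr <- trace[order(trace$t_s), , drop = FALSE]
  keep <- c(TRUE, diff(tr$t_s) > 0)
  tr <- tr[keep, , drop = FALSE]
  if (nrow(tr) < 3L)
    extraction_error("need >= 3 move samples with distinct times",
                     "too_few_points")
  dt <- diff(tr$t_s)
  v <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2) / dt
  mv <- mean(v)
  if (mv <= 0) extraction_error("no movement in trace", "no_movement")
  stats::sd(v) / mv
}

#' Sway path (chorea and balance tests)
#'
#' Cumulative path length of the tri-axial acceleration trajectory:
#' sum over samples of the Euclidean norm of consecutive acceleration
#' differences. Constant offsets (gravity) cancel in the differencing, so no
#' gravity removal is applied. Computed on the 50 Hz uniformly resampled
#' stream.
#'
#' @param recording A [sensor_recording] with an accelerometer stream.
#' @param fs Resampling rate in Hz.
#' @return Sway path in m/s^2.
#' @export
sway_path <- function(recording, fs = HD_IMU_FS) {
  if (is.null(recording$acc)) extraction_error("no accelerometer stream",
                                               "missing_stream")
  acc <- resample_uniform(recording$t, recording$acc, fs)
  if (!is.matrix(acc) || nrow(acc) < 2L)
    extraction_error("fewer than 2 samples", "too_few_samples")
  d <- diff(acc)
  sum(sqrt(rowSums(d^2)))
}

#' Median turn speed (U-turn test)
#'
#' Smooths the yaw-axis angular rate with a 0.5 s moving average, detects
#' turns as maximal contiguous regions with |omega| above `rate_thresh` that
#' last at least `min_duration` seconds and accumulate at least `min_angle`
#' radians, and returns the median of per-turn speeds (cumulative angle over
#' duration). Region boundaries are refined on the raw (unsmoothed) rate so
#' the smoothing window does not dilate the turn and bias speeds low. At
#' least three turns are required.
#'
#' @param recording A [sensor_recording] with a gyroscope stream; yaw is the
#'   third gyroscope axis (vertical axis of the waist-worn device).
#' @param fs Resampling rate in Hz.
#' @param rate_thresh Yaw-rate threshold in rad/s defining a turn region.
#' @param min_duration Minimum turn duration in seconds.
#' @param min_angle Minimum cumulative angle in radians (default pi/2).
#' @param smooth_window Moving-average window in seconds.
#' @param min_turns Minimum number of detected turns.
#' @return Median turn speed in rad/s.
#' @export
median_turn_speed <- function(recording, fs = HD_IMU_FS, rate_thresh = 0.3,
                              min_duration = 0.5, min_angle = pi / 2,
                              smooth_window = 0.5, min_turns = 3L) {
  if (is.null(recording$gyro)) extraction_error("no gyroscope stream",
                                                "missing_stream")
  yaw <- resample_uniform(recording$t, recording$gyro[, 3L], fs)
  w <- moving_average(yaw, round(smooth_window * fs))
  active <- abs(w) > rate_thresh
  runs <- rle(active)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  speeds <- numeric(0)
  dt <- 1 / fs
  for (r in which(runs$values)) {
    idx <- starts[r]:ends[r]
    # the moving average stretches the region beyond the actual turn; refine
    # the boundaries on the raw rate so per-turn speed is unbiased
    hot <- idx[abs(yaw[idx]) > rate_thresh]
    if (length(hot)) idx <- min(hot):max(hot)
    dur <- length(idx) * dt
    ang <- sum(abs(yaw[idx])) * dt
    if (dur >= min_duration && ang >= min_angle) speeds <- c(speeds, ang / dur)
  }
  if (length(speeds) < min_turns)
    extraction_error(sprintf("only %d turns detected", length(speeds)),
                     "too_few_turns")
  stats::median(speeds)
}

#' Step frequency variance (walking test)
#'
#' Band-passes the acceleration magnitude to the locomotor band
#' (0.5-3.5 Hz), detects step peaks with a minimum separation of 0.25 s and a
#' relative prominence threshold, converts consecutive step intervals to
#' per-step frequencies f_i = 1/(t_{i+1}-t_i), and returns their variance.
#' At least ten steps are required.
#'
#' @param recording A [sensor_recording] with an accelerometer stream.
#' @param fs Resampling rate in Hz.
#' @param band Locomotor frequency band in Hz.
#' @param min_step_sep Minimum inter-step separation in seconds.
#' @param height_frac Peaks below this fraction of the maximum band-passed
#'   amplitude are ignored.
#' @param min_steps Minimum number of detected steps.
#' @return Variance of per-step frequency in Hz^2.
#' @export
step_frequency_variance <- function(recording, fs = HD_IMU_FS,
                                    band = c(0.5, 3.5), min_step_sep = 0.25,
                                    height_frac = 0.4, min_steps = 10L) {
  if (is.null(recording$acc)) extraction_error("no accelerometer stream",
                                               "missing_stream")
  acc <- resample_uniform(recording$t, recording$acc, fs)
  mag <- sqrt(rowSums(acc^2))
  filt <- fft_bandpass(mag, fs, band[1L], band[2L])
  pk <- find_peaks(filt, min_sep = max(1L, round(min_step_sep * fs)),
                   min_height = height_frac * max(filt))
  if (length(pk) < min_steps)
    extraction_error(sprintf("only %d steps detected", length(pk)),
                     "too_few_steps")
  f <- fs / diff(pk)
  stats::var(f)
}

#' Extract the predefined feature from one session
#'
#' Dispatches to the per-test extractor and returns a one-row feature record.
#' Sessions whose payload fails the extractor's minimum-evidence gate yield
#' `qc_status = "fail"` with a reason instead of an error; a payload that does
#' not match the test type at all is a configuration error.
#'
#' @param session A session list as produced by [synthesize_session()]:
#'   fields `test`, `hand`, `placement`, `day`, `participant_id`, `payload`.
#' @return One-row data frame with columns participant_id, day, test, hand,
#'   placement, feature, value, units, qc_status, qc_reason.
#' @export
extract_features <- function(session) {
  r <- .extract_value(session)
  data.frame(participant_id = session$participant_id %||% NA_character_,
             day = session$day %||% NA_integer_,
             test = session$test, hand = session$hand %||% "NA",
             placement = session$placement %||% "pouch",
             feature = r$feature, value = r$value,
             units = HD_FEATURE_UNITS[[r$feature]],
             qc_status = r$status, qc_reason = r$reason,
             stringsAsFactors = FALSE)
}

## Fast internal extraction path used both by extract_features() and the
## streaming pipeline (which collects plain vectors instead of data frames).
.extract_value <- function(session) {
  test <- session$test
  if (!test %in% HD_TESTS) stop("unknown test type: ", test)
  feature <- HD_FEATURE_OF_TEST[[test]]
  res <- tryCatch({
    p <- session$payload
    switch(test,
      sdmt = sdmt_correct_answers(p$responses, p$key),
      swr = swr_correct_words(p$displayed, p$recognized),
      tapping = mean_intertap_interval(p),
      draw = spiral_speed_variability(p[p$phase != "up", , drop = FALSE]),
      chorea = sway_path(p),
      balance = sway_path(p),
      uturn = median_turn_speed(p),
      walking = step_frequency_variance(p))
  }, hd_extraction_error = function(e) e)
  if (inherits(res, "hd_extraction_error")) {
    list(feature = feature, value = NA_real_, status = "fail",
         reason = res$reason)
  } else {
    list(feature = feature, value = as.numeric(res), status = "pass",
         reason = "")
  }
}
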