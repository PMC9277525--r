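# Independent brute-force implementations of each extractor's defining
# formula. These are deliberately written with plain loops (and, where a
# transform is part of the definition, the base fft primitive) so they share
# no code path with the package implementation.

oracle_sway_path <- function(acc) {
  s <- 0
  for (i in seq_len(nrow(acc) - 1L)) {
    d <- acc[i + 1L, ] - acc[i, ]
    s <- s + sqrt(sum(d^2))
  }
  s
}

oracle_intertap_ms <- function(touches) {
  ev <- touches[order(touches$t_s), ]
  downs <- ev$t_s[ev$phase == "down"]
  ups <- ev$t_s[ev$phase == "up"]
  gaps <- c()
  for (i in seq_along(ups)) {
    nxt <- downs[downs > ups[i]]
    if (length(nxt)) gaps <- c(gaps, min(nxt) - ups[i])
  }
  1000 * mean(gaps)
}

oracle_speed_cv <- function(trace) {
  v <- c()
  for (i in seq_len(nrow(trace) - 1L)) {
    dt <- trace$t_s[i + 1L] - trace$t_s[i]
    v <- c(v, sqrt((trace$x_mm[i + 1L] - trace$x_mm[i])^2 +
                     (trace$y_mm[i + 1L] - trace$y_mm[i])^2) / dt)
  }
  sd(v) / mean(v)
}

# Exhaustive LCS: length of the longest subsequence of `a` that is also a
# subsequence of `b`. Exponential; only for length(a) <= 12.
oracle_lcs_exhaustive <- function(a, b) {
  is_subseq <- function(s, x) {
    j <- 1L
    for (w in x) {
      if (j <= length(s) && identical(s[j], w)) j <- j + 1L
    }
    j > length(s)
  }
  best <- 0L
  for (mask in 0:(2^length(a) - 1L)) {
    sel <- a[bitwAnd(mask, 2^(seq_along(a) - 1L)) > 0L]
    if (length(sel) > best && is_subseq(sel, b)) best <- length(sel)
  }
  best
}

oracle_sdmt_count <- function(responses, key) {
  n <- 0L
  for (i in seq_len(nrow(responses))) {
    if (key[[responses$symbol[i]]] == responses$digit[i]) n <- n + 1L
  }
  n
}

# Independent moving average / band-pass / peak logic used by the turn-speed
# and step-variance oracles.
oracle_movavg <- function(x, w) {
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    out[i] <- mean(x[max(1L, i - h):min(length(x), i + h)])
  }
  out
}

oracle_turn_speed <- function(t, yaw, fs = 50, thr = 0.3, min_dur = 0.5,
                              min_ang = pi / 2) {
  g <- approx(t, yaw, xout = seq(min(t), max(t), by = 1 / fs))$y
  w <- oracle_movavg(g, round(0.5 * fs))
  speeds <- c()
  i <- 1L
  n <- length(w)
  while (i <= n) {
    if (abs(w[i]) > thr) {
      j <- i
      while (j < n && abs(w[j + 1L]) > thr) j <- j + 1L
      # refine boundaries on the raw rate, as in the definition
      hot <- (i:j)[abs(g[i:j]) > thr]
      lo <- if (length(hot)) min(hot) else i
      hi <- if (length(hot)) max(hot) else j
      dur <- (hi - lo + 1L) / fs
      ang <- sum(abs(g[lo:hi])) / fs
      if (dur >= min_dur && ang >= min_ang) speeds <- c(speeds, ang / dur)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(speeds) < 3L) return(NULL)
  median(speeds)
}

oracle_step_freq_var <- function(t, acc, fs = 50, band = c(0.5, 3.5),
                                 min_sep = 0.25, frac = 0.4) {
  grid <- seq(min(t), max(t), by = 1 / fs)
  mag <- sqrt(approx(t, acc[, 1], grid)$y^2 + approx(t, acc[, 2], grid)$y^2 +
                approx(t, acc[, 3], grid)$y^2)
  n <- length(mag)
  X <- fft(mag - mean(mag))
  for (i in seq_len(n)) {
    f <- (i - 1) / n * fs
    f <- min(f, fs - f)
    if (f < band[1] || f > band[2]) X[i] <- 0
  }
  y <- Re(fft(X, inverse = TRUE)) / n
  # peaks: local maxima above threshold, greedy by height, min separation
  cand <- c()
  for (i in 2:(n - 1L)) {
    if (y[i] > y[i - 1L] && y[i] >= y[i + 1L] && y[i] >= frac * max(y))
      cand <- c(cand, i)
  }
  keep <- c()
  for (i in cand[order(-y[cand])]) {
    if (all(abs(keep - i) >= round(min_sep * fs)) || !length(keep))
      keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 10L) return(NULL)
  f <- fs / diff(keep)
  sum((f - mean(f))^2) / (length(f) - 1)
}

# Build a sensor recording with rectangular yaw pulses of given peak rates,
# each spanning ~pi radians.
make_uturn_recording <- function(rates, fs = 50, gap = 6) {
  dur <- gap
  pulses <- list()
  for (k in seq_along(rates)) {
    pd <- pi / rates[k]
    pulses[[k]] <- c(start = dur, end = dur + pd, rate = rates[k])
    dur <- dur + pd + gap
  }
  t <- seq(0, dur, by = 1 / fs)
  yaw <- numeric(length(t))
  sgn <- 1
  for (p in pulses) {
    yaw[t >= p["start"] & t <= p["end"]] <- sgn * p["rate"]
    sgn <- -sgn
  }
  sensor_recording(t, acc = matrix(0, length(t), 3) + c(0, 0, 9.81),
                   gyro = cbind(0 * t, 0 * t, yaw))
}

# Impulse-train walking recording with given step times.
make_walking_recording <- function(step_times, dur, fs = 50, amp = 3,
                                   width = 0.05) {
  t <- seq(0, dur, by = 1 / fs)
  az <- numeric(length(t))
  for (st in step_times) az <- az + amp * exp(-(t - st)^2 / (2 * width^2))
  sensor_recording(t, acc = cbind(0 * t, 0 * t, az + 9.81))
}

tiny_participant <- function(severity = 0.3, seed = 1) {
  coh <- generate_cohort(cohort_spec("OLE", "manifest", 1,
                                     severity_mean = severity,
                                     severity_sd = 0, seed = seed))
  coh[1, ]
}

# Feature table stub for QC / aggregation tests.
feature_stub <- function(n, test = "chorea", fail = 0,
                         id = "P1", hand = "D", days = seq_len(n),
                         values = seq_len(n), study = "OLE",
                         cohort = "manifest") {
  status <- rep("pass", n)
  if (fail > 0) status[seq_len(fail)] <- "fail"
  data.frame(participant_id = id, study = study, cohort = cohort,
             day = days, test = test, hand = hand,
             feature = HD_FEATURE_OF_TEST[[test]], value = values,
             units = "x", qc_status = status, qc_reason = "",
             stringsAsFactors = FALSE)
}
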