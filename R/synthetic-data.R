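## Synthetic cohorts, schedules and raw test sessions.
##
## A single latent severity scalar in [0, 1] drives both the in-clinic
## clinical scores and every sensor signature, giving the downstream pipeline
## a recoverable ground truth: convergent-validity correlations, known-groups
## separation and QC/severity associations all follow from this one latent.
## Participant-level trait effects (stable log-scale multipliers) create the
## between-subject variance needed for non-trivial test-retest reliability;
## session-level noise creates the within-subject variance.

#' Cohort specification
#'
#' @param study One of `"OLE"`, `"HD_NHS"`, `"DIGITAL_HD"`.
#' @param cohort One of `"control"`, `"premanifest"`, `"manifest"`.
#' @param n_participants Number of participants (>= 1).
#' @param severity_mean,severity_sd Mean and SD of the latent severity;
#'   draws are truncated to [0, 1].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(study, cohort, n_participants,
                        severity_mean = NULL, severity_sd = NULL, seed = 1L) {
  if (!study %in% HD_STUDIES) stop("unknown study: ", study)
  if (!cohort %in% HD_COHORTS) stop("unknown cohort: ", cohort)
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("n_participants must be >= 1")
  defaults <- list(control = c(0.02, 0.02), premanifest = c(0.06, 0.03),
                   manifest = c(0.28, 0.13))[[cohort]]
  structure(list(study = study, cohort = cohort,
                 n_participants = as.integer(n_participants),
                 severity_mean = severity_mean %||% defaults[1L],
                 severity_sd = severity_sd %||% defaults[2L],
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## Age distributions (mean, sd) per cohort, loosely matched to the three
## study populations: controls/premanifest are younger on average than
## manifest participants.
.age_params <- list(control = c(48, 13.8), premanifest = c(45, 10),
                    manifest = c(50, 11.5))

#' Generate a synthetic cohort
#'
#' Draws the latent severity, then clinical scores as monotone functions of
#' severity plus noise (TMS, chorea, finger taps, balance and intertap
#' interval increase with severity; SWR and SDMT counts decrease), all clamped
#' to their scale ranges. Also draws the stable per-test participant traits
#' used by [synthesize_session()].
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per participant: identifiers, age,
#'   dominant hand, latent severity, clinical scores and trait columns.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_participants
  with_seed(derive_seed(spec$seed, match(spec$study, HD_STUDIES),
                        match(spec$cohort, HD_COHORTS)), {
    s <- rtruncnorm(n, spec$severity_mean, spec$severity_sd, 0, 1)
    ap <- .age_params[[spec$cohort]]
    age <- clamp(stats::rnorm(n, ap[1L], ap[2L]), 18, 80)
    df <- data.frame(
      id = sprintf("%s_%s_%03d", spec$study, toupper(substr(spec$cohort, 1, 3)),
                   seq_len(n)),
      study = spec$study, cohort = spec$cohort,
      age = round(age, 1),
      dominant_hand = ifelse(stats::runif(n) < 0.87, "right", "left"),
      severity = s,
      tms = clamp(round(100 * s + stats::rnorm(n, 0, 2.5)), 0, 124),
      # functional capacity stays at the 13 ceiling until severity clears the
      # premanifest range; noise scales with severity so controls stay pinned
      tfc = clamp(round(13 - 10 * pmax(0, s - 0.05) +
                          stats::rnorm(n, 0, 0.05 + 2 * s)), 0, 13),
      chorea_d = clamp(round(7 * s + stats::rnorm(n, 0, 0.5)), 0, 4),
      chorea_nd = clamp(round(7 * s + stats::rnorm(n, 0, 0.5)), 0, 4),
      finger_taps_d = clamp(round(6 * s + stats::rnorm(n, 0, 0.5)), 0, 4),
      finger_taps_nd = clamp(round(6 * s + stats::rnorm(n, 0, 0.5)), 0, 4),
      balance_score = clamp(round(9 * s + stats::rnorm(n, 0, 0.6)), 0, 8),
      swr_clinic = clamp(round(101 - 85 * s + stats::rnorm(n, 0, 12)), 0, 200),
      sdmt_clinic = clamp(round(62 - 90 * s + stats::rnorm(n, 0, 7)), 0, 110),
      intertap_clinic_ms = round(180 + 500 * s + stats::rnorm(n, 0, 25), 1),
      stringsAsFactors = FALSE)
    for (tr in paste0("trait_", HD_TESTS)) df[[tr]] <- stats::rnorm(n)
    df
  })
}

#' Generate a 4-week test schedule for one participant
#'
#' Daily tests (tapping, draw, chorea per hand; balance, U-turn, walking) are
#' scheduled on all 28 days; SDMT and SWR are scheduled weekly on days 1, 8,
#' 15 and 22. Each scheduled test is completed independently with probability
#' `adherence_prob`; ambulatory tests (balance, U-turn, walking) are carried
#' in the trouser pocket instead of the waist pouch independently with
#' probability `pocket_prob`.
#'
#' @param participant One row of a [generate_cohort()] frame (or any list with
#'   an `id` field).
#' @param adherence_prob,pocket_prob Probabilities in [0, 1].
#' @param seed Integer seed.
#' @return Data frame with columns id, day, test, hand, scheduled, completed,
#'   placement.
#' @export
generate_schedule <- function(participant, adherence_prob = 0.8,
                              pocket_prob = 0.15, seed = 1L) {
  stopifnot(adherence_prob >= 0, adherence_prob <= 1,
            pocket_prob >= 0, pocket_prob <= 1)
  daily <- data.frame(
    test = c("tapping", "tapping", "draw", "draw", "chorea", "chorea",
             "balance", "uturn", "walking"),
    hand = c("D", "ND", "D", "ND", "D", "ND", "NA", "NA", "NA"),
    stringsAsFactors = FALSE)
  days <- rep(seq_len(HD_STUDY_DAYS), each = nrow(daily))
  grid <- data.frame(day = days, daily[rep(seq_len(nrow(daily)),
                                           HD_STUDY_DAYS), ],
                     row.names = NULL)
  weekly <- expand.grid(day = HD_WEEKLY_DAYS, test = HD_WEEKLY_TESTS,
                        stringsAsFactors = FALSE)
  weekly$hand <- "NA"
  grid <- rbind(grid, weekly[, c("day", "test", "hand")])
  grid <- grid[order(grid$day, match(grid$test, HD_TESTS)), ]
  n <- nrow(grid)
  with_seed(derive_seed(seed, 7L), {
    completed <- stats::runif(n) < adherence_prob
    placement <- rep("pouch", n)
    amb <- grid$test %in% HD_POUCH_TESTS
    placement[amb] <- ifelse(stats::runif(sum(amb)) < pocket_prob,
                             "pocket", "pouch")
    data.frame(id = participant$id, day = grid$day, test = grid$test,
               hand = grid$hand, scheduled = TRUE, completed = completed,
               placement = placement, stringsAsFactors = FALSE,
               row.names = NULL)
  })
}

#' Generator tuning constants
#'
#' All severity slopes, baseline levels and noise scales used by
#' [synthesize_session()]. Each test family has a baseline value at severity
#' 0, a linear severity slope, a participant-trait weight and a session-noise
#' weight (both on the log scale, so effects are multiplicative and values
#' stay positive).
#'
#' @return Named list of generator parameters.
#' @export
sim_params <- function() {
  list(
    fs = HD_IMU_FS,
    # chorea/balance: RMS amplitude (m/s^2) of 1-8 Hz band-limited noise
    chorea = list(a0 = 0.08, a1 = 1.0, band = c(1, 8), tw = 0.18, sw = 0.06),
    balance = list(a0 = 0.05, a1 = 0.6, band = c(1, 8), tw = 0.18, sw = 0.06),
    # u-turn: peak yaw rate (rad/s) of the ~pi-rad turns, 6 turns per session
    uturn = list(w0 = 1.9, w1 = -1.1, n_turns = 6L, tw = 0.08, sw = 0.04),
    # walking: step interval (s) and step-interval jitter SD (s). Cadence is
    # held constant across severity: the feature is interval *variability*,
    # and a severity-dependent cadence would push the step rate toward the
    # band edge where impulse interference compresses measured variability.
    walking = list(interval0 = 0.50, interval1 = 0,
                   jitter0 = 0.010, jitter1 = 0.055, amp = 3, noise = 0.15,
                   tw = 0.15, sw = 0.06),
    # tapping: mean/SD of the in-air interval (ms), on-glass dwell (ms)
    tapping = list(air0 = 120, air1 = 450, sd0 = 25, sd1 = 120, glass = 80,
                   tw = 0.15, sw = 0.06),
    # draw: target speed CV, base drawing speed (mm/s), early-lift probability
    draw = list(cv0 = 0.12, cv1 = 0.55, v0 = 60, v1 = -25,
                lift0 = 0.02, lift1 = 0.30, tw = 0.15, sw = 0.06),
    # sdmt: mean response time (s) and error probability
    sdmt = list(rt0 = 1.45, rt1 = 2.6, rt_sd_frac = 0.18,
                err0 = 0.02, err1 = 0.25, tw = 0.08, sw = 0.04),
    # swr: reading rate (words/s) and recognizer miss probability
    swr = list(rate0 = 2.2, rate1 = -1.3, miss0 = 0.02, miss1 = 0.30,
               tw = 0.08, sw = 0.04)
  )
}

## Severity-dependent level with multiplicative trait/session effects.
.level <- function(base, slope, s, trait, tw, z, sw) {
  (base + slope * s) * exp(tw * trait + sw * z)
}

#' Synthesize the raw payload of one active-test session
#'
#' Builds a raw data payload whose extracted feature is monotone in the
#' participant's latent severity: band-limited sway noise for chorea/balance,
#' embedded ~180-degree yaw turns for the U-turn test, quasi-periodic step
#' impulses with severity-proportional interval jitter for walking,
#' alternating touch events for speeded tapping, a spiral trace with
#' severity-proportional speed variability for draw-a-shape, symbol-response
#' pairs for the digital SDMT and displayed/recognized word streams for the
#' digital SWR.
#'
#' @param participant One row of a [generate_cohort()] frame.
#' @param test One of the eight active tests.
#' @param hand `"D"`, `"ND"` or `"NA"`.
#' @param seed Integer seed; identical inputs give identical payloads.
#' @param day Study day (metadata only).
#' @param placement `"pouch"` or `"pocket"` (metadata; the generator does not
#'   alter the signal by placement — placement-based QC uses the metadata).
#' @param params Generator constants, see [sim_params()].
#' @return Session list: test, hand, day, placement, participant_id, payload.
#' @export
synthesize_session <- function(participant, test, hand = "NA", seed = 1L,
                               day = 1L, placement = "pouch",
                               params = sim_params()) {
  if (!test %in% HD_TESTS) stop("unknown test type: ", test)
  s <- participant$severity
  trait <- participant[[paste0("trait_", test)]] %||% 0
  fs <- params$fs
  payload <- with_seed(derive_seed(seed, match(test, HD_TESTS),
                                   match(hand, c("D", "ND", "NA")), day), {
    z <- stats::rnorm(1)  # session-level noise shared by the whole payload
    switch(test,
      chorea = .sim_sway(params$chorea, s, trait, z, fs, 30),
      balance = .sim_sway(params$balance, s, trait, z, fs, 30),
      uturn = .sim_uturn(params$uturn, s, trait, z, fs),
      walking = .sim_walking(params$walking, s, trait, z, fs),
      tapping = .sim_tapping(params$tapping, s, trait, z),
      draw = .sim_draw(params$draw, s, trait, z, fs),
      sdmt = .sim_sdmt(params$sdmt, s, trait, z),
      swr = .sim_swr(params$swr, s, trait, z))
  })
  list(test = test, hand = hand, day = as.integer(day),
       placement = placement, participant_id = participant$id,
       payload = payload)
}

.sim_sway <- function(p, s, trait, z, fs, dur) {
  n <- dur * fs + 1L
  amp <- .level(p$a0, p$a1, s, trait, p$tw, z, p$sw)
  ax <- .bandlimited_noise(n, fs, p$band, amp)
  ay <- .bandlimited_noise(n, fs, p$band, amp)
  az <- .bandlimited_noise(n, fs, p$band, amp)
  sensor_recording(t = seq(0, dur, by = 1 / fs),
                   acc = cbind(ax, ay, az + 9.81))
}

.bandlimited_noise <- function(n, fs, band, rms) {
  w <- stats::rnorm(n)
  f <- fft_bandpass(w, fs, band[1L], band[2L])
  f / stats::sd(f) * rms
}

.sim_uturn <- function(p, s, trait, z, fs, dur = 60) {
  n <- dur * fs + 1L
  t <- seq(0, dur, by = 1 / fs)
  omega <- .level(p$w0, p$w1, s, trait, p$tw, z, p$sw)
  omega <- max(omega, 0.45)
  yaw <- stats::rnorm(n, 0, 0.05)
  centers <- seq(6, dur - 6, length.out = p$n_turns) + stats::rnorm(p$n_turns, 0, 0.6)
  sgn <- rep_len(c(1, -1), p$n_turns)
  for (k in seq_len(p$n_turns)) {
    turn_dur <- pi / omega           # rectangular pulse covering ~180 degrees
    idx <- which(t >= centers[k] - turn_dur / 2 & t <= centers[k] + turn_dur / 2)
    yaw[idx] <- yaw[idx] + sgn[k] * omega
  }
  acc <- cbind(stats::rnorm(n, 0, 0.3), stats::rnorm(n, 0, 0.3),
               9.81 + stats::rnorm(n, 0, 0.3))
  sensor_recording(t = t, acc = acc, gyro = cbind(stats::rnorm(n, 0, 0.05),
                                                  stats::rnorm(n, 0, 0.05),
                                                  yaw))
}

.sim_walking <- function(p, s, trait, z, fs, dur = 120) {
  n <- dur * fs + 1L
  t <- seq(0, dur, by = 1 / fs)
  interval <- p$interval0 + p$interval1 * s
  jitter <- .level(p$jitter0, p$jitter1, s, trait, p$tw, z, p$sw)
  steps <- numeric(0)
  tk <- 0.5
  while (tk < dur - 0.5) {
    steps <- c(steps, tk)
    tk <- tk + max(0.3, interval + stats::rnorm(1, 0, jitter))
  }
  nz <- p$noise %||% 0.15
  az <- stats::rnorm(n, 0, nz)
  width <- 0.05
  half <- ceiling(3 * width * fs)
  for (st in steps) {
    c0 <- round(st * fs) + 1L
    idx <- max(1L, c0 - half):min(n, c0 + half)
    az[idx] <- az[idx] + p$amp * exp(-(t[idx] - st)^2 / (2 * width^2))
  }
  acc <- cbind(stats::rnorm(n, 0, nz), stats::rnorm(n, 0, nz), az + 9.81)
  sensor_recording(t = t, acc = acc)
}

.sim_tapping <- function(p, s, trait, z, dur = 30) {
  air_mean <- .level(p$air0, p$air1, s, trait, p$tw, z, p$sw) / 1000
  air_sd <- (p$sd0 + p$sd1 * s) / 1000
  glass <- p$glass / 1000
  t <- 0
  times <- numeric(0); phase <- character(0)
  while (t < dur) {
    times <- c(times, t); phase <- c(phase, "down")
    t <- t + glass
    if (t >= dur) break
    times <- c(times, t); phase <- c(phase, "up")
    t <- t + max(0.02, stats::rnorm(1, air_mean, air_sd))
  }
  data.frame(t_s = times, x_mm = 30 + stats::rnorm(length(times), 0, 1.5),
             y_mm = 60 + stats::rnorm(length(times), 0, 1.5),
             phase = phase, stringsAsFactors = FALSE)
}

.sim_draw <- function(p, s, trait, z, fs, b = 2.5, turns = 3) {
  theta_max <- 2 * pi * turns
  th_dense <- seq(0, theta_max, length.out = 4000L)
  seg <- sqrt((b * th_dense)^2 + b^2) * c(0, diff(th_dense))
  cum_len <- cumsum(seg)
  total_len <- cum_len[length(cum_len)]
  cv <- .level(p$cv0, p$cv1, s, trait, p$tw, z, p$sw)
  v0 <- max(10, p$v0 + p$v1 * s)
  sigma <- sqrt(log(1 + cv^2))
  target_len <- total_len
  lifted_early <- stats::runif(1) < clamp(p$lift0 + p$lift1 * s, 0, 0.9)
  if (lifted_early) target_len <- total_len * stats::runif(1, 0.10, 0.45)
  dist <- 0; lens <- 0
  while (dist < target_len && length(lens) < 30 * fs) {
    v <- v0 * exp(sigma * stats::rnorm(1) - sigma^2 / 2)
    dist <- dist + v / fs
    lens <- c(lens, min(dist, target_len))
  }
  th <- stats::approx(cum_len, th_dense, xout = pmin(lens, total_len),
                      rule = 2)$y
  tr <- data.frame(t_s = (seq_along(th) - 1) / fs,
                   x_mm = 50 + b * th * cos(th), y_mm = 70 + b * th * sin(th),
                   phase = c("down", rep("move", length(th) - 2L), "up"),
                   stringsAsFactors = FALSE)
  attr(tr, "frac_drawn") <- target_len / total_len
  tr
}

.sim_sdmt <- function(p, s, trait, z, dur = 90) {
  rt_mean <- .level(p$rt0, p$rt1, s, trait, p$tw, z, p$sw)
  err <- clamp(p$err0 + p$err1 * s, 0, 0.9)
  key_set <- HD_SDMT_KEYS[[sample.int(3L, 1L)]]
  t <- 0; k <- 0
  symbols <- character(0); digits <- integer(0); times <- numeric(0)
  rt_sd <- (p$rt_sd_frac %||% 0.18) * rt_mean
  repeat {
    rt <- if (rt_sd > 0) max(0.35, stats::rnorm(1, rt_mean, rt_sd)) else rt_mean
    if (t + rt > dur) break
    t <- t + rt; k <- k + 1
    sym <- HD_SDMT_SYMBOLS[(k - 1L) %% 9L + 1L]  # fixed symbol sequence
    correct <- as.integer(key_set[[sym]])
    d <- if (stats::runif(1) < err) sample(setdiff(1:9, correct), 1L) else correct
    symbols <- c(symbols, sym); digits <- c(digits, d); times <- c(times, t)
  }
  list(key = key_set,
       responses = data.frame(symbol = symbols, digit = digits, t_s = times,
                              stringsAsFactors = FALSE))
}

.sim_swr <- function(p, s, trait, z, dur = 45) {
  rate <- max(0.3, .level(p$rate0, p$rate1, s, trait, p$tw, z, p$sw))
  miss <- clamp(p$miss0 + p$miss1 * s, 0, 0.95)
  displayed <- sample(HD_SWR_VOCAB, HD_SWR_WORDS, replace = TRUE)
  n_read <- min(HD_SWR_WORDS, floor(dur * rate))
  spoken <- displayed[seq_len(n_read)]
  recognized <- spoken[stats::runif(n_read) >= miss]
  list(displayed = displayed, recognized = recognized)
}

#' Simulate a test-retest panel with known reliability
#'
#' Per-participant means are drawn with between-subject SD `sigma_b`; each
#' session value adds independent noise with SD `sigma_w`. With
#' `sessions_per_interval = 1` the intraclass correlation of the two interval
#' values is exactly sigma_b^2 / (sigma_b^2 + sigma_w^2); with more sessions
#' per interval the interval medians have smaller effective within-subject
#' variance and the aggregated reliability is correspondingly higher.
#'
#' @param n Number of participants.
#' @param sigma_b,sigma_w Between- and within-subject SDs.
#' @param sessions_per_interval Sessions simulated in each 2-week interval.
#' @param mu Grand mean.
#' @param seed Integer seed.
#' @return Long data frame: id, interval, session, value.
#' @export
simulate_retest_panel <- function(n, sigma_b, sigma_w,
                                  sessions_per_interval = 1L, mu = 0,
                                  seed = 1L) {
  with_seed(derive_seed(seed, 11L), {
    mu_i <- stats::rnorm(n, mu, sigma_b)
    m <- sessions_per_interval
    data.frame(
      id = rep(sprintf("P%03d", seq_len(n)), each = 2L * m),
      interval = rep(rep(1:2, each = m), n),
      session = rep(seq_len(m), 2L * n),
      value = rep(mu_i, each = 2L * m) + stats::rnorm(2L * m * n, 0, sigma_w),
      stringsAsFactors = FALSE)
  })
}
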