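# Generator contracts: determinism, clinical-score invariants, schedule
# structure, adherence calibration and severity-monotone sensor signatures.

test_that("generate_cohort is deterministic and respects scale ranges", {
  spec <- cohort_spec("OLE", "manifest", 40, seed = 9)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  expect_true(all(c1$severity >= 0 & c1$severity <= 1))
  expect_true(all(c1$tms >= 0 & c1$tms <= 124))
  expect_true(all(c1$tfc >= 0 & c1$tfc <= 13))
  expect_true(all(c1$chorea_d %in% 0:4 & c1$finger_taps_nd %in% 0:4))
  expect_true(all(c1$balance_score >= 0 & c1$balance_score <= 8))
  # severity recoverable from TMS at this n
  expect_gt(cor(c1$severity, c1$tms, method = "spearman"), 0)
})

test_that("control cohorts look like controls", {
  ctrl <- generate_cohort(cohort_spec("DIGITAL_HD", "control", 20, seed = 3))
  expect_true(all(ctrl$tfc == 13))
  expect_lt(mean(ctrl$tms), 5)          # TMS near zero for healthy controls
  expect_gt(mean(ctrl$sdmt_clinic), 50)
})

test_that("severity_sd = 0 collapses the cohort to one severity", {
  coh <- generate_cohort(cohort_spec("HD_NHS", "manifest", 15,
                                     severity_mean = 0.3, severity_sd = 0,
                                     seed = 2))
  expect_identical(length(unique(coh$severity)), 1L)
})

test_that("cohort_spec validates its inputs", {
  expect_error(cohort_spec("BAD", "manifest", 5), "unknown study")
  expect_error(cohort_spec("OLE", "bad", 5), "unknown cohort")
  expect_error(cohort_spec("OLE", "manifest", 0), "n_participants")
})

test_that("schedules have the daily/weekly structure", {
  p <- tiny_participant()
  sc <- generate_schedule(p, adherence_prob = 1, pocket_prob = 0, seed = 5)
  expect_true(all(sc$completed))                 # adherence 1
  expect_true(all(sc$scheduled))
  expect_true(all(sc$placement == "pouch"))      # pocket_prob 0
  daily <- sc[!sc$test %in% c("sdmt", "swr"), ]
  expect_setequal(unique(daily$day), 1:28)
  # 9 daily administrations per day (3 per-hand tests x 2 + 3 ambulatory)
  expect_true(all(table(daily$day) == 9))
  weekly <- sc[sc$test %in% c("sdmt", "swr"), ]
  expect_setequal(unique(weekly$day), c(1, 8, 15, 22))
  expect_identical(nrow(weekly), 8L)
})

test_that("completion fraction matches the adherence probability", {
  p <- tiny_participant()
  # ~268 scheduled tests x 400 participants: binomial mean oracle
  frac <- mean(unlist(lapply(1:400, function(i)
    generate_schedule(p, adherence_prob = 0.72, pocket_prob = 0.1,
                      seed = i)$completed)))
  expect_equal(frac, 0.72, tolerance = 0.01 / 0.72)
})

test_that("sessions are deterministic under the seed", {
  p <- tiny_participant()
  s1 <- synthesize_session(p, "walking", seed = 123, day = 4)
  s2 <- synthesize_session(p, "walking", seed = 123, day = 4)
  expect_identical(s1, s2)
  s3 <- synthesize_session(p, "walking", seed = 124, day = 4)
  expect_false(identical(s1$payload$acc, s3$payload$acc))
})

test_that("session payloads match their test type", {
  p <- tiny_participant()
  ch <- synthesize_session(p, "chorea", hand = "D", seed = 1)$payload
  expect_s3_class(ch, "sensor_recording")
  expect_gte(1 / median(diff(ch$t)), 50)          # >= 50 Hz
  expect_equal(diff(range(ch$t)), 30)             # 30 s
  ut <- synthesize_session(p, "uturn", seed = 1)$payload
  expect_false(is.null(ut$gyro))
  expect_equal(diff(range(ut$t)), 60)
  wk <- synthesize_session(p, "walking", seed = 1)$payload
  expect_lte(diff(range(wk$t)), 120)
  expect_error(synthesize_session(p, "jogging", seed = 1), "unknown test")
})

test_that("chorea sway separates severity extremes", {
  p0 <- tiny_participant(severity = 0)
  p1 <- tiny_participant(severity = 1)
  v0 <- sapply(1:20, function(i)
    extract_features(synthesize_session(p0, "chorea", hand = "D",
                                        seed = i))$value)
  v1 <- sapply(1:20, function(i)
    extract_features(synthesize_session(p1, "chorea", hand = "D",
                                        seed = i))$value)
  expect_lt(max(v0), min(v1))
})

test_that("zero jitter gives a periodic gait with ~zero frequency variance", {
  params <- sim_params()
  params$walking$jitter0 <- 0
  params$walking$jitter1 <- 0
  params$walking$noise <- 0
  params$walking$tw <- 0
  params$walking$sw <- 0
  p <- tiny_participant(severity = 0)
  ses <- synthesize_session(p, "walking", seed = 8, params = params)
  expect_lt(extract_features(ses)$value, 1e-4)
})

test_that("a perfect participant scores 90 on the 90-second digital SDMT", {
  params <- sim_params()
  params$sdmt <- list(rt0 = 1, rt1 = 0, rt_sd_frac = 0, err0 = 0, err1 = 0,
                      tw = 0, sw = 0)
  p <- tiny_participant(severity = 0)
  ses <- synthesize_session(p, "sdmt", seed = 4, params = params)
  expect_identical(nrow(ses$payload$responses), 90L)
  expect_equal(extract_features(ses)$value, 90)
})

test_that("every feature tracks severity in the expected direction", {
  # 50 manifest participants, one session per test each; signs must match
  # the known-groups/convergent expectations (impairment raises sway, CV,
  # intertap and step variance; lowers turn speed and cognitive counts)
  coh <- generate_cohort(cohort_spec("HD_NHS", "manifest", 50,
                                     severity_mean = 0.3, severity_sd = 0.15,
                                     seed = 21))
  expected <- c(chorea = 1, balance = 1, draw = 1, tapping = 1, walking = 1,
                uturn = -1, sdmt = -1, swr = -1)
  for (tst in names(expected)) {
    vals <- vapply(seq_len(nrow(coh)), function(j)
      extract_features(synthesize_session(coh[j, ], tst, hand = "D",
                                          seed = 1000 + j))$value,
      numeric(1))
    rho <- cor(coh$severity, vals, method = "spearman", use = "complete.obs")
    expect_gt(rho * expected[[tst]], 0.2, label = paste("sign for", tst))
  }
})

test_that("retest panels reproduce their construction reliability", {
  # one session per interval: ICC of the pair is exactly sb^2/(sb^2+sw^2)
  pan <- simulate_retest_panel(200, sigma_b = 1, sigma_w = 0.5, seed = 31)
  w <- reshape(pan[, c("id", "interval", "value")], idvar = "id",
               timevar = "interval", direction = "wide")
  icc <- test_retest_icc(w$value.1, w$value.2)
  expect_equal(icc$estimate, 1 / 1.25, tolerance = 0.06)
  # three sessions per interval, median-aggregated: effective within-subject
  # variance is that of a median of 3, estimated by an independent
  # simulation oracle
  sw <- 0.8
  pan3 <- simulate_retest_panel(150, sigma_b = 1, sigma_w = sw,
                                sessions_per_interval = 3, seed = 32)
  pan3$test <- "chorea"; pan3$qc_status <- "pass"
  pan3$day <- ifelse(pan3$interval == 1, 1, 15) + pan3$session
  key <- interaction(pan3$id, pan3$interval)
  med <- aggregate(value ~ id + interval, pan3, median)
  wm <- reshape(med, idvar = "id", timevar = "interval", direction = "wide")
  icc3 <- test_retest_icc(wm$value.1, wm$value.2)
  set.seed(99)
  var_med3 <- var(apply(matrix(rnorm(3 * 20000, 0, sw), ncol = 3), 1, median))
  expect_equal(icc3$estimate, 1 / (1 + var_med3), tolerance = 0.05)
})
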