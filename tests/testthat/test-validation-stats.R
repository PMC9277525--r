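# ICC, convergent-validity correlations and known-groups comparisons.

test_that("ICC(A,1) matches the two-way ANOVA oracle", {
  # frozen oracle values computed independently (two-way random-effects,
  # absolute-agreement, single-measurement ICC with McGraw-Wong F CIs)
  r <- test_retest_icc(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5))
  expect_equal(r$estimate, 0.852941, tolerance = 1e-6)
  expect_equal(r$ci_low, 0.2281, tolerance = 1e-3)
  expect_equal(r$ci_high, 0.9783, tolerance = 1e-3)
  expect_equal(r$n, 6L)
  # second frozen case, n = 12
  a <- c(-0.801931425253, -1.324358995628, -0.248361622095, 0.420445238066,
         1.13604653249, 0.109706399322, -0.552647320536, -0.784780355344,
         0.748745770735, 1.634783042959, 0.272768775845, -1.233328664031)
  b <- c(-1.281064027971, -0.524349451129, -0.146920401841, -0.445622183154,
         1.094198436081, -0.471906587401, -0.867291367567, -1.028783266983,
         0.392089084918, 1.911472278135, 0.241225789882, -1.528044293047)
  r2 <- test_retest_icc(a, b)
  expect_equal(r2$estimate, 0.893232, tolerance = 1e-6)
  expect_equal(r2$ci_low, 0.6822, tolerance = 1e-3)
  expect_equal(r2$ci_high, 0.9677, tolerance = 1e-3)
})

test_that("ICC handles identity, invariances and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(test_retest_icc(x, x)$estimate, 1)
  # relabeling the intervals leaves the estimate unchanged
  y <- x + rnorm(6, 0, 0.2)
  expect_equal(test_retest_icc(x, y)$estimate,
               test_retest_icc(y, x)$estimate)
  # a common affine rescaling of both intervals leaves it unchanged
  expect_equal(test_retest_icc(3 * x - 5, 3 * y - 5)$estimate,
               test_retest_icc(x, y)$estimate, tolerance = 1e-12)
  expect_error(test_retest_icc(c(1, 2), c(1, 2)), ">= 3")
  expect_true(test_retest_icc(rep(1, 5), rep(1, 5))$undefined)
  # pairs with missing values are dropped
  expect_equal(test_retest_icc(c(x, NA), c(y, 2))$n, 6L)
})

test_that("ICC recovers a constructed reliability of 0.9 at n = 100", {
  pan <- simulate_retest_panel(100, sigma_b = 1, sigma_w = 1 / 3, seed = 7)
  w <- reshape(pan[, c("id", "interval", "value")], idvar = "id",
               timevar = "interval", direction = "wide")
  est <- test_retest_icc(w$value.1, w$value.2)$estimate
  expect_gt(est, 0.85)
  expect_lt(est, 0.95)
})

test_that("convergent_validity computes both correlation flavours", {
  set.seed(5)
  x <- rnorm(60)
  # exact monotone transform: Spearman rho = 1
  r <- convergent_validity(x, exp(2 * x), method = "spearman")
  expect_equal(r$coefficient, 1)
  # Spearman is invariant to strictly monotone transforms of either side
  y <- x + rnorm(60, 0, 0.5)
  r1 <- convergent_validity(x, y, method = "spearman")
  r2 <- convergent_validity(exp(x), y^3 + 5 * y, method = "spearman")
  expect_equal(r1$coefficient, r2$coefficient)
  expect_error(convergent_validity(1:4, 1:4), ">= 5")
  expect_true(convergent_validity(rep(1, 10), rnorm(10))$undefined)
  # method is recorded; CI brackets the estimate
  rp <- convergent_validity(x, y, method = "pearson")
  expect_identical(rp$method, "pearson")
  expect_true(rp$ci_low < rp$coefficient && rp$coefficient < rp$ci_high)
})

test_that("noisy linear association matches the attenuation formula", {
  # y = x + e with known SDs: population r = sx / sqrt(sx^2 + se^2)
  set.seed(12)
  sx <- 2; se <- 1.5
  x <- rnorm(200, 0, sx)
  y <- x + rnorm(200, 0, se)
  expected_r <- sx / sqrt(sx^2 + se^2)
  r <- convergent_validity(y, x, method = "pearson")
  expect_equal(r$coefficient, expected_r, tolerance = 0.1)
  expect_lt(r$p_value, 1e-10)
})

test_that("known_groups residualization and tests behave as specified", {
  set.seed(77)
  n <- 120
  d <- data.frame(age = runif(n, 30, 70),
                  study = sample(c("OLE", "HD_NHS", "DIGITAL_HD"), n, TRUE),
                  group = sample(letters[1:5], n, TRUE))
  # zero noise, single study: the age slope is removed exactly
  d1 <- transform(d, value = 3 + 0.25 * age, study = "OLE")
  suppressWarnings(kg1 <- known_groups(d1))
  expect_equal(kg1$age_coef, 0.25, tolerance = 1e-6)
  expect_lt(max(abs(kg1$residuals$residual)), 1e-6)
  expect_equal(kg1$kruskal_H, 0)
  # three studies with distinct intercepts: mixed model recovers the slope
  # despite the study confounding, and marginal residuals keep the study
  # shifts while conditional residuals absorb them
  shift <- c(OLE = 0, HD_NHS = 4, DIGITAL_HD = -3)
  d2 <- transform(d, value = 1 + 0.25 * age + shift[d$study] +
                    rnorm(n, 0, 0.01))
  kg2 <- known_groups(d2)
  expect_identical(kg2$model, "mixed")
  expect_equal(kg2$age_coef, 0.25, tolerance = 0.01)
  # within each study, marginal residuals are constant up to the tiny noise
  by_study <- split(kg2$residuals$residual, kg2$residuals$study)
  expect_true(all(vapply(by_study, sd, numeric(1)) < 0.1))
  expect_equal(nrow(kg2$pairwise), 10L)  # 5 choose 2
  kg2c <- known_groups(d2, residual_type = "conditional")
  expect_lt(max(abs(kg2c$residuals$residual)), 0.5)
})

test_that("pairwise Mann-Whitney p-values are symmetric in group order", {
  set.seed(3)
  d <- data.frame(value = rnorm(80), age = runif(80, 30, 70),
                  study = rep(c("OLE", "HD_NHS"), 40),
                  group = sample(c("g1", "g2", "g3", "g4"), 80, TRUE))
  kg <- known_groups(d)
  d_rev <- d
  d_rev$group <- factor(d$group, levels = c("g4", "g3", "g2", "g1"))
  kg_rev <- known_groups(transform(d_rev, group = as.character(group)))
  m1 <- kg$pairwise[order(kg$pairwise$group1, kg$pairwise$group2), ]
  m2 <- kg_rev$pairwise[order(kg_rev$pairwise$group1,
                              kg_rev$pairwise$group2), ]
  expect_equal(m1$p_value, m2$p_value)
})

test_that("null known-groups rejection rate is near the nominal level", {
  # reduced-size sanity check of the type-I error (the acceptance suite runs
  # the full 1000-replicate version)
  reps <- 150
  rej <- logical(reps)
  studies <- c("DIGITAL_HD", "DIGITAL_HD", "DIGITAL_HD", "OLE", "HD_NHS")
  for (i in seq_len(reps)) {
    set.seed(4000 + i)
    d <- data.frame(value = rnorm(100), age = runif(100, 30, 70),
                    study = rep(studies, each = 20),
                    group = rep(paste0("g", 1:5), each = 20))
    rej[i] <- known_groups(d)$kruskal_p < 0.05
  }
  expect_gte(mean(rej), 0.01)
  expect_lte(mean(rej), 0.11)
})

test_that("Mann-Whitney detects a 1.5-SD shift with high power", {
  reps <- 60
  hit <- logical(reps)
  for (i in seq_len(reps)) {
    set.seed(6000 + i)
    d <- data.frame(
      value = c(rnorm(40, 0, 1), rnorm(40, 1.5, 1)),
      age = runif(80, 30, 70),
      study = rep(c("OLE", "HD_NHS"), 40),
      group = rep(c("control", "manifest"), each = 40))
    d$value <- d$value + 0.2 * d$age   # age trend removed by the model
    pw <- known_groups(d)$pairwise
    hit[i] <- pw$p_value[1] < 0.05
  }
  expect_gt(mean(hit), 0.9)
})
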