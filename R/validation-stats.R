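## Cross-sectional validation statistics: test-retest reliability,
## convergent validity, and known-groups comparisons.

#' Test-retest intraclass correlation (two-way random, absolute agreement)
#'
#' ICC(A,1) in the McGraw & Wong taxonomy: a two-way random-effects,
#' absolute-agreement, single-measurement ICC between the first and second
#' 2-week interval medians. The 95% CI uses the F-distribution bounds of the
#' same two-way model. Pairs with a missing value in either interval are
#' dropped before computation.
#'
#' @param interval1,interval2 Paired numeric vectors (same participants, same
#'   order).
#' @param conf_level Confidence level.
#' @return `icc_result` list: estimate, ci_low, ci_high, n, the ANOVA mean
#'   squares, and the ICC form identifier.
#' @export
test_retest_icc <- function(interval1, interval2, conf_level = 0.95) {
  stopifnot(length(interval1) == length(interval2))
  ok <- is.finite(interval1) & is.finite(interval2)
  x <- interval1[ok]; y <- interval2[ok]
  n <- length(x)
  if (n < 3L) stop("need >= 3 complete pairs for the ICC")
  k <- 2L
  mat <- cbind(x, y)
  grand <- mean(mat)
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= .Machine$double.eps * abs(msr)) {
    return(structure(list(estimate = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n = n, undefined = TRUE,
                          reason = "zero total variance",
                          form = "ICC(A,1)"), class = "icc_result"))
  }
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  # McGraw & Wong (1996) CI for ICC(A,1)
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(estimate = icc, ci_low = ci_low, ci_high = ci_high, n = n,
                 msr = msr, msc = msc, mse = mse, undefined = FALSE,
                 form = "ICC(A,1)"), class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(sprintf("ICC undefined (%s), n = %d\n", x$reason, x$n))
  } else {
    cat(sprintf("%s = %.3f (95%% CI %.3f-%.3f), n = %d pairs\n",
                x$form, x$estimate, x$ci_low, x$ci_high, x$n))
  }
  invisible(x)
}

#' Convergent validity correlation
#'
#' Pearson or Spearman correlation between an aggregated digital feature and
#' an in-clinic clinical score, with a two-sided p-value and a Fisher-z 95%
#' CI (for Spearman, using the 1.06/(n-3) variance approximation). With
#' `method = "auto"`, Pearson is chosen when Shapiro-Wilk does not reject
#' normality (alpha = 0.05) for both variables, Spearman otherwise.
#'
#' @param feature,score Paired numeric vectors; incomplete pairs are dropped.
#' @param method `"pearson"`, `"spearman"` or `"auto"`.
#' @param conf_level Confidence level for the CI.
#' @return `correlation_result` list: method, coefficient, ci_low, ci_high,
#'   p_value, n.
#' @export
convergent_validity <- function(feature, score,
                                method = c("spearman", "pearson", "auto"),
                                conf_level = 0.95) {
  method <- match.arg(method)
  ok <- is.finite(feature) & is.finite(score)
  x <- feature[ok]; y <- score[ok]
  n <- length(x)
  if (n < 5L) stop("need >= 5 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(list(undefined = TRUE, reason = "constant input", n = n),
                     class = "correlation_result"))
  if (method == "auto") {
    method <- if (stats::shapiro.test(x)$p.value > 0.05 &&
                  stats::shapiro.test(y)$p.value > 0.05) "pearson"
              else "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  se <- if (method == "pearson") sqrt(1 / (n - 3)) else sqrt(1.06 / (n - 3))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- atanh(clamp(r, -1 + 1e-12, 1 - 1e-12))
  structure(list(method = method, coefficient = r,
                 ci_low = tanh(z - zq * se), ci_high = tanh(z + zq * se),
                 p_value = ct$p.value, n = n, undefined = FALSE),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(sprintf("correlation undefined (%s), n = %d\n", x$reason, x$n))
  } else {
    cat(sprintf("%s r = %.3f (95%% CI %.3f to %.3f), p = %.3g, n = %d\n",
                x$method, x$coefficient, x$ci_low, x$ci_high, x$p_value, x$n))
  }
  invisible(x)
}

#' Known-groups comparison on age- and study-adjusted residuals
#'
#' Fits `value ~ age + (1 | study)` by REML and compares model residuals
#' across groups with a Kruskal-Wallis test and all pairwise two-sided
#' Mann-Whitney U tests (unadjusted p-values). By default the residuals are
#' marginal (observed minus the fixed-effect age prediction): several groups
#' coincide with whole studies, so subtracting the BLUP study intercepts
#' would absorb part of the very group differences under test and makes the
#' Kruskal-Wallis test conservative under the null. Conditional residuals
#' (additionally subtracting the BLUP study intercepts) are available via
#' `residual_type`. When the mixed model cannot be fitted (single study or
#' degenerate variance), falls back to a fixed-intercept age regression with
#' a warning.
#'
#' @param data Data frame with columns `value`, `age`, `study`, `group`.
#' @param residual_type `"marginal"` (default) or `"conditional"`.
#' @return `known_groups_result` list: per-group residual summaries,
#'   Kruskal-Wallis statistic and p, pairwise test table, fitted age
#'   coefficient, and the model type used.
#' @export
known_groups <- function(data, residual_type = c("marginal", "conditional")) {
  residual_type <- match.arg(residual_type)
  stopifnot(all(c("value", "age", "study", "group") %in% names(data)))
  d <- data[is.finite(data$value) & is.finite(data$age), , drop = FALSE]
  groups <- unique(d$group)
  if (length(groups) < 2L) stop("need >= 2 nonempty groups")
  fit_type <- "mixed"
  resid_vals <- NULL; age_coef <- NA_real_
  if (length(unique(d$study)) >= 2L) {
    fit <- tryCatch(
      suppressMessages(lme4::lmer(value ~ age + (1 | study), data = d,
                                  REML = TRUE)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      resid_vals <- if (residual_type == "conditional") {
        stats::residuals(fit)              # y - Xb - Zu
      } else {
        d$value - stats::predict(fit, re.form = NA)  # y - Xb
      }
      age_coef <- unname(lme4::fixef(fit)["age"])
    }
  }
  if (is.null(resid_vals)) {
    fit_type <- "fixed"
    warning("mixed model not estimable; using fixed-intercept age regression")
    fit <- stats::lm(value ~ age, data = d)
    resid_vals <- stats::residuals(fit)
    age_coef <- unname(stats::coef(fit)["age"])
  }
  d$residual <- resid_vals
  grp_summ <- do.call(rbind, lapply(split(d$residual, d$group), function(r) {
    data.frame(n = length(r), median = stats::median(r),
               q1 = unname(stats::quantile(r, 0.25)),
               q3 = unname(stats::quantile(r, 0.75)))
  }))
  grp_summ <- cbind(group = rownames(grp_summ), grp_summ)
  rownames(grp_summ) <- NULL
  kw <- if (stats::sd(d$residual) <=
              1e-10 * max(1, stats::sd(d$value))) {
    # residuals identical up to numerical noise (e.g. the noise-free limit)
    list(statistic = c(H = 0), p.value = 1)
  } else {
    stats::kruskal.test(d$residual, factor(d$group))
  }
  pairs <- utils::combn(sort(unique(as.character(d$group))), 2L)
  pw <- do.call(rbind, apply(pairs, 2L, function(pr) {
    a <- d$residual[d$group == pr[1L]]
    b <- d$residual[d$group == pr[2L]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(group1 = pr[1L], group2 = pr[2L], U = unname(wt$statistic),
               p_value = wt$p.value, stringsAsFactors = FALSE)
  }))
  rownames(pw) <- NULL
  structure(list(groups = grp_summ, kruskal_H = unname(kw$statistic),
                 kruskal_p = kw$p.value, pairwise = pw, age_coef = age_coef,
                 model = fit_type, residuals = d),
            class = "known_groups_result")
}

#' @export
print.known_groups_result <- function(x, ...) {
  cat(sprintf("Known-groups comparison (%s model): H = %.3f, p = %.3g\n",
              x$model, x$kruskal_H, x$kruskal_p))
  cat(sprintf("  %d groups, %d pairwise Mann-Whitney tests, age coef %.4g\n",
              nrow(x$groups), nrow(x$pairwise), x$age_coef))
  invisible(x)
}
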