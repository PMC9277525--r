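## Execution quality control.
##
## The original QC criteria (which sessions count as "improperly executed")
## were never published in full; the checks here are reconstructed from the
## reported behaviour and are explicitly labelled as such in reports:
##   * placement: ambulatory tests (walking, U-turn, balance) carried in the
##     trouser pocket instead of the waist pouch are always excluded;
##   * duration: sensor recordings shorter than a fraction of the nominal
##     test length are excluded;
##   * completeness: a draw-a-shape attempt ends at the first finger lift, so
##     traces covering less than half the reference spiral are excluded;
##   * payload: structurally incomplete payloads are excluded.
## Minimum-evidence gates (>= 2 taps, >= 3 turns, >= 10 steps) live in the
## extractors and surface through the same qc_status field.

#' Default QC rule set
#'
#' @param min_duration_frac Minimum recorded duration as a fraction of the
#'   nominal test length (sensor-based tests).
#' @param min_draw_coverage Minimum fraction of the reference spiral drawn
#'   before the first finger lift.
#' @param placement_tests Tests requiring waist-pouch placement.
#' @return A `qc_rules` list, one entry per active test.
#' @export
qc_rules_default <- function(min_duration_frac = 0.9,
                             min_draw_coverage = 0.5,
                             placement_tests = HD_POUCH_TESTS) {
  rules <- lapply(HD_TESTS, function(test) {
    list(test = test,
         min_duration = if (test %in% c("chorea", "balance", "uturn",
                                        "walking"))
           min_duration_frac * HD_TEST_DURATION[[test]] else NULL,
         require_pouch = test %in% placement_tests,
         min_draw_coverage = if (test == "draw") min_draw_coverage else NULL)
  })
  names(rules) <- HD_TESTS
  structure(rules, class = "qc_rules")
}

#' Apply QC rules to one session
#'
#' A session fails if any predicate of its test's rule set fails. Predicates
#' are pure functions of the session, so QC is idempotent and
#' order-independent across sessions.
#'
#' @param session A session list (see [synthesize_session()]).
#' @param rules A rule set from [qc_rules_default()].
#' @return List with `status` (`"pass"`/`"fail"`) and `reason` (`""` on pass).
#' @export
apply_qc <- function(session, rules = qc_rules_default()) {
  rule <- rules[[session$test]]
  if (is.null(rule)) stop("no QC rule set for test: ", session$test)
  if (rule$require_pouch && identical(session$placement, "pocket"))
    return(list(status = "fail", reason = "placement"))
  p <- session$payload
  if (is.null(p)) return(list(status = "fail", reason = "payload_missing"))
  if (!is.null(rule$min_duration)) {
    if (is.null(p$t) || diff(range(p$t)) < rule$min_duration)
      return(list(status = "fail", reason = "duration"))
  }
  if (!is.null(rule$min_draw_coverage)) {
    frac <- attr(p, "frac_drawn")
    if (is.null(frac)) {
      up <- which(p$phase == "up")
      frac <- if (length(up)) up[1L] / nrow(p) else 1
    }
    if (frac < rule$min_draw_coverage)
      return(list(status = "fail", reason = "incomplete"))
  }
  list(status = "pass", reason = "")
}

#' QC summary report
#'
#' Tabulates exclusions per stratum, per-subject pass rates, and participants
#' lost per test (no 2-week interval retaining at least the aggregation
#' minimum of passing observations).
#'
#' @param features Long feature/session table with at least columns
#'   `participant_id`, `test`, `hand`, `qc_status`; `study`, `cohort` and
#'   `day` are used when present.
#' @param precision Decimal places for printed fail-rate percentages.
#' @param n_min Named per-test minimum-observation map (see `HD_NMIN`).
#' @return A `qc_report` list: `strata` (excluded/total/fail-rate table),
#'   `participant` (per-subject pass rates per test), `lost` (participants
#'   lost per test/hand), and the `precision` used.
#' @export
qc_report <- function(features, precision = 1, n_min = HD_NMIN) {
  stopifnot(all(c("participant_id", "test", "hand", "qc_status") %in%
                  names(features)))
  f <- features
  f$study <- f$study %||% "all"
  f$cohort <- f$cohort %||% "all"
  key <- interaction(f$study, f$cohort, f$test, f$hand, drop = TRUE)
  strata <- do.call(rbind, lapply(split(f, key), function(g) {
    data.frame(study = g$study[1L], cohort = g$cohort[1L], test = g$test[1L],
               hand = g$hand[1L], excluded = sum(g$qc_status != "pass"),
               total = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(strata) <- NULL
  strata <- strata[strata$total > 0L, , drop = FALSE]  # undefined rates omitted
  strata$fail_rate <- round(100 * strata$excluded / strata$total, precision)

  pkey <- interaction(f$participant_id, f$test, f$hand, drop = TRUE)
  participant <- do.call(rbind, lapply(split(f, pkey), function(g) {
    data.frame(participant_id = g$participant_id[1L], test = g$test[1L],
               hand = g$hand[1L], attempted = nrow(g),
               passed = sum(g$qc_status == "pass"),
               pass_rate = sum(g$qc_status == "pass") / nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(participant) <- NULL

  lost <- NULL
  if ("day" %in% names(f)) {
    lost <- do.call(rbind, lapply(split(f, pkey), function(g) {
      nm <- n_min[[g$test[1L]]] %||% 3L
      ok <- g$qc_status == "pass"
      n1 <- sum(ok & g$day >= 1L & g$day <= 14L)
      n2 <- sum(ok & g$day >= 15L & g$day <= 28L)
      data.frame(participant_id = g$participant_id[1L], test = g$test[1L],
                 hand = g$hand[1L], lost = (n1 < nm) && (n2 < nm),
                 stringsAsFactors = FALSE)
    }))
    rownames(lost) <- NULL
  }
  structure(list(strata = strata, participant = participant, lost = lost,
                 precision = precision, criteria = "reconstructed"),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (criteria: reconstructed)\n")
  cat(sprintf("  %d strata, %d participant-test combinations\n",
              nrow(x$strata), nrow(x$participant)))
  worst <- x$strata[order(-x$strata$fail_rate), ][1L, ]
  cat(sprintf("  highest fail rate: %s %s (%s/%s) %.*f%%\n", worst$test,
              worst$hand, worst$excluded, worst$total, x$precision,
              worst$fail_rate))
  invisible(x)
}

#' Association between per-subject QC pass rate and clinical severity
#'
#' Spearman correlation between each participant's QC pass rate on one test
#' (draw-a-shape by default) and clinical scores (UHDRS-TMS and maximal
#' chorea upper limb). A negative correlation means more severely affected
#' participants fail QC more often.
#'
#' @param report A [qc_report()].
#' @param participants A [generate_cohort()]-style frame with `id`, `tms`,
#'   `chorea_d`, `chorea_nd`.
#' @param test Test whose pass rate is analysed.
#' @return List of `correlation_result` objects (one per clinical score),
#'   or entries flagged `undefined` when pass rates are constant.
#' @export
pass_rate_severity_association <- function(report, participants,
                                           test = "draw") {
  pr <- report$participant[report$participant$test == test, , drop = FALSE]
  rate <- tapply(pr$pass_rate, pr$participant_id, mean)  # pool hands
  idx <- match(names(rate), participants$id)
  ok <- !is.na(idx)
  rate <- rate[ok]; idx <- idx[ok]
  if (length(rate) < 10L) stop("need >= 10 participants with defined pass rates")
  scores <- list(tms = participants$tms[idx],
                 chorea_max = pmax(participants$chorea_d[idx],
                                   participants$chorea_nd[idx]))
  lapply(scores, function(sc) {
    if (stats::sd(rate) == 0 || stats::sd(sc) == 0) {
      return(list(undefined = TRUE,
                  reason = "constant pass rates or scores", n = length(rate)))
    }
    convergent_validity(rate, sc, method = "spearman")
  })
}
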