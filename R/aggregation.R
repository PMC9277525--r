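## Two-week median aggregation and adherence accounting.
##
## Reported feature values are medians over 2-week intervals (days 1-14 and
## 15-28, both ends closed). If fewer than n_min QC-passing observations are
## available for a participant, feature and interval, the interval value is
## missing: n_min is 1 for the weekly cognitive tests (SDMT, SWR) and 3 for
## all daily tests. Even-count medians use the midpoint convention
## (stats::median).

#' Median-aggregate one participant-feature series over a 2-week interval
#'
#' @param features Feature rows for one participant and one feature/hand:
#'   data frame with columns `day` (1-28), `value`, `qc_status`, `test`.
#' @param interval 1 (days 1-14) or 2 (days 15-28).
#' @param n_min Named per-test minimum-observation map.
#' @return One-row data frame: interval, median (NA when missing),
#'   n_observations, missing.
#' @export
aggregate_interval <- function(features, interval, n_min = HD_NMIN) {
  stopifnot(interval %in% c(1L, 2L))
  if (any(features$day < 1L | features$day > HD_STUDY_DAYS))
    stop("day index outside 1-28")
  lo <- if (interval == 1L) 1L else 15L
  hi <- if (interval == 1L) 14L else 28L
  ok <- features$qc_status == "pass" & features$day >= lo &
    features$day <= hi & !is.na(features$value)
  vals <- features$value[ok]
  nm <- if (nrow(features)) n_min[[features$test[1L]]] %||% 3L else 3L
  missing <- length(vals) < nm
  data.frame(interval = as.integer(interval),
             median = if (missing) NA_real_ else stats::median(vals),
             n_observations = length(vals), missing = missing)
}

#' Aggregate a full feature table over both 2-week intervals
#'
#' Applies [aggregate_interval()] per participant, test, hand and interval.
#'
#' @param features Long feature table (one row per session) with columns
#'   `participant_id`, `test`, `hand`, `feature`, `day`, `value`,
#'   `qc_status`.
#' @param n_min Named per-test minimum-observation map.
#' @return Long data frame: participant_id, test, hand, feature, interval,
#'   median, n_observations, missing.
#' @export
aggregate_features <- function(features, n_min = HD_NMIN) {
  key <- interaction(features$participant_id, features$test, features$hand,
                     drop = TRUE)
  out <- lapply(split(features, key), function(g) {
    rows <- rbind(aggregate_interval(g, 1L, n_min),
                  aggregate_interval(g, 2L, n_min))
    data.frame(participant_id = g$participant_id[1L], test = g$test[1L],
               hand = g$hand[1L], feature = g$feature[1L], rows,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Adherence summary
#'
#' Proportion of scheduled active tests completed over the 4-week window,
#' reported per study when a `study` column is present (overall otherwise).
#'
#' @param schedules Schedule table with logical columns `scheduled` and
#'   `completed` (see [generate_schedule()]); optional `study` column.
#' @param precision Decimal places of the reported percentage.
#' @return Data frame: study, completed, scheduled, percent.
#' @export
adherence <- function(schedules, precision = 2) {
  grp <- schedules$study %||% rep("all", nrow(schedules))
  out <- do.call(rbind, lapply(split(schedules, grp), function(g) {
    sched <- sum(g$scheduled)
    if (sched == 0L) {
      warning("zero scheduled tests in stratum; adherence undefined")
      return(data.frame(study = g$study[1L] %||% "all", completed = 0L,
                        scheduled = 0L, percent = NA_real_))
    }
    data.frame(study = if (is.null(g$study)) "all" else g$study[1L],
               completed = sum(g$completed & g$scheduled), scheduled = sched,
               percent = round(100 * sum(g$completed & g$scheduled) / sched,
                               precision),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
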