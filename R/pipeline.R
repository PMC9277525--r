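## End-to-end orchestration: simulate -> extract -> qc -> aggregate ->
## validate, with file-based artifacts so each stage can be run and tested in
## isolation. A run is reproducible from the configuration and seed alone.

#' Default pipeline configuration
#'
#' Cohort sizes mirror the three validated study populations (OLE n=46
#' manifest; HD NHS n=94 manifest; Digital-HD 20 controls / 20 premanifest /
#' 39 manifest), study-level adherence matches the reported completion
#' proportions, and pocket-carriage probabilities are set so ambulatory-test
#' placement exclusions land in the reported 17-31% range.
#'
#' @param seed Integer master seed.
#' @param outdir Output directory (NULL = in-memory only).
#' @return `pipeline_config` list, fully JSON-serializable.
#' @export
default_config <- function(seed = 1L, outdir = NULL) {
  structure(list(
    seed = as.integer(seed),
    outdir = outdir,
    cohorts = list(
      list(study = "OLE", cohort = "manifest", n = 46L),
      list(study = "HD_NHS", cohort = "manifest", n = 94L),
      list(study = "DIGITAL_HD", cohort = "control", n = 20L),
      list(study = "DIGITAL_HD", cohort = "premanifest", n = 20L),
      list(study = "DIGITAL_HD", cohort = "manifest", n = 39L)),
    adherence_prob = list(OLE = 0.90, HD_NHS = 0.72, DIGITAL_HD = 0.69),
    pocket_prob = list(OLE = 0.30, HD_NHS = 0.22, DIGITAL_HD = 0.18),
    qc = list(min_duration_frac = 0.9, min_draw_coverage = 0.5),
    n_min = as.list(HD_NMIN),
    correlation_methods = list(sdmt = "pearson", swr = "pearson",
                               tapping = "pearson", draw = "spearman",
                               chorea = "spearman", balance = "spearman",
                               uturn = "spearman", walking = "spearman"),
    precision = list(adherence = 2, qc = 1),
    write_raw = FALSE), class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config A `pipeline_config` list.
#' @param path File path.
#' @return `read_config` returns a validated `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_config(structure(cfg, class = "pipeline_config"))
}

#' @rdname write_config
#' @export
validate_config <- function(config) {
  req <- c("seed", "cohorts", "adherence_prob", "pocket_prob", "qc", "n_min",
           "correlation_methods", "precision")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop("config missing fields: ", paste(miss, collapse = ", "))
  for (co in config$cohorts) {
    if (!co$study %in% HD_STUDIES) stop("bad study in config: ", co$study)
    if (!co$cohort %in% HD_COHORTS) stop("bad cohort in config: ", co$cohort)
    if (co$n < 1) stop("cohort n must be >= 1")
  }
  for (p in unlist(config$adherence_prob)) {
    if (p < 0 || p > 1) stop("adherence_prob outside [0, 1]")
  }
  config
}

## group label used for known-groups comparisons: the three Digital-HD
## cohorts plus the two manifest-only study populations.
.kg_group <- function(study, cohort) {
  ifelse(study == "DIGITAL_HD", paste0("DigitalHD_", cohort), study)
}

#' Simulate all cohorts and schedules of a configured run
#'
#' @param config A `pipeline_config`.
#' @return List with `participants` and `schedules` data frames.
#' @export
simulate_study <- function(config) {
  config <- validate_config(config)
  parts <- list(); scheds <- list()
  for (i in seq_along(config$cohorts)) {
    co <- config$cohorts[[i]]
    spec <- cohort_spec(co$study, co$cohort, co$n,
                        severity_mean = co$severity_mean %||% NULL,
                        severity_sd = co$severity_sd %||% NULL,
                        seed = derive_seed(config$seed, 100L + i))
    cohort <- generate_cohort(spec)
    parts[[i]] <- cohort
    adh <- config$adherence_prob[[co$study]]
    pock <- config$pocket_prob[[co$study]]
    scheds[[i]] <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(j) {
      sc <- generate_schedule(cohort[j, ], adherence_prob = adh,
                              pocket_prob = pock,
                              seed = derive_seed(config$seed, 200L + i, j))
      sc$study <- co$study
      sc$cohort <- co$cohort
      sc
    }))
  }
  list(participants = do.call(rbind, parts), schedules = do.call(rbind, scheds))
}

## Empty feature table with the canonical columns.
.empty_features <- function() {
  data.frame(participant_id = character(0), study = character(0),
             cohort = character(0), day = integer(0), test = character(0),
             hand = character(0), placement = character(0),
             feature = character(0), value = numeric(0), units = character(0),
             qc_status = character(0), qc_reason = character(0),
             stringsAsFactors = FALSE)
}

#' Synthesize, QC and extract features for every completed session
#'
#' Streams over the completed sessions of a simulated study: synthesizes each
#' raw payload deterministically from the run seed, applies the execution QC
#' rules, runs the feature extractor, and collects one row per session. A
#' session failing placement/duration/completeness QC keeps its extracted
#' value (when computable) but carries `qc_status = "fail"`.
#'
#' @param participants,schedules Output of [simulate_study()].
#' @param config A `pipeline_config`.
#' @param raw_dir If non-NULL, raw session payloads are also written as CSV
#'   files under this directory with a JSON manifest (intended for small
#'   runs).
#' @return Long feature table, one row per completed session.
#' @export
extract_study <- function(participants, schedules, config, raw_dir = NULL) {
  rules <- qc_rules_default(
    min_duration_frac = config$qc$min_duration_frac,
    min_draw_coverage = config$qc$min_draw_coverage)
  done <- schedules[schedules$completed, , drop = FALSE]
  n <- nrow(done)
  if (n == 0L) return(.empty_features())
  pidx <- match(done$id, participants$id)
  value <- numeric(n); feature <- character(n)
  status <- character(n); reason <- character(n)
  manifest <- if (!is.null(raw_dir)) vector("list", n) else NULL
  params <- sim_params()
  for (i in seq_len(n)) {
    part <- participants[pidx[i], ]
    ses <- synthesize_session(part, done$test[i], hand = done$hand[i],
                              seed = derive_seed(config$seed, 300L, pidx[i]),
                              day = done$day[i], placement = done$placement[i],
                              params = params)
    qc <- apply_qc(ses, rules)
    ex <- .extract_value(ses)
    feature[i] <- ex$feature
    value[i] <- ex$value
    if (qc$status == "fail") {
      status[i] <- "fail"; reason[i] <- qc$reason
    } else {
      status[i] <- ex$status; reason[i] <- ex$reason
    }
    if (!is.null(raw_dir)) {
      manifest[[i]] <- write_session_files(ses, raw_dir, i)
    }
  }
  if (!is.null(raw_dir)) {
    jsonlite::write_json(manifest, file.path(raw_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  data.frame(participant_id = done$id, study = done$study,
             cohort = done$cohort, day = done$day, test = done$test,
             hand = done$hand, placement = done$placement, feature = feature,
             value = value, units = unname(HD_FEATURE_UNITS[feature]),
             qc_status = status, qc_reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write one session's raw payload to plain-text files
#'
#' Sensor payloads become CSVs with columns t_s, ax, ay, az, gx, gy, gz;
#' touch payloads t_s, x_mm, y_mm, phase; SDMT/SWR payloads go to response
#' CSVs. Returns the manifest entry for the session.
#'
#' @param session A session list.
#' @param dir Output directory (created if needed).
#' @param index Integer used in the file name.
#' @return Manifest entry (list of metadata and relative file paths).
#' @export
write_session_files <- function(session, dir, index) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("session_%05d_%s_%s_d%02d", index, session$participant_id,
                  session$test, session$day)
  p <- session$payload
  files <- character(0)
  if (inherits(p, "sensor_recording")) {
    df <- data.frame(t_s = p$t,
                     ax = if (is.null(p$acc)) NA else p$acc[, 1L],
                     ay = if (is.null(p$acc)) NA else p$acc[, 2L],
                     az = if (is.null(p$acc)) NA else p$acc[, 3L],
                     gx = if (is.null(p$gyro)) NA else p$gyro[, 1L],
                     gy = if (is.null(p$gyro)) NA else p$gyro[, 2L],
                     gz = if (is.null(p$gyro)) NA else p$gyro[, 3L])
    files <- paste0(stem, "_sensor.csv")
    utils::write.csv(df, file.path(dir, files), row.names = FALSE)
  } else if (is.data.frame(p)) {
    files <- paste0(stem, "_touch.csv")
    utils::write.csv(p, file.path(dir, files), row.names = FALSE)
  } else if (session$test == "sdmt") {
    files <- c(paste0(stem, "_responses.csv"), paste0(stem, "_key.csv"))
    utils::write.csv(p$responses, file.path(dir, files[1L]), row.names = FALSE)
    utils::write.csv(data.frame(symbol = names(p$key),
                                digit = as.integer(p$key)),
                     file.path(dir, files[2L]), row.names = FALSE)
  } else if (session$test == "swr") {
    files <- paste0(stem, "_words.csv")
    nmax <- max(length(p$displayed), length(p$recognized))
    utils::write.csv(data.frame(
      displayed = c(p$displayed, rep(NA, nmax - length(p$displayed))),
      recognized = c(p$recognized, rep(NA, nmax - length(p$recognized)))),
      file.path(dir, files), row.names = FALSE)
  }
  list(participant_id = session$participant_id, test = session$test,
       hand = session$hand, day = session$day, placement = session$placement,
       files = as.list(files))
}

#' Read a sensor session CSV back into a recording
#'
#' @param path Path to a `*_sensor.csv` written by [write_session_files()].
#' @return A [sensor_recording].
#' @export
read_sensor_csv <- function(path) {
  df <- utils::read.csv(path)
  acc <- if (!all(is.na(df$ax))) as.matrix(df[, c("ax", "ay", "az")]) else NULL
  gyro <- if (!all(is.na(df$gx))) as.matrix(df[, c("gx", "gy", "gz")]) else NULL
  sensor_recording(df$t_s, acc = acc, gyro = gyro)
}

#' Validation statistics over an aggregated run
#'
#' Computes the three cross-sectional validation surfaces: per-feature,
#' per-study test-retest ICCs between the two interval medians; per-group
#' convergent-validity correlations between interval-1 medians and their
#' paired clinical scores; and per-feature known-groups comparisons over the
#' five groups (three Digital-HD cohorts plus the two manifest study
#' populations).
#'
#' @param aggregated Output of [aggregate_features()] (with `study`/`cohort`
#'   columns joined).
#' @param participants Participant table.
#' @param config A `pipeline_config`.
#' @return List: `icc` (Table-3-shaped frame), `convergent` (Table-4-shaped
#'   frame), `known_groups` (per-feature list).
#' @export
validate_study <- function(aggregated, participants, config = default_config()) {
  rows <- .feature_rows()
  agg <- merge(aggregated,
               participants[, c("id", "study", "cohort", "age")],
               by.x = "participant_id", by.y = "id")
  icc_tab <- list(); conv_tab <- list(); kg <- list()
  for (r in seq_len(nrow(rows))) {
    test <- rows$test[r]; hand <- rows$hand[r]
    sub <- agg[agg$test == test & agg$hand == hand, , drop = FALSE]
    if (!nrow(sub)) next
    wide <- merge(sub[sub$interval == 1L, c("participant_id", "study",
                                            "cohort", "age", "median")],
                  sub[sub$interval == 2L, c("participant_id", "median")],
                  by = "participant_id", suffixes = c("_1", "_2"))
    label <- if (hand == "NA") test else paste0(test, "_", hand)
    # --- test-retest ICC per study
    for (st in unique(wide$study)) {
      w <- wide[wide$study == st, ]
      res <- tryCatch(test_retest_icc(w$median_1, w$median_2),
                      error = function(e) NULL)
      if (is.null(res) || isTRUE(res$undefined)) next
      icc_tab[[length(icc_tab) + 1L]] <- data.frame(
        test = test, hand = hand, feature = label, study = st,
        icc = res$estimate, ci_low = res$ci_low, ci_high = res$ci_high,
        n = res$n, stringsAsFactors = FALSE)
    }
    # --- convergent validity per study group (manifest-only studies whole,
    #     Digital-HD split by cohort), interval-1 medians vs clinical score
    score_col <- .clinical_pair(test, hand)
    method <- config$correlation_methods[[test]] %||% "spearman"
    pr <- participants[match(wide$participant_id, participants$id), ]
    wide$score <- pr[[score_col]]
    wide$group <- .kg_group(wide$study, wide$cohort)
    for (g in unique(wide$group)) {
      w <- wide[wide$group == g & is.finite(wide$median_1) &
                  is.finite(wide$score), ]
      res <- tryCatch(convergent_validity(w$median_1, w$score, method = method),
                      error = function(e) NULL)
      if (is.null(res) || isTRUE(res$undefined)) next
      conv_tab[[length(conv_tab) + 1L]] <- data.frame(
        test = test, hand = hand, feature = label, group = g,
        clinical_score = score_col, method = res$method,
        coefficient = res$coefficient, ci_low = res$ci_low,
        ci_high = res$ci_high, p_value = res$p_value, n = res$n,
        stringsAsFactors = FALSE)
    }
    # --- known-groups on interval-1 medians
    kgd <- data.frame(value = wide$median_1, age = wide$age,
                      study = wide$study,
                      group = .kg_group(wide$study, wide$cohort))
    kgd <- kgd[is.finite(kgd$value), ]
    if (length(unique(kgd$group)) >= 2L && nrow(kgd) >= 10L) {
      kg[[label]] <- known_groups(kgd)
    }
  }
  list(icc = do.call(rbind, icc_tab), convergent = do.call(rbind, conv_tab),
       known_groups = kg)
}

## The 11 reported feature rows: per-hand tests contribute two rows.
.feature_rows <- function() {
  data.frame(
    test = c("sdmt", "swr", "tapping", "tapping", "draw", "draw",
             "chorea", "chorea", "balance", "uturn", "walking"),
    hand = c("NA", "NA", "D", "ND", "D", "ND", "D", "ND", "NA", "NA", "NA"),
    stringsAsFactors = FALSE)
}

## Clinical score paired with each digital feature.
.clinical_pair <- function(test, hand) {
  switch(test,
    sdmt = "sdmt_clinic", swr = "swr_clinic",
    tapping = "intertap_clinic_ms",
    draw = if (hand == "ND") "finger_taps_nd" else "finger_taps_d",
    chorea = if (hand == "ND") "chorea_nd" else "chorea_d",
    balance = "balance_score", uturn = "tms", walking = "tms")
}

#' Run the full pipeline
#'
#' Executes simulate -> extract -> qc -> aggregate -> validate and, when
#' `config$outdir` is set, writes all artifacts (participants, schedules,
#' features, QC report, aggregated medians, adherence, ICC and correlation
#' tables, known-groups JSON, and the run manifest).
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param stage One of `"all"`, `"simulate"`, `"extract"`, `"qc"`,
#'   `"aggregate"`, `"validate"`. Stages after `"simulate"` read their inputs
#'   from `config$outdir` when run in isolation.
#' @return Invisibly, a list with all in-memory artifacts of the executed
#'   stages.
#' @export
run_pipeline <- function(config = default_config(), stage = "all") {
  config <- validate_config(config)
  stage <- match.arg(stage, c("all", "simulate", "extract", "qc", "aggregate",
                              "validate"))
  out <- config$outdir
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)
  art <- list(config = config)
  rank <- c(simulate = 1L, extract = 2L, qc = 3L, aggregate = 4L,
            validate = 5L)
  target <- if (stage == "all") 5L else rank[[stage]]
  # a single requested stage reuses upstream artifacts from outdir when they
  # exist; otherwise upstream stages are recomputed in memory (deterministic
  # under the config seed either way)
  fresh <- function(s) stage == "all" || stage == s ||
    is.null(out) || !file.exists(file.path(out, s))
  load_csv <- function(name) {
    df <- utils::read.csv(file.path(out, name), stringsAsFactors = FALSE)
    if ("hand" %in% names(df)) df$hand[is.na(df$hand)] <- "NA"  # literal label
    df
  }

  # --- simulate
  if (!is.null(out) && stage != "simulate" &&
      file.exists(file.path(out, "participants.csv"))) {
    art$participants <- load_csv("participants.csv")
    art$schedules <- load_csv("schedules.csv")
  } else {
    sim <- simulate_study(config)
    art$participants <- sim$participants
    art$schedules <- sim$schedules
    if (!is.null(out)) {
      utils::write.csv(sim$participants, file.path(out, "participants.csv"),
                       row.names = FALSE)
      utils::write.csv(sim$schedules, file.path(out, "schedules.csv"),
                       row.names = FALSE)
    }
  }
  if (target <= rank[["simulate"]]) return(invisible(art))

  # --- extract
  if (!is.null(out) && stage != "extract" &&
      file.exists(file.path(out, "features.csv"))) {
    art$features <- load_csv("features.csv")
  } else {
    raw_dir <- if (isTRUE(config$write_raw) && !is.null(out))
      file.path(out, "raw") else NULL
    art$features <- extract_study(art$participants, art$schedules, config,
                                  raw_dir = raw_dir)
    if (!is.null(out)) {
      utils::write.csv(art$features, file.path(out, "features.csv"),
                       row.names = FALSE)
    }
  }
  if (target <= rank[["extract"]]) return(invisible(art))

  # --- qc
  if (stage %in% c("all", "qc")) {
    if (nrow(art$features)) {
      art$qc <- qc_report(art$features,
                          precision = config$precision$qc %||% 1,
                          n_min = unlist(config$n_min))
      if (!is.null(out)) {
        utils::write.csv(art$qc$strata, file.path(out, "qc_strata.csv"),
                         row.names = FALSE)
        utils::write.csv(art$qc$participant,
                         file.path(out, "qc_participant.csv"),
                         row.names = FALSE)
        jsonlite::write_json(
          list(criteria = "reconstructed",
               n_sessions = nrow(art$features),
               n_excluded = sum(art$features$qc_status != "pass"),
               lost = if (!is.null(art$qc$lost))
                 lapply(split(art$qc$lost, art$qc$lost$test), function(g)
                   sum(g$lost)) else NULL),
          file.path(out, "qc_summary.json"), auto_unbox = TRUE, digits = NA)
      }
    }
  }
  if (target <= rank[["qc"]]) return(invisible(art))

  # --- aggregate
  if (!is.null(out) && stage != "aggregate" &&
      file.exists(file.path(out, "aggregated.csv"))) {
    art$aggregated <- load_csv("aggregated.csv")
    art$adherence <- utils::read.csv(file.path(out, "adherence.csv"),
                                     stringsAsFactors = FALSE)
  } else {
    art$adherence <- adherence(art$schedules,
                               precision = config$precision$adherence %||% 2)
    art$aggregated <- if (nrow(art$features))
      aggregate_features(art$features, n_min = unlist(config$n_min))
    else NULL
    if (!is.null(out)) {
      utils::write.csv(art$adherence, file.path(out, "adherence.csv"),
                       row.names = FALSE)
      jsonlite::write_json(art$adherence, file.path(out, "adherence.json"),
                           auto_unbox = TRUE, digits = NA)
      if (!is.null(art$aggregated)) {
        utils::write.csv(art$aggregated, file.path(out, "aggregated.csv"),
                         row.names = FALSE)
      }
    }
  }
  if (target <= rank[["aggregate"]]) {
    if (!is.null(out)) write_config(config, file.path(out, "run_config.json"))
    return(invisible(art))
  }

  # --- validate
  if (!is.null(art$aggregated) && nrow(art$aggregated)) {
    art$validation <- validate_study(art$aggregated, art$participants, config)
    if (!is.null(out)) {
      if (!is.null(art$validation$icc)) {
        utils::write.csv(art$validation$icc, file.path(out, "table3_icc.csv"),
                         row.names = FALSE)
      }
      if (!is.null(art$validation$convergent)) {
        utils::write.csv(art$validation$convergent,
                         file.path(out, "table4_convergent.csv"),
                         row.names = FALSE)
      }
      kg_json <- lapply(art$validation$known_groups, function(k) {
        list(kruskal_H = k$kruskal_H, kruskal_p = k$kruskal_p,
             age_coef = k$age_coef, model = k$model,
             pairwise = k$pairwise)
      })
      jsonlite::write_json(kg_json, file.path(out, "known_groups.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }
  if (!is.null(out)) {
    write_config(config, file.path(out, "run_config.json"))
  }
  invisible(art)
}

#' Command-line entry point
#'
#' Parses `<stage> --config <path> --seed <int> --outdir <dir>
#' --precision <int>` style arguments and runs the pipeline. A wrapper script
#' is installed under `inst/cli/hdpipeline.R`.
#'
#' @param args Character vector of CLI arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the pipeline artifact list.
#' @export
hd_pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stage <- "all"
  if (length(args) && !startsWith(args[1L], "--")) {
    stage <- args[1L]
    args <- args[-1L]
  }
  opt <- list(config = NULL, seed = NULL, outdir = NULL, precision = NULL)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args))
      stop("unknown or incomplete CLI option: ", args[i])
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  config <- if (!is.null(opt$config)) read_config(opt$config)
            else default_config()
  if (!is.null(opt$seed)) config$seed <- as.integer(opt$seed)
  if (!is.null(opt$outdir)) config$outdir <- opt$outdir
  if (!is.null(opt$precision)) {
    config$precision$qc <- as.integer(opt$precision)
  }
  run_pipeline(config, stage = stage)
}
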