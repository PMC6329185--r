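cohort_columns <- c("patient_id", "sex", "age_y", "abo", "pt_pct", "aptt_s",
                    "fibrinogen_gL", "platelets_per_nL", "fviii_pct",
                    "vwf_ag_pct", "vwf_rco_pct", "vwf_cb_pct",
                    "bleeding_history", "multimer_abnormal")

#' Read a trace CSV
#'
#' Expects a header `time_s,amplitude_mm` (comma separator, dot decimal,
#' UTF-8) with one row per sample; a multi-channel file carries an additional
#' `channel` column. Rows must be numeric and times non-decreasing within a
#' channel; offending lines are reported by file line number.
#'
#' @param path CSV file.
#' @return a single [rotem_trace], or a named list of them for a
#'   multi-channel file.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) abort_invalid_input(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "amplitude_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_schema(paste0(path, ": missing required columns: ",
                        paste(miss, collapse = ", ")))
  for (col in need) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals))
    if (length(bad))
      abort_schema(sprintf("%s: non-numeric %s at line %d", path, col,
                           bad[1] + 1L))  # +1 for the header line
    df[[col]] <- vals
  }
  build <- function(sub, channel) {
    nonmono <- which(diff(sub$time_s) < 0)
    if (length(nonmono))
      abort_schema(sprintf("%s: non-monotone time_s at line %d", path,
                           sub$line[nonmono[1] + 1L]))
    rotem_trace(sub$time_s, sub$amplitude_mm, channel = channel)
  }
  df$line <- seq_len(nrow(df)) + 1L
  if ("channel" %in% names(df)) {
    out <- lapply(split(df, df$channel), function(sub)
      build(sub, channel = sub$channel[1]))
    out[unique(df$channel)]
  } else {
    build(df, channel = "extem")
  }
}

#' Write traces to CSV
#'
#' One trace writes `time_s,amplitude_mm`; a list of traces writes a
#' multi-channel file with a `channel` column. Round-trips through
#' [read_trace_csv()] to within 1e-9.
#'
#' @param traces a [rotem_trace] or named list of them.
#' @param path output file.
#' @export
write_trace_csv <- function(traces, path) {
  if (inherits(traces, "rotem_trace")) {
    df <- data.frame(time_s = traces$times, amplitude_mm = traces$amplitudes)
  } else {
    df <- do.call(rbind, lapply(traces, function(tr) {
      data.frame(channel = tr$channel, time_s = tr$times,
                 amplitude_mm = tr$amplitudes)
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort CSV
#'
#' Per-patient laboratory table. Required columns: `patient_id, sex, age_y,
#' abo, pt_pct, aptt_s, fibrinogen_gL, platelets_per_nL, fviii_pct,
#' vwf_ag_pct, vwf_rco_pct, vwf_cb_pct, bleeding_history,
#' multimer_abnormal`; extra columns (e.g. assay
#' AUCs, derived scores) are passed through. Logical columns accept
#' TRUE/FALSE or 0/1; `multimer_abnormal` may be empty (unknown).
#'
#' @param path CSV file.
#' @return data.frame, one row per patient.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort_invalid_input(paste("no such file:", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cohort_columns, names(df))
  if (length(miss))
    abort_schema(paste0(path, ": missing required columns: ",
                        paste(miss, collapse = ", ")))
  num_cols <- c("age_y", "pt_pct", "aptt_s", "fibrinogen_gL",
                "platelets_per_nL", "fviii_pct", "vwf_ag_pct", "vwf_rco_pct",
                "vwf_cb_pct")
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      abort_schema(sprintf("%s: non-numeric %s at line %d", path, col,
                           bad[1] + 1L))
    df[[col]] <- vals
  }
  for (col in c("bleeding_history", "multimer_abnormal"))
    df[[col]] <- as.logical(df[[col]])
  df
}

#' @rdname read_cohort_csv
#' @param cohort data.frame to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes a report list to JSON with a `schema_version` field; numbers
#' are written at full precision.
#'
#' @param report named list.
#' @param path output file.
#' @param schema_version report schema tag.
#' @export
write_report <- function(report, path, schema_version = "1.0") {
  report <- c(list(schema_version = schema_version), report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

run_config_keys <- c("seed", "device_scale", "noise_cv", "cutoffs", "cohort",
                     "paths", "verbosity")

#' Read a run configuration
#'
#' YAML configuration driving a full pipeline run: `seed`, `device_scale`,
#' `noise_cv`, `cutoffs` (ricotem_minus_cutoff_pct, ricotem_plus_cutoff_pct),
#' `cohort` (per-class counts), `paths`, `verbosity`. Unknown keys are
#' rejected by name so typos cannot silently change a run.
#'
#' @param path YAML file.
#' @return validated list with `cutoffs` as a [cutoff_config()] and `cohort`
#'   as a [cohort_spec()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_invalid_input(paste("no such file:", path))
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), run_config_keys)
  if (length(unknown))
    abort_schema(paste0(path, ": unknown config keys: ",
                        paste(unknown, collapse = ", "),
                        " (known: ", paste(run_config_keys, collapse = ", "), ")"))
  seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
  cut_args <- y$cutoffs %||% list()
  cohort_args <- y$cohort %||% list()
  cohort_args$seed <- seed
  if (!is.null(y$noise_cv)) cohort_args$noise_cv <- y$noise_cv
  list(seed = seed,
       device_scale = y$device_scale %||% 100,
       cutoffs = do.call(cutoff_config, cut_args),
       cohort = do.call(cohort_spec, cohort_args),
       paths = y$paths %||% list(),
       verbosity = y$verbosity %||% "info")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
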