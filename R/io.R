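# Recording files are a two-column CSV (time_s, value) plus a JSON sidecar
# carrying the metadata; delta tables are plain CSV. Desk-scale data
# (<= 120,000 rows per recording) and diffability argue for text over a
# binary container.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a recording to CSV + JSON sidecar
#'
#' The CSV has a header `time_s,value` and one row per sample (values at
#' full double precision, lossless round trip); the sidecar records fs,
#' channel, metadata, units, sample count and a `schema_version`.
#'
#' @param recording A [vc_recording()] with at least one sample.
#' @param path Destination CSV path (sidecar written next to it with the
#'   `.json` extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  if (!inherits(recording, "vc_recording"))
    stop_myovib("not_recording", "expected a vc_recording object")
  n <- length(recording$samples)
  if (n == 0L) stop_myovib("empty_recording", "refusing to write an empty recording")
  t <- (seq_len(n) - 1) / recording$fs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_s,value", con)
  writeLines(paste(sprintf("%.12g", t), sprintf("%.17g", recording$samples),
                   sep = ","), con)
  meta <- list(schema_version = 1L, fs = recording$fs,
               channel = recording$channel, subject_id = recording$subject_id,
               leg = recording$leg, stage = recording$stage,
               vibration = recording$vibration, units = recording$units,
               n_samples = n)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording from CSV + JSON sidecar
#'
#' Validates the file pair strictly: the sidecar must exist and declare a
#' known channel and stage; the time column must be uniform with step
#' `1/fs` (tolerance 1e-9 s); the row count must match the sidecar. Each
#' failure raises a distinct named condition (`myovib_error_missing_sidecar`,
#' `myovib_error_nonuniform_grid`, `myovib_error_unknown_stage`,
#' `myovib_error_length_mismatch`, `myovib_error_fs_mismatch`).
#'
#' @param path Path to the CSV file.
#' @return A [vc_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    stop_myovib("missing_file", "no such file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop_myovib("missing_sidecar", "missing sidecar JSON: ", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  for (f in c("fs", "channel", "subject_id", "leg", "stage", "vibration",
              "units", "n_samples"))
    if (is.null(meta[[f]]))
      stop_myovib("bad_sidecar", "sidecar lacks field: ", f)
  if (!meta$stage %in% vc_stages())
    stop_myovib("unknown_stage", "unknown stage label in sidecar: ", meta$stage)
  if (!meta$channel %in% .channels)
    stop_myovib("unknown_channel", "unknown channel: ", meta$channel)
  if (meta$units != channel_units(meta$channel))
    stop_myovib("unit_mismatch", "units ", meta$units,
                " do not match channel ", meta$channel)
  dat <- utils::read.csv(path)
  if (!identical(names(dat), c("time_s", "value")))
    stop_myovib("bad_header", "expected columns time_s,value; found: ",
                paste(names(dat), collapse = ","))
  if (nrow(dat) != meta$n_samples)
    stop_myovib("length_mismatch",
                sprintf("CSV has %d rows but sidecar declares %d",
                        nrow(dat), meta$n_samples))
  dt <- diff(dat$time_s)
  if (any(dt <= 0) || any(abs(dt - 1 / meta$fs) > 1e-9))
    stop_myovib("nonuniform_grid",
                "time column is not a uniform grid with step 1/fs")
  if (abs(dat$time_s[1]) > 1e-9)
    stop_myovib("fs_mismatch", "time column must start at 0")
  vc_recording(dat$value, fs = meta$fs, channel = meta$channel,
               subject_id = meta$subject_id, leg = meta$leg,
               stage = meta$stage, vibration = meta$vibration)
}

#' Write / read a delta table CSV
#'
#' One row per (subject, leg, stage, vibration, feature); `feature` is
#' `delta_stiffness` or `delta_iemg`.
#'
#' @param delta_table A delta table `data.frame`.
#' @param path CSV path.
#' @return `read_delta_table` returns the validated `data.frame`.
#' @export
write_delta_table <- function(delta_table, path) {
  utils::write.csv(delta_table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_delta_table
#' @export
read_delta_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_delta_table(d)
}

validate_delta_table <- function(d) {
  need <- c("subject_id", "leg", "stage", "vibration", "feature", "value")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_myovib("bad_table", "delta table lacks column(s): ",
                paste(miss, collapse = ", "),
                "; found: ", paste(names(d), collapse = ", "))
  bad <- setdiff(unique(d$stage), vc_stages())
  if (length(bad))
    stop_myovib("unknown_stage", "unknown stage label(s): ",
                paste(bad, collapse = ", "))
  if (!is.numeric(d$value))
    stop_myovib("bad_table", "value column must be numeric")
  dup <- duplicated(d[c("subject_id", "leg", "stage", "vibration", "feature")])
  if (any(dup))
    stop_myovib("bad_table", "duplicated (subject, leg, stage, vibration, feature) rows")
  d
}

#' Read a supplementary delta-value workbook
#'
#' Reads stage-wise delta values deposited as a spreadsheet (XLSX, needs
#' the readxl package) or CSV export, and normalizes them into the package
#' delta-table layout. Column names are matched case-insensitively with
#' whitespace stripped; a `mapping` can rename nonstandard headers
#' (e.g. `mapping = c(value = "delta stiffness")`). Unknown extra columns
#' are preserved as attributes and flagged in the log. Sign is preserved —
#' deltas may be negative.
#'
#' @param path XLSX or CSV path.
#' @param mapping Optional named character vector mapping standard names
#'   (`subject_id`, `leg`, `stage`, `vibration`, `feature`, `value`) to the
#'   headers used in the file.
#' @param sheet Sheet index or name for XLSX input.
#' @return A validated delta-table `data.frame`; extra columns in attribute
#'   `"extra_columns"`.
#' @export
read_supplementary_deltas <- function(path, mapping = NULL, sheet = 1) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_myovib("missing_dependency",
                  "reading XLSX requires the readxl package; export to CSV instead")
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  canon <- function(x) gsub("[[:space:]_.-]+", "", tolower(trimws(x)))
  hdr <- canon(names(raw))
  want <- c("subject_id", "leg", "stage", "vibration", "feature", "value")
  out <- list()
  for (w in want) {
    target <- if (!is.null(mapping) && w %in% names(mapping)) mapping[[w]] else w
    hit <- which(hdr == canon(target))
    if (length(hit) == 1L) out[[w]] <- raw[[hit]]
  }
  miss <- setdiff(c("subject_id", "leg", "stage", "value"), names(out))
  if (length(miss))
    stop_myovib("parse_error",
                "could not map required column(s) ", paste(miss, collapse = ", "),
                "; headers found: ", paste(names(raw), collapse = " | "))
  if (is.null(out$vibration)) out$vibration <- "on"
  if (is.null(out$feature)) out$feature <- "delta_stiffness"
  d <- as.data.frame(out, stringsAsFactors = FALSE)
  used <- vapply(want, function(w) {
    target <- if (!is.null(mapping) && w %in% names(mapping)) mapping[[w]] else w
    hit <- which(hdr == canon(target))
    if (length(hit) == 1L) names(raw)[hit] else NA_character_
  }, character(1))
  extra <- setdiff(names(raw), stats::na.omit(used))
  if (length(extra)) {
    log_msg("warn", "supplementary_extra_columns",
            columns = paste(extra, collapse = ";"))
    attr(d, "extra_columns") <- raw[extra]
  }
  validate_delta_table(d)
  d
}

# Run configuration -------------------------------------------------------

#' Read a run configuration file (YAML or JSON)
#'
#' A single structured file with sections `analysis` (stiffness and EMG
#' parameters), `stats` (alpha, correction, sampling-unit mode), `io`
#' (output directory, log level) and `scenario` (passed to
#' [vc_scenario()]); all sections are optional and merged over package
#' defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list with the four sections.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.list(cfg)) stop_myovib("bad_config", "config must be a mapping")
  unknown <- setdiff(names(cfg), c("analysis", "stats", "io", "scenario"))
  if (length(unknown))
    stop_myovib("bad_config", "unknown config section(s): ",
                paste(unknown, collapse = ", "))
  cfg
}

# Logging ------------------------------------------------------------------

.log_state <- new.env(parent = emptyenv())
.log_state$level <- "warn"
.log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

#' Set the package log level
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("warn", "debug", "info", "error")) {
  level <- match.arg(level)
  old <- .log_state$level
  .log_state$level <- level
  invisible(old)
}

# Timestamped, leveled, key=value log lines on stderr.
log_msg <- function(level, event, ...) {
  if (.log_levels[[level]] < .log_levels[[.log_state$level]]) return(invisible())
  kv <- list(...)
  extras <- if (length(kv))
    paste(names(kv), vapply(kv, as.character, ""), sep = "=", collapse = " ")
  else ""
  message(sprintf("%s level=%s event=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), level, event, extras))
}
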