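#' Assemble a run configuration
#'
#' Validated container for one end-to-end run: exactly one of `scenario`
#' (simulate) or `input_dir` (read recordings from disk) must be given.
#'
#' @param scenario A [vc_scenario()], or `NULL`.
#' @param input_dir Directory of recording CSV/JSON pairs, or `NULL`.
#' @param stiffness A [stiffness_params()].
#' @param emg An [emg_params()].
#' @param alpha Significance level.
#' @param correction `"none"` or `"holm"`.
#' @param out_dir Output directory, or `NULL` to keep results in memory.
#' @param seed Root seed override (defaults to the scenario's seed).
#' @param write_recordings Also write every simulated recording to
#'   `out_dir/recordings` (off by default: 448 files for the full design).
#' @param normality_screen Run the KS normality screen per cell.
#' @param log_level Package log level for the run.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = NULL, input_dir = NULL,
                       stiffness = stiffness_params(), emg = emg_params(),
                       alpha = 0.05, correction = "none",
                       out_dir = NULL, seed = NULL,
                       write_recordings = FALSE,
                       normality_screen = TRUE,
                       log_level = "warn") {
  if (is.null(scenario) == is.null(input_dir))
    stop_myovib("bad_config", "exactly one of scenario / input_dir must be set")
  if (!is.null(scenario)) {
    if (!inherits(scenario, "vc_scenario"))
      stop_myovib("bad_config", "scenario must be a vc_scenario")
    if (!is.null(seed)) scenario$seed <- as.integer(seed)
  }
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop_myovib("bad_config", "input_dir does not exist: ", input_dir)
  structure(list(scenario = scenario, input_dir = input_dir,
                 stiffness = stiffness, emg = emg, alpha = alpha,
                 correction = correction, out_dir = out_dir,
                 write_recordings = write_recordings,
                 normality_screen = normality_screen,
                 log_level = log_level),
            class = "run_config")
}

#' Feature extraction: recordings to delta table
#'
#' Runs the stiffness pipeline on every vibration-on accelerometer
#' recording (stiffness needs the vibratory stimulus) and the EMG pipeline
#' on every EMG recording (both vibration conditions, normalized per leg
#' across all stages and conditions), then forms baseline-subtracted
#' per-subject medians.
#'
#' @param recordings Named list of [vc_recording()]s (e.g.
#'   `simulate_experiment(...)$recordings`).
#' @param stiffness A [stiffness_params()].
#' @param emg An [emg_params()].
#' @param baseline_stage Baseline stage label.
#' @return A list with `delta_table` (both features combined),
#'   `invalid_windows` (count of degenerate stiffness windows), and
#'   `emg_peaks` (per-leg normalization peaks).
#' @export
compute_delta_table <- function(recordings, stiffness = stiffness_params(),
                                emg = emg_params(), baseline_stage = "T0") {
  is_ch <- function(r, ch) r$channel == ch
  acc_on <- Filter(function(r) is_ch(r, "ACC") && r$vibration == "on",
                   recordings)
  emg_all <- Filter(function(r) is_ch(r, "EMG"), recordings)
  if (length(acc_on) == 0L && length(emg_all) == 0L)
    stop_myovib("empty_input", "no ACC or EMG recordings supplied")

  stiff_series <- lapply(acc_on, process_stiffness, params = stiffness)
  invalid <- sum(vapply(stiff_series, function(s) sum(!s$valid), integer(1)))
  d_stiff <- if (length(stiff_series))
    delta_stiffness(stiff_series, baseline_stage) else NULL

  emg_by_leg <- split(emg_all, vapply(emg_all, function(r)
    paste(r$subject_id, r$leg, sep = "|"), ""))
  peaks <- list()
  iemg_series <- list()
  for (key in names(emg_by_leg)) {
    env <- lapply(emg_by_leg[[key]], emg_envelope, params = emg)
    if (emg$on_normalized) {
      norm <- normalize_to_peak(env)
      env <- norm$recordings
      peaks[[key]] <- norm$peak
    }
    iemg_series <- c(iemg_series, lapply(env, iemg, params = emg))
  }
  d_iemg <- if (length(iemg_series))
    delta_iemg(iemg_series, baseline_stage) else NULL

  list(delta_table = rbind(d_stiff, d_iemg),
       invalid_windows = invalid,
       emg_peaks = peaks)
}

#' Run the full pipeline: simulate / load, extract, compare, report
#'
#' Deterministic given the configuration (and its seed): simulates or loads
#' the recordings, extracts stiffness and IEMG deltas, runs the comparison
#' battery and box-plot summaries, and (if `out_dir` is set) writes
#' `delta_table.csv`, `comparisons.csv`, `boxplots.csv`, `normality.csv`
#' and a `manifest.json` with content hashes. Any stage failure aborts with
#' the failing stage named; partial outputs are retained next to a `FAILED`
#' marker file.
#'
#' @param config A [run_config()].
#' @return A list of class `vc_run`: `delta_table`, `comparisons`,
#'   `boxplots`, `normality`, `invalid_windows`, `manifest`.
#' @export
run_full_pipeline <- function(config) {
  if (!inherits(config, "run_config"))
    stop_myovib("bad_config", "expected a run_config")
  old_level <- set_log_level(config$log_level)
  on.exit(set_log_level(old_level), add = TRUE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        writeLines(paste("stage:", name, "-", conditionMessage(e)),
                   file.path(config$out_dir, "FAILED"))
      }
      stop_myovib("stage_failure",
                  "pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  recordings <- run_stage("acquire", {
    if (!is.null(config$scenario)) {
      log_msg("info", "simulate", seed = config$scenario$seed)
      simulate_experiment(config$scenario)$recordings
    } else {
      files <- list.files(config$input_dir, pattern = "\\.csv$",
                          full.names = TRUE)
      if (length(files) == 0L)
        stop_myovib("empty_input", "no CSV recordings in ", config$input_dir)
      lapply(files, read_recording)
    }
  })

  feats <- run_stage("features",
                     compute_delta_table(recordings, config$stiffness, config$emg))
  delta_table <- feats$delta_table
  comparisons <- run_stage("compare",
                           compare_all(delta_table, alpha = config$alpha,
                                       correction = config$correction))
  boxplots <- run_stage("summarize", boxplot_summaries(delta_table))
  normality <- if (config$normality_screen)
    run_stage("normality", normality_screen(delta_table)) else NULL

  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- run_stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      paths <- c(delta_table = file.path(config$out_dir, "delta_table.csv"),
                 comparisons = file.path(config$out_dir, "comparisons.csv"),
                 boxplots = file.path(config$out_dir, "boxplots.csv"))
      write_delta_table(delta_table, paths[["delta_table"]])
      utils::write.csv(comparisons, paths[["comparisons"]], row.names = FALSE)
      utils::write.csv(boxplots, paths[["boxplots"]], row.names = FALSE)
      if (!is.null(normality)) {
        paths[["normality"]] <- file.path(config$out_dir, "normality.csv")
        utils::write.csv(normality, paths[["normality"]], row.names = FALSE)
      }
      if (config$write_recordings && !is.null(config$scenario)) {
        rec_dir <- file.path(config$out_dir, "recordings")
        dir.create(rec_dir, showWarnings = FALSE)
        for (r in recordings)
          write_recording(r, file.path(rec_dir, paste0(
            gsub("[^A-Za-z0-9]+", "_", recording_key(r)), ".csv")))
      }
      man <- list(
        package_version = as.character(utils::packageVersion("myovib")),
        seed = if (!is.null(config$scenario)) config$scenario$seed else NA,
        alpha = config$alpha, correction = config$correction,
        invalid_windows = feats$invalid_windows,
        n_recordings = length(recordings),
        files = as.list(vapply(paths, function(p)
          unname(tools::md5sum(p)), character(1))))
      jsonlite::write_json(man, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      man
    })
  }

  structure(list(delta_table = delta_table, comparisons = comparisons,
                 boxplots = boxplots, normality = normality,
                 invalid_windows = feats$invalid_windows,
                 manifest = manifest),
            class = "vc_run")
}

#' @export
print.vc_run <- function(x, ...) {
  nsig <- sum(x$comparisons$significant, na.rm = TRUE)
  cat(sprintf("<vc_run> %d delta rows, %d comparisons (%d significant), %d invalid windows\n",
              nrow(x$delta_table), nrow(x$comparisons), nsig,
              x$invalid_windows))
  invisible(x)
}

# KS screen on every feature x vibration x leg x stage cell of the delta
# table. Baseline cells are identically zero by construction, so their
# screen is reported as NA (zero variance), not an error.
normality_screen <- function(delta_table, n_mc = 2000) {
  by <- interaction(delta_table$feature, delta_table$vibration,
                    delta_table$leg, delta_table$stage, drop = TRUE)
  out <- lapply(split(delta_table, by), function(g) {
    res <- tryCatch(ks_normality(g$value, n_mc = n_mc),
                    myovib_error = function(e) NULL)
    data.frame(feature = g$feature[1], vibration = g$vibration[1],
               leg = g$leg[1], stage = g$stage[1], n = nrow(g),
               D = if (is.null(res)) NA_real_ else res$statistic,
               p = if (is.null(res)) NA_real_ else res$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Replicate a scenario and tabulate rejection rates
#'
#' Runs the full pipeline across `n_replicates` seeded replicates of the
#' configuration's scenario (replicate `i` reseeds the scenario with
#' `seed + i`) and tabulates, per comparison, the fraction of replicates in
#' which it was significant, with binomial standard errors. Replicates that
#' fail are counted and skipped.
#'
#' @param config A [run_config()] with a scenario.
#' @param n_replicates Number of replicates (>= 1).
#' @return A `data.frame` keyed by comparison with columns
#'   `rejection_rate`, `se`, `n_ok`; failed-replicate count in attribute
#'   `"n_failed"`.
#' @export
replicate_experiments <- function(config, n_replicates) {
  if (!inherits(config, "run_config") || is.null(config$scenario))
    stop_myovib("bad_config", "replicate_experiments needs a scenario config")
  if (n_replicates < 1) stop_myovib("bad_config", "n_replicates must be >= 1")
  base_seed <- config$scenario$seed
  acc <- NULL
  key <- NULL
  n_failed <- 0L
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$out_dir <- NULL
    cfg$normality_screen <- FALSE
    cfg$scenario$seed <- as.integer((base_seed + i) %% 2147483647)
    run <- tryCatch(run_full_pipeline(cfg), error = function(e) {
      log_msg("warn", "replicate_failed", replicate = i,
              msg = conditionMessage(e))
      NULL
    })
    if (is.null(run)) { n_failed <- n_failed + 1L; next }
    cmp <- run$comparisons
    if (is.null(acc)) {
      key <- cmp[c("comparison_kind", "feature", "vibration", "stage", "leg")]
      acc <- matrix(0L, nrow = nrow(cmp), ncol = 2,
                    dimnames = list(NULL, c("sig", "ok")))
    }
    ok <- !is.na(cmp$significant)
    acc[, "ok"] <- acc[, "ok"] + ok
    acc[, "sig"] <- acc[, "sig"] + (ok & cmp$significant)
  }
  if (is.null(acc))
    stop_myovib("stage_failure", "every replicate failed")
  rate <- ifelse(acc[, "ok"] > 0, acc[, "sig"] / acc[, "ok"], NA_real_)
  out <- cbind(key,
               data.frame(rejection_rate = rate,
                          se = sqrt(pmax(rate * (1 - rate), 0) /
                                      pmax(acc[, "ok"], 1)),
                          n_ok = acc[, "ok"]))
  attr(out, "n_failed") <- n_failed
  out
}
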