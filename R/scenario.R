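#' Synthetic-experiment scenario
#'
#' A scenario fully specifies one simulated congestion experiment: how many
#' subjects, which stages, how tissue stiffness evolves over stages in each
#' leg, how EMG amplitude evolves, recording durations, sampling rate, noise
#' levels and the root seed. The defaults reproduce the conditions of the
#' animal study the package models: 8 subjects, seven stages, 2-minute
#' vibration-on and 30-second vibration-off recordings at 1000 Hz.
#'
#' Stage effects are expressed as multiplicative factors relative to
#' baseline: `stiffness_multipliers_experimental[s]` scales the true tissue
#' stiffness of the experimental leg at stage `s` (the control leg defaults
#' to all 1.0), and `emg_amplitude_factors_*` scale the EMG envelope. The
#' default experimental stiffness ramp (1.0 -> 1.6) emulates progressive
#' congestion-induced swelling; the EMG factors encode the modest,
#' control-leg-dominant amplitude changes the congestion study reported.
#'
#' Between-subject heterogeneity is lognormal on tissue stiffness, moving
#' mass, and EMG scale (coefficient of variation `subject_cv`, default 10 %).
#'
#' @param n_subjects Number of subjects (default 8).
#' @param stages Ordered subset of [vc_stages()] starting with `"T0"`.
#' @param tissue Baseline [tissue_model()] shared by both legs at `T0`.
#' @param unit [vibration_unit()] providing mass and drive parameters.
#' @param stiffness_multipliers_experimental Per-stage factors (>= 1) applied
#'   to experimental-leg stiffness.
#' @param stiffness_multipliers_control Per-stage factors for the control
#'   leg (default all 1).
#' @param emg_amplitude_factors_experimental,emg_amplitude_factors_control
#'   Per-stage EMG envelope scale factors.
#' @param emg_base_scale Baseline EMG envelope scale in a.u.
#' @param duration_on,duration_off Vibration-on / vibration-off recording
#'   durations in seconds (defaults 120 and 30).
#' @param fs Sampling rate in Hz (default 1000).
#' @param noise_sd Accelerometer sensor noise sd in m/s².
#' @param drift_amplitude Low-frequency baseline wander amplitude in m/s².
#' @param drift_frequency Drift frequency in Hz (< 2).
#' @param subject_cv Lognormal coefficient of variation of per-subject
#'   tissue/EMG parameters.
#' @param acc_mode `"impulse"` (free-decay ring-downs, the default: the
#'   ring-down frequency encodes tissue stiffness) or `"continuous"`
#'   (motor-imposed steady sinusoid, stiffness-blind; see vignette).
#' @param seed Integer root seed; every recording derives its own
#'   deterministic substream from it.
#' @return An object of class `vc_scenario`.
#' @examples
#' sc <- vc_scenario(duration_on = 3, duration_off = 2, n_subjects = 2)
#' sc
#' @export
vc_scenario <- function(n_subjects = 8,
                        stages = vc_stages(),
                        tissue = tissue_model(),
                        unit = vibration_unit(),
                        stiffness_multipliers_experimental =
                          c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6)[seq_along(stages)],
                        stiffness_multipliers_control = rep(1, length(stages)),
                        emg_amplitude_factors_experimental =
                          c(1.0, 0.98, 0.96, 0.94, 0.93, 0.92, 0.91)[seq_along(stages)],
                        emg_amplitude_factors_control =
                          c(1.0, 1.04, 1.06, 1.08, 1.08, 1.07, 1.06)[seq_along(stages)],
                        emg_base_scale = 1.0,
                        duration_on = 120, duration_off = 30,
                        fs = 1000,
                        noise_sd = 0.5,
                        drift_amplitude = 0.2,
                        drift_frequency = 0.8,
                        subject_cv = 0.10,
                        acc_mode = c("impulse", "continuous"),
                        seed = 20230803) {
  acc_mode <- match.arg(acc_mode)
  if (n_subjects < 1) stop_myovib("bad_scenario", "n_subjects must be >= 1")
  if (length(stages) < 1 || stages[1] != "T0")
    stop_myovib("bad_scenario", "stages must begin with T0")
  if (!all(stages %in% vc_stages()))
    stop_myovib("unknown_stage", "stages must be drawn from vc_stages()")
  if (anyDuplicated(stages)) stop_myovib("bad_scenario", "duplicated stage labels")
  for (nm in c("stiffness_multipliers_experimental", "stiffness_multipliers_control",
               "emg_amplitude_factors_experimental", "emg_amplitude_factors_control")) {
    v <- get(nm)
    if (length(v) != length(stages))
      stop_myovib("bad_scenario", nm, " must have one entry per stage")
  }
  if (abs(stiffness_multipliers_experimental[1] - 1) > 1e-12 ||
      abs(stiffness_multipliers_control[1] - 1) > 1e-12)
    stop_myovib("bad_scenario", "stiffness multipliers at T0 must equal 1.0")
  if (any(stiffness_multipliers_experimental < 1))
    stop_myovib("bad_scenario", "experimental stiffness multipliers must be >= 1")
  if (fs <= 2 * 160)
    stop_myovib("aliasing", "fs must exceed twice the upper analysis band edge")
  if (duration_on <= 0 || duration_off <= 0)
    stop_myovib("bad_scenario", "durations must be positive")
  if (drift_frequency >= 2)
    stop_myovib("bad_scenario", "drift_frequency must be below 2 Hz")
  if (subject_cv < 0) stop_myovib("bad_scenario", "subject_cv must be >= 0")
  fn <- natural_frequency(tissue)
  if (fn < 75 || fn > 160)
    stop_myovib("bad_scenario",
                sprintf("baseline natural frequency %.1f Hz outside the 75-160 Hz analysis band", fn))
  structure(
    list(scenario_version = 1L,
         n_subjects = as.integer(n_subjects), stages = stages,
         tissue = tissue, unit = unit,
         stiffness_multipliers_experimental = stiffness_multipliers_experimental,
         stiffness_multipliers_control = stiffness_multipliers_control,
         emg_amplitude_factors_experimental = emg_amplitude_factors_experimental,
         emg_amplitude_factors_control = emg_amplitude_factors_control,
         emg_base_scale = emg_base_scale,
         duration_on = duration_on, duration_off = duration_off,
         fs = fs, noise_sd = noise_sd,
         drift_amplitude = drift_amplitude, drift_frequency = drift_frequency,
         subject_cv = subject_cv, acc_mode = acc_mode,
         seed = as.integer(seed)),
    class = "vc_scenario")
}

#' @export
print.vc_scenario <- function(x, ...) {
  cat(sprintf("<vc_scenario v%d> %d subjects x %d stages, %s mode, seed %d\n",
              x$scenario_version, x$n_subjects, length(x$stages), x$acc_mode,
              x$seed))
  cat(sprintf("  on %g s / off %g s @ %g Hz; stiffness ramp %s\n",
              x$duration_on, x$duration_off, x$fs,
              paste(x$stiffness_multipliers_experimental, collapse = " ")))
  invisible(x)
}

#' Write / read a scenario as JSON
#'
#' The JSON layout carries a `scenario_version` field; readers reject
#' versions they do not understand.
#'
#' @param scenario A [vc_scenario()].
#' @param path File path.
#' @return `read_scenario` returns a [vc_scenario()]; `write_scenario`
#'   returns `path` invisibly.
#' @export
write_scenario <- function(scenario, path) {
  if (!inherits(scenario, "vc_scenario"))
    stop_myovib("bad_scenario", "not a vc_scenario")
  x <- unclass(scenario)
  x$tissue <- unclass(x$tissue)
  x$unit <- unclass(x$unit)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$scenario_version) || x$scenario_version != 1L)
    stop_myovib("bad_scenario", "unsupported scenario_version: ",
                x$scenario_version)
  vc_scenario(
    n_subjects = x$n_subjects, stages = x$stages,
    tissue = do.call(tissue_model, as.list(x$tissue)),
    unit = do.call(vibration_unit, as.list(x$unit)),
    stiffness_multipliers_experimental = x$stiffness_multipliers_experimental,
    stiffness_multipliers_control = x$stiffness_multipliers_control,
    emg_amplitude_factors_experimental = x$emg_amplitude_factors_experimental,
    emg_amplitude_factors_control = x$emg_amplitude_factors_control,
    emg_base_scale = x$emg_base_scale,
    duration_on = x$duration_on, duration_off = x$duration_off,
    fs = x$fs, noise_sd = x$noise_sd,
    drift_amplitude = x$drift_amplitude, drift_frequency = x$drift_frequency,
    subject_cv = x$subject_cv, acc_mode = x$acc_mode, seed = x$seed)
}
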