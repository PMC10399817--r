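#' EMG feature-extraction parameters
#'
#' @param window_ms Sliding-window length in milliseconds (default 256).
#' @param overlap_ms Window overlap in milliseconds (default 128; the step
#'   is `window_ms - overlap_ms`).
#' @param envelope_cutoff Low-pass cutoff of the software envelope in Hz.
#' @param on_normalized Compute integrated EMG on the peak-normalized
#'   envelope (the study's processing order); set `FALSE` for raw-envelope
#'   sensitivity analyses.
#' @return An object of class `emg_params`.
#' @export
emg_params <- function(window_ms = 256, overlap_ms = 128,
                       envelope_cutoff = 10, on_normalized = TRUE) {
  if (overlap_ms < 0 || overlap_ms >= window_ms)
    stop_myovib("bad_params", "need 0 <= overlap_ms < window_ms")
  if (envelope_cutoff <= 0)
    stop_myovib("bad_params", "envelope_cutoff must be > 0")
  structure(list(window_ms = window_ms, overlap_ms = overlap_ms,
                 envelope_cutoff = envelope_cutoff,
                 on_normalized = on_normalized),
            class = "emg_params")
}

#' Rectify-and-smooth EMG envelope
#'
#' Full-wave rectification followed by a zero-phase 2nd-order Butterworth
#' low-pass at `envelope_cutoff` (DC gain 1). A software stand-in for the
#' electrode's onboard rectify-and-filter stage, which is not reproducible
#' off the hardware. Filter ringing below zero is clipped at 0 so the
#' envelope stays nonnegative.
#'
#' @param recording A [vc_recording()] with channel `"EMG"`.
#' @param params An [emg_params()].
#' @return The enveloped [vc_recording()].
#' @export
emg_envelope <- function(recording, params = emg_params()) {
  assert_channel(recording, "EMG")
  fs <- recording$fs
  if (params$envelope_cutoff >= fs / 2)
    stop_myovib("bad_params", "envelope_cutoff must be below Nyquist")
  filt <- butter_lowpass(params$envelope_cutoff, fs)
  out <- recording
  out$samples <- pmax(0, zero_phase_filter(filt, abs(recording$samples),
                                           pad = min(length(recording$samples) - 1L,
                                                     as.integer(fs / 2)),
                                           pad_mode = "reflect"))
  out
}

#' Normalize enveloped EMG to the per-leg peak
#'
#' Divides every enveloped sample of one leg by the single maximum observed
#' across all that leg's stages and vibration conditions, so outputs lie in
#' `[0, 1]` and the peak sample maps to exactly 1. Normalization scope is
#' per leg across all stages: per-stage normalization would erase exactly
#' the stage effects the analysis is after.
#'
#' @param recordings A list of enveloped [vc_recording()]s belonging to one
#'   leg (any stages / vibration conditions).
#' @return A list with `recordings` (normalized) and `peak` (the divisor).
#' @export
normalize_to_peak <- function(recordings) {
  if (inherits(recordings, "vc_recording")) recordings <- list(recordings)
  if (length(recordings) == 0L)
    stop_myovib("empty_input", "no recordings to normalize")
  peak <- max(vapply(recordings, function(r) max(r$samples), numeric(1)))
  if (peak <= 0)
    stop_myovib("zero_peak", "all-zero leg: peak EMG is not positive")
  recs <- lapply(recordings, function(r) { r$samples <- r$samples / peak; r })
  list(recordings = recs, peak = peak)
}

#' Integrated EMG over sliding windows
#'
#' The integrated EMG (IEMG) of a window is the sum of absolute signal
#' values across the window — the discrete area under the rectified curve.
#' Windows are `window_ms` long and slide by `window_ms - overlap_ms`
#' (256/128 ms at 1000 Hz: 256-sample windows stepping 128 samples); the
#' window count is `floor((N - W) / step) + 1`.
#'
#' @param recording A (normalized, enveloped) [vc_recording()] with channel
#'   `"EMG"`.
#' @param params An [emg_params()].
#' @return A `data.frame` of class `iemg_series` with columns
#'   `window_index`, `t_start`, `iemg`; metadata attached as attributes.
#' @export
iemg <- function(recording, params = emg_params()) {
  assert_channel(recording, "EMG")
  fs <- recording$fs
  W <- round(params$window_ms * fs / 1000)
  step <- W - round(params$overlap_ms * fs / 1000)
  n <- length(recording$samples)
  if (n < W)
    stop_myovib("too_short",
                sprintf("recording (%d samples) shorter than one %d-sample window", n, W))
  n_win <- floor((n - W) / step) + 1L
  starts <- (seq_len(n_win) - 1L) * step + 1L
  cs <- c(0, cumsum(abs(recording$samples)))
  vals <- cs[starts + W] - cs[starts]
  out <- structure(list(window_index = seq_len(n_win) - 1L,
                        t_start = (starts - 1L) / fs,
                        iemg = vals),
                   class = c("iemg_series", "data.frame"),
                   row.names = seq_len(n_win))
  attr(out, "meta") <- recording[c("subject_id", "leg", "stage",
                                   "vibration", "fs")]
  out
}

#' Baseline-subtracted integrated-EMG deltas
#'
#' Per subject, leg and vibration condition: the median windowed IEMG at
#' each stage minus the median at baseline. Negative deltas are meaningful
#' (EMG amplitude may fall under congestion).
#'
#' @param series_list A list of `iemg_series` objects.
#' @param baseline_stage Baseline stage label (default `"T0"`).
#' @return A `data.frame` with columns `subject_id`, `leg`, `stage`,
#'   `vibration`, `feature` (`"delta_iemg"`), `value`.
#' @export
delta_iemg <- function(series_list, baseline_stage = "T0") {
  if (inherits(series_list, "iemg_series")) series_list <- list(series_list)
  meta <- lapply(series_list, attr, "meta")
  tab <- data.frame(
    subject_id = vapply(meta, `[[`, "", "subject_id"),
    leg = vapply(meta, `[[`, "", "leg"),
    stage = vapply(meta, `[[`, "", "stage"),
    vibration = vapply(meta, `[[`, "", "vibration"),
    median = vapply(series_list, function(s) stats::median(s$iemg), numeric(1)),
    stringsAsFactors = FALSE)
  delta_from_medians(tab, baseline_stage, feature = "delta_iemg")
}

#' EMG pipeline for one leg of one subject
#'
#' Envelope each recording, normalize to the leg-wide peak, then extract
#' windowed IEMG. Vibration-on and vibration-off recordings flow through
#' the identical operator chain.
#'
#' @param recordings List of raw EMG [vc_recording()]s for one subject-leg.
#' @param params An [emg_params()].
#' @return A list of `iemg_series`, one per input recording.
#' @export
process_emg_leg <- function(recordings, params = emg_params()) {
  env <- lapply(recordings, emg_envelope, params = params)
  if (params$on_normalized) env <- normalize_to_peak(env)$recordings
  lapply(env, iemg, params = params)
}
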