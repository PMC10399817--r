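#' Canonical venous-congestion stage labels
#'
#' The experiment applies a phased blockage of the common iliac vein:
#' baseline (`T0`), 50 % blockage immediately and one hour later
#' (`T50-1`, `T50-2`), 100 % blockage (`T100-1`, `T100-2`), and additional
#' occlusion of the superficial veins (`TS-1`, `TS-2`). The set is a closed
#' enumeration; readers reject any other label.
#'
#' @return Character vector of the seven stage labels in protocol order.
#' @export
vc_stages <- function() .stages

.stages <- c("T0", "T50-1", "T50-2", "T100-1", "T100-2", "TS-1", "TS-2")

.channels <- c("ACC", "EMG")
.legs <- c("experimental", "control")
.vibrations <- c("on", "off")

channel_units <- function(channel) {
  switch(channel, ACC = "m/s^2", EMG = "a.u.",
         stop_myovib("unknown_channel", "unknown channel: ", channel))
}

#' Classed error helper
#'
#' All validation failures in the package raise conditions with class
#' `myovib_error_<what>` so callers (and tests) can match them by name.
#' @noRd
stop_myovib <- function(what, ...) {
  stop(errorCondition(paste0(...),
                      class = c(paste0("myovib_error_", what), "myovib_error")))
}

#' Construct a single-channel recording
#'
#' A recording is one uniformly sampled channel (accelerometer in m/s² or
#' surface EMG in arbitrary units) together with the metadata that places it
#' in the experiment: subject, leg, congestion stage, and whether the
#' vibration unit was running.
#'
#' @param samples Numeric vector of samples.
#' @param fs Sampling rate in Hz (1000 for protocol-faithful runs).
#' @param channel `"ACC"` or `"EMG"`.
#' @param subject_id Subject identifier string.
#' @param leg `"experimental"` or `"control"`.
#' @param stage One of [vc_stages()].
#' @param vibration `"on"` or `"off"`.
#' @return An object of class `vc_recording`.
#' @examples
#' r <- vc_recording(sin(2 * pi * 110 * (0:999) / 1000), fs = 1000,
#'                   channel = "ACC")
#' r
#' @export
vc_recording <- function(samples, fs, channel = "ACC",
                         subject_id = "S1",
                         leg = "experimental",
                         stage = "T0",
                         vibration = "on") {
  if (!channel %in% .channels)
    stop_myovib("unknown_channel", "channel must be ACC or EMG")
  if (!leg %in% .legs)
    stop_myovib("bad_leg", "leg must be experimental or control")
  if (!vibration %in% .vibrations)
    stop_myovib("bad_vibration", "vibration must be on or off")
  if (!is.numeric(samples) || anyNA(samples))
    stop_myovib("bad_samples", "samples must be numeric and free of NA")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_myovib("bad_fs", "fs must be a positive scalar")
  if (is.na(match(stage, .stages)))
    stop_myovib("unknown_stage", "unknown stage label: ", stage)
  structure(
    list(samples = as.numeric(samples), fs = fs, channel = channel,
         subject_id = as.character(subject_id), leg = leg, stage = stage,
         vibration = vibration, units = channel_units(channel)),
    class = "vc_recording")
}

#' @export
print.vc_recording <- function(x, ...) {
  cat(sprintf("<vc_recording> %s %s | subject %s, %s leg, stage %s, vibration %s\n",
              x$channel, x$units, x$subject_id, x$leg, x$stage, x$vibration))
  cat(sprintf("  %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.vc_recording <- function(x) length(x$samples)

#' Duration of a recording in seconds
#' @param recording A [vc_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$samples) / recording$fs
}

assert_channel <- function(recording, channel) {
  if (!inherits(recording, "vc_recording"))
    stop_myovib("not_recording", "expected a vc_recording object")
  if (recording$channel != channel)
    stop_myovib("wrong_channel", "expected ", channel, " channel, got ",
                recording$channel)
  invisible(recording)
}

recording_key <- function(r) {
  paste(r$subject_id, r$leg, r$stage, r$vibration, r$channel, sep = "|")
}
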