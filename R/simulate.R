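# Synthetic accelerometer / EMG generation.
#
# Seeding: every stochastic draw comes from a substream seed derived from
# the root seed plus an FNV-1a hash of a label ("subject|leg|stage|..."), so
# adding a stage or subject never perturbs the other recordings, and the
# whole experiment is bit-reproducible from the scenario alone.

# 32-bit FNV-1a, in doubles (split multiply keeps products below 2^53).
fnv1a <- function(label) {
  bytes <- utf8ToInt(label)
  h <- 2166136261
  for (b in bytes) {
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 2^32
  }
  h
}

substream_seed <- function(root_seed, label) {
  as.integer((root_seed + fnv1a(label)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Closed-form surface waveforms ------------------------------------------

# Impulse-style stimulation: a myotonometer-like compress-release cycle,
# restarted once per second. The probe recompresses the tissue over `t_r`
# seconds (raised cosine, spectral content far below the analysis band),
# then releases it from rest; the tissue rings down freely at the damped
# natural frequency. Returns displacement x(t) and its analytic second
# derivative a(t).
impulse_waveform <- function(t, tissue, X0, t_r = 0.06, period = 1) {
  wn <- 2 * pi * natural_frequency(tissue)
  zeta <- damping_ratio(tissue)
  wd <- wn * sqrt(1 - zeta^2)
  s <- zeta * wn
  tau <- t %% period
  ramp <- tau < t_r
  x <- a <- numeric(length(t))
  x[ramp] <- X0 * (1 - cos(pi * tau[ramp] / t_r)) / 2
  a[ramp] <- X0 * (pi / t_r)^2 / 2 * cos(pi * tau[ramp] / t_r)
  tt <- tau[!ramp] - t_r
  env <- X0 * exp(-s * tt)
  x[!ramp] <- env * cos(wd * tt)
  a[!ramp] <- env * ((s^2 - wd^2) * cos(wd * tt) + 2 * s * wd * sin(wd * tt))
  list(x = x, a = a)
}

#' Simulate an accelerometer recording
#'
#' Generates the surface acceleration measured over vibrating soft tissue,
#' from the closed-form response of an underdamped single-degree-of-freedom
#' tissue model (no ODE solver), plus white Gaussian sensor noise and
#' additive low-frequency baseline drift.
#'
#' Two stimulation modes are provided:
#' \describe{
#'   \item{`"continuous"`}{the motor imposes a steady sinusoid at its drive
#'     frequency; the measured acceleration is
#'     `drive_amplitude * sin(2*pi*f*t)`. The ratio of peak acceleration to
#'     displacement then equals the squared drive angular frequency
#'     regardless of tissue stiffness.}
#'   \item{`"impulse"`}{compress-release cycles restarted once per second:
#'     the tissue rings down freely at its damped natural frequency, which
#'     encodes the stiffness; this is the mode under which the stiffness
#'     estimator is informative.}
#' }
#'
#' @param tissue A [tissue_model()]; must be underdamped.
#' @param unit A [vibration_unit()].
#' @param duration Recording length in seconds (> 0).
#' @param fs Sampling rate in Hz; must exceed twice the natural frequency.
#' @param noise_sd White sensor-noise standard deviation in m/s².
#' @param drift_amplitude Amplitude of the low-frequency drift in m/s².
#' @param drift_frequency Drift frequency in Hz (must be below 2 Hz).
#' @param mode Stimulation mode; see Details.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param subject_id,leg,stage,vibration Metadata for the [vc_recording()].
#' @return A [vc_recording()] with channel `"ACC"`.
#' @examples
#' tm <- tissue_model()
#' r <- simulate_acc(tm, vibration_unit(), duration = 2, fs = 1000,
#'                   noise_sd = 0, drift_amplitude = 0, seed = 1)
#' @export
simulate_acc <- function(tissue, unit, duration, fs = 1000,
                         noise_sd = 0, drift_amplitude = 0,
                         drift_frequency = 0.8,
                         mode = c("continuous", "impulse"),
                         seed = NULL,
                         subject_id = "S1", leg = "experimental",
                         stage = "T0", vibration = "on") {
  mode <- match.arg(mode)
  if (duration <= 0) stop_myovib("bad_duration", "duration must be positive")
  fn <- natural_frequency(tissue)
  zeta <- damping_ratio(tissue)
  if (zeta >= 1)
    stop_myovib("overdamped", sprintf("zeta = %.3f >= 1: overdamped tissue unsupported", zeta))
  if (fs <= 2 * fn)
    stop_myovib("aliasing",
                sprintf("fs = %g Hz does not exceed twice f_n = %.1f Hz", fs, fn))
  if (drift_frequency >= 2)
    stop_myovib("bad_drift", "drift_frequency must be below 2 Hz")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  clean <- if (unit$drive_amplitude == 0) {
    numeric(n)
  } else if (mode == "continuous") {
    unit$drive_amplitude * sin(2 * pi * unit$drive_frequency * t)
  } else {
    wn <- 2 * pi * fn
    impulse_waveform(t, tissue, X0 = unit$drive_amplitude / wn^2)$a
  }
  samples <- with_seed(seed, {
    out <- clean
    if (drift_amplitude > 0) {
      phase <- stats::runif(1, 0, 2 * pi)
      out <- out + drift_amplitude * sin(2 * pi * drift_frequency * t + phase)
    }
    if (noise_sd > 0) out <- out + stats::rnorm(n, 0, noise_sd)
    out
  })
  vc_recording(samples, fs = fs, channel = "ACC", subject_id = subject_id,
               leg = leg, stage = stage, vibration = vibration)
}

#' Simulate a relaxed-muscle EMG recording
#'
#' Surface EMG of relaxed muscle is modelled as zero-mean Gaussian noise
#' band-limited to 20–450 Hz whose per-sample standard deviation equals
#' `envelope_scale`; congestion-stage effects enter through the scale.
#'
#' @param envelope_scale Standard deviation of the signal in a.u. (>= 0).
#' @param duration Recording length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @param band Two-element frequency band in Hz.
#' @param subject_id,leg,stage,vibration Metadata for the [vc_recording()].
#' @return A [vc_recording()] with channel `"EMG"`.
#' @export
simulate_emg <- function(envelope_scale, duration, fs = 1000, seed = NULL,
                         band = c(20, 450),
                         subject_id = "S1", leg = "experimental",
                         stage = "T0", vibration = "on") {
  if (envelope_scale < 0) stop_myovib("bad_scale", "envelope_scale must be >= 0")
  if (duration <= 0) stop_myovib("bad_duration", "duration must be positive")
  n <- round(duration * fs)
  samples <- if (envelope_scale == 0) numeric(n) else
    with_seed(seed, bandlimited_noise(n, fs, band[1], band[2], envelope_scale))
  vc_recording(samples, fs = fs, channel = "EMG", subject_id = subject_id,
               leg = leg, stage = stage, vibration = vibration)
}

#' Simulate a whole congestion experiment
#'
#' Produces one recording per subject x leg x stage x vibration condition x
#' channel. Experimental-leg tissue stiffness at stage `s` is the baseline
#' stiffness times `stiffness_multipliers_experimental[s]`; per-subject
#' tissue stiffness, moving mass and EMG scale vary lognormally around the
#' scenario values (CV `subject_cv`), drawn from subject-specific substreams
#' of the root seed.
#'
#' @param scenario A [vc_scenario()].
#' @return An object of class `vc_experiment`: a list with `recordings`
#'   (named list of [vc_recording()]) and `scenario`.
#' @examples
#' sc <- vc_scenario(n_subjects = 1, stages = c("T0", "T50-1"),
#'                   duration_on = 2, duration_off = 1, seed = 7)
#' ex <- simulate_experiment(sc)
#' length(ex$recordings)  # 1 subject x 2 legs x 2 stages x 2 vib x 2 channels
#' @export
simulate_experiment <- function(scenario) {
  if (!inherits(scenario, "vc_scenario"))
    stop_myovib("bad_scenario", "expected a vc_scenario")
  sc <- scenario
  sdlog <- sqrt(log(1 + sc$subject_cv^2))
  recs <- list()
  for (si in seq_len(sc$n_subjects)) {
    subject <- sprintf("S%02d", si)
    draws <- with_seed(substream_seed(sc$seed, paste0(subject, "|tissue")), {
      stats::rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
    k_subj <- sc$tissue$stiffness_k * draws[1]
    M_subj <- sc$tissue$moving_mass_M * draws[2]
    emg_subj <- sc$emg_base_scale * draws[3]
    for (leg in .legs) {
      mult <- if (leg == "experimental") sc$stiffness_multipliers_experimental
              else sc$stiffness_multipliers_control
      emg_fac <- if (leg == "experimental") sc$emg_amplitude_factors_experimental
                 else sc$emg_amplitude_factors_control
      for (gi in seq_along(sc$stages)) {
        stage <- sc$stages[gi]
        tis <- tissue_model(stiffness_k = k_subj * mult[gi],
                            damping_c = sc$tissue$damping_c,
                            moving_mass_M = M_subj)
        for (vib in .vibrations) {
          dur <- if (vib == "on") sc$duration_on else sc$duration_off
          lab <- paste(subject, leg, stage, vib, sep = "|")
          unit_v <- sc$unit
          if (vib == "off") unit_v$drive_amplitude <- 0
          acc <- simulate_acc(tis, unit_v, dur, fs = sc$fs,
                              noise_sd = sc$noise_sd,
                              drift_amplitude = sc$drift_amplitude,
                              drift_frequency = sc$drift_frequency,
                              mode = sc$acc_mode,
                              seed = substream_seed(sc$seed, paste0(lab, "|ACC")),
                              subject_id = subject, leg = leg, stage = stage,
                              vibration = vib)
          emg <- simulate_emg(emg_subj * emg_fac[gi], dur, fs = sc$fs,
                              seed = substream_seed(sc$seed, paste0(lab, "|EMG")),
                              subject_id = subject, leg = leg, stage = stage,
                              vibration = vib)
          recs[[recording_key(acc)]] <- acc
          recs[[recording_key(emg)]] <- emg
        }
      }
    }
  }
  structure(list(recordings = recs, scenario = sc), class = "vc_experiment")
}

#' @export
print.vc_experiment <- function(x, ...) {
  cat(sprintf("<vc_experiment> %d recordings (%d subjects x %d stages)\n",
              length(x$recordings), x$scenario$n_subjects,
              length(x$scenario$stages)))
  invisible(x)
}
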