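#' Underdamped tissue model
#'
#' Soft tissue under the vibrating unit is modelled as a single-degree-of-
#' freedom mass-spring-damper: effective oscillating tissue mass `M` (kg),
#' stiffness `k` (N/m) and viscous damping `c` (N·s/m). The model must be
#' underdamped (damping ratio `zeta = c / (2 * sqrt(k * M)) < 1`) so that a
#' free oscillation at the damped natural frequency exists; overdamped
#' parameter sets are rejected.
#'
#' The defaults place the natural frequency `f_n = sqrt(k/M) / (2*pi)` at
#' 90 Hz, inside the 75–160 Hz analysis band, with light damping
#' (`zeta = 0.01`). Light damping keeps the ring-down oscillating across the
#' full 1-second analysis window; see the methods vignette for why heavier
#' damping interacts badly with the band-pass transient.
#'
#' @param stiffness_k Tissue stiffness in N/m (> 0).
#' @param damping_c Viscous damping in N·s/m (>= 0).
#' @param moving_mass_M Effective oscillating tissue mass in kg (> 0).
#' @return An object of class `tissue_model` with fields `stiffness_k`,
#'   `damping_c`, `moving_mass_M`.
#' @examples
#' tm <- tissue_model()
#' natural_frequency(tm)
#' damping_ratio(tm)
#' @export
tissue_model <- function(stiffness_k = 15988, damping_c = 0.5657,
                         moving_mass_M = 0.05) {
  if (stiffness_k <= 0) stop_myovib("bad_tissue", "stiffness_k must be > 0")
  if (damping_c < 0) stop_myovib("bad_tissue", "damping_c must be >= 0")
  if (moving_mass_M <= 0) stop_myovib("bad_tissue", "moving_mass_M must be > 0")
  tm <- structure(list(stiffness_k = stiffness_k, damping_c = damping_c,
                       moving_mass_M = moving_mass_M), class = "tissue_model")
  if (damping_ratio(tm) >= 1)
    stop_myovib("overdamped",
                sprintf("tissue is not underdamped (zeta = %.3f >= 1)",
                        damping_ratio(tm)))
  tm
}

#' Natural frequency of a tissue model
#' @param tissue A [tissue_model()].
#' @return Undamped natural frequency in Hz.
#' @export
natural_frequency <- function(tissue) {
  sqrt(tissue$stiffness_k / tissue$moving_mass_M) / (2 * pi)
}

#' Damping ratio of a tissue model
#' @param tissue A [tissue_model()].
#' @return Dimensionless damping ratio `zeta`.
#' @export
damping_ratio <- function(tissue) {
  tissue$damping_c / (2 * sqrt(tissue$stiffness_k * tissue$moving_mass_M))
}

#' @export
print.tissue_model <- function(x, ...) {
  cat(sprintf("<tissue_model> k = %.4g N/m, c = %.4g N s/m, M = %.4g kg\n",
              x$stiffness_k, x$damping_c, x$moving_mass_M))
  cat(sprintf("  f_n = %.1f Hz, zeta = %.4f\n",
              natural_frequency(x), damping_ratio(x)))
  invisible(x)
}

#' Vibrating unit attached to the skin
#'
#' The stimulus source: a small cylinder-type vibration motor strapped over
#' the tibialis anterior. Its mass enters the stiffness formula
#' `m * a_max / delta_l` directly; the default 0.030 kg matches the motor
#' used in the congestion experiment.
#'
#' @param mass_m Unit mass in kg (> 0); default 0.030.
#' @param drive_frequency Drive frequency in Hz for continuous stimulation;
#'   default 110 Hz (centre of the 75–160 Hz analysis band).
#' @param drive_amplitude Peak surface acceleration imposed by the unit, in
#'   m/s² (default 30, comparable to a phone-class vibration motor).
#' @return An object of class `vibration_unit`.
#' @export
vibration_unit <- function(mass_m = 0.030, drive_frequency = 110,
                           drive_amplitude = 30) {
  if (mass_m <= 0) stop_myovib("bad_unit", "mass_m must be > 0")
  if (drive_frequency <= 0) stop_myovib("bad_unit", "drive_frequency must be > 0")
  if (drive_amplitude < 0) stop_myovib("bad_unit", "drive_amplitude must be >= 0")
  structure(list(mass_m = mass_m, drive_frequency = drive_frequency,
                 drive_amplitude = drive_amplitude), class = "vibration_unit")
}
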