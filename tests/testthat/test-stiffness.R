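make_acc <- function(samples, fs = 1000, ...) {
  vc_recording(samples, fs = fs, channel = "ACC", ...)
}

test_that("band-pass passes the analysis band and rejects out-of-band tones", {
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  mid <- t >= 1.5 & t < 3.5   # 2000 samples: 110 Hz falls on an exact bin
  zero <- acc_bandpass(make_acc(numeric(1000)))
  expect_true(all(zero$samples == 0))
  inband <- acc_bandpass(make_acc(sin(2 * pi * 110 * t)))
  expect_length(inband$samples, length(t))
  expect_equal(fft_amplitude(inband$samples[mid]), 1, tolerance = 0.01)
  low <- acc_bandpass(make_acc(sin(2 * pi * 10 * t)))
  expect_lt(max(abs(low$samples[mid])), 0.01)
  expect_error(acc_bandpass(make_acc(t, fs = 300)),
               class = "myovib_error_bad_band")
  expect_error(acc_bandpass(const_emg(t)), class = "myovib_error_wrong_channel")
})

test_that("detrend removes exactly a straight line and is idempotent", {
  fs <- 1000
  t <- (0:999) / fs
  line <- detrend(make_acc(3 + 2 * t))
  expect_lt(max(abs(line$samples)), 1e-9)
  # a cosine over integer periods on a symmetric grid is orthogonal to a
  # line (a sine is not: its first moment over a period is -T^2/(2*pi))
  s <- cos(2 * pi * 100 * (t + 0.5 / fs))   # 100 full periods in 1 s
  ds <- detrend(make_acc(s))
  expect_equal(ds$samples, s, tolerance = 1e-6)
  twice <- detrend(detrend(make_acc(rnorm(500))))
  once <- detrend(make_acc(twice$samples))
  expect_equal(twice$samples, once$samples, tolerance = 1e-12)
  expect_error(detrend(make_acc(1)), class = "myovib_error_too_short")
})

test_that("double integration recovers the analytic displacement of a tone", {
  fs <- 1000
  t <- (0:(5 * fs - 1)) / fs
  A <- 1e-4
  w <- 2 * pi * 110
  acc <- make_acc(-A * w^2 * sin(w * t))
  disp <- double_integrate(acc)
  expect_length(disp, length(t))
  mid <- t > 1.5 & t < 3.5
  expect_equal(max(abs(disp[mid])), A, tolerance = 0.02)
  # no residual linear trend by construction
  fit <- lm.fit(cbind(1, seq_along(disp)), disp)
  expect_lt(abs(fit$coefficients[2]) * length(disp), 1e-9 * max(abs(disp)))
  expect_true(all(double_integrate(make_acc(numeric(2000))) == 0))
})

test_that("the trapezoid integrator variant is available and drift-free", {
  fs <- 1000
  t <- (0:(3 * fs - 1)) / fs
  p <- stiffness_params(integration = "trapezoid")
  disp <- double_integrate(make_acc(sin(2 * pi * 110 * t)), p)
  fit <- lm.fit(cbind(1, seq_along(disp)), disp)
  expect_lt(abs(fit$coefficients[2]) * length(disp), 1e-9)
})

test_that("window stiffness matches m * omega^2 for an in-band tone", {
  fs <- 1000
  f <- 110
  un <- vibration_unit(drive_frequency = f)
  r <- simulate_acc(tissue_model(), un, 5, fs, noise_sd = 0,
                    drift_amplitude = 0, mode = "continuous")
  s <- process_stiffness(r)
  expect_equal(nrow(s), 5L)
  expect_true(all(s$valid))
  truth <- 0.030 * (2 * pi * f)^2
  expect_equal(s$stiffness, rep(truth, 5), tolerance = 0.05)
  # Eq-2 identity is recomputable from the stored columns
  expect_equal(s$stiffness, 0.030 * s$a_max / s$delta_l, tolerance = 1e-12)
})

test_that("free-decay stiffness recovers m * k / M for light damping", {
  tm <- tissue_model()   # zeta = 0.01
  expect_lte(damping_ratio(tm), 0.05)
  r <- simulate_acc(tm, vibration_unit(), 5, 1000, noise_sd = 0.5,
                    drift_amplitude = 0.2, mode = "impulse", seed = 21)
  s <- process_stiffness(r)
  truth <- 0.030 * tm$stiffness_k / tm$moving_mass_M
  expect_equal(median(s$stiffness[s$valid]), truth, tolerance = 0.05)
})

test_that("stiffness estimates scale with true stiffness (equivariance)", {
  tm1 <- tissue_model()
  tm2 <- tissue_model(stiffness_k = 1.3 * tm1$stiffness_k,
                      damping_c = tm1$damping_c,
                      moving_mass_M = tm1$moving_mass_M)
  est <- vapply(list(tm1, tm2), function(tm) {
    r <- simulate_acc(tm, vibration_unit(), 4, 1000, noise_sd = 0,
                      drift_amplitude = 0, mode = "impulse")
    s <- process_stiffness(r)
    median(s$stiffness[s$valid])
  }, numeric(1))
  expect_equal(est[2] / est[1], 1.3, tolerance = 0.02)
})

test_that("degenerate displacement invalidates windows instead of dividing", {
  fs <- 1000
  acc <- acc_bandpass(make_acc(sin(2 * pi * 110 * (0:1999) / fs)))
  s <- window_stiffness(acc, numeric(2000))
  expect_true(all(!s$valid))
  expect_true(all(s$reason == "degenerate_displacement"))
  expect_true(all(is.na(s$stiffness)))
  expect_error(window_stiffness(acc, numeric(10)),
               class = "myovib_error_length_mismatch")
  expect_error(window_stiffness(acc_bandpass(make_acc(numeric(500))),
                                numeric(500)),
               class = "myovib_error_zero_windows")
})

test_that("the composed pipeline equals manual composition", {
  r <- simulate_acc(tissue_model(), vibration_unit(), 3, 1000,
                    noise_sd = 0.5, drift_amplitude = 0.2, mode = "impulse",
                    seed = 5)
  params <- stiffness_params()
  manual <- {
    f <- detrend(acc_bandpass(r, params))
    window_stiffness(f, double_integrate(f, params), params)
  }
  expect_identical(process_stiffness(r, params), manual)
})

test_that("baseline-delta stiffness is zero at baseline and tracks medians", {
  # two stages with known medians via constructed series
  mk <- function(stage, values, subject = "S01", leg = "experimental") {
    r <- simulate_acc(tissue_model(), vibration_unit(), 2, 1000,
                      noise_sd = 0, drift_amplitude = 0, mode = "impulse",
                      stage = stage, subject_id = subject, leg = leg)
    s <- process_stiffness(r)
    s$stiffness <- values[seq_len(nrow(s))]
    s
  }
  d <- delta_stiffness(list(mk("T0", c(100, 100)), mk("T50-1", c(130, 130))))
  expect_equal(d$value[d$stage == "T0"], 0)
  expect_equal(d$value[d$stage == "T50-1"], 30)
  expect_error(delta_stiffness(list(mk("T50-1", c(1, 1)))),
               class = "myovib_error_missing_baseline")
})

test_that("programmed stiffness ramps produce strictly increasing deltas", {
  sc <- vc_scenario(n_subjects = 2, stages = c("T0", "T50-1", "T100-1", "TS-1"),
                    stiffness_multipliers_experimental = c(1, 1.2, 1.4, 1.6),
                    duration_on = 2, duration_off = 1,
                    noise_sd = 0, drift_amplitude = 0, subject_cv = 0,
                    seed = 31)
  ex <- simulate_experiment(sc)
  acc_on <- Filter(function(r) r$channel == "ACC" && r$vibration == "on" &&
                     r$leg == "experimental", ex$recordings)
  d <- delta_stiffness(lapply(acc_on, process_stiffness))
  med <- tapply(d$value, d$stage, median)[c("T0", "T50-1", "T100-1", "TS-1")]
  expect_true(all(diff(med) > 0))
})
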