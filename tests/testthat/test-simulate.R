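test_that("continuous mode with no noise reproduces the drive sinusoid exactly", {
  fs <- 1000
  un <- vibration_unit(drive_frequency = 110, drive_amplitude = 2.5)
  r <- simulate_acc(tissue_model(), un, duration = 2, fs = fs,
                    noise_sd = 0, drift_amplitude = 0, mode = "continuous")
  t <- (seq_len(2000) - 1) / fs
  expect_equal(r$samples, 2.5 * sin(2 * pi * 110 * t), tolerance = 1e-12)
})

test_that("zero drive amplitude and zero noise give an all-zero recording", {
  un <- vibration_unit(drive_amplitude = 0)
  for (mode in c("continuous", "impulse")) {
    r <- simulate_acc(tissue_model(), un, duration = 1, fs = 1000,
                      noise_sd = 0, drift_amplitude = 0, mode = mode)
    expect_true(all(r$samples == 0))
  }
})

test_that("accelerometer simulation is deterministic in the seed", {
  tm <- tissue_model()
  un <- vibration_unit()
  a <- simulate_acc(tm, un, 1, 1000, noise_sd = 0.5, drift_amplitude = 0.2,
                    seed = 7)
  b <- simulate_acc(tm, un, 1, 1000, noise_sd = 0.5, drift_amplitude = 0.2,
                    seed = 7)
  c <- simulate_acc(tm, un, 1, 1000, noise_sd = 0.5, drift_amplitude = 0.2,
                    seed = 8)
  expect_identical(a$samples, b$samples)
  expect_false(identical(a$samples, c$samples))
})

test_that("invalid tissue, sampling rate or duration are rejected", {
  expect_error(tissue_model(stiffness_k = 100, damping_c = 100,
                            moving_mass_M = 0.05),
               class = "myovib_error_overdamped")
  tm <- tissue_model()
  expect_error(simulate_acc(tm, vibration_unit(), 1, fs = 150),
               class = "myovib_error_aliasing")
  expect_error(simulate_acc(tm, vibration_unit(), -1, fs = 1000),
               class = "myovib_error_bad_duration")
})

test_that("EMG noise scale controls the sample standard deviation", {
  r0 <- simulate_emg(0, duration = 1, fs = 1000)
  expect_true(all(r0$samples == 0))
  r1 <- simulate_emg(1, duration = 30, fs = 1000, seed = 3)
  r2 <- simulate_emg(2, duration = 30, fs = 1000, seed = 3)
  expect_equal(sd(r2$samples) / sd(r1$samples), 2, tolerance = 0.05)
  expect_equal(sd(r1$samples), 1, tolerance = 0.05)
  expect_identical(simulate_emg(1, 2, 1000, seed = 5)$samples,
                   simulate_emg(1, 2, 1000, seed = 5)$samples)
  expect_error(simulate_emg(-1, 1, 1000), class = "myovib_error_bad_scale")
})

test_that("a full experiment has one recording per design cell", {
  sc <- vc_scenario(duration_on = 0.5, duration_off = 0.3, seed = 1)
  ex <- simulate_experiment(sc)
  # 8 subjects x 2 legs x 7 stages x 2 vibration conditions x 2 channels
  expect_length(ex$recordings, 448)
  keys <- names(ex$recordings)
  expect_equal(anyDuplicated(keys), 0L)
  expect_identical(simulate_experiment(sc)$recordings[[17]]$samples,
                   ex$recordings[[17]]$samples)
})

test_that("stage multipliers raise the true natural frequency monotonically", {
  tm <- tissue_model()
  mult <- c(1.0, 1.2, 1.4, 1.6)
  fn <- vapply(mult, function(m)
    natural_frequency(tissue_model(stiffness_k = tm$stiffness_k * m,
                                   damping_c = tm$damping_c,
                                   moving_mass_M = tm$moving_mass_M)),
    numeric(1))
  expect_true(all(diff(fn) > 0))
})

test_that("scenario JSON round trip preserves every field", {
  sc <- tiny_scenario(n_subjects = 3, seed = 99)
  path <- withr::local_tempfile(fileext = ".json")
  write_scenario(sc, path)
  sc2 <- read_scenario(path)
  expect_equal(sc2, sc)
})

test_that("scenario validation enforces the protocol invariants", {
  expect_error(vc_scenario(stages = c("T50-1", "T0")),
               class = "myovib_error_bad_scenario")
  expect_error(tiny_scenario(stiffness_multipliers_experimental =
                               c(1.1, rep(1, 6))),
               class = "myovib_error_bad_scenario")
  expect_error(tiny_scenario(fs = 300), class = "myovib_error_aliasing")
  expect_error(vc_scenario(stages = c("T0", "T75")),
               class = "myovib_error_unknown_stage")
})
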