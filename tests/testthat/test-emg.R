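test_that("the software envelope rectifies and has unit DC gain", {
  zero <- emg_envelope(const_emg(numeric(1000)))
  expect_true(all(zero$samples == 0))
  # constant -c rectifies to +c; DC gain of the low-pass is 1
  cst <- emg_envelope(const_emg(rep(-2.5, 2000)))
  trim <- 500:1500
  expect_equal(cst$samples[trim], rep(2.5, length(trim)), tolerance = 0.01)
  one <- emg_envelope(const_emg(rep(1, 2000)))
  expect_equal(one$samples[trim], rep(1, length(trim)), tolerance = 1e-6)
  expect_true(all(one$samples >= 0))
  expect_error(emg_envelope(vc_recording(1:10, 1000, channel = "ACC")),
               class = "myovib_error_wrong_channel")
})

test_that("peak normalization divides by the leg-wide maximum once", {
  r1 <- const_emg(c(rep(1, 100), 5, rep(1, 99)), stage = "T0")
  r2 <- const_emg(rep(2, 200), stage = "T50-1")
  norm <- normalize_to_peak(list(r1, r2))
  expect_equal(norm$peak, 5)
  expect_equal(max(vapply(norm$recordings, function(r) max(r$samples), 0)), 1)
  expect_true(all(vapply(norm$recordings, function(r)
    all(r$samples >= 0 & r$samples <= 1), NA)))
  # single-stage leg: same as dividing by that stage's own max
  solo <- normalize_to_peak(list(r1))
  expect_equal(solo$recordings[[1]]$samples, r1$samples / max(r1$samples))
  # idempotent on already-normalized data
  again <- normalize_to_peak(norm$recordings)
  expect_equal(again$peak, 1)
  expect_equal(again$recordings[[1]]$samples, norm$recordings[[1]]$samples)
  expect_error(normalize_to_peak(list(const_emg(numeric(10)))),
               class = "myovib_error_zero_peak")
})

test_that("IEMG closed forms: zeros, ones, window count, linearity", {
  expect_true(all(iemg(const_emg(numeric(1000)))$iemg == 0))
  ones <- iemg(const_emg(rep(1, 1000)))
  expect_true(all(ones$iemg == 256))
  # 30 s at 1000 Hz: floor((30000 - 256) / 128) + 1 = 233 windows
  expect_equal(nrow(iemg(const_emg(numeric(30000)))), 233L)
  x <- abs(rnorm(3000))
  expect_equal(iemg(const_emg(3.5 * x))$iemg, 3.5 * iemg(const_emg(x))$iemg,
               tolerance = 1e-12)
  expect_error(iemg(const_emg(numeric(100))), class = "myovib_error_too_short")
})

test_that("IEMG window bookkeeping strides 128 samples from zero", {
  s <- iemg(const_emg(numeric(2000)))
  expect_equal(s$window_index, 0:(nrow(s) - 1))
  expect_equal(diff(s$t_start), rep(0.128, nrow(s) - 1))
})

test_that("baseline-delta IEMG is zero at baseline and preserves sign", {
  mk <- function(stage, const) {
    r <- const_emg(rep(const, 2000), stage = stage)
    iemg(r)
  }
  d <- delta_iemg(list(mk("T0", 10 / 256), mk("T100-1", 7 / 256)))
  expect_equal(d$value[d$stage == "T0"], 0)
  expect_equal(d$value[d$stage == "T100-1"], -3, tolerance = 1e-9)
  expect_error(delta_iemg(list(mk("T100-1", 1))),
               class = "myovib_error_missing_baseline")
})

test_that("doubling the envelope scale doubles raw median IEMG", {
  p <- emg_params(on_normalized = FALSE)
  r1 <- simulate_emg(1, 5, 1000, seed = 4)
  r2 <- simulate_emg(2, 5, 1000, seed = 4)
  m1 <- median(process_emg_leg(list(r1), p)[[1]]$iemg)
  m2 <- median(process_emg_leg(list(r2), p)[[1]]$iemg)
  expect_equal(m2 / m1, 2, tolerance = 1e-9)
})

test_that("vibration-on and -off recordings flow through the same chain", {
  on <- simulate_emg(1, 2, 1000, seed = 6, vibration = "on")
  off <- simulate_emg(1, 0.5, 1000, seed = 6, vibration = "off")
  out <- process_emg_leg(list(on, off))
  expect_length(out, 2)
  expect_equal(attr(out[[1]], "meta")$vibration, "on")
  expect_equal(attr(out[[2]], "meta")$vibration, "off")
})
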