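# Internal DSP helpers: signal extension, zero-phase Butterworth filtering,
# spectral integration/differentiation, band-limited noise synthesis.
#
# Both the zero-phase filter and the spectral integrator need the signal
# extended beyond its ends: a finite record carries no information about the
# signal outside it, and whatever the extension implies leaks back in as an
# edge transient. For narrow-band signals an autoregressive (maximum-entropy)
# extension is close to ideal -- it continues the dominant oscillations with
# the right frequency and phase -- so edge transients stay at numerical-noise
# level. Degenerate inputs (constant, too short) fall back to odd reflection.

# Burg's method, lean and vectorized (coefficients in the x[t] = sum
# a_i x[t-i] + e convention, matching stats::ar.burg), with Andersen's
# recursive update of the error-energy denominator.
burg_coef <- function(x, order) {
  x <- x - mean(x)
  n <- length(x)
  ff <- x[-1L]
  bb <- x[-n]
  den <- sum(ff * ff) + sum(bb * bb)
  den0 <- den
  a <- numeric(0)
  for (k in seq_len(order)) {
    # once the prediction error hits numerical noise the fit is done;
    # further reflection coefficients are rounding garbage
    if (!is.finite(den) || den <= 1e-14 * den0) break
    rc <- 2 * sum(ff * bb) / den
    if (!is.finite(rc) || abs(rc) >= 1) break
    a <- if (k == 1L) rc else c(a - rc * rev(a), rc)
    if (k == order) break
    fn <- ff - rc * bb
    bn <- bb - rc * ff
    m <- length(fn)
    den <- (1 - rc * rc) * den - fn[1L] * fn[1L] - bn[m] * bn[m]
    ff <- fn[-1L]
    bb <- bn[-m]
  }
  a
}

ar_extend <- function(x, pad, order = 12L, fit_len = 1024L,
                      mode = c("ar", "reflect")) {
  mode <- match.arg(mode)
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(x)
  # grow the right pad so the padded length is FFT-friendly (2^a 3^b 5^c)
  target <- stats::nextn(n + 2L * pad)
  pad_r <- min(pad + (target - (n + 2L * pad)), n - 1L)
  reflect_ext <- function(seg, p) {
    m <- length(seg)
    pp <- min(p, m - 1L)
    out <- 2 * seg[m] - seg[(m - 1L):(m - pp)]
    if (pp < p) out <- c(out, rep(out[pp], p - pp))
    out
  }
  extrapolate <- function(seg, p) {
    m <- length(seg)
    if (mode == "reflect") return(reflect_ext(seg, p))
    scale <- max(abs(seg))
    if (m <= 2L * order || scale == 0 || stats::sd(seg) < 1e-12 * scale)
      return(rep(seg[m], p))
    mu <- mean(seg)
    co <- burg_coef(seg, order)
    if (length(co) == 0L || anyNA(co) || sum(abs(co)) > 1e3)
      return(reflect_ext(seg, p))
    out <- stats::filter(rep(0, p), co, method = "recursive",
                         init = rev(utils::tail(seg, length(co)) - mu))
    as.numeric(out) + mu
  }
  fl <- min(n, fit_len)
  right <- extrapolate(x[(n - fl + 1L):n], pad_r)
  left <- rev(extrapolate(rev(x[1L:fl]), pad))
  c(left, x, right)
}

# Zero-phase (forward-backward) IIR filtering with AR-extension padding:
# net phase is zero and the magnitude response is the square of the one-pass
# design. Realized by multiplying the spectrum of the extended signal by
# |H(e^jw)|^2 evaluated from the filter coefficients, which is the
# forward-backward response exactly (the padding absorbs wrap-around).
# Output length equals input length.
zero_phase_filter <- function(filt, x, pad = 1000L, pad_mode = "ar") {
  n <- length(x)
  if (n < 2L) return(x)
  pad <- min(pad, n - 1L)
  xp <- ar_extend(x, pad, mode = pad_mode)
  m <- length(xp)
  H2 <- zp_response(filt, m)
  y <- Re(stats::fft(stats::fft(xp) * H2, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

# |H(e^jw)|^2 of an IIR filter at the m DFT bin frequencies, cached.
zp_response <- function(filt, m) {
  key <- paste0("zpf_", m, "_",
                paste(signif(c(filt$b, filt$a), 12), collapse = ","))
  hit <- .myovib_cache[[key]]
  if (!is.null(hit)) return(hit)
  z <- exp(-2i * pi * seq.int(0L, m - 1L) / m)
  H <- polyval_vec(filt$b, z) / polyval_vec(filt$a, z)
  H2 <- Mod(H)^2
  .myovib_cache[[key]] <- H2
  H2
}

polyval_vec <- function(coefs, z) {
  acc <- rep_len(0 + 0i, length(z))
  for (c0 in coefs) acc <- acc * z + c0
  acc
}

butter_bandpass <- function(low, high, fs, order = 4L) {
  key <- sprintf("bpd_%g_%g_%g_%d", low, high, fs, order)
  hit <- .myovib_cache[[key]]
  if (is.null(hit)) {
    hit <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
    .myovib_cache[[key]] <- hit
  }
  hit
}

butter_lowpass <- function(cutoff, fs, order = 2L) {
  key <- sprintf("lpd_%g_%g_%d", cutoff, fs, order)
  hit <- .myovib_cache[[key]]
  if (is.null(hit)) {
    hit <- signal::butter(order, cutoff / (fs / 2), type = "low")
    .myovib_cache[[key]] <- hit
  }
  hit
}

# Apply a frequency-response multiplier H(f) via FFT on an AR-extended copy
# of the signal; Hfun receives signed frequencies in Hz.
spectral_apply <- function(x, Hfun, fs, pad = 1000L) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- ar_extend(x, pad)
  m <- length(xp)
  fr <- c(0:floor(m / 2), seq.int(-(ceiling(m / 2) - 1L), -1L))[1:m] * fs / m
  y <- Re(stats::fft(stats::fft(xp) * Hfun(fr), inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

# Spectral double integration: divide by (j*omega)^2 = -omega^2, suppressing
# content below fmin (integration amplifies low frequencies without bound;
# the analysis band starts well above fmin, so in-band gain is exact).
spectral_double_integrate <- function(x, fs, fmin, pad = 1000L) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- ar_extend(x, pad)
  m <- length(xp)
  key <- sprintf("int2_%d_%g_%g", m, fs, fmin)
  H <- .myovib_cache[[key]]
  if (is.null(H)) {
    fr <- c(0:floor(m / 2), seq.int(-(ceiling(m / 2) - 1L), -1L))[1:m] * fs / m
    H <- numeric(m)
    keep <- abs(fr) >= fmin
    H[keep] <- -1 / (2 * pi * fr[keep])^2
    .myovib_cache[[key]] <- H
  }
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

# Cumulative trapezoid (kept as the literal time-domain integrator variant).
cumtrapz_uniform <- function(y, h) {
  n <- length(y)
  c(0, cumsum((y[-1L] + y[-n]) / 2) * h)
}

# Least-squares removal of an intercept + slope.
detrend_linear_vec <- function(y) {
  n <- length(y)
  tt <- seq_len(n) - (n + 1) / 2
  y - mean(y) - tt * (sum(tt * y) / sum(tt * tt))
}

# Zero-mean Gaussian noise band-limited to [low, high] Hz with standard
# deviation exactly calibrated (by Parseval) so that the population sd of
# each sample equals `sd_target`. Synthesis: mask the DFT of white noise.
bandlimited_noise <- function(n, fs, low, high, sd_target) {
  if (sd_target == 0) return(numeric(n))
  z <- stats::rnorm(n)
  fr <- abs(c(0:floor(n / 2), seq.int(-(ceiling(n / 2) - 1L), -1L))[1:n]) * fs / n
  mask <- fr >= low & fr <= high
  kept <- sum(mask)
  if (kept == 0L) stop_myovib("empty_band", "no DFT bins inside the band")
  y <- Re(stats::fft(stats::fft(z) * mask, inverse = TRUE)) / n
  y * sd_target / sqrt(kept / n)
}
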