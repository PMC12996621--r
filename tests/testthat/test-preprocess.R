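test_that("band-pass design matches the Butterworth magnitude response", {
  for (band in c("eng", "imemg", "eng_only", "hybrid")) {
    spec <- filter_spec(band)
    sos <- butter_bandpass_sos(spec$order, spec$low, spec$high, 30000)
    h_edges <- Mod(sos_response(sos, c(spec$low, spec$high), 30000))
    expect_equal(h_edges, c(1, 1) / sqrt(2), tolerance = 1e-6)
    h_mid <- Mod(sos_response(sos, sqrt(spec$low * spec$high), 30000))
    expect_equal(h_mid, 1, tolerance = 1e-6)
  }
  # independent cross-check against r-signal at a benign specification
  ba <- signal::butter(4, c(0.1, 0.3), type = "pass")
  fgrid <- seq(0.01, 0.95, by = 0.02)      # in units of Nyquist
  z <- exp(-1i * pi * fgrid)
  # b,a are in ascending delay order -> evaluate sum b_k z^-k directly
  h_ref <- Mod(vapply(seq_along(z), function(i) {
    sum(ba$b * z[i]^(seq_along(ba$b) - 1)) /
      sum(ba$a * z[i]^(seq_along(ba$a) - 1))
  }, complex(1)))
  sos <- butter_bandpass_sos(4, 0.1, 0.3, fs = 2)  # Nyquist = 1
  h_sos <- Mod(sos_response(sos, fgrid, fs = 2))
  expect_equal(h_sos, h_ref, tolerance = 1e-8)
})

test_that("zero-phase band-pass passes the band and rejects outside it", {
  fs <- 30000
  t <- (0:(fs - 1)) / fs
  spec <- filter_spec("eng")
  mid <- 5001:25000
  # 3 kHz sine passes essentially unchanged (squared response ~ 1)
  y <- bandpass_filter(sin(2 * pi * 3000 * t), fs, spec)
  expect_equal(sd(y[mid]) / sd(sin(2 * pi * 3000 * t)[mid]), 1,
               tolerance = 0.01)
  # 60 Hz attenuated by >= 40 dB
  y60 <- bandpass_filter(sin(2 * pi * 60 * t), fs, spec)
  expect_lt(sd(y60[mid]) / sd(sin(2 * pi * 60 * t)[mid]), 0.01)
  # constant offset rejected (beyond the start-up transient)
  ydc <- bandpass_filter(rep(3, fs), fs, spec)
  expect_lt(max(abs(ydc[mid])), 3e-6)
  expect_lt(abs(mean(ydc[mid])), 3e-6)
  # cutoffs at or above Nyquist are an error
  expect_error(bandpass_filter(t, 10000, spec), "Nyquist")
})

test_that("filtering is linear and shape-preserving", {
  fs <- 30000
  set.seed(5)
  x <- rnorm(3000); y <- rnorm(3000)
  spec <- filter_spec("eng")
  lhs <- bandpass_filter(2 * x - 3 * y, fs, spec)
  rhs <- 2 * bandpass_filter(x, fs, spec) - 3 * bandpass_filter(y, fs, spec)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  m <- matrix(rnorm(4 * 3000), 4, 3000)
  out <- bandpass_filter(m, fs, spec)
  expect_equal(dim(out), dim(m))
  # matrix path agrees with the vector path
  expect_equal(out[2, ], bandpass_filter(m[2, ], fs, spec),
               tolerance = 1e-8)
})

test_that("band energy of filtered white noise is confined to the band", {
  fs <- 30000
  set.seed(7)
  x <- rnorm(fs)
  y <- bandpass_filter(x, fs, filter_spec("eng"))
  p <- Mod(fft(y))^2
  freq <- (seq_along(p) - 1) * fs / length(p)
  half <- freq <= fs / 2
  stop_lo <- half & freq < 100
  stop_hi <- half & freq > 12000
  pass <- half & freq > 500 & freq < 6000
  expect_lt(sum(p[stop_lo | stop_hi]), 0.001 * sum(p[pass]))
})

test_that("powerline notch cascade removes harmonics, spares the rest", {
  fs <- 30000
  spec <- filter_spec("eng")
  # zero in, zero out
  expect_equal(notch_powerline(rep(0, 1000), fs, spec), rep(0, 1000))
  # steady-state 50 Hz attenuation >= 20 dB (interior of a long signal;
  # the Q=100 biquad rings in over ~0.6 s)
  t <- (0:(6 * fs - 1)) / fs
  y <- notch_powerline(sin(2 * pi * 50 * t), fs, spec)
  mid <- (2 * fs):(4 * fs)
  expect_lt(sd(y[mid]) / sd(sin(2 * pi * 50 * t)[mid]), 0.1)
  # a non-harmonic frequency passes at the level the cascade response
  # predicts (the 1000 Hz notch skirt reaches 1013 Hz; zero-phase
  # application squares the magnitude response)
  ns <- notch_sos(fs, spec)
  predicted <- Mod(sos_response(ns, 1013, fs))^2
  y2 <- notch_powerline(sin(2 * pi * 1013 * t), fs, spec)
  expect_equal(sd(y2[mid]) / sd(sin(2 * pi * 1013 * t)[mid]), predicted,
               tolerance = 0.02)
  expect_gt(predicted, 0.8)  # skirt loss, not a notch
  # no applicable harmonic: warning + identity
  x <- rnorm(100)
  expect_warning(out <- notch_powerline(x, 90, spec), "harmonic")
  expect_identical(out, x)
})

test_that("band cutoffs can be overridden in the spec", {
  sp <- filter_spec("eng", low = 300, high = 6000)
  expect_equal(c(sp$low, sp$high), c(300, 6000))
  sos <- butter_bandpass_sos(sp$order, sp$low, sp$high, 30000)
  expect_equal(Mod(sos_response(sos, c(300, 6000), 30000)),
               c(1, 1) / sqrt(2), tolerance = 1e-6)
})

test_that("notch harmonics stop at the configured maximum and Nyquist", {
  spec <- filter_spec("eng")
  expect_equal(nrow(notch_sos(30000, spec)), 200)   # 50..10000 Hz
  expect_equal(nrow(notch_sos(2000, spec)), 19)     # 50..950 Hz
})
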