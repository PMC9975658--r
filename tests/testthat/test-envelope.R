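test_that("hilbert envelope recovers amplitude and modulation", {
  fs <- 2000
  t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  tone <- audio_recording(0.7 * sin(2 * pi * 100 * t), fs)
  env <- hilbert_envelope(tone)
  core <- env$values[(fs / 4):(length(t) - fs / 4)]
  expect_equal(median(core), 0.7, tolerance = 1e-3)
  expect_true(all(env$values >= 0))

  zero <- hilbert_envelope(audio_recording(numeric(500), fs))
  expect_true(all(zero$values == 0))

  # AM tone: envelope tracks 1 + 0.5 cos(2 pi 4 t)
  am <- audio_recording((1 + 0.5 * cos(2 * pi * 4 * t)) *
                          sin(2 * pi * 500 * t), fs)
  env_am <- hilbert_envelope(am)
  idx <- (fs / 4):(length(t) - fs / 4)
  expect_equal(env_am$values[idx], (1 + 0.5 * cos(2 * pi * 4 * t))[idx],
               tolerance = 0.01)
})

test_that("cochlear envelope responds to slow amplitude modulation", {
  fs <- 8000
  silence <- cochlear_envelope(audio_recording(numeric(4000), fs),
                               n_channels = 8, band = c(180, 3500))
  expect_true(all(silence$values == 0))

  t <- seq(0, 1 - 1 / fs, by = 1 / fs)
  tone <- cochlear_envelope(audio_recording(0.5 * sin(2 * pi * 1000 * t),
                                            fs),
                            n_channels = 8, band = c(180, 3500))
  core <- tone$values[2000:6000]
  expect_true(all(core > 0))
  expect_lt(sd(core) / mean(core), 0.1)

  # 4 Hz AM noise: envelope spectrum peaks at 4 Hz
  a <- am_noise_audio(mod_hz = 4, fs = fs, dur = 4, seed = 2)
  env <- cochlear_envelope(a, n_channels = 8, band = c(180, 3500))
  env100 <- resample_envelope(env, 100)
  v <- env100$values - mean(env100$values)
  spec <- Mod(fft(v))[2:40]
  f_axis <- (1:39) / (length(v) / 100)
  expect_equal(f_axis[which.max(spec)], 4, tolerance = 0.3)

  expect_error(cochlear_envelope(a, band = c(180, 7246)),
               class = "speechsync_invalid_parameter") # above 4 kHz Nyquist
})

test_that("envelope resampling preserves content and refuses upsampling", {
  const <- envelope_series(rep(2.5, 1000), 1000, kind = "synthetic")
  down <- resample_envelope(const, 100)
  expect_equal(down$values, rep(2.5, 100), tolerance = 1e-9)
  expect_equal(duration(down), duration(const), tolerance = 1 / 100)

  fs <- 8000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  osc <- envelope_series(1 + 0.5 * sin(2 * pi * 4 * t), fs,
                         kind = "synthetic")
  osc100 <- resample_envelope(osc, 100)
  v <- osc100$values - mean(osc100$values)
  spec <- Mod(fft(v))[2:40]
  expect_equal(which.max(spec), 4 * 4 + 1 - 1) # 4 Hz * 4 s duration
  expect_error(resample_envelope(osc100, 200),
               class = "speechsync_invalid_parameter")
})

test_that("bandpass phase extraction is zero phase and accurate", {
  fs <- 100
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  env <- envelope_series(1 + 0.8 * sin(2 * pi * 4.5 * t), fs,
                         kind = "synthetic")
  ph <- bandpass_phase(env)
  d <- diff(ph$phase)
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  # unwrapped phase advances at 2 pi * 4.5 rad/s
  expect_equal(mean(d) * fs, 2 * pi * 4.5, tolerance = 0.01)

  # identical inputs give identical phase series
  ph2 <- bandpass_phase(env)
  expect_identical(ph$phase, ph2$phase)

  # a delayed copy shows the expected constant phase lag
  delay <- 0.05
  env_d <- envelope_series(1 + 0.8 * sin(2 * pi * 4.5 * (t - delay)), fs,
                           kind = "synthetic")
  ph_d <- bandpass_phase(env_d)
  lag <- Arg(mean(exp(1i * (ph$phase - ph_d$phase))))
  expect_equal(lag, 2 * pi * 4.5 * delay, tolerance = 0.02)

  expect_error(bandpass_phase(env, band = c(3.5, 60)),
               class = "speechsync_invalid_parameter")
})

test_that("zero-phase filtering commutes with time reversal", {
  set.seed(4)
  x <- rnorm(2048)
  fwd <- speechsync:::zero_phase_bandpass(x, 100, 3.5, 5.5)
  rev_filt <- rev(speechsync:::zero_phase_bandpass(rev(x), 100, 3.5, 5.5))
  expect_equal(fwd, rev_filt, tolerance = 1e-9)
})

test_that("the envelope-to-phase pipeline preserves the generating phase", {
  fs <- 100
  t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  gen_phase <- 2 * pi * 4.5 * t
  env <- envelope_series(1 + 0.8 * cos(gen_phase), fs, kind = "synthetic")
  ph <- bandpass_phase(env) # trims 1 s edges
  gen_trim <- gen_phase[(fs + 1):(length(t) - fs)]
  expect_gt(plv(ph$phase, gen_trim), 0.99)
})

test_that("WAV files round-trip through read and write", {
  fs <- 8000
  x <- 0.4 * sin(2 * pi * 440 * seq(0, 0.2, by = 1 / fs))
  path16 <- tempfile(fileext = ".wav")
  write_wav(audio_recording(x, fs), path16, bits = 16)
  back16 <- read_wav(path16)
  expect_equal(back16$sample_rate, fs)
  expect_equal(back16$samples, x, tolerance = 1e-4)
  path32 <- tempfile(fileext = ".wav")
  write_wav(audio_recording(x, fs), path32, bits = 32)
  back32 <- read_wav(path32)
  expect_equal(back32$samples, x, tolerance = 1e-7)
  expect_warning(audio_recording(cbind(x, x), fs), "mono")
  unlink(c(path16, path32))
})
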