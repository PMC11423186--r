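sine_rec <- function(freq, fs = 25000, dur = 1, layout = grid_layout(2, 1)) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq * t)
  mea_recording(rbind(x, x), fs, layout = layout)
}

rms <- function(x) sqrt(mean(x^2))

test_that("all-zero input stays all-zero through the band-pass", {
  rec <- mea_recording(matrix(0, 2, 5000), 25000, layout = grid_layout(2, 1))
  out <- bandpass_filter(rec)
  expect_true(all(out$data == 0))
})

test_that("in-band and out-of-band tones follow the analytic response", {
  spec <- filter_spec()
  fs <- 25000
  # single (causal) pass against the closed-form Chebyshev-I magnitude
  rec1k <- sine_rec(1000, fs, dur = 2)
  out <- bandpass_filter(rec1k, spec, causal = TRUE)
  # discard the transient before measuring steady-state gain
  meas <- rms(out$data[1, 20001:50000]) / rms(rec1k$data[1, 20001:50000])
  oracle <- chebyshev_bandpass_gain(spec, 1000, fs)
  expect_equal(meas, oracle, tolerance = 0.02)
  # 1 kHz sits in the passband: gain within the design ripple of unity
  expect_gte(oracle, 10^(-spec$ripple_db / 20) - 1e-9)

  # 10 Hz tone: attenuated by at least 20 dB (analytically far more)
  rec10 <- sine_rec(10, fs, dur = 2)
  out10 <- bandpass_filter(rec10, spec, causal = TRUE)
  att_db <- -20 * log10(rms(out10$data[1, 20001:50000]) / rms(rec10$data[1, 20001:50000]))
  expect_gt(att_db, 20)
  expect_gt(-20 * log10(chebyshev_bandpass_gain(spec, 10, fs)), 20)
})

test_that("band-edge gain equals the designed ripple within 0.1 dB", {
  spec <- filter_spec(ripple_db = 1)
  fs <- 25000
  flt <- optobeat:::cheby_coeffs(spec, fs)
  # evaluate the transfer function of the designed coefficients directly
  eval_h <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    num <- sum(flt$b * z^(seq_along(flt$b) - 1))
    den <- sum(flt$a * z^(seq_along(flt$a) - 1))
    abs(num / den)
  }
  meas_db <- 20 * log10(vapply(c(150, 2500), eval_h, numeric(1)))
  oracle_db <- 20 * log10(chebyshev_bandpass_gain(spec, c(150, 2500), fs))
  expect_equal(meas_db, oracle_db, tolerance = 0.1)
  expect_equal(oracle_db, c(-1, -1), tolerance = 1e-6)
})

test_that("DC is rejected below -40 dB", {
  spec <- filter_spec()
  expect_lt(20 * log10(chebyshev_bandpass_gain(spec, 1e-3, 25000)), -40)
  rec <- mea_recording(matrix(100, 2, 25000), 25000, layout = grid_layout(2, 1))
  out <- bandpass_filter(rec)
  expect_lt(rms(out$data[1, 5000:20000]) / 100, 0.01)
})

test_that("filter is linear and shape-preserving (LTI property)", {
  set.seed(5)
  fs <- 25000
  lay <- grid_layout(2, 1)
  x <- rnorm(10000)
  y <- rnorm(10000)
  fx <- bandpass_trace(x, fs)
  fy <- bandpass_trace(y, fs)
  fxy <- bandpass_trace(x + y, fs)
  expect_equal(fxy, fx + fy, tolerance = 1e-9)
  expect_equal(bandpass_trace(3 * x, fs), 3 * fx, tolerance = 1e-9)
})

test_that("filter validates against Nyquist and adapts for low rates", {
  rec <- mea_recording(matrix(0, 2, 1000), 1000, layout = grid_layout(2, 1))
  expect_error(bandpass_filter(rec), "Nyquist")
  spec <- adapt_filter_spec(filter_spec(), 1000)
  expect_equal(spec$high_hz, 450)
  expect_no_error(bandpass_filter(rec, spec))
  expect_error(adapt_filter_spec(filter_spec(), 300), "too low")
})

test_that("channel metrics recover constructed SNR and flag silent channels", {
  lay <- grid_layout(4, 1)
  beats <- generate_beat_times(5, 6)
  wf <- wavefront_params("planar", speed_mm_s = 50)
  # spikes of 100 uV on 5 uV noise -> snr ~ 20
  rec <- synthesize_recording(beats, wf, spike_template(100, 2), lay,
    noise_rms_uV = 5, dead_channels = 4, duration_s = 6, seed = 2
  )
  qc <- channel_metrics(rec)
  live <- qc[qc$channel_id != 4, ]
  expect_true(all(abs(live$snr - 20) / 20 < 0.1))
  expect_true(all(live$included))
  # noise-only channel: snr ~ 0, excluded at threshold 2
  dead_row <- qc[qc$channel_id == 4, ]
  expect_lt(dead_row$snr, 2)
  expect_false(dead_row$included)
})

test_that("zero-variance channels get snr 0 without division errors", {
  lay <- grid_layout(2, 1)
  rec <- mea_recording(matrix(0, 2, 1000), 25000, layout = lay)
  qc <- channel_metrics(rec)
  expect_equal(qc$snr, c(0, 0))
  expect_equal(qc$rms_noise_uV, c(0, 0))
  expect_false(any(qc$included))
})

test_that("SNR is invariant to voltage rescaling (property)", {
  lay <- grid_layout(4, 1)
  beats <- generate_beat_times(5, 6)
  rec <- synthesize_recording(
    beats, wavefront_params("planar"), spike_template(300, 2), lay,
    noise_rms_uV = 7, duration_s = 6, seed = 4
  )
  qc1 <- channel_metrics(rec)
  for (k in c(0.25, 5)) {
    rec_k <- rec
    rec_k$data <- rec_k$data * k
    qc_k <- channel_metrics(rec_k)
    expect_equal(qc_k$snr, qc1$snr, tolerance = 0.01)
  }
})

test_that("QC excludes dead channels and propagates the layout subset", {
  fx <- make_fixture("dead_channels", seed = 1)
  filtered <- bandpass_filter(fx$recording)
  qc <- channel_metrics(filtered)
  expect_equal(sum(qc$included), 29)
  clean <- apply_qc(filtered, qc)
  expect_equal(nrow(clean$data), 29)
  expect_equal(nrow(clean$layout), 29)
  expect_false(any(fx$truth$dead_channels %in% clean$channel_ids))
  # default fixtures sit inside the healthy operating envelope
  live <- qc[qc$included, ]
  expect_true(all(live$rms_noise_uV < 10))
  expect_true(all(live$snr > 15))

  # healthy recording: identity
  fx2 <- make_fixture("nt_baseline", seed = 1)
  f2 <- bandpass_filter(fx2$recording)
  qc2 <- channel_metrics(f2)
  expect_equal(nrow(apply_qc(f2, qc2)$data), 32)

  # absurd threshold: empty-result error advising review
  qc3 <- channel_metrics(f2, snr_threshold = 1e6)
  expect_error(apply_qc(f2, qc3), "threshold")
})
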