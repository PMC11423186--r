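test_that("spike templates are peak-normalized and biphasic at morphology 0", {
  for (m in c(-1, -0.5, 0, 0.5, 1)) {
    w <- sample_template(spike_template(300, 2, m), 25000)
    expect_equal(max(abs(w)), 300, tolerance = 0.01)
  }
  w0 <- sample_template(spike_template(300, 2, 0), 25000)
  # biphasic charge balance: integrates to ~0 relative to its own mass
  expect_lt(abs(sum(w0)) / sum(abs(w0)), 1e-3)
  # monophasic extremes keep the sign of the morphology parameter
  expect_gt(min(sample_template(spike_template(100, 2, 1), 25000)), -1e-9)
  expect_lt(max(sample_template(spike_template(100, 2, -1), 25000)), 1e-9)
})

test_that("planar wavefront delays follow geometry exactly", {
  lay <- grid_layout(4, 1, pitch_um = 200)
  wf <- wavefront_params("planar", speed_mm_s = 50, direction_deg = 0)
  d <- wavefront_delays(wf, lay)
  # 0.2 mm / 50 mm/s = 4 ms between columns
  expect_equal(unname(d), c(0, 4, 8, 12) / 1000, tolerance = 1e-12)
  # radial delays are distance/speed
  wfr <- wavefront_params("radial", speed_mm_s = 20, origin_um = c(0, 0))
  dr <- wavefront_delays(wfr, lay)
  expect_equal(unname(dr), c(0, 0.2, 0.4, 0.6) / 20, tolerance = 1e-12)
})

test_that("zero beats and zero noise give an all-zero recording", {
  lay <- tiny_layout()
  rec <- synthesize_recording(
    numeric(0), wavefront_params("planar"), spike_template(), lay,
    noise_rms_uV = 0, duration_s = 0.5
  )
  expect_true(all(rec$data == 0))
})

test_that("dead channels carry noise only and spike counts are conserved", {
  lay <- default_mea_layout()
  beats <- generate_beat_times(5.7, 6)
  wf <- wavefront_params("planar", speed_mm_s = 50, direction_deg = 30)
  dead <- c(5, 16, 28)
  # vanishing noise floor keeps the MAD-based threshold defined while the
  # spikes are effectively noiseless
  rec <- synthesize_recording(beats, wf, spike_template(300, 2), lay,
    noise_rms_uV = 0.01, dead_channels = dead, duration_s = 6.1, seed = 3
  )
  for (ch in seq_len(nrow(rec$data))) {
    pk <- detect_peaks(rec$data[ch, ], rec$sample_rate_hz)
    if (rec$channel_ids[ch] %in% dead) {
      expect_equal(nrow(pk), 0)
      expect_lt(max(abs(rec$data[ch, ])), 1)
    } else {
      # synthesis followed by peak detection returns exactly the generated
      # beat count (spike-count conservation)
      expect_equal(nrow(pk), length(beats))
    }
  }
})

test_that("realized noise RMS matches the requested level within 5%", {
  lay <- grid_layout(2, 1)
  rec <- synthesize_recording(
    numeric(0), wavefront_params("planar"), spike_template(), lay,
    noise_rms_uV = 7, duration_s = 6, sample_rate_hz = 25000, seed = 9
  )
  expect_equal(sd(rec$data[1, ]), 7, tolerance = 0.05)
  expect_length(rec$data[1, ], 150000)
})

test_that("template width exceeding the beat interval warns of overlap", {
  lay <- tiny_layout()
  beats <- generate_beat_times(10, 1) # 100 ms interval
  expect_warning(
    synthesize_recording(beats, wavefront_params("planar"),
      spike_template(300, width_ms = 150), lay,
      noise_rms_uV = 0, duration_s = 1.2
    ),
    "overlap"
  )
})

test_that("make_fixture presets reproduce their designs", {
  fx <- make_fixture("nt_baseline", seed = 1)
  expect_equal(nrow(fx$recording$data), 32)
  expect_equal(fx$truth$rate_bps, 5.7)
  expect_equal(ncol(fx$recording$data) / fx$recording$sample_rate_hz, 6)

  fd <- make_fixture("dead_channels", seed = 1)
  expect_length(fd$truth$dead_channels, 3)

  fs <- make_fixture("bpac_stepwise", seed = 1, waveform = FALSE)
  expect_equal(fs$protocol$irradiance_uW_mm2, c(0, 0.3, 27))
  expect_equal(
    fs$protocol$t_end_s - fs$protocol$t_start_s,
    c(5, 30, 15) * 60
  )

  fc <- make_fixture("bpac_cycles", seed = 1)
  expect_null(fc$recording)
  lit <- fc$protocol$irradiance_uW_mm2 > 0
  expect_equal(sum(lit), 2)
  expect_equal(unique(fc$protocol$t_end_s[lit] - fc$protocol$t_start_s[lit]), 25 * 60)

  expect_error(make_fixture("nope"), "available")
})

test_that("fixtures write recording, protocol and ground truth sidecar", {
  dir <- withr::local_tempdir()
  fx <- make_fixture("dead_channels", seed = 2)
  write_fixture(fx, dir)
  expect_true(file.exists(file.path(dir, "recording.csv")))
  expect_true(file.exists(file.path(dir, "protocol.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_equal(sort(truth$dead_channels), sort(fx$truth$dead_channels))
})
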