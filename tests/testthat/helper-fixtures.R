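# shared builders for small synthetic inputs used across the suite

tiny_layout <- function(n = 4) grid_layout(2, n / 2, pitch_um = 200)

# a short planar-wave recording with known ground truth
planar_recording <- function(speed = 50, direction = 30, rate = 5.7,
                             duration = 1.8, noise = 0, layout = grid_layout(4, 8),
                             fs = 25000, jitter_ms = 0, seed = 0,
                             amplitude = 300, morphology = 0) {
  beats <- generate_beat_times(rate, duration)
  wf <- wavefront_params("planar",
    speed_mm_s = speed,
    direction_deg = direction, jitter_ms = jitter_ms
  )
  synthesize_recording(
    beats, wf, spike_template(amplitude, 2, morphology), layout,
    noise_rms_uV = noise, sample_rate_hz = fs,
    duration_s = duration + 0.1, seed = seed
  )
}

# synthetic fold series following a first-order rise after an edge
exp_fold_series <- function(tau_min, edge_s = 300, total_s = 3000,
                            seg_s = 10, amp = 0.14, noise_sd = 0,
                            seed = 1) {
  t <- seq(0, total_s - seg_s, by = seg_s)
  y <- ifelse(t < edge_s, 1, 1 + amp * (1 - exp(-(t - edge_s) / (tau_min * 60))))
  if (noise_sd > 0) {
    y <- withr::with_seed(seed, y + rnorm(length(y), sd = noise_sd))
  }
  s <- tibble::tibble(segment_start_s = t, bps = 5 * y, fold = y)
  class(s) <- c("beat_series", class(s))
  attr(s, "bps0") <- 5
  s
}
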