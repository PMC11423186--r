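#' Synthetic experiment presets
#'
#' `make_fixture()` builds ready-made synthetic experiments mirroring the
#' study designs the package analyses:
#'
#' * `nt_baseline` - 6 s of 32-channel baseline beating at 5.7 beats s⁻¹
#'   (non-transduced rate), planar wavefront at 50 mm s⁻¹.
#' * `dead_channels` - as `nt_baseline` at the bPAC basal rate, with 3
#'   designated channels carrying noise only.
#' * `bpac_light_step` - 5 min dark then continuous 27 µW mm⁻² light
#'   (20 min by default), driving the photoresponse cascade.
#' * `bpac_cycles` - two 25-min light / 30-min dark cycles after a 5-min
#'   dark lead-in.
#' * `bpac_stepwise` - stepwise 0 / 0.3 / 27 µW mm⁻² for 5 / 30 / 15 min.
#' * `multiday` - four daily sessions (5 min dark + 25 min light) with
#'   drifting baseline rates.
#'
#' Short presets synthesize full 25 kSa/s waveforms. For the multi-minute
#' presets the waveform is synthesized at 1 kSa/s (with a correspondingly
#' wider spike template so spikes stay resolvable), or skipped entirely
#' with `waveform = FALSE`, which returns beat times and the rate series
#' only; multi-hour 25 kSa/s 32-channel matrices would be needlessly large.
#'
#' @param name Preset id (see above).
#' @param seed Integer seed controlling jitter and noise.
#' @param waveform Synthesize the voltage matrix? Default `TRUE` for the
#'   short presets, `FALSE` for `bpac_cycles` and `multiday`.
#' @param sample_rate_hz Override the preset's sampling rate.
#' @param light_min Light-epoch duration override (minutes), where the
#'   preset has a single light step.
#' @param n_dead Number of noise-only channels for `dead_channels`.
#' @return A list of class `mea_fixture`: `name`, `recording` (or `NULL`),
#'   `protocol`, `params` ([photo_response_params()] or `NULL`),
#'   `rate_series`, `beat_times` (array-level, s), `truth` (list of
#'   generating values: rates, speed, dead ids, expected plateau fold).
#' @examples
#' fx <- make_fixture("nt_baseline", seed = 1)
#' fx$truth$rate_bps # 5.7
#' @export
make_fixture <- function(name, seed = 0, waveform = NULL,
                         sample_rate_hz = NULL, light_min = NULL,
                         n_dead = 3) {
  presets <- c(
    "nt_baseline", "bpac_light_step", "bpac_cycles", "bpac_stepwise",
    "dead_channels", "multiday"
  )
  if (!name %in% presets) {
    abort(paste0(
      "unknown preset '", name, "'; available: ",
      paste(presets, collapse = ", ")
    ))
  }
  layout <- default_mea_layout()
  wf <- wavefront_params("planar",
    speed_mm_s = 50, direction_deg = 30,
    jitter_ms = 1
  )
  switch(name,
    nt_baseline = fixture_baseline(
      layout, wf,
      rate = 5.7, seed = seed,
      sample_rate_hz = sample_rate_hz %||% 25000,
      dead = integer(), name = name
    ),
    dead_channels = fixture_baseline(
      layout, wf,
      rate = 4.3, seed = seed,
      sample_rate_hz = sample_rate_hz %||% 25000,
      dead = layout$electrode_id[round(seq(5, nrow(layout) - 4,
        length.out = n_dead
      ))],
      name = name
    ),
    bpac_light_step = fixture_photoresponse(
      layout, wf,
      protocol = stim_protocol(
        c(0, 300), c(300, 300 + (light_min %||% 20) * 60), c(0, 27)
      ),
      seed = seed, waveform = waveform %||% TRUE,
      sample_rate_hz = sample_rate_hz %||% 1000, name = name
    ),
    bpac_stepwise = fixture_photoresponse(
      layout, wf,
      protocol = stim_protocol(
        c(0, 300, 2100), c(300, 2100, 3000), c(0, 0.3, 27)
      ),
      seed = seed, waveform = waveform %||% TRUE,
      sample_rate_hz = sample_rate_hz %||% 1000, name = name
    ),
    bpac_cycles = fixture_photoresponse(
      layout, wf,
      protocol = stim_protocol(
        c(0, 300, 1800, 3600, 5100),
        c(300, 1800, 3600, 5100, 6900),
        c(0, 27, 0, 27, 0)
      ),
      seed = seed, waveform = waveform %||% FALSE,
      sample_rate_hz = sample_rate_hz %||% 1000, name = name
    ),
    multiday = fixture_multiday(layout, wf, seed = seed)
  )
}

fixture_baseline <- function(layout, wf, rate, seed, sample_rate_hz, dead,
                             name, duration_s = 6) {
  beats <- generate_beat_times(rate, duration_s,
    jitter_ms = 0, seed = derive_seed(seed, "beats")
  )
  template <- spike_template(300, width_ms = 2)
  rec <- synthesize_recording(
    beats, wf, template, layout,
    noise_rms_uV = 7, dead_channels = dead,
    sample_rate_hz = sample_rate_hz, duration_s = duration_s,
    seed = derive_seed(seed, "noise")
  )
  structure(
    list(
      name = name, recording = rec, protocol = stim_protocol(),
      params = NULL,
      rate_series = tibble::tibble(
        time_s = c(0, duration_s), rate_bps = rep(rate, 2)
      ),
      beat_times = beats,
      truth = list(
        rate_bps = rate, speed_mm_s = wf$speed_mm_s,
        direction_deg = wf$direction_deg, dead_channels = dead,
        noise_rms_uV = 7, amplitude_uV = 300
      )
    ),
    class = "mea_fixture"
  )
}

fixture_photoresponse <- function(layout, wf, protocol, seed, waveform,
                                  sample_rate_hz, name,
                                  params = photo_response_params()) {
  duration_s <- max(protocol$t_end_s)
  sim <- simulate_photoresponse(params, protocol, duration_s, dt_s = 1)
  beats <- generate_beat_times(sim, duration_s,
    jitter_ms = 1,
    seed = derive_seed(seed, "beats")
  )
  rec <- NULL
  if (waveform) {
    template <- spike_template(300,
      width_ms = max(2, 12000 / sample_rate_hz)
    )
    rec <- synthesize_recording(
      beats, wf, template, layout,
      noise_rms_uV = 7, sample_rate_hz = sample_rate_hz,
      duration_s = duration_s, seed = derive_seed(seed, "noise")
    )
  }
  plateau_fold <- steady_state_fold(params, max(protocol$irradiance_uW_mm2))
  structure(
    list(
      name = name, recording = rec, protocol = protocol, params = params,
      rate_series = sim, beat_times = beats,
      truth = list(
        rate_bps = params$R0, speed_mm_s = wf$speed_mm_s,
        direction_deg = wf$direction_deg, dead_channels = integer(),
        steady_state_fold = plateau_fold,
        noise_rms_uV = 7, amplitude_uV = 300
      )
    ),
    class = "mea_fixture"
  )
}

fixture_multiday <- function(layout, wf, seed) {
  baselines <- c(4.1, 4.0, 5.2, 5.1)
  days <- purrr::map(seq_along(baselines), function(d) {
    params <- photo_response_params(R0 = baselines[d])
    protocol <- stim_protocol(c(0, 300), c(300, 1800), c(0, 27))
    sim <- simulate_photoresponse(params, protocol, 1800, dt_s = 1)
    beats <- generate_beat_times(sim, 1800,
      jitter_ms = 1,
      seed = derive_seed(seed + d, "beats")
    )
    list(
      day = d, params = params, protocol = protocol, rate_series = sim,
      beat_times = beats
    )
  })
  structure(
    list(
      name = "multiday", recording = NULL,
      protocol = days[[1]]$protocol, params = days[[1]]$params,
      rate_series = days[[1]]$rate_series, beat_times = days[[1]]$beat_times,
      days = days,
      truth = list(
        baseline_bps = baselines,
        steady_state_fold = steady_state_fold(days[[1]]$params, 27),
        dead_channels = integer()
      )
    ),
    class = "mea_fixture"
  )
}

#' @export
print.mea_fixture <- function(x, ...) {
  cat(sprintf(
    "<mea_fixture> preset '%s': %s, %d epochs, %d beats\n",
    x$name,
    if (is.null(x$recording)) {
      "rate-level"
    } else {
      sprintf(
        "%d ch x %d samples", nrow(x$recording$data), ncol(x$recording$data)
      )
    },
    nrow(x$protocol), length(x$beat_times)
  ))
  invisible(x)
}

#' Write a fixture (recording, protocol, ground truth) to a directory
#'
#' @param fixture A [make_fixture()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(fixture$recording)) {
    write_recording(fixture$recording, file.path(dir, "recording.csv"))
  }
  write_protocol(fixture$protocol, file.path(dir, "protocol.csv"))
  jsonlite::write_json(
    c(fixture$truth, list(beat_times_s = fixture$beat_times)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
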