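#' Extracellular spike templates
#'
#' Spike waveforms are a peak-normalized blend of a Gaussian lobe and a
#' biphasic component built from two unequal-width Gaussians of opposite
#' sign whose areas cancel. `morphology` interpolates between negative
#' monophasic (-1), biphasic (0) and positive monophasic (+1) shapes,
#' mirroring the morphology drift seen in multi-day cultures. At
#' `morphology = 0` the template integrates to ~0 (biphasic charge
#' balance) with a dominant leading lobe, as in extracellular cardiac
#' field potentials, so the largest |deflection| is unambiguous. The
#' template's reference sample sits on that dominant extremum.
#'
#' @param amplitude_uV Peak absolute amplitude, µV.
#' @param width_ms Characteristic width (≈ full support) in ms; the Gaussian
#'   sigma is `width_ms / 6`.
#' @param morphology Value in `[-1, 1]` blending the two lobes.
#' @return A list of class `spike_template`.
#' @examples
#' tpl <- spike_template(300, 2, 0)
#' v <- sample_template(tpl, 25000)
#' max(abs(v)) # ~300
#' @export
spike_template <- function(amplitude_uV = 300, width_ms = 2, morphology = 0) {
  if (amplitude_uV <= 0) abort("amplitude_uV must be positive")
  if (width_ms <= 0) abort("width_ms must be positive")
  if (abs(morphology) > 1) abort("morphology must lie in [-1, 1]")
  structure(
    list(
      amplitude_uV = amplitude_uV, width_ms = width_ms,
      morphology = morphology
    ),
    class = "spike_template"
  )
}

#' @rdname spike_template
#' @param template A [spike_template()].
#' @param sample_rate_hz Sampling rate in Hz.
#' @return `sample_template()`: numeric vector of the waveform (µV), centred
#'   on its reference sample `attr(, "center")`.
#' @export
sample_template <- function(template, sample_rate_hz) {
  sigma_s <- template$width_ms / 10 / 1000
  half <- max(2L, ceiling(6.5 * sigma_s * sample_rate_hz))
  t <- (-half:half) / sample_rate_hz
  g <- exp(-t^2 / (2 * (1.5 * sigma_s)^2))
  # zero-net-area biphasic: narrow leading lobe, broad shallow return lobe
  s1 <- 0.8 * sigma_s
  s2 <- 1.2 * sigma_s
  d <- 0.75 * sigma_s
  b <- exp(-(t + d)^2 / (2 * s1^2)) - (s1 / s2) * exp(-(t - d)^2 / (2 * s2^2))
  m <- template$morphology
  w <- m * g + (1 - abs(m)) * b
  w <- w / max(abs(w)) * template$amplitude_uV
  attr(w, "center") <- which.max(abs(w))
  w
}

#' Wavefront geometries
#'
#' Describes how activation sweeps the array. A planar wavefront travelling
#' at `speed_mm_s` along `direction_deg` delays electrode `p` by
#' `(p . u) / speed`; a radial wavefront from `origin_um` delays it by
#' `|p - origin| / speed`. Per-beat Gaussian timing jitter (`jitter_ms`)
#' models beat-to-beat variability of the activation sequence.
#'
#' @param mode `"planar"` or `"radial"`.
#' @param speed_mm_s Propagation speed, mm s⁻¹ (> 0).
#' @param direction_deg Direction of travel (degrees, planar mode;
#'   0 = +x, 90 = +y).
#' @param origin_um Length-2 vector, radial source position in µm.
#' @param jitter_ms Per-beat timing jitter SD, ms.
#' @return A list of class `wavefront_params`.
#' @export
wavefront_params <- function(mode = c("planar", "radial"), speed_mm_s = 50,
                             direction_deg = 0, origin_um = c(0, 0),
                             jitter_ms = 0) {
  mode <- match.arg(mode)
  if (speed_mm_s <= 0) abort("speed_mm_s must be positive")
  if (jitter_ms < 0) abort("jitter_ms must be >= 0")
  structure(
    list(
      mode = mode, speed_mm_s = speed_mm_s, direction_deg = direction_deg,
      origin_um = origin_um, jitter_ms = jitter_ms
    ),
    class = "wavefront_params"
  )
}

#' Per-electrode activation delays of a wavefront
#'
#' @param wavefront A [wavefront_params()].
#' @param layout An [electrode_layout()].
#' @return Named numeric vector of delays in seconds (not offset-corrected),
#'   one per electrode.
#' @export
wavefront_delays <- function(wavefront, layout) {
  p_mm <- cbind(layout$x_um, layout$y_um) / 1000
  if (wavefront$mode == "planar") {
    th <- wavefront$direction_deg * pi / 180
    proj <- p_mm %*% c(cos(th), sin(th))
    d <- as.numeric(proj) / wavefront$speed_mm_s
  } else {
    d <- sqrt(rowSums(sweep(p_mm, 2, wavefront$origin_um / 1000)^2)) /
      wavefront$speed_mm_s
  }
  setNames(d - min(d), layout$electrode_id)
}

#' Generate beat times from a rate series
#'
#' An integrate-and-fire clock: a beat is emitted each time the integral of
#' the instantaneous rate advances by one, so the realized count tracks
#' `integral(R dt)` exactly (up to edge effects), preserving the kinetics of
#' the driving rate. Optional Gaussian jitter is added per beat.
#'
#' @param rate Either a constant rate in beats s⁻¹, or a tibble with
#'   `time_s` and `rate_bps` columns (e.g. from [simulate_photoresponse()]).
#' @param duration_s Length of the generated train, s.
#' @param jitter_ms Per-beat Gaussian jitter SD, ms.
#' @param seed Integer seed for the jitter; ignored when `jitter_ms = 0`.
#' @return Sorted numeric vector of beat times, s.
#' @examples
#' generate_beat_times(5, 6) # 30 beats, 0.2 s apart
#' @export
generate_beat_times <- function(rate, duration_s, jitter_ms = 0, seed = 0) {
  if (is.numeric(rate) && length(rate) == 1) {
    rate <- tibble::tibble(
      time_s = c(0, duration_s),
      rate_bps = rep(rate, 2)
    )
  }
  if (any(rate$rate_bps <= 0)) abort("rate must be positive throughout")
  t <- rate$time_s
  r <- rate$rate_bps
  if (max(t) < duration_s) {
    t <- c(t, duration_s)
    r <- c(r, tail(r, 1))
  }
  keep <- t <= duration_s
  if (sum(keep) < length(t)) {
    # clip at duration with interpolated endpoint
    r_end <- approx(t, r, xout = duration_s)$y
    t <- c(t[keep], duration_s)
    r <- c(r[keep], r_end)
  }
  # cumulative phase by trapezoid; piecewise-linear R makes this exact
  phase <- c(0, cumsum(diff(t) * (head(r, -1) + r[-1]) / 2))
  n <- floor(tail(phase, 1) + 1e-9)
  if (n < 1) {
    return(numeric(0))
  }
  beats <- approx(phase, t, xout = seq_len(n), ties = "ordered")$y
  if (jitter_ms > 0) {
    withr::with_seed(seed, {
      beats <- beats + rnorm(n, sd = jitter_ms / 1000)
    })
    beats <- sort(pmin(pmax(beats, 0), duration_s))
  }
  beats
}

#' Synthesize a multichannel recording from beat times
#'
#' Each live channel receives a copy of the spike template at every beat,
#' shifted by that electrode's wavefront delay (plus per-beat jitter shared
#' across the array), riding on white Gaussian noise. Dead channels carry
#' noise only.
#'
#' @param beats Sorted beat times, s.
#' @param wavefront A [wavefront_params()].
#' @param template A [spike_template()].
#' @param layout An [electrode_layout()].
#' @param noise_rms_uV Noise standard deviation, µV (default 7).
#' @param dead_channels Electrode ids rendered noise-only.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param duration_s Recording length, s; default covers the last beat plus
#'   margin.
#' @param seed Integer seed for noise and beat jitter.
#' @return An [mea_recording()].
#' @export
synthesize_recording <- function(beats, wavefront, template, layout,
                                 noise_rms_uV = 7, dead_channels = integer(),
                                 sample_rate_hz = 25000, duration_s = NULL,
                                 seed = 0) {
  if (is.unsorted(beats)) abort("beats must be sorted")
  if (!all(dead_channels %in% layout$electrode_id)) {
    abort("dead_channels must be a subset of layout electrode ids")
  }
  duration_s <- duration_s %||%
    (if (length(beats)) max(beats) + 0.1 else 1)
  n_samp <- ceiling(duration_s * sample_rate_hz)
  delays <- wavefront_delays(wavefront, layout)
  w <- sample_template(template, sample_rate_hz)
  ctr <- attr(w, "center")
  if (length(beats) > 1) {
    ibi <- median(diff(beats))
    if (template$width_ms / 1000 >= ibi) {
      warn("template width exceeds the median inter-beat interval; spikes overlap")
    }
  }
  withr::with_seed(seed, {
    jit <- if (wavefront$jitter_ms > 0 && length(beats)) {
      rnorm(length(beats), sd = wavefront$jitter_ms / 1000)
    } else {
      rep(0, length(beats))
    }
    data <- matrix(0, nrow = nrow(layout), ncol = n_samp)
    for (ch in seq_len(nrow(layout))) {
      id <- layout$electrode_id[ch]
      trace <- rnorm(n_samp, sd = noise_rms_uV)
      if (!(id %in% dead_channels)) {
        centers <- round((beats + jit + delays[[as.character(id)]]) *
          sample_rate_hz) + 1L
        for (c0 in centers) {
          lo <- c0 - ctr + 1L
          hi <- c0 + (length(w) - ctr)
          wlo <- max(1L, 1L - lo + 1L)
          whi <- length(w) - max(0L, hi - n_samp)
          lo <- max(1L, lo)
          hi <- min(n_samp, hi)
          if (lo <= hi) trace[lo:hi] <- trace[lo:hi] + w[wlo:whi]
        }
      }
      data[ch, ] <- trace
    }
  })
  mea_recording(data, sample_rate_hz,
    layout = layout,
    channel_ids = layout$electrode_id, t0_s = 0
  )
}
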