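#' Detect extracellular spikes on a single trace
#'
#' Spikes are local extrema of `|v|` exceeding `threshold_k` times the
#' robust noise scale (MAD x 1.4826), separated by at least `refractory_ms`.
#' When two candidate extrema fall within the refractory window the larger
#' deflection wins. The amplitude reported is the signed extremum.
#'
#' @param x Numeric trace (µV), ideally band-pass filtered.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param threshold_k Threshold in noise-scale units (default 5).
#' @param refractory_ms Minimum spike separation, ms (default 80).
#' @param t0_s Time of the first sample, s.
#' @return Tibble with `time_s` and `amplitude_uV`, one row per spike,
#'   sorted by time. Empty tibble when nothing crosses threshold.
#' @export
detect_peaks <- function(x, sample_rate_hz, threshold_k = 5,
                         refractory_ms = 80, t0_s = 0) {
  noise <- mad(x)
  empty <- tibble::tibble(time_s = numeric(), amplitude_uV = numeric())
  if (noise == 0) {
    return(empty)
  }
  thr <- threshold_k * noise
  a <- abs(x)
  above <- a > thr
  if (!any(above)) {
    return(empty)
  }
  # contiguous supra-threshold runs -> one candidate per run (max |v|)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  cand <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(a[seg])]
  }, integer(1))
  # enforce refractory period, keeping the larger deflection
  refr <- refractory_ms / 1000 * sample_rate_hz
  cand <- cand[order(cand)]
  keep <- logical(length(cand))
  last <- -Inf
  last_idx <- 0L
  for (j in seq_along(cand)) {
    if (cand[j] - last >= refr) {
      keep[j] <- TRUE
      last <- cand[j]
      last_idx <- j
    } else if (a[cand[j]] > a[cand[last_idx]]) {
      keep[last_idx] <- FALSE
      keep[j] <- TRUE
      last <- cand[j]
      last_idx <- j
    }
  }
  cand <- cand[keep]
  tibble::tibble(
    time_s = t0_s + (cand - 1) / sample_rate_hz,
    amplitude_uV = x[cand]
  )
}

#' Detect spikes on every channel of a recording
#'
#' @param rec A filtered [mea_recording()].
#' @inheritParams detect_peaks
#' @return Tibble with `channel_id`, `time_s`, `amplitude_uV`.
#' @export
detect_spikes <- function(rec, threshold_k = 5, refractory_ms = 80) {
  purrr::map_dfr(seq_len(nrow(rec$data)), function(ch) {
    pk <- detect_peaks(rec$data[ch, ], rec$sample_rate_hz,
      threshold_k = threshold_k, refractory_ms = refractory_ms,
      t0_s = rec$t0_s
    )
    dplyr::mutate(pk, channel_id = rec$channel_ids[ch], .before = 1)
  })
}

#' Beating rate from spike times
#'
#' The rate within a window is the reciprocal of the median inter-beat
#' interval (>= 3 spikes), the reciprocal of the single interval (2
#' spikes), or 0 (< 2 spikes). The median-interval estimator is robust to a
#' missed beat and, unlike a count per window, is not quantized to
#' 1/window.
#'
#' @param spike_times_s Numeric spike times, s.
#' @param t_start_s,t_end_s Optional window bounds; default all spikes.
#' @return Beating rate in beats s⁻¹.
#' @examples
#' beating_rate(seq(0, 6, by = 0.17544)) # ~5.7
#' @export
beating_rate <- function(spike_times_s, t_start_s = -Inf, t_end_s = Inf) {
  s <- sort(spike_times_s[spike_times_s >= t_start_s & spike_times_s < t_end_s])
  if (length(s) < 2) {
    return(0)
  }
  1 / median(diff(s))
}

#' Segment-wise beating rates across channels
#'
#' Cuts spike trains into fixed-length segments (6 s by default, the
#' conventional analysis window) and computes the per-channel
#' median-interval rate in each segment, plus the array-level rate (median
#' across channels with a nonzero rate).
#'
#' @param spikes Tibble from [detect_spikes()] (`channel_id`, `time_s`).
#' @param segment_len_s Segment length, s (default 6).
#' @param duration_s Total span to segment; default last spike time.
#' @return Tibble with `segment_start_s`, `channel_id`, `bps`; array-level
#'   rows have `channel_id = NA`.
#' @export
segment_rates <- function(spikes, segment_len_s = 6, duration_s = NULL) {
  duration_s <- duration_s %||% max(spikes$time_s)
  n_seg <- max(1L, floor(duration_s / segment_len_s + 1e-9))
  starts <- (seq_len(n_seg) - 1) * segment_len_s
  seg <- floor(spikes$time_s / segment_len_s)
  obs <- spikes[seg < n_seg, ] |>
    dplyr::mutate(segment_start_s = seg[seg < n_seg] * segment_len_s) |>
    dplyr::group_by(.data$channel_id, .data$segment_start_s) |>
    dplyr::summarise(bps = beating_rate(.data$time_s), .groups = "drop")
  per_ch <- tidyr::expand_grid(
    segment_start_s = starts,
    channel_id = sort(unique(spikes$channel_id))
  ) |>
    dplyr::left_join(obs, by = c("segment_start_s", "channel_id")) |>
    dplyr::mutate(bps = dplyr::coalesce(.data$bps, 0))
  arr <- per_ch |>
    dplyr::group_by(.data$segment_start_s) |>
    dplyr::summarise(
      channel_id = NA_integer_,
      bps = {
        live <- .data$bps[.data$bps > 0]
        if (length(live)) median(live) else 0
      },
      .groups = "drop"
    )
  dplyr::bind_rows(per_ch, arr) |>
    dplyr::arrange(.data$segment_start_s, .data$channel_id)
}

#' Fold-change series relative to the first segment
#'
#' Normalizes an array-level rate series by the rate of its first segment
#' (BPS0), the standard normalization that removes culture-to-culture
#' baseline variability. `fold` is exactly 1 in the first segment.
#'
#' @param rates Either the output of [segment_rates()] (array-level rows
#'   are used) or a tibble with `segment_start_s` and `bps`.
#' @return A tibble of class `beat_series` with `segment_start_s`, `bps`,
#'   `fold`; `attr(, "bps0")` holds the baseline.
#' @export
fold_series <- function(rates) {
  arr <- if ("channel_id" %in% names(rates)) {
    dplyr::filter(rates, is.na(.data$channel_id))
  } else {
    rates
  }
  arr <- dplyr::arrange(arr, .data$segment_start_s)
  bps0 <- arr$bps[1]
  if (!is.finite(bps0) || bps0 <= 0) {
    abort("first-segment rate (BPS0) must be positive to form fold changes")
  }
  out <- tibble::tibble(
    segment_start_s = arr$segment_start_s,
    bps = arr$bps,
    fold = arr$bps / bps0
  )
  attr(out, "bps0") <- bps0
  class(out) <- c("beat_series", class(out))
  out
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "<beat_series> %d segments, BPS0 = %.3g\n", nrow(x), attr(x, "bps0")
  ))
  NextMethod()
}

#' Plot a fold-change series
#'
#' @param object A [fold_series()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beat_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    .data$segment_start_s / 60, .data$fold
  )) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (min)", y = expression(BPS / BPS[0])) +
    ggplot2::theme_minimal()
}
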