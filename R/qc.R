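#' Per-channel signal metrics and channel QC
#'
#' Computes, for each channel of a filtered recording: a robust noise scale
#' (`rms_noise_uV`, median absolute deviation x 1.4826, so spikes do not
#' inflate it), the spike amplitude (`peak_amplitude_uV`, median absolute
#' extremum over detected spikes), their ratio (`snr`), and an inclusion
#' flag. Channels with no detected spikes, or with zero variance, get
#' `snr = 0` and are excluded. The conventional inclusion rule keeps
#' channels with `snr >= 2`.
#'
#' @param rec A filtered [mea_recording()].
#' @param snr_threshold Minimum SNR for inclusion (default 2).
#' @param threshold_k Detection threshold in units of the noise scale
#'   (passed to [detect_peaks()]).
#' @param refractory_ms Minimum spike separation, ms.
#' @param min_spikes Minimum number of detected spikes for the amplitude
#'   (and hence SNR) to be considered measurable (default 3, the same floor
#'   the rate estimator needs); channels below it get `snr = 0`, so an
#'   isolated noise excursion cannot qualify a silent channel.
#' @return A tibble of class `qc_report` with one row per channel:
#'   `channel_id`, `rms_noise_uV`, `peak_amplitude_uV`, `n_spikes`, `snr`,
#'   `included`; the counts summary is in `attr(, "summary")`.
#' @examples
#' fx <- make_fixture("dead_channels", seed = 1)
#' qc <- channel_metrics(bandpass_filter(fx$recording))
#' sum(qc$included) # 29
#' @export
channel_metrics <- function(rec, snr_threshold = 2, threshold_k = 5,
                            refractory_ms = 80, min_spikes = 3) {
  if (!inherits(rec, "mea_recording")) abort("rec must be an mea_recording")
  rows <- purrr::map(seq_len(nrow(rec$data)), function(ch) {
    x <- rec$data[ch, ]
    noise <- mad(x)
    if (noise == 0) {
      return(tibble::tibble(
        channel_id = rec$channel_ids[ch], rms_noise_uV = 0,
        peak_amplitude_uV = 0, n_spikes = 0L, snr = 0
      ))
    }
    pk <- detect_peaks(x, rec$sample_rate_hz,
      threshold_k = threshold_k,
      refractory_ms = refractory_ms
    )
    amp <- if (nrow(pk) > 0) median(abs(pk$amplitude_uV)) else 0
    tibble::tibble(
      channel_id = rec$channel_ids[ch], rms_noise_uV = noise,
      peak_amplitude_uV = amp, n_spikes = nrow(pk),
      snr = if (nrow(pk) >= min_spikes) amp / noise else 0
    )
  })
  rep <- dplyr::bind_rows(rows)
  rep$included <- rep$snr >= snr_threshold
  attr(rep, "summary") <- list(
    n_channels = nrow(rep), n_included = sum(rep$included),
    n_excluded = sum(!rep$included), snr_threshold = snr_threshold
  )
  class(rep) <- c("qc_report", class(rep))
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<qc_report> %d/%d channels included (snr >= %g)\n",
    s$n_included, s$n_channels, s$snr_threshold
  ))
  NextMethod()
}

#' Restrict a recording to QC-included channels
#'
#' @param rec An [mea_recording()].
#' @param report A [channel_metrics()] report for the same channels.
#' @return The recording restricted to included channels, layout subset
#'   accordingly.
#' @export
apply_qc <- function(rec, report) {
  if (!setequal(report$channel_id, rec$channel_ids)) {
    abort("QC report channels do not match the recording")
  }
  keep <- report$channel_id[report$included]
  if (length(keep) == 0) {
    abort(paste0(
      "all channels excluded by QC; review the SNR threshold (",
      attr(report, "summary")$snr_threshold, ")"
    ))
  }
  recording_subset(rec, keep)
}

#' Write a QC report to CSV
#'
#' @param report A [channel_metrics()] report.
#' @param path Output CSV path.
#' @export
write_qc_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
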