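#' Multichannel extracellular recordings
#'
#' A `mea_recording` bundles a channels x samples voltage matrix (µV) with its
#' sample rate, start time and electrode layout. Channel ids map rows of the
#' matrix onto electrodes of the layout. Voltages are assumed gain-corrected
#' (amplifier gain already divided out).
#'
#' @param data Numeric matrix, channels x samples, in µV.
#' @param sample_rate_hz Sampling rate in Hz (default 25000).
#' @param layout An [electrode_layout()]. Defaults to [default_mea_layout()]
#'   when it has as many electrodes as `data` has rows.
#' @param channel_ids Integer electrode ids, one per row of `data`; must be a
#'   subset of `layout$electrode_id`.
#' @param t0_s Recording start time in seconds (default 0).
#' @return An object of class `mea_recording`.
#' @examples
#' rec <- mea_recording(matrix(rnorm(4 * 100), 4), 1000,
#'   layout = grid_layout(2, 2)
#' )
#' rec
#' @export
mea_recording <- function(data, sample_rate_hz = 25000, layout = NULL,
                          channel_ids = NULL, t0_s = 0) {
  if (!is.matrix(data) || !is.numeric(data)) abort("data must be a numeric matrix")
  if (nrow(data) == 0 || ncol(data) == 0) abort("recording must have at least one channel and one sample")
  if (!is.numeric(sample_rate_hz) || sample_rate_hz <= 0) abort("sample_rate_hz must be positive")
  if (is.null(layout)) layout <- default_mea_layout()
  if (is.null(channel_ids)) {
    if (nrow(data) != nrow(layout)) {
      abort(sprintf(
        "data has %d channels but layout has %d electrodes; supply channel_ids",
        nrow(data), nrow(layout)
      ))
    }
    channel_ids <- layout$electrode_id
  }
  channel_ids <- as.integer(channel_ids)
  if (length(channel_ids) != nrow(data)) {
    abort("channel_ids must have one entry per data row")
  }
  if (!all(channel_ids %in% layout$electrode_id)) {
    abort("channel_ids must be a subset of layout electrode ids")
  }
  structure(
    list(
      data = data, sample_rate_hz = as.numeric(sample_rate_hz),
      t0_s = as.numeric(t0_s), layout = layout, channel_ids = channel_ids
    ),
    class = "mea_recording"
  )
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "<mea_recording> %d channels x %d samples @ %g kSa/s (%.3g s)\n",
    nrow(x$data), ncol(x$data), x$sample_rate_hz / 1000,
    ncol(x$data) / x$sample_rate_hz
  ))
  invisible(x)
}

#' @export
dim.mea_recording <- function(x) dim(x$data)

#' Sample times of a recording
#'
#' @param rec An [mea_recording()].
#' @return Numeric vector of sample times in seconds (recording clock).
#' @export
recording_times <- function(rec) {
  rec$t0_s + (seq_len(ncol(rec$data)) - 1) / rec$sample_rate_hz
}

#' Restrict a recording to a subset of channels
#'
#' @param rec An [mea_recording()].
#' @param ids Electrode ids to keep.
#' @return The restricted recording; the layout is subset accordingly.
#' @export
recording_subset <- function(rec, ids) {
  keep <- rec$channel_ids %in% ids
  if (!any(keep)) abort("no channels left after subsetting")
  mea_recording(
    rec$data[keep, , drop = FALSE],
    sample_rate_hz = rec$sample_rate_hz,
    layout = layout_subset(rec$layout, rec$channel_ids[keep]),
    channel_ids = rec$channel_ids[keep],
    t0_s = rec$t0_s
  )
}

# voltages are stored on disk at 32-bit float precision; %.9g round-trips a
# float32 exactly, so write -> read -> write is lossless after the first
# quantization.
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
    size = 4L, n = length(x)
  )
}

#' Read and write recordings
#'
#' The on-disk container is a pair of plain-text files: `<path>` holds the
#' voltage matrix as CSV (one column per channel, header = channel ids,
#' values in µV at 32-bit float precision) and `<path>.json` is a sidecar
#' with `sample_rate_hz`, `t0_s`, `channel_ids` and the electrode layout.
#' A write/read cycle reproduces the stored matrix bit-identically.
#'
#' @param path Path to the CSV file (the sidecar lives at `<path>.json`).
#' @param rec An [mea_recording()].
#' @return `read_recording()` returns an [mea_recording()];
#'   `write_recording()` invisibly returns `path`.
#' @export
write_recording <- function(rec, path) {
  if (!inherits(rec, "mea_recording")) abort("rec must be an mea_recording")
  m <- matrix(as_float32(t(rec$data)), ncol = nrow(rec$data))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(rec$channel_ids, collapse = ","), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.9g", r), collapse = ",")), con)
  jsonlite::write_json(
    list(
      sample_rate_hz = rec$sample_rate_hz, t0_s = rec$t0_s,
      channel_ids = rec$channel_ids,
      layout = as.data.frame(rec$layout)
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) abort(paste0("recording file not found: ", path))
  side <- sidecar_path(path)
  if (!file.exists(side)) abort(paste0("metadata sidecar not found: ", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (field in c("sample_rate_hz", "t0_s", "channel_ids", "layout")) {
    if (is.null(meta[[field]])) {
      abort(paste0("recording metadata is missing required field '", field, "'"))
    }
  }
  tab <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  if (ncol(tab) != length(meta$channel_ids)) {
    abort("channel count in CSV does not match sidecar channel_ids")
  }
  if (anyNA(tab)) abort("ragged or non-numeric channel data in recording CSV")
  layout <- electrode_layout(
    meta$layout$electrode_id, meta$layout$x_um, meta$layout$y_um,
    meta$layout$is_reference
  )
  mea_recording(
    t(as.matrix(tab)),
    sample_rate_hz = meta$sample_rate_hz,
    layout = layout,
    channel_ids = meta$channel_ids,
    t0_s = meta$t0_s
  )
}
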