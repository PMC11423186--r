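#' Optical stimulation protocols
#'
#' A stimulus protocol is a piecewise-constant irradiance schedule: an ordered
#' set of epochs `(t_start_s, t_end_s, irradiance_uW_mm2)` on the recording
#' clock. Epochs must not overlap; gaps are treated as dark (0 µW mm⁻²) and
#' the lookup [protocol_irradiance()] is right-continuous.
#'
#' @param t_start_s,t_end_s Epoch boundaries in seconds.
#' @param irradiance_uW_mm2 Irradiance during each epoch, µW mm⁻² (>= 0).
#' @return A tibble of class `stim_protocol`.
#' @examples
#' # 5 min dark, then 20 min at 27 uW/mm2
#' p <- stim_protocol(c(0, 300), c(300, 1500), c(0, 27))
#' protocol_irradiance(p, c(0, 299, 300, 1500))
#' @export
stim_protocol <- function(t_start_s = numeric(), t_end_s = numeric(),
                          irradiance_uW_mm2 = numeric()) {
  p <- tibble::tibble(
    t_start_s = as.numeric(t_start_s),
    t_end_s = as.numeric(t_end_s),
    irradiance_uW_mm2 = as.numeric(irradiance_uW_mm2)
  )
  if (nrow(p) > 0) {
    if (any(p$t_end_s <= p$t_start_s)) abort("epochs must have t_end_s > t_start_s")
    if (any(p$irradiance_uW_mm2 < 0)) abort("irradiance must be >= 0")
    p <- dplyr::arrange(p, .data$t_start_s)
    if (any(p$t_start_s[-1] < p$t_end_s[-nrow(p)] - 1e-12)) {
      abort("protocol epochs overlap")
    }
  }
  class(p) <- c("stim_protocol", class(p))
  p
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d epochs, %g s total\n", nrow(x),
    if (nrow(x)) max(x$t_end_s) - min(x$t_start_s) else 0
  ))
  NextMethod()
}

#' Load a protocol from CSV or JSON
#'
#' The file holds rows/records with fields `t_start_s`, `t_end_s`,
#' `irradiance_uW_mm2`. An empty file yields a zero-length (all-dark)
#' protocol.
#'
#' @param path Path to a `.csv` or `.json` protocol file.
#' @return A [stim_protocol()].
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) abort(paste0("protocol file not found: ", path))
  is_json <- grepl("\\.json$", path, ignore.case = TRUE)
  tab <- if (is_json) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else if (length(readLines(path, n = 2)) < 2) {
    data.frame()
  } else {
    utils::read.csv(path)
  }
  if (nrow(tab) == 0) {
    return(stim_protocol())
  }
  for (field in c("t_start_s", "t_end_s", "irradiance_uW_mm2")) {
    if (is.null(tab[[field]])) {
      abort(paste0("protocol is missing required field '", field, "'"))
    }
  }
  stim_protocol(tab$t_start_s, tab$t_end_s, tab$irradiance_uW_mm2)
}

#' Write a protocol to CSV
#'
#' @param protocol A [stim_protocol()].
#' @param path Output CSV path.
#' @export
write_protocol <- function(protocol, path) {
  utils::write.csv(as.data.frame(protocol), path, row.names = FALSE)
  invisible(path)
}

#' @rdname stim_protocol
#' @param protocol A [stim_protocol()].
#' @param t_s Times (s) at which to evaluate the irradiance.
#' @export
protocol_irradiance <- function(protocol, t_s) {
  out <- numeric(length(t_s))
  for (i in seq_len(nrow(protocol))) {
    hit <- t_s >= protocol$t_start_s[i] & t_s < protocol$t_end_s[i]
    out[hit] <- protocol$irradiance_uW_mm2[i]
  }
  out
}

#' Protocol epoch boundaries clipped to a time window
#'
#' Expands a protocol into contiguous constant-irradiance spans covering
#' `[0, duration_s]`, inserting dark spans for gaps. Used by the simulator.
#'
#' @param protocol A [stim_protocol()].
#' @param duration_s Window length in seconds.
#' @return Tibble with `t_start_s`, `t_end_s`, `irradiance_uW_mm2` covering
#'   the window without gaps.
#' @keywords internal
protocol_spans <- function(protocol, duration_s) {
  edges <- sort(unique(c(
    0, duration_s,
    protocol$t_start_s, protocol$t_end_s
  )))
  edges <- edges[edges >= 0 & edges <= duration_s]
  if (length(edges) < 2) edges <- c(0, duration_s)
  mids <- head(edges, -1) + diff(edges) / 2
  tibble::tibble(
    t_start_s = head(edges, -1),
    t_end_s = edges[-1],
    irradiance_uW_mm2 = protocol_irradiance(protocol, mids)
  )
}
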