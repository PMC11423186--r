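#' Rise/decay kinetics of a fold-change series
#'
#' Quantifies the response of a fold-change series to a stimulus edge:
#' baseline is the mean fold over a pre-edge window, plateau the mean over
#' the final 20% of the epoch, and t50/t90 are the first times (from the
#' edge, in minutes) at which the smoothed, linearly interpolated normalized
#' response crosses 0.5 and 0.9. Smoothing is a centered moving average of
#' `smooth_segments` segments. When the plateau-baseline separation is
#' below twice the series noise scale the series is flagged unresponsive
#' and no crossing times are reported.
#'
#' @param series A [fold_series()] result (or tibble with
#'   `segment_start_s`, `fold`).
#' @param edge_time_s Time of the stimulus edge, s.
#' @param epoch_end_s End of the post-edge epoch, s; default end of series.
#' @param baseline_window_s Pre-edge window used for the baseline, s
#'   (default 120). A short window close to the edge keeps the baseline
#'   unbiased when the pre-edge state is itself still converging.
#' @param smooth_segments Moving-average window, in segments (default 5).
#' @return A list of class `kinetics_summary`: `baseline_level`,
#'   `plateau_level`, `t50_min`, `t90_min`, `direction` (`"rise"` or
#'   `"decay"`), `responded`.
#' @export
extract_kinetics <- function(series, edge_time_s, epoch_end_s = NULL,
                             baseline_window_s = 120, smooth_segments = 5) {
  t <- series$segment_start_s
  y <- series$fold
  epoch_end_s <- epoch_end_s %||% max(t)
  if (edge_time_s <= min(t) || edge_time_s >= epoch_end_s) {
    abort("edge_time_s must fall inside the series")
  }
  post <- t >= edge_time_s & t <= epoch_end_s
  if (sum(post) < 10) abort("need at least 10 segments after the edge")

  # centered moving average; shrinks to the available window at the ends
  k <- smooth_segments
  sm <- as.numeric(stats::filter(y, rep(1 / k, k), sides = 2))
  half <- (k - 1) %/% 2
  for (i in which(is.na(sm))) {
    lo <- max(1, i - half)
    hi <- min(length(y), i + half)
    sm[i] <- mean(y[lo:hi])
  }

  pre <- t < edge_time_s & t >= edge_time_s - baseline_window_s
  if (!any(pre)) abort("no segments in the baseline window before the edge")
  baseline <- mean(y[pre])
  epoch_len <- epoch_end_s - edge_time_s
  plat_win <- t >= epoch_end_s - 0.2 * epoch_len & t <= epoch_end_s
  plateau <- mean(y[plat_win])

  # noise scale: sd of first differences in the baseline window (white part)
  noise <- if (sum(pre) >= 3) sd(diff(y[pre])) / sqrt(2) else 0
  responded <- abs(plateau - baseline) >= 2 * noise && plateau != baseline

  direction <- if (plateau >= baseline) "rise" else "decay"
  t50 <- t90 <- NA_real_
  if (responded) {
    z <- (sm[post] - baseline) / (plateau - baseline)
    tz <- (t[post] - edge_time_s) / 60
    t50 <- first_crossing(tz, z, 0.5)
    t90 <- first_crossing(tz, z, 0.9)
  }
  structure(
    list(
      baseline_level = baseline, plateau_level = plateau,
      t50_min = t50, t90_min = t90, direction = direction,
      responded = responded
    ),
    class = "kinetics_summary"
  )
}

first_crossing <- function(t, z, level) {
  up <- z >= level
  if (up[1]) {
    return(0)
  }
  i <- which(up)[1]
  if (is.na(i)) {
    return(NA_real_)
  }
  # linear interpolation between the straddling points
  t[i - 1] + (level - z[i - 1]) / (z[i] - z[i - 1]) * (t[i] - t[i - 1])
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat(sprintf(
    "<kinetics_summary> %s: baseline %.4g -> plateau %.4g, t50 = %.3g min, t90 = %.3g min%s\n",
    x$direction, x$baseline_level, x$plateau_level, x$t50_min, x$t90_min,
    if (x$responded) "" else " (no response)"
  ))
  invisible(x)
}

#' @export
tidy.kinetics_summary <- function(x, ...) {
  tibble::tibble(
    direction = x$direction, baseline = x$baseline_level,
    plateau = x$plateau_level, t50_min = x$t50_min, t90_min = x$t90_min,
    responded = x$responded
  )
}

#' Per-epoch plateau summary over an alternating light/dark protocol
#'
#' Computes the plateau fold (mean of the final 20% of segments in each
#' epoch) for every protocol epoch, labels epochs light/dark, and reports
#' each light epoch's elevation over its preceding dark epoch. Epochs
#' spanning fewer than 5 segments are skipped with a warning.
#'
#' @param series A [fold_series()] result.
#' @param protocol A [stim_protocol()]; gaps count as dark epochs.
#' @return Tibble with `epoch`, `t_start_s`, `t_end_s`,
#'   `irradiance_uW_mm2`, `state`, `n_segments`, `plateau_fold`,
#'   `delta_vs_prev_dark` (light rows only).
#' @export
cycle_summary <- function(series, protocol) {
  spans <- protocol_spans(protocol, max(series$segment_start_s) + 1e-9)
  if (nrow(spans) < 2) abort("need at least 2 protocol epochs")
  rows <- purrr::map(seq_len(nrow(spans)), function(i) {
    inside <- series$segment_start_s >= spans$t_start_s[i] &
      series$segment_start_s < spans$t_end_s[i]
    n <- sum(inside)
    if (n < 5) {
      warn(sprintf("epoch %d spans only %d segments; skipped", i, n))
      return(NULL)
    }
    len <- spans$t_end_s[i] - spans$t_start_s[i]
    plat <- series$segment_start_s >= spans$t_end_s[i] - 0.2 * len & inside
    tibble::tibble(
      epoch = i, t_start_s = spans$t_start_s[i], t_end_s = spans$t_end_s[i],
      irradiance_uW_mm2 = spans$irradiance_uW_mm2[i],
      state = if (spans$irradiance_uW_mm2[i] > 0) "light" else "dark",
      n_segments = n,
      plateau_fold = mean(series$fold[plat])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no epoch spans enough segments to summarise")
  out$delta_vs_prev_dark <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (out$state[i] == "light" && i > 1 && out$state[i - 1] == "dark") {
      out$delta_vs_prev_dark[i] <- out$plateau_fold[i] - out$plateau_fold[i - 1]
    }
  }
  out
}
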