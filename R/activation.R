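#' Group per-channel spikes into array-wide beats
#'
#' Spikes from all channels are clustered into beats: candidate beat times
#' are taken from the channel with the most spikes, and every channel's
#' nearest spike within +/- 40% of the global median inter-beat interval is
#' assigned to the beat. Beats missing more than half the live channels are
#' dropped.
#'
#' @param spikes Tibble from [detect_spikes()] (`channel_id`, `time_s`).
#' @param window_frac Assignment window as a fraction of the median
#'   inter-beat interval (default 0.4).
#' @return Tibble with `beat_id`, `channel_id`, `time_s`, `amplitude_uV`
#'   (if present); empty (with a warning) when nothing clusters.
#' @export
beat_cluster <- function(spikes, window_frac = 0.4) {
  chans <- unique(spikes$channel_id)
  if (length(chans) < 4) abort("need spikes on at least 4 channels")
  ibi <- spikes |>
    dplyr::group_by(.data$channel_id) |>
    dplyr::summarise(m = if (dplyr::n() >= 2) median(diff(sort(.data$time_s))) else NA_real_) |>
    dplyr::pull(.data$m)
  ibi <- median(ibi, na.rm = TRUE)
  if (!is.finite(ibi)) {
    warn("no channel has >= 2 spikes; no beats clustered")
    return(tibble::tibble(
      beat_id = integer(), channel_id = integer(), time_s = numeric()
    ))
  }
  win <- window_frac * ibi
  counts <- table(spikes$channel_id)
  anchor_ch <- as.integer(names(counts)[which.max(counts)])
  anchors <- sort(spikes$time_s[spikes$channel_id == anchor_ch])
  out <- purrr::map(seq_along(anchors), function(b) {
    hit <- spikes |>
      dplyr::mutate(dt = abs(.data$time_s - anchors[b])) |>
      dplyr::filter(.data$dt <= win) |>
      dplyr::group_by(.data$channel_id) |>
      dplyr::slice_min(.data$dt, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select(-"dt")
    if (nrow(hit) <= length(chans) / 2) {
      return(NULL)
    }
    dplyr::mutate(hit, beat_id = b, .before = 1)
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    warn("no clusterable beats")
    return(tibble::tibble(
      beat_id = integer(), channel_id = integer(), time_s = numeric()
    ))
  }
  out$beat_id <- match(out$beat_id, sort(unique(out$beat_id)))
  out
}

#' Per-electrode activation times for one beat
#'
#' The `"extremum"` fiducial is the time of the spike's largest absolute
#' deflection (the detection time itself). The `"xcorr"` fiducial is the
#' lag maximizing the cross-correlation of each channel's waveform against
#' the earliest channel's waveform; it requires the filtered recording.
#' Times are shifted so the earliest electrode is 0. When the two methods
#' disagree by more than 2 ms on more than a quarter of channels, a quality
#' warning is attached as `attr(, "quality_warning")`.
#'
#' @param beat One beat's rows from [beat_cluster()].
#' @param method `"extremum"` (default) or `"xcorr"`.
#' @param rec Filtered [mea_recording()]; required for `"xcorr"`.
#' @param window_ms Waveform window around each spike for `"xcorr"`, ms.
#' @param check_agreement Cross-check the two fiducials (needs `rec`).
#' @return Tibble with `channel_id`, `time_ms` (min = 0).
#' @export
activation_times <- function(beat, method = c("extremum", "xcorr"),
                             rec = NULL, window_ms = 10,
                             check_agreement = FALSE) {
  method <- match.arg(method)
  if (nrow(beat) < 4) abort("beat cluster must span at least 4 electrodes")
  t_ex <- beat$time_s
  times <- if (method == "extremum") {
    t_ex
  } else {
    xcorr_times(beat, rec, window_ms)
  }
  out <- tibble::tibble(
    channel_id = beat$channel_id,
    time_ms = (times - min(times)) * 1000
  )
  if (check_agreement && !is.null(rec)) {
    alt <- if (method == "extremum") xcorr_times(beat, rec, window_ms) else t_ex
    dis <- abs((times - min(times)) - (alt - min(alt))) * 1000 > 2
    if (mean(dis) > 0.25) {
      attr(out, "quality_warning") <- sprintf(
        "extremum and xcorr fiducials disagree by > 2 ms on %d/%d channels",
        sum(dis), length(dis)
      )
    }
  }
  out
}

xcorr_times <- function(beat, rec, window_ms) {
  if (is.null(rec)) abort("xcorr fiducials need the filtered recording")
  fs <- rec$sample_rate_hz
  half <- round(window_ms / 1000 * fs)
  snip <- function(ch, t) {
    i <- round((t - rec$t0_s) * fs) + 1
    lo <- max(1, i - half)
    hi <- min(ncol(rec$data), i + half)
    row <- which(rec$channel_ids == ch)
    list(x = rec$data[row, lo:hi], offset = (lo - 1) / fs + rec$t0_s)
  }
  ref_i <- which.min(beat$time_s)
  ref <- snip(beat$channel_id[ref_i], beat$time_s[ref_i])
  vapply(seq_len(nrow(beat)), function(j) {
    s <- snip(beat$channel_id[j], beat$time_s[j])
    len <- min(length(s$x), length(ref$x))
    s$x <- s$x[seq_len(len)]
    cc <- stats::ccf(s$x, ref$x[seq_len(len)],
      lag.max = len - 1, plot = FALSE,
      demean = FALSE
    )
    lag <- cc$lag[which.max(cc$acf)]
    # lag maximizing ccf(x, ref) estimates the shift of x relative to ref
    # in samples, measured between the two snippet clocks
    ref$offset + lag / fs + (s$offset - ref$offset)
  }, numeric(1))
}

#' Thin-plate interpolation of activation times
#'
#' Interpolates scattered per-electrode activation times onto a regular
#' grid with a thin-plate spline (kernel `r^2 log r` plus an affine term,
#' zero smoothing), which honours the electrode values exactly and
#' reproduces affine surfaces - hence planar wavefronts - exactly.
#'
#' @param times Tibble with `channel_id`, `time_ms`.
#' @param layout An [electrode_layout()] covering those channels.
#' @param grid_step_um Grid spacing, µm (default 25, pitch/8).
#' @return A list of class `iso_surface`: `x_um`, `y_um` (grid axes),
#'   `t_ms` (matrix, rows = y, cols = x), plus the electrode table.
#' @export
interpolate_surface <- function(times, layout, grid_step_um = 25) {
  pts <- dplyr::inner_join(times, as.data.frame(layout)[c("electrode_id", "x_um", "y_um")],
    by = c(channel_id = "electrode_id")
  )
  if (nrow(pts) < 4) abort("need at least 4 electrodes to interpolate")
  xy <- cbind(pts$x_um, pts$y_um)
  if (qr(cbind(1, xy))$rank < 3) abort("electrodes are collinear; cannot interpolate a surface")
  n <- nrow(xy)
  # solve in unit-scaled coordinates for conditioning; affine reproduction
  # is scale-invariant so the interpolant is unchanged
  sc <- max(diff(range(xy[, 1])), diff(range(xy[, 2])))
  xys <- xy / sc
  d <- as.matrix(stats::dist(xys))
  K <- tps_kernel(d)
  P <- cbind(1, xys)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(pts$time_ms, rep(0, 3))
  coefs <- solve(A, rhs)
  w <- coefs[1:n]
  a <- coefs[n + 1:3]

  gx <- seq(min(pts$x_um), max(pts$x_um), by = grid_step_um)
  gy <- seq(min(pts$y_um), max(pts$y_um), by = grid_step_um)
  grid <- as.matrix(expand.grid(x = gx, y = gy)) / sc
  dg <- sqrt(outer(grid[, 1], xys[, 1], "-")^2 + outer(grid[, 2], xys[, 2], "-")^2)
  z <- tps_kernel(dg) %*% w + cbind(1, grid) %*% a
  structure(
    list(
      x_um = gx, y_um = gy,
      t_ms = matrix(z, nrow = length(gy), ncol = length(gx), byrow = TRUE),
      electrodes = pts
    ),
    class = "iso_surface"
  )
}

tps_kernel <- function(r) {
  k <- r^2 * log(r)
  k[!is.finite(k)] <- 0
  k
}

#' Velocity field from an interpolated activation surface
#'
#' The gradient of the activation-time surface is taken by central
#' differences; each local conduction-velocity vector is the inverse of the
#' gradient vector, `v = grad(T) / |grad(T)|^2`, pointing in the direction
#' of wave travel with speed `1/|grad(T)|` (mm s⁻¹, since times are ms and
#' positions µm). Vectors outside the electrode convex hull, with nearly
#' flat gradient, or faster than `speed_cap_mm_s` are excluded; the summary
#' is the mean and SEM over the remaining vectors.
#'
#' @param surface An [interpolate_surface()] result.
#' @param speed_cap_mm_s Exclude speeds above this cap (default 200).
#' @param eps_ms_per_um Gradient magnitudes below this are treated as flat.
#' @return A list of class `velocity_field`: tibble `vectors` (`x_um`,
#'   `y_um`, `vx`, `vy`, `speed_mm_s`), `mean_speed_mm_s`, `sem_speed_mm_s`,
#'   `n_vectors`, `mean_direction_deg`.
#' @export
velocity_field <- function(surface, speed_cap_mm_s = 200,
                           eps_ms_per_um = 1e-6) {
  gx <- surface$x_um
  gy <- surface$y_um
  T <- surface$t_ms
  if (length(gx) < 3 || length(gy) < 3) abort("grid too small for central differences")
  hx <- gx[2] - gx[1]
  hy <- gy[2] - gy[1]
  # central differences on the interior
  dTdx <- (T[, 3:length(gx)] - T[, 1:(length(gx) - 2)]) / (2 * hx)
  dTdy <- (T[3:length(gy), ] - T[1:(length(gy) - 2), ]) / (2 * hy)
  ix <- 2:(length(gx) - 1)
  iy <- 2:(length(gy) - 1)
  g1 <- dTdx[iy, , drop = FALSE]
  g2 <- dTdy[, ix, drop = FALSE]
  pts <- expand.grid(y = gy[iy], x = gx[ix])
  gvx <- as.vector(g1)
  gvy <- as.vector(g2)
  gnorm2 <- gvx^2 + gvy^2

  el <- surface$electrodes
  hull <- grDevices::chull(el$x_um, el$y_um)
  inside <- pracma::inpolygon(
    pts$x, pts$y, el$x_um[hull], el$y_um[hull],
    boundary = TRUE
  )
  ok <- inside & sqrt(gnorm2) > eps_ms_per_um
  speed <- 1 / sqrt(gnorm2[ok]) # um/ms == mm/s
  vx <- gvx[ok] / gnorm2[ok]
  vy <- gvy[ok] / gnorm2[ok]
  keep <- speed <= speed_cap_mm_s
  if (!any(keep)) {
    abort("degenerate activation map: no velocity vectors survive exclusion")
  }
  vec <- tibble::tibble(
    x_um = pts$x[ok][keep], y_um = pts$y[ok][keep],
    vx = vx[keep], vy = vy[keep], speed_mm_s = speed[keep]
  )
  structure(
    list(
      vectors = vec,
      mean_speed_mm_s = mean(vec$speed_mm_s),
      sem_speed_mm_s = sd(vec$speed_mm_s) / sqrt(nrow(vec)),
      n_vectors = nrow(vec),
      mean_direction_deg = atan2(mean(vec$vy), mean(vec$vx)) * 180 / pi
    ),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "<velocity_field> %.3g +/- %.2g mm/s (SEM, n = %d), direction %.1f deg\n",
    x$mean_speed_mm_s, x$sem_speed_mm_s, x$n_vectors, x$mean_direction_deg
  ))
  invisible(x)
}

#' Full activation map of a recording
#'
#' Convenience wrapper running [detect_spikes()] (unless spikes are
#' supplied), [beat_cluster()], per-beat [activation_times()] and
#' [interpolate_surface()], then pooling velocity vectors across beats into
#' a single [velocity_field()] summary, the per-chip speed convention.
#'
#' @param rec A filtered, QC'd [mea_recording()].
#' @param spikes Optional precomputed [detect_spikes()] table.
#' @param method Fiducial method, see [activation_times()].
#' @param grid_step_um Interpolation grid step, µm.
#' @param speed_cap_mm_s Speed exclusion cap, mm s⁻¹.
#' @param max_beats Cap on the number of beats mapped (default all).
#' @return A list of class `activation_map`: `beats` (per-beat tibble of
#'   electrode times), `surfaces` (list of [interpolate_surface()] results),
#'   pooled `vectors`, `mean_speed_mm_s`, `sem_speed_mm_s`, `n_vectors`,
#'   `n_beats`.
#' @export
activation_map <- function(rec, spikes = NULL,
                           method = c("extremum", "xcorr"),
                           grid_step_um = 25, speed_cap_mm_s = 200,
                           max_beats = Inf) {
  method <- match.arg(method)
  spikes <- spikes %||% detect_spikes(rec)
  clusters <- beat_cluster(spikes)
  if (nrow(clusters) == 0) abort("no beats found to map")
  ids <- sort(unique(clusters$beat_id))
  if (length(ids) > max_beats) ids <- ids[seq_len(max_beats)]
  per_beat <- list()
  surfaces <- list()
  vecs <- list()
  for (b in ids) {
    beat <- dplyr::filter(clusters, .data$beat_id == b)
    if (nrow(beat) < 4) next
    at <- activation_times(beat, method = method, rec = rec)
    surf <- interpolate_surface(at, rec$layout, grid_step_um)
    vf <- velocity_field(surf, speed_cap_mm_s)
    per_beat[[length(per_beat) + 1]] <- dplyr::mutate(at, beat_id = b, .before = 1)
    surfaces[[length(surfaces) + 1]] <- surf
    vecs[[length(vecs) + 1]] <- dplyr::mutate(vf$vectors, beat_id = b, .before = 1)
  }
  if (length(vecs) == 0) abort("no beat produced a usable activation map")
  pooled <- dplyr::bind_rows(vecs)
  structure(
    list(
      beats = dplyr::bind_rows(per_beat), surfaces = surfaces,
      vectors = pooled,
      mean_speed_mm_s = mean(pooled$speed_mm_s),
      sem_speed_mm_s = sd(pooled$speed_mm_s) / sqrt(nrow(pooled)),
      n_vectors = nrow(pooled), n_beats = length(surfaces),
      mean_direction_deg = atan2(mean(pooled$vy), mean(pooled$vx)) * 180 / pi
    ),
    class = "activation_map"
  )
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf(
    "<activation_map> %d beats, pooled speed %.3g +/- %.2g mm/s (SEM, n = %d)\n",
    x$n_beats, x$mean_speed_mm_s, x$sem_speed_mm_s, x$n_vectors
  ))
  invisible(x)
}

#' @export
tidy.activation_map <- function(x, ...) x$beats

#' @export
glance.activation_map <- function(x, ...) {
  tibble::tibble(
    mean_speed_mm_s = x$mean_speed_mm_s,
    sem_speed_mm_s = x$sem_speed_mm_s,
    n_vectors = x$n_vectors, n_beats = x$n_beats
  )
}

#' Plot an isochronal activation map
#'
#' Filled-contour rendering of the (first or chosen beat's) interpolated
#' activation-time surface with electrode markers; the colour scale is in
#' ms after the earliest electrode.
#'
#' @param object An [activation_map()] result.
#' @param beat Index of the beat surface to draw (default 1).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.activation_map <- function(object, beat = 1, ...) {
  surf <- object$surfaces[[beat]]
  df <- expand.grid(x_um = surf$x_um, y_um = surf$y_um)
  df$t_ms <- as.vector(t(surf$t_ms))
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$t_ms)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$t_ms), color = "white", linewidth = 0.3) +
    ggplot2::geom_point(
      data = surf$electrodes, shape = 21, fill = "white", size = 1.5
    ) +
    ggplot2::scale_fill_viridis_c(name = "activation (ms)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Render an isochronal map to a PNG file
#'
#' @param map An [activation_map()] result.
#' @param path Output PNG path.
#' @param beat Beat surface to render.
#' @param width,height Device size in inches.
#' @return `path`, invisibly.
#' @export
render_isochronal_map <- function(map, path, beat = 1, width = 4, height = 5) {
  p <- autoplot(map, beat = beat)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
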