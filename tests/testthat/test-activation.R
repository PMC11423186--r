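test_that("synchronized beats cluster into complete array-wide beats", {
  spikes <- tidyr::expand_grid(
    channel_id = 1:8,
    beat = 1:30
  ) |>
    dplyr::mutate(time_s = beat * 0.2, beat = NULL)
  cl <- beat_cluster(spikes)
  expect_equal(length(unique(cl$beat_id)), 30)
  expect_true(all(table(cl$beat_id) == 8))
})

test_that("clustering preserves injected wavefront delays", {
  lay <- grid_layout(4, 8)
  delays <- wavefront_delays(
    wavefront_params("planar", speed_mm_s = 50, direction_deg = 0), lay
  )
  spikes <- tidyr::expand_grid(channel_id = lay$electrode_id, beat = 1:10) |>
    dplyr::mutate(
      time_s = beat * 0.2 + unname(delays[as.character(channel_id)]),
      beat = NULL
    )
  cl <- beat_cluster(spikes)
  expect_equal(length(unique(cl$beat_id)), 10)
  b1 <- dplyr::filter(cl, .data$beat_id == 5) |> dplyr::arrange(channel_id)
  expect_equal(
    b1$time_s - min(b1$time_s),
    unname(delays[as.character(b1$channel_id)]),
    tolerance = 1e-9
  )
  # silent channel is excluded without error
  spikes2 <- dplyr::filter(spikes, channel_id != 7)
  cl2 <- beat_cluster(spikes2)
  expect_false(7 %in% cl2$channel_id)
  expect_equal(length(unique(cl2$beat_id)), 10)
})

test_that("activation times follow column geometry for planar waves", {
  rec <- planar_recording(speed = 50, direction = 0, layout = grid_layout(4, 8))
  recf <- bandpass_filter(rec)
  spikes <- detect_spikes(recf)
  cl <- beat_cluster(spikes)
  beat <- dplyr::filter(cl, beat_id == 3)
  at <- activation_times(beat)
  at <- dplyr::inner_join(at, as.data.frame(rec$layout),
    by = c(channel_id = "electrode_id")
  )
  for (col in unique(at$x_um)) {
    # column delay = pitch/speed: 0, 4, 8, 12 ms
    expect_equal(
      median(at$time_ms[at$x_um == col]), col / 1000 / 50 * 1000,
      tolerance = 0.05
    )
  }
  # identical waveforms with zero delays -> all times 0
  rec0 <- planar_recording(speed = 1e9, layout = grid_layout(4, 8))
  sp0 <- detect_spikes(bandpass_filter(rec0))
  b0 <- dplyr::filter(beat_cluster(sp0), beat_id == 2)
  expect_true(all(activation_times(b0)$time_ms < 0.05))
})

test_that("extremum and xcorr fiducials agree across spike morphologies", {
  for (m in c(-0.8, 0, 0.8)) {
    rec <- planar_recording(
      speed = 50, direction = 30, layout = grid_layout(4, 8),
      morphology = m, duration = 1
    )
    recf <- bandpass_filter(rec)
    spikes <- detect_spikes(recf)
    beat <- dplyr::filter(beat_cluster(spikes), beat_id == 2)
    t_ex <- activation_times(beat, "extremum")
    t_xc <- activation_times(beat, "xcorr", rec = recf)
    j <- dplyr::inner_join(t_ex, t_xc, by = "channel_id")
    expect_lt(max(abs(j$time_ms.x - j$time_ms.y)), 1)
  }
})

test_that("thin-plate interpolation reproduces affine surfaces exactly", {
  lay <- grid_layout(4, 8)
  v <- 50
  times <- tibble::tibble(
    channel_id = lay$electrode_id,
    time_ms = lay$x_um / 1000 / v * 1000 # T = x/v, planar along +x
  )
  surf <- interpolate_surface(times, lay)
  truth <- outer(surf$y_um, surf$x_um, function(y, x) x / 1000 / v * 1000)
  expect_lt(max(abs(surf$t_ms - truth)) / max(abs(truth)), 1e-3)
  # constant surface stays constant
  surfc <- interpolate_surface(
    dplyr::mutate(times, time_ms = 3), lay
  )
  expect_lt(max(abs(surfc$t_ms - 3)), 1e-9)
  # collinear electrodes are rejected
  expect_error(
    interpolate_surface(times[1:4, ], grid_layout(4, 1)),
    "collinear"
  )
})

test_that("radial sources give concentric isochrones and recoverable origin", {
  lay <- default_mea_layout()
  origin <- c(400, 400)
  v <- 30
  d <- sqrt((lay$x_um - origin[1])^2 + (lay$y_um - origin[2])^2)
  times <- tibble::tibble(
    channel_id = lay$electrode_id, time_ms = d / 1000 / v * 1000
  )
  surf <- interpolate_surface(times, lay)
  # monotone in radius along rays through the origin
  grid_t <- surf$t_ms
  ox <- which.min(abs(surf$x_um - origin[1]))
  oy <- which.min(abs(surf$y_um - origin[2]))
  ray <- grid_t[oy, ox:length(surf$x_um)]
  expect_true(all(diff(ray) > -1e-6))
  # origin = argmin of the surface, within one pitch
  idx <- which(grid_t == min(grid_t), arr.ind = TRUE)[1, ]
  expect_lt(abs(surf$x_um[idx[2]] - origin[1]), 200)
  expect_lt(abs(surf$y_um[idx[1]] - origin[2]), 200)
})

test_that("velocity field inverts planar gradients exactly", {
  lay <- grid_layout(4, 8)
  v <- 50
  times <- tibble::tibble(
    channel_id = lay$electrode_id,
    time_ms = lay$x_um / 1000 / v * 1000
  )
  surf <- interpolate_surface(times, lay)
  vf <- velocity_field(surf)
  expect_equal(vf$mean_speed_mm_s, v, tolerance = 1e-6)
  expect_lt(vf$sem_speed_mm_s, 1e-6)
  expect_equal(vf$mean_direction_deg, 0, tolerance = 1e-3)
  # constant surface -> degenerate map error
  surfc <- interpolate_surface(dplyr::mutate(times, time_ms = 1), lay)
  expect_error(velocity_field(surfc), "degenerate")
})

test_that("speed estimates are invariant to time origin and reference", {
  lay <- grid_layout(4, 8)
  times <- tibble::tibble(
    channel_id = lay$electrode_id,
    time_ms = lay$x_um * 0.02 + lay$y_um * 0.005
  )
  v1 <- velocity_field(interpolate_surface(times, lay))
  v2 <- velocity_field(interpolate_surface(
    dplyr::mutate(times, time_ms = time_ms + 17), lay
  ))
  expect_equal(v1$mean_speed_mm_s, v2$mean_speed_mm_s, tolerance = 1e-9)
})

test_that("end-to-end map recovers planar speed and direction (noiseless)", {
  for (v in c(20, 50, 80)) {
    rec <- planar_recording(
      speed = v, direction = 30, duration = 1.2,
      layout = grid_layout(4, 8)
    )
    m <- activation_map(bandpass_filter(rec))
    expect_lt(abs(m$mean_speed_mm_s - v) / v, 0.05)
    expect_lt(abs(m$mean_direction_deg - 30), 5)
  }
})

test_that("end-to-end map tolerates 7 uV noise within 10% (property)", {
  errs <- vapply(1:20, function(seed) {
    rec <- planar_recording(
      speed = 50, direction = 30, duration = 1.2,
      layout = grid_layout(4, 8), noise = 7, seed = seed
    )
    m <- activation_map(bandpass_filter(rec))
    abs(m$mean_speed_mm_s - 50) / 50
  }, numeric(1))
  expect_lt(max(errs), 0.10)
})

test_that("per-beat speeds stay stable over a 1-min stationary window", {
  rec <- planar_recording(
    speed = 50, direction = 30, duration = 60.5, rate = 5.7,
    layout = grid_layout(4, 8), noise = 7, seed = 2, jitter_ms = 1
  )
  m <- activation_map(bandpass_filter(rec))
  per_beat <- m$vectors |>
    dplyr::group_by(beat_id) |>
    dplyr::summarise(speed = mean(speed_mm_s))
  cv <- sd(per_beat$speed) / mean(per_beat$speed)
  expect_lt(cv, 0.10)
})

test_that("isochronal maps render to PNG", {
  rec <- planar_recording(speed = 50, duration = 0.8, layout = grid_layout(4, 8))
  m <- activation_map(bandpass_filter(rec))
  path <- withr::local_tempfile(fileext = ".png")
  render_isochronal_map(m, path)
  expect_true(file.exists(path) && file.size(path) > 1000)
  expect_s3_class(autoplot(m), "ggplot")
})
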