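#' Segment-wise rates straight from array-level beat times
#'
#' For rate-level analyses (no waveform), cuts a beat-time train into
#' fixed segments and applies the median-interval rate estimator.
#'
#' @param beat_times_s Sorted beat times, s.
#' @param segment_len_s Segment length, s (default 6).
#' @param duration_s Total span; default last beat.
#' @return Tibble with `segment_start_s`, `bps`.
#' @export
rates_from_beats <- function(beat_times_s, segment_len_s = 6,
                             duration_s = NULL) {
  duration_s <- duration_s %||% max(beat_times_s)
  n_seg <- max(1L, floor(duration_s / segment_len_s + 1e-9))
  starts <- (seq_len(n_seg) - 1) * segment_len_s
  tibble::tibble(
    segment_start_s = starts,
    bps = purrr::map_dbl(starts, function(t0) {
      beating_rate(beat_times_s, t0, t0 + segment_len_s)
    })
  )
}

#' Run configuration for the end-to-end pipeline
#'
#' Exactly one of `preset` (a [make_fixture()] id) or `recording_path`
#' (a [read_recording()] container) must be given; every stage's knobs sit
#' in its own block and default to the module defaults.
#'
#' @param preset Simulation preset id, or `NULL`.
#' @param recording_path Path to a stored recording, or `NULL`.
#' @param protocol_path Optional protocol CSV/JSON for stored recordings.
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param segment_len_s Beat-analysis segment length, s.
#' @param filter,qc,detection,mapping Named lists overriding stage defaults
#'   (see [filter_spec()], [channel_metrics()], [detect_spikes()],
#'   [activation_map()]).
#' @param map Compute the activation map stage (default `TRUE` when a
#'   waveform is present).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(preset = NULL, recording_path = NULL,
                       protocol_path = NULL, seed = 0, segment_len_s = 6,
                       filter = list(), qc = list(), detection = list(),
                       mapping = list(), map = TRUE) {
  if (is.null(preset) == is.null(recording_path)) {
    abort("exactly one of `preset` or `recording_path` must be set")
  }
  filter <- utils::modifyList(
    list(low_hz = 150, high_hz = 2500, order = 2, ripple_db = 1, causal = FALSE),
    filter
  )
  qc <- utils::modifyList(list(snr_threshold = 2), qc)
  detection <- utils::modifyList(
    list(threshold_k = 5, refractory_ms = 80), detection
  )
  mapping <- utils::modifyList(
    list(
      method = "extremum", grid_step_um = 25, speed_cap_mm_s = 200,
      max_beats = Inf
    ),
    mapping
  )
  structure(
    list(
      preset = preset, recording_path = recording_path,
      protocol_path = protocol_path, seed = seed,
      segment_len_s = segment_len_s, filter = filter, qc = qc,
      detection = detection, mapping = mapping, map = map
    ),
    class = "run_config"
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> band-pass filter -> channel QC -> spike
#' detection -> segment rates and fold-change series -> kinetics (when the
#' protocol has a light edge) -> activation map, deterministically for a
#' fixed seed. When `out_dir` is given, each completed stage's output is
#' written (CSV/JSON) together with a run manifest; a failing stage leaves
#' earlier outputs in place and is recorded in the manifest.
#'
#' @param config A [run_config()] (or a plain list of its arguments).
#' @param out_dir Optional output directory.
#' @return A list of class `pipeline_result` with elements `fixture`,
#'   `recording`, `qc`, `spikes`, `rates`, `fold`, `kinetics`, `map`,
#'   `manifest`, `failed_stage` (`NULL` on success).
#' @examples
#' res <- run_pipeline(run_config(preset = "nt_baseline", seed = 1))
#' res$fold$bps[1] # ~5.7
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(manifest = list(
    config = unclass(config), config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("optobeat"))
  ))
  class(res) <- "pipeline_result"
  emit <- function(name, obj, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    obj
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      res$failed_stage <<- list(stage = name, message = conditionMessage(e))
      NULL
    })
  }

  # --- input ---------------------------------------------------------
  protocol <- stim_protocol()
  if (!is.null(config$preset)) {
    fixture <- stage("simulate", make_fixture(config$preset, seed = config$seed))
    if (is.null(fixture)) {
      return(finish_run(res, out_dir))
    }
    res$fixture <- fixture
    rec <- fixture$recording
    protocol <- fixture$protocol
  } else {
    rec <- stage("read", read_recording(config$recording_path))
    if (is.null(rec)) {
      return(finish_run(res, out_dir))
    }
    if (!is.null(config$protocol_path)) {
      protocol <- load_protocol(config$protocol_path)
    }
  }
  res$protocol <- protocol

  duration_s <- NULL
  fold <- NULL
  if (!is.null(rec)) {
    # --- filter + QC -------------------------------------------------
    spec <- filter_spec(
      config$filter$low_hz, config$filter$high_hz,
      config$filter$order, config$filter$ripple_db
    )
    spec <- adapt_filter_spec(spec, rec$sample_rate_hz)
    filtered <- stage("filter", bandpass_filter(rec, spec, causal = config$filter$causal))
    if (is.null(filtered)) {
      return(finish_run(res, out_dir))
    }
    qc <- stage("qc", channel_metrics(filtered,
      snr_threshold = config$qc$snr_threshold,
      threshold_k = config$detection$threshold_k,
      refractory_ms = config$detection$refractory_ms
    ))
    if (is.null(qc)) {
      return(finish_run(res, out_dir))
    }
    res$qc <- emit("qc_report.csv", qc, write_qc_report)
    clean <- stage("apply_qc", apply_qc(filtered, qc))
    if (is.null(clean)) {
      return(finish_run(res, out_dir))
    }
    res$recording <- clean

    # --- beats -------------------------------------------------------
    spikes <- stage("detect", detect_spikes(clean,
      threshold_k = config$detection$threshold_k,
      refractory_ms = config$detection$refractory_ms
    ))
    if (is.null(spikes)) {
      return(finish_run(res, out_dir))
    }
    res$spikes <- emit(
      "beat_table.csv", spikes,
      function(o, p) utils::write.csv(o, p, row.names = FALSE)
    )
    duration_s <- ncol(clean$data) / clean$sample_rate_hz
    rates <- stage("rates", segment_rates(spikes,
      segment_len_s = config$segment_len_s, duration_s = duration_s
    ))
    if (is.null(rates)) {
      return(finish_run(res, out_dir))
    }
    res$rates <- rates
    fold <- stage("fold", fold_series(rates))
  } else if (!is.null(res$fixture)) {
    # rate-level fixture: fold series straight from beat times
    duration_s <- max(res$fixture$protocol$t_end_s)
    fold <- stage("fold", fold_series(rates_from_beats(
      res$fixture$beat_times, config$segment_len_s, duration_s
    )))
  }
  if (is.null(fold)) {
    return(finish_run(res, out_dir))
  }
  res$fold <- emit(
    "fold_series.csv", fold,
    function(o, p) utils::write.csv(as.data.frame(o), p, row.names = FALSE)
  )

  # --- kinetics ------------------------------------------------------
  lit <- protocol$irradiance_uW_mm2 > 0
  if (any(lit)) {
    edge <- min(protocol$t_start_s[lit])
    end <- min(protocol$t_end_s[lit])
    n_post <- sum(fold$segment_start_s >= edge & fold$segment_start_s <= end)
    if (edge > min(fold$segment_start_s) && n_post >= 10) {
      kin <- stage(
        "kinetics",
        extract_kinetics(fold, edge_time_s = edge, epoch_end_s = end)
      )
      if (!is.null(kin)) {
        res$kinetics <- emit(
          "kinetics.json", kin,
          function(o, p) {
            jsonlite::write_json(tidy(o), p, auto_unbox = TRUE, digits = NA)
          }
        )
      }
    }
  }

  # --- activation map ------------------------------------------------
  if (config$map && !is.null(res$recording) && !is.null(res$spikes) &&
    length(unique(res$spikes$channel_id)) >= 4) {
    m <- stage("map", activation_map(res$recording,
      spikes = res$spikes,
      method = config$mapping$method,
      grid_step_um = config$mapping$grid_step_um,
      speed_cap_mm_s = config$mapping$speed_cap_mm_s,
      max_beats = config$mapping$max_beats
    ))
    if (!is.null(m)) {
      res$map <- emit(
        "activation_summary.csv", m,
        function(o, p) utils::write.csv(glance(o), p, row.names = FALSE)
      )
    }
  }
  finish_run(res, out_dir)
}

finish_run <- function(res, out_dir) {
  res$manifest$failed_stage <- res$failed_stage
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      res$manifest[c("config_hash", "seed", "package_version", "failed_stage")],
      file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  done <- intersect(
    c("qc", "spikes", "fold", "kinetics", "map"), names(x)
  )
  cat("  stages completed:", paste(done, collapse = ", "), "\n")
  if (!is.null(x$failed_stage)) {
    cat(sprintf(
      "  FAILED at '%s': %s\n", x$failed_stage$stage, x$failed_stage$message
    ))
  }
  invisible(x)
}

#' Simulated dose-response experiment over an intensity ladder
#'
#' Runs one photoresponse simulation per irradiance level (a 5-min dark
#' lead-in followed by a light epoch), measures each run's plateau fold
#' change (mean of the final 20% of the light epoch), and fits the Hill
#' dose-response model to the plateau-versus-irradiance points. The
#' default ladder is the canonical 7-level design spanning 0-27 µW mm⁻².
#'
#' @param intensities Irradiance ladder, µW mm⁻² (>= 4 levels incl. 0).
#' @param params A [photo_response_params()].
#' @param light_min Light-epoch duration per level, minutes (default 30).
#' @param segment_len_s Fold-series segment length, s.
#' @param jitter_ms Beat-clock jitter; 0 gives the noiseless design.
#' @param seed Root seed.
#' @param fix_hill,n_boot Passed to [fit_dose_response()].
#' @return A list of class `dose_response_experiment`: `points` (tibble
#'   irradiance/response), `fit` (a [fit_dose_response()] result).
#' @export
run_dose_response_experiment <- function(intensities = c(0, 0.03, 0.3, 0.7, 2.7, 7, 27),
                                         params = photo_response_params(),
                                         light_min = 30, segment_len_s = 6,
                                         jitter_ms = 1, seed = 0,
                                         fix_hill = TRUE, n_boot = 0) {
  if (length(unique(intensities)) < 4) {
    abort("intensity ladder must contain at least 4 distinct levels")
  }
  duration_s <- 300 + light_min * 60
  points <- purrr::map_dfr(seq_along(intensities), function(i) {
    I <- intensities[i]
    protocol <- if (I > 0) {
      stim_protocol(c(0, 300), c(300, duration_s), c(0, I))
    } else {
      stim_protocol(0, duration_s, 0)
    }
    sim <- simulate_photoresponse(params, protocol, duration_s, dt_s = 1)
    beats <- generate_beat_times(sim, duration_s,
      jitter_ms = jitter_ms,
      seed = derive_seed(seed + i, "beats")
    )
    fold <- fold_series(rates_from_beats(beats, segment_len_s, duration_s))
    light_len <- duration_s - 300
    plat <- fold$segment_start_s >= duration_s - 0.2 * light_len
    tibble::tibble(
      irradiance_uW_mm2 = I,
      response = mean(fold$fold[plat]),
      n = 1
    )
  })
  fit <- fit_dose_response(points,
    fix_hill = fix_hill, n_boot = n_boot,
    seed = seed
  )
  structure(
    list(points = points, fit = fit),
    class = "dose_response_experiment"
  )
}

#' @export
print.dose_response_experiment <- function(x, ...) {
  cat(sprintf(
    "<dose_response_experiment> %d levels, EC50 = %.3g uW/mm2\n",
    nrow(x$points), coef(x$fit)[["ec50"]]
  ))
  invisible(x)
}
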