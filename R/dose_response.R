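#' Fit an agonist-versus-response (Hill) curve to plateau responses
#'
#' Fits `response = bottom + (top - bottom) * I^h / (I^h + ec50^h)` to
#' plateau fold changes measured at a ladder of irradiance levels, by
#' weighted least squares (weights = replicate counts). The model is
#' parameterized on the linear dose axis, so the zero-irradiance point
#' enters directly (no log-dose pseudo-value). By default the Hill slope is
#' fixed at 1, the Michaelis-Menten limit appropriate for a single
#' photoreceptor binding step; `fix_hill = FALSE` frees it. Confidence
#' intervals come from a seeded parametric bootstrap.
#'
#' @param points Tibble with columns `irradiance_uW_mm2`, `response`
#'   (fold), optional `n` (replicates, default 1) and `sd` (dispersion,
#'   used by the bootstrap).
#' @param fix_hill Fix the Hill slope at 1 (default) or fit it.
#' @param fit_bottom Fit the zero-dose asymptote (default) or pin it to the
#'   observed zero-dose response.
#' @param n_boot Parametric bootstrap resamples for CIs (default 200; 0
#'   disables).
#' @param seed Seed for the bootstrap.
#' @return A list of class `dose_response_fit` with `coefficients`
#'   (`bottom`, `top`, `ec50`, `hill_n`), `points`, `residual_norm`,
#'   `converged`, and bootstrap `conf_int` (2.5/97.5 percentiles) when
#'   requested.
#' @examples
#' pts <- tibble::tibble(
#'   irradiance_uW_mm2 = c(0, 0.03, 0.3, 0.7, 2.7, 7, 27),
#'   response = 1 + 0.17 * irradiance_uW_mm2 / (irradiance_uW_mm2 + 0.56)
#' )
#' fit <- fit_dose_response(pts, n_boot = 0)
#' coef(fit)[["ec50"]] # 0.56
#' @export
fit_dose_response <- function(points, fix_hill = TRUE, fit_bottom = TRUE,
                              n_boot = 200, seed = 0) {
  pts <- tibble::as_tibble(points)
  if (!"n" %in% names(pts)) pts$n <- 1
  if (!"sd" %in% names(pts)) pts$sd <- NA_real_
  for (f in c("irradiance_uW_mm2", "response")) {
    if (is.null(pts[[f]])) abort(paste0("points must contain '", f, "'"))
  }
  levels <- sort(unique(pts$irradiance_uW_mm2))
  if (length(levels) < 4) abort("need >= 4 distinct irradiance levels")
  if (min(levels) > 0) abort("the ladder must include a zero-irradiance point")
  spread <- diff(range(pts$response))
  noise <- if (any(is.finite(pts$sd))) {
    stats::median(pts$sd, na.rm = TRUE)
  } else {
    0
  }
  if (spread <= 2 * noise || spread == 0) {
    abort("responses are flat across the ladder; EC50 is unidentifiable")
  }
  fit <- hill_fit_once(pts, fix_hill, fit_bottom)
  ci <- NULL
  if (n_boot > 0) {
    sds <- ifelse(is.finite(pts$sd), pts$sd, stats::sd(stats::resid(fit$nls)))
    boot <- withr::with_seed(derive_seed(seed, "boot"), {
      purrr::map(seq_len(n_boot), function(b) {
        bp <- pts
        bp$response <- predict(fit$nls) + rnorm(nrow(pts), sd = sds / sqrt(pts$n))
        out <- try(hill_fit_once(bp, fix_hill, fit_bottom), silent = TRUE)
        if (inherits(out, "try-error")) NULL else out$coefficients
      })
    })
    boot <- do.call(rbind, Filter(Negate(is.null), boot))
    if (!is.null(boot) && nrow(boot) >= 20) {
      ci <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975))
    }
  }
  structure(
    list(
      coefficients = fit$coefficients, points = pts,
      residual_norm = sqrt(sum(stats::resid(fit$nls)^2)),
      converged = fit$converged, conf_int = ci,
      fix_hill = fix_hill, nls = fit$nls
    ),
    class = "dose_response_fit"
  )
}

hill_fit_once <- function(pts, fix_hill, fit_bottom) {
  # nb: the dose must not be named `I` inside the nls formula (base::I)
  dose <- pts$irradiance_uW_mm2
  y <- pts$response
  w <- pts$n
  start_bottom <- y[which.min(dose)]
  start_top <- max(y)
  pos <- dose[dose > 0]
  # log-parameterization keeps ec50 (and the Hill slope) positive without
  # box constraints, which nls.lm handles poorly near the optimum
  start_lec50 <- mean(log(pos))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  if (fix_hill && fit_bottom) {
    m <- minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) * dose / (dose + exp(lec50)),
      start = list(bottom = start_bottom, top = start_top, lec50 = start_lec50),
      weights = w, control = ctrl
    )
    co <- c(coef(m)[c("bottom", "top")], ec50 = exp(coef(m)[["lec50"]]), hill_n = 1)
  } else if (fix_hill && !fit_bottom) {
    b0 <- start_bottom
    m <- minpack.lm::nlsLM(
      y ~ b0 + (top - b0) * dose / (dose + exp(lec50)),
      start = list(top = start_top, lec50 = start_lec50),
      weights = w, control = ctrl
    )
    co <- c(bottom = b0, coef(m)["top"], ec50 = exp(coef(m)[["lec50"]]), hill_n = 1)
  } else {
    m <- minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) * dose^exp(lh) /
        (dose^exp(lh) + exp(lec50)^exp(lh)),
      start = list(
        bottom = start_bottom, top = start_top, lec50 = start_lec50,
        lh = 0
      ),
      weights = w, control = ctrl
    )
    co <- c(
      coef(m)[c("bottom", "top")],
      ec50 = exp(coef(m)[["lec50"]]), hill_n = exp(coef(m)[["lh"]])
    )
  }
  co <- setNames(as.numeric(co), c("bottom", "top", "ec50", "hill_n"))
  list(
    coefficients = co, nls = m,
    converged = m$convInfo$isConv %||% TRUE
  )
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
print.dose_response_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "<dose_response_fit> EC50 = %.3g uW/mm2, bottom = %.4g, top = %.4g, hill = %.3g%s\n",
    co[["ec50"]], co[["bottom"]], co[["top"]], co[["hill_n"]],
    if (x$converged) "" else " (NOT converged)"
  ))
  invisible(x)
}

#' @export
tidy.dose_response_fit <- function(x, ...) {
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = as.numeric(x$coefficients)
  )
  if (!is.null(x$conf_int)) {
    ci_terms <- colnames(x$conf_int)
    out$conf.low <- x$conf_int[1, ][match(out$term, ci_terms)]
    out$conf.high <- x$conf_int[2, ][match(out$term, ci_terms)]
  }
  out
}

#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    ec50 = x$coefficients[["ec50"]],
    span = x$coefficients[["top"]] - x$coefficients[["bottom"]],
    residual_norm = x$residual_norm,
    n_points = nrow(x$points),
    converged = x$converged
  )
}

#' Predict the fold response at given irradiances
#'
#' @param fit A [fit_dose_response()] result.
#' @param irradiance_uW_mm2 Irradiance values, µW mm⁻² (>= 0).
#' @return Predicted fold responses.
#' @export
predict_response <- function(fit, irradiance_uW_mm2) {
  if (!fit$converged) abort("fit did not converge; refusing to predict")
  if (any(irradiance_uW_mm2 < 0)) abort("irradiance must be >= 0")
  co <- fit$coefficients
  ih <- irradiance_uW_mm2^co[["hill_n"]]
  co[["bottom"]] + (co[["top"]] - co[["bottom"]]) * ih / (ih + co[["ec50"]]^co[["hill_n"]])
}

#' Plot a dose-response fit
#'
#' @param object A [fit_dose_response()] result.
#' @param ... Unused.
#' @return A ggplot with the measured plateaus and the fitted Hill curve on
#'   a log-like dose axis (zero dose drawn at the left edge).
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  pts <- object$points
  pos <- pts$irradiance_uW_mm2[pts$irradiance_uW_mm2 > 0]
  floor_dose <- min(pos) / 4
  grid <- c(0, exp(seq(log(floor_dose), log(max(pos)), length.out = 120)))
  curve <- tibble::tibble(
    irradiance_uW_mm2 = grid,
    response = predict_response(object, grid)
  )
  shift <- function(x) pmax(x, floor_dose)
  ggplot2::ggplot(pts, ggplot2::aes(shift(.data$irradiance_uW_mm2), .data$response)) +
    ggplot2::geom_line(data = curve, color = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression(irradiance ~ (mu * W ~ mm^-2)),
      y = expression(BPS / BPS[0])
    ) +
    ggplot2::theme_minimal()
}
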