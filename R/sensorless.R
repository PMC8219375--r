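# Sensorless AO: scan amplitudes of each Zernike mode, score each image
# with a quality metric, Gaussian-fit the metric peak, and apply the
# amplitude that maximises it.

#' Scan plan for sensorless correction
#'
#' @param modes Noll indices in correction order.
#' @param amplitudes numeric vector of scan offsets in radians applied to
#'   every mode (default 7 points over +/- 1.5 rad), or a list with one
#'   vector per mode. Each vector needs >= 3 distinct values.
#' @return An object of class `scan_plan`.
#' @export
scan_plan <- function(modes, amplitudes = seq(-1.5, 1.5, length.out = 7)) {
  modes <- as.integer(modes)
  if (length(modes) < 1) stop("need at least one mode")
  if (!is.list(amplitudes))
    amplitudes <- rep(list(as.numeric(amplitudes)), length(modes))
  if (length(amplitudes) != length(modes))
    stop("one amplitude list per mode required")
  for (a in amplitudes)
    if (length(unique(a)) < 3) stop("each amplitude list needs >= 3 distinct values")
  structure(list(modes = modes, amplitudes = amplitudes), class = "scan_plan")
}

#' Fit a Gaussian peak to metric samples
#'
#' Fits `S = offset + height * exp(-(a - centre)^2 / (2 width^2))` by
#' Levenberg-Marquardt least squares. If the fit fails, the height is not
#' positive, or the centre falls outside the scanned range, `fit_ok` is
#' `FALSE` and the best sampled amplitude is returned instead.
#'
#' @param a scanned amplitudes (>= 3 values).
#' @param S metric values at those amplitudes.
#' @return List with `a_max`, `s_max`, `fit_ok` and `fit` (named parameter
#'   vector, or NULL).
#' @export
fit_gaussian_peak <- function(a, S) {
  if (length(a) < 3 || length(S) != length(a))
    stop("need >= 3 (amplitude, metric) samples")
  lo <- min(a); hi <- max(a)
  fallback <- list(a_max = a[which.max(S)], s_max = max(S),
                   fit_ok = FALSE, fit = NULL)
  start <- list(offset = min(S), height = max(S) - min(S),
                centre = a[which.max(S)], width = (hi - lo) / 3)
  if (start$height <= 0) return(fallback)
  fit <- tryCatch(
    minpack.lm::nlsLM(S ~ offset + height * exp(-(a - centre)^2 / (2 * width^2)),
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fallback)
  p <- stats::coef(fit)
  if (!all(is.finite(p)) || p["height"] <= 0 ||
      p["centre"] < lo || p["centre"] > hi)
    return(fallback)
  list(a_max = unname(p["centre"]),
       s_max = unname(p["offset"] + p["height"]),
       fit_ok = TRUE, fit = p)
}

#' Run a sensorless correction routine
#'
#' Three workflows are supported. `sequential_immediate`: for each mode,
#' acquire an image per scan amplitude and score it as soon as it arrives,
#' fit the peak, and fold the mode's correction into all subsequent
#' acquisitions. `sequential_deferred`: identical except all images of the
#' current mode are acquired before any is scored. `simultaneous`: acquire
#' every image for every mode with no intermediate correction, then fit all
#' modes and report the full correction at once.
#'
#' Image acquisition is delegated to `image_fn`, a caller-supplied procedure
#' receiving the absolute [mode_vector()] offset to apply (accumulated
#' correction plus probe amplitude) and returning an image; hardware
#' orchestration stays outside this routine. `image_fn` is called exactly
#' `length(modes) * length(amplitudes)` times in every workflow.
#'
#' @param image_fn function(mode_vector) -> image matrix.
#' @param plan a [scan_plan()].
#' @param metric registered metric name.
#' @param workflow one of `"sequential_immediate"`, `"sequential_deferred"`,
#'   `"simultaneous"`.
#' @param metric_params extra parameters passed to the metric.
#' @return An object of class `scan_result`: list with `per_mode` (one
#'   record per mode: samples, fit, `chosen`), `correction` (the total
#'   correction [mode_vector()]), `workflow`, `metric` and `n_images`.
#' @export
run_sensorless <- function(image_fn, plan, metric = "fourier_power",
                           workflow = c("sequential_immediate",
                                        "sequential_deferred",
                                        "simultaneous"),
                           metric_params = list()) {
  workflow <- match.arg(workflow)
  stopifnot(inherits(plan, "scan_plan"))
  M <- max(plan$modes)
  correction <- numeric(M)
  n_images <- 0L
  per_mode <- vector("list", length(plan$modes))
  names(per_mode) <- plan$modes

  probe <- function(base, mode, amp) {
    v <- base
    v[mode] <- v[mode] + amp
    n_images <<- n_images + 1L
    image_fn(mode_vector(v))
  }
  score_mode <- function(i, base) {
    amps <- plan$amplitudes[[i]]
    mode <- plan$modes[i]
    if (workflow == "sequential_immediate") {
      S <- vapply(amps, function(aj)
        compute_metric(probe(base, mode, aj), metric, metric_params), numeric(1))
    } else {
      imgs <- lapply(amps, function(aj) probe(base, mode, aj))
      S <- vapply(imgs, function(im)
        compute_metric(im, metric, metric_params), numeric(1))
    }
    fit <- fit_gaussian_peak(amps, S)
    # clamp to the scanned range (the fit already falls back when outside)
    chosen <- min(max(fit$a_max, min(amps)), max(amps))
    list(mode = mode, amplitudes = amps, metric_values = S,
         fit = fit$fit, fit_ok = fit$fit_ok, chosen = chosen)
  }

  if (workflow == "simultaneous") {
    for (i in seq_along(plan$modes))
      per_mode[[i]] <- score_mode(i, base = numeric(M))
    for (i in seq_along(plan$modes))
      correction[plan$modes[i]] <- correction[plan$modes[i]] + per_mode[[i]]$chosen
  } else {
    for (i in seq_along(plan$modes)) {
      per_mode[[i]] <- score_mode(i, base = correction)
      correction[plan$modes[i]] <- correction[plan$modes[i]] + per_mode[[i]]$chosen
    }
  }
  structure(list(per_mode = per_mode, correction = mode_vector(correction),
                 workflow = workflow, metric = metric, n_images = n_images),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  ch <- vapply(x$per_mode, `[[`, numeric(1), "chosen")
  cat(sprintf("<scan_result> %s / %s: %d modes, %d images\n",
              x$workflow, x$metric, length(x$per_mode), x$n_images))
  for (i in seq_along(x$per_mode))
    cat(sprintf("  Noll %2d: chosen %+.3f rad (fit %s)\n",
                x$per_mode[[i]]$mode, ch[i],
                if (x$per_mode[[i]]$fit_ok) "ok" else "fallback"))
  invisible(x)
}

#' Tabulate a scan result
#' @param object a [run_sensorless()] result.
#' @param ... unused.
#' @return Data frame with one row per (mode, amplitude) sample plus the
#'   per-mode chosen amplitude and fit flag.
#' @export
summary.scan_result <- function(object, ...) {
  do.call(rbind, lapply(object$per_mode, function(pm)
    data.frame(mode = pm$mode, amplitude = pm$amplitudes,
               metric = pm$metric_values, chosen = pm$chosen,
               fit_ok = pm$fit_ok, row.names = NULL)))
}

#' Wire a sensorless image function to the simulated bench
#'
#' Returns an `image_fn` for [run_sensorless()] that images a synthetic
#' object through a pupil carrying a fixed (unknown to the routine)
#' aberration plus the requested mode offset.
#'
#' @param scope a [sim_scope()].
#' @param aberration a [mode_vector()] of the injected aberration.
#' @param grid_size pupil grid (must match the scope object).
#' @return function(mode_vector) -> image.
#' @export
bench_image_fn <- function(scope, aberration, grid_size = scope$pupil_size) {
  force(scope); force(aberration)
  function(offset) {
    M <- max(max(mode_indices(aberration)), max(mode_indices(offset)))
    total <- mode_amplitudes_full(aberration, M) + mode_amplitudes_full(offset, M)
    image_object(scope, synthesize(mode_vector(total), grid_size))
  }
}
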