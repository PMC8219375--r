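# Closed-loop wavefront flattening by direct sensing: measure the residual,
# fit the selected Zernike modes, add the opposite amplitudes to the
# accumulated correction, apply, repeat.

#' Iterative closed-loop wavefront flattening
#'
#' Each iteration measures the wavefront, records its RMS error, and (unless
#' the threshold stop fires) adds `-gain` times the measured amplitudes of
#' the selected modes to the cumulative correction, which is applied
#' absolutely via [set_phase()]. With `stop_mode = "either"` the loop exits
#' as soon as a measured RMS falls below `rms_threshold`; with
#' `"iterations_only"` it always runs exactly `max_iter` iterations (the
#' photobleaching-conscious choice for sample correction).
#'
#' @param mirror the adaptive element.
#' @param sensor a [sim_sensor()].
#' @param phase_method registered phase-acquisition method name.
#' @param C a [control_matrix()]; installed as the active control matrix.
#' @param modes Noll indices to correct; modes outside this list are never
#'   written to the correction vector.
#' @param max_iter maximum number of iterations N (>= 1).
#' @param rms_threshold RMS stop threshold delta in radians.
#' @param stop_mode `"either"` or `"iterations_only"`.
#' @param gain loop gain applied to each measured residual (default 1).
#' @param aberration optional static [phase_map()] added to the mirror
#'   surface before sensing (the aberration being corrected).
#' @param central_fraction pupil-area fraction for the RMS measure
#'   (default 1 = full pupil).
#' @param phase_params extra parameters for the phase method.
#' @param seed optional sensor-noise seed.
#' @return An object of class `flatten_history`: list with `history` (data
#'   frame: iteration, rms, corrected flag), `measured` and `correction`
#'   (per-iteration [mode_vector()] lists), `final_rms` (measured after the
#'   last applied correction) and `stop_reason`.
#' @export
flatten <- function(mirror, sensor, phase_method = "direct", C, modes,
                    max_iter = 10L, rms_threshold = 0,
                    stop_mode = c("either", "iterations_only"), gain = 1,
                    aberration = NULL, central_fraction = 1,
                    phase_params = list(), seed = NULL) {
  stop_mode <- match.arg(stop_mode)
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (rms_threshold < 0) stop("rms_threshold must be >= 0")
  M <- ncol(C$C)
  modes <- as.integer(modes)
  if (any(modes < 1 | modes > M)) stop("modes outside the calibrated range")
  old_C <- mirror$control_matrix
  mirror$control_matrix <- C
  on.exit(mirror$control_matrix <- old_C)

  measure <- function() {
    total <- phase_add(mirror_surface(mirror), aberration)
    raw <- sense(sensor, total, seed = seed)
    acquire_phase(raw, phase_method, phase_params)
  }

  # resume from the device's current modal request, if any, so repeated
  # flatten calls refine rather than discard an existing correction
  correction <- numeric(M)
  req <- mirror$mode_request
  if (!is.null(req) && length(req) == M) correction <- req
  rms <- numeric(0)
  measured <- list()
  corrections <- list()
  stop_reason <- "iterations_exhausted"
  final_rms <- NA_real_
  for (k in seq_len(max_iter)) {
    ph <- tryCatch(measure(), error = function(e) e)
    if (inherits(ph, "error")) {
      stop_reason <- paste0("phase_acquisition_error: ", conditionMessage(ph))
      break
    }
    rms[k] <- rms_error(ph, central_fraction)
    a_meas <- decompose(ph, M)
    measured[[k]] <- a_meas
    if (stop_mode == "either" && rms[k] < rms_threshold) {
      stop_reason <- "threshold_reached"
      corrections[[k]] <- mode_vector(correction)
      final_rms <- rms[k]
      break
    }
    correction[modes] <- correction[modes] - gain * a_meas$amplitudes[modes]
    corrections[[k]] <- mode_vector(correction)
    set_phase(correction, mirror)
  }
  if (!is.finite(final_rms))
    final_rms <- rms_error(measure(), central_fraction)
  structure(list(
    history = data.frame(iteration = seq_along(rms), rms = rms),
    measured = measured, correction = corrections,
    final_rms = final_rms, stop_reason = stop_reason,
    modes = modes, gain = gain),
    class = "flatten_history")
}

#' @export
print.flatten_history <- function(x, ...) {
  cat(sprintf("<flatten_history> %d iterations, RMS %.4g -> %.4g rad (%s)\n",
              nrow(x$history), x$history$rms[1], x$final_rms, x$stop_reason))
  invisible(x)
}

#' @export
plot.flatten_history <- function(x, ...) {
  graphics::plot(x$history$iteration, x$history$rms, type = "b", log = "y",
                 xlab = "iteration", ylab = "RMS wavefront error (rad)", ...)
  invisible(x)
}
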