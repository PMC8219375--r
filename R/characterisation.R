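# Characterisation: how accurately does the calibrated element recreate
# each Zernike mode, and how much does it couple into the others?

#' Characterise Zernike-mode recreation accuracy
#'
#' For each mode: apply a fixed amplitude through the control matrix,
#' measure the wavefront, decompose it, and store the measured amplitudes
#' normalised by the applied amplitude. Row = applied mode, column =
#' measured mode. The mirror is reset between modes and left flat on exit.
#'
#' @param mirror the adaptive element.
#' @param sensor a [sim_sensor()].
#' @param phase_method registered phase-acquisition method name.
#' @param C a [control_matrix()]; also installed as the device's active
#'   control matrix for the duration of the assay.
#' @param modes Noll indices to assay; defaults to the calibrated modes
#'   minus piston.
#' @param amplitude applied amplitude in radians (default 1).
#' @param phase_params extra parameters for the phase method.
#' @param seed optional sensor-noise seed.
#' @return An object of class `characterisation_assay`: list with `matrix`
#'   (length(modes) x length(modes), radians per unit applied),
#'   `mode_indices`, `applied_amplitude` and `saturated_rows`.
#' @export
characterise <- function(mirror, sensor, phase_method = "direct", C,
                         modes = NULL, amplitude = 1,
                         phase_params = list(), seed = NULL) {
  if (amplitude <= 0) stop("amplitude must be > 0")
  M <- ncol(C$C)
  if (is.null(modes)) modes <- setdiff(C$mode_indices, 1L)
  modes <- as.integer(modes)
  if (any(modes > M)) stop("requested modes exceed the calibrated range")
  old_C <- mirror$control_matrix
  mirror$control_matrix <- C
  on.exit({
    send(mirror, numeric(mirror$n_actuators))
    mirror$control_matrix <- old_C
  })
  n <- length(modes)
  A <- matrix(NA_real_, n, n, dimnames = list(applied = modes, measured = modes))
  sat <- logical(n)
  for (i in seq_len(n)) {
    a <- numeric(M)
    a[modes[i]] <- amplitude
    res <- set_phase(a, mirror)
    sat[i] <- res$saturated
    raw <- sense(sensor, mirror_surface(mirror), seed = seed)
    meas <- decompose(acquire_phase(raw, phase_method, phase_params), M)
    A[i, ] <- meas$amplitudes[modes] / amplitude
    send(mirror, numeric(mirror$n_actuators))
  }
  structure(list(matrix = A, mode_indices = modes,
                 applied_amplitude = amplitude, saturated_rows = sat),
            class = "characterisation_assay")
}

#' @export
print.characterisation_assay <- function(x, ...) {
  d <- diag(x$matrix)
  cat(sprintf("<characterisation_assay> %d modes (Noll %d..%d), diagonal %.3f..%.3f\n",
              length(x$mode_indices), min(x$mode_indices), max(x$mode_indices),
              min(d), max(d)))
  if (any(x$saturated_rows))
    cat(sprintf("  saturation during modes: %s\n",
                paste(x$mode_indices[x$saturated_rows], collapse = ", ")))
  invisible(x)
}

#' @export
plot.characterisation_assay <- function(x, main = "characterisation assay", ...) {
  graphics::image(x$mode_indices, x$mode_indices, t(x$matrix),
                  xlab = "measured Noll index", ylab = "applied Noll index",
                  main = main, ...)
  invisible(x)
}

#' Per-mode accuracy and coupling summary of an assay
#'
#' @param assay a [characterise()] result.
#' @return Data frame with columns `mode`, `accuracy` (diagonal element) and
#'   `coupling` (largest off-diagonal |element| in the mode's row).
#' @export
assay_summary <- function(assay) {
  A <- assay$matrix
  n <- nrow(A)
  coupling <- vapply(seq_len(n), function(i) {
    if (n == 1) 0 else max(abs(A[i, -i]))
  }, numeric(1))
  data.frame(mode = assay$mode_indices, accuracy = diag(A),
             coupling = coupling, row.names = NULL)
}

#' Select well-recreated modes from an assay
#'
#' @param assay a [characterise()] result.
#' @param accuracy_range `(lo, hi)` acceptance band for the diagonal.
#' @param coupling_max maximum tolerated off-diagonal coupling.
#' @return Sorted integer vector of Noll indices passing both criteria
#'   (possibly empty).
#' @export
select_modes <- function(assay, accuracy_range = c(0.75, 1.25),
                         coupling_max = 0.25) {
  if (accuracy_range[1] >= accuracy_range[2])
    stop("accuracy_range must satisfy lo < hi")
  s <- assay_summary(assay)
  sort(s$mode[s$accuracy >= accuracy_range[1] & s$accuracy <= accuracy_range[2] &
                s$coupling <= coupling_max])
}
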