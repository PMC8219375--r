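# Automated calibration: step each actuator through set positions, extract
# the wavefront, decompose into Zernike modes, and regress amplitude against
# control signal to build the influence matrix B (modes x actuators). The
# control matrix C is the thresholded SVD pseudo-inverse of B.

#' Step one actuator and record the modal response
#'
#' All other actuators are held at rest. For each position the signal is
#' sent, a raw sensor image acquired, the phase extracted with the selected
#' phase-acquisition method, and the wavefront decomposed into M Zernike
#' modes, giving one row of the scan matrix.
#'
#' @param h actuator index.
#' @param positions control-signal values (default 5 evenly spaced over
#'   +/- 0.8 of the stroke, keeping clear of the clamp).
#' @param mirror a [make_sim_mirror()] device (or any object supporting
#'   [send()] and [mirror_surface()] with an `n_actuators` field).
#' @param sensor a [sim_sensor()].
#' @param phase_method registered phase-acquisition method name.
#' @param M number of Zernike modes to decompose into.
#' @param phase_params extra parameters for the phase method.
#' @param aberration optional static [phase_map()] added to the mirror
#'   surface before sensing (system aberration).
#' @param seed optional seed forwarded to the sensor noise draw.
#' @return An object of class `actuator_scan`: list with `A` (p x M matrix
#'   of mode amplitudes per position), `positions` and `actuator`.
#' @export
measure_actuator <- function(h, positions = NULL, mirror, sensor,
                             phase_method = "direct", M,
                             phase_params = list(), aberration = NULL,
                             seed = NULL) {
  if (is.null(positions))
    positions <- seq(-0.8, 0.8, length.out = 5) * mirror$stroke_limit
  if (length(positions) < 2) stop("need at least 2 positions")
  if (any(abs(positions) > mirror$stroke_limit))
    stop("calibration positions exceed the stroke limit")
  A <- matrix(NA_real_, length(positions), M)
  d <- numeric(mirror$n_actuators)
  for (i in seq_along(positions)) {
    d[h] <- positions[i]
    send(mirror, d)
    total <- phase_add(mirror_surface(mirror), aberration)
    raw <- sense(sensor, total, seed = seed)
    ph <- tryCatch(acquire_phase(raw, phase_method, phase_params),
                   error = function(e)
                     stop(sprintf("phase acquisition failed at position %d of actuator %d: %s",
                                  i, h, conditionMessage(e))))
    A[i, ] <- decompose(ph, M)$amplitudes
  }
  d[h] <- 0
  send(mirror, d)
  structure(list(A = A, positions = positions, actuator = h),
            class = "actuator_scan")
}

#' Fit one influence-matrix column from an actuator scan
#'
#' Ordinary least squares of mode amplitude against control signal, with an
#' intercept (the rest wavefront need not be flat); only the slope enters B.
#'
#' @param scan an `actuator_scan` from [measure_actuator()].
#' @return List with `slopes` (length-M column of B) and `residuals`
#'   (per-mode residual standard deviation).
#' @export
fit_influence <- function(scan) {
  p <- scan$positions
  if (length(unique(p)) < 2) stop("degenerate positions: all equal")
  X <- cbind(1, p)
  fit <- qr.solve(X, scan$A)            # 2 x M: intercepts, slopes
  res <- scan$A - X %*% fit
  list(slopes = as.numeric(fit[2, ]),
       residuals = sqrt(colMeans(res^2)))
}

#' Calibrate an adaptive element to an influence matrix
#'
#' Loops [measure_actuator()] + [fit_influence()] over all N actuators (N is
#' discovered from the device's `n_actuators` attribute) and assembles B
#' column by column.
#'
#' @inheritParams measure_actuator
#' @param p number of positions per actuator (used when `positions` is NULL).
#' @param positions explicit control-signal values, overriding `p`.
#' @return An object of class `influence_matrix`: list with `B` (M x N),
#'   `mode_indices`, `fit_residuals` (M x N) and `positions`.
#' @export
calibrate <- function(mirror, sensor, phase_method = "direct", p = 5, M,
                      positions = NULL, phase_params = list(),
                      aberration = NULL, seed = NULL) {
  if (is.null(positions))
    positions <- seq(-0.8, 0.8, length.out = p) * mirror$stroke_limit
  N <- mirror$n_actuators
  B <- matrix(NA_real_, M, N)
  R <- matrix(NA_real_, M, N)
  for (h in seq_len(N)) {
    scan <- measure_actuator(h, positions, mirror, sensor, phase_method, M,
                             phase_params, aberration, seed)
    fit <- fit_influence(scan)
    B[, h] <- fit$slopes
    R[, h] <- fit$residuals
  }
  structure(list(B = B, mode_indices = seq_len(M), fit_residuals = R,
                 positions = positions),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix> %d modes x %d actuators, max |B| = %.4g\n",
              nrow(x$B), ncol(x$B), max(abs(x$B))))
  invisible(x)
}

#' Control matrix from an influence matrix
#'
#' Entries of B below `entry_threshold` of the largest |entry| are zeroed
#' (small influences amplify into large actuator demands on inversion), then
#' the Moore-Penrose pseudo-inverse is taken by SVD with a relative
#' singular-value cutoff.
#'
#' @param B an `influence_matrix` (or bare M x N matrix).
#' @param entry_threshold relative entry threshold in [0, 1).
#' @param sv_cutoff relative singular-value cutoff in [0, 1).
#' @return An object of class `control_matrix`: list with `C` (N x M),
#'   `mode_indices`, `entry_threshold`, `sv_cutoff`, `source`.
#' @export
control_matrix <- function(B, entry_threshold = 0.005, sv_cutoff = 0.01) {
  if (entry_threshold < 0 || entry_threshold >= 1 ||
      sv_cutoff < 0 || sv_cutoff >= 1)
    stop("thresholds must be in [0, 1)")
  modes <- if (inherits(B, "influence_matrix")) B$mode_indices else seq_len(nrow(B))
  Bm <- if (inherits(B, "influence_matrix")) B$B else as.matrix(B)
  Bt <- Bm
  Bt[abs(Bt) < entry_threshold * max(abs(Bt))] <- 0
  if (all(Bt == 0)) stop("influence matrix entirely zeroed by threshold")
  sv <- svd(Bt)
  # numerically-zero singular values are always dropped (Moore-Penrose);
  # sv_cutoff tightens the cut relative to the largest singular value
  tol <- max(dim(Bt)) * .Machine$double.eps * sv$d[1]
  keep <- sv$d >= max(sv_cutoff * sv$d[1], tol) & sv$d > 0
  dinv <- ifelse(keep, 1 / sv$d, 0)
  C <- sv$v %*% (dinv * t(sv$u))
  structure(list(C = C, mode_indices = modes,
                 entry_threshold = entry_threshold, sv_cutoff = sv_cutoff,
                 source = "calibration"),
            class = "control_matrix")
}

#' @export
print.control_matrix <- function(x, ...) {
  cat(sprintf("<control_matrix> %d actuators x %d modes (entry thr %.3g, sv cutoff %.3g, %s)\n",
              nrow(x$C), ncol(x$C), x$entry_threshold, x$sv_cutoff, x$source))
  invisible(x)
}

#' Convert mode amplitudes to actuator signals and send them
#'
#' Computes d = C a and sends it to the mirror; clamped actuators raise the
#' saturation flag.
#'
#' @param C a [control_matrix()].
#' @param a a [mode_vector()] (or numeric vector over C's mode indices).
#' @param mirror the adaptive element.
#' @return List with `d` (the requested control vector, before clamping) and
#'   `saturated`.
#' @export
apply_modes <- function(C, a, mirror) {
  M <- ncol(C$C)
  if (inherits(a, "mode_vector")) {
    if (max(mode_indices(a)) > M)
      stop("mode vector extends beyond the calibrated mode range")
    av <- mode_amplitudes_full(a, M)
  } else {
    if (length(a) != M)
      stop(sprintf("expected %d mode amplitudes, got %d", M, length(a)))
    av <- as.numeric(a)
  }
  if (nrow(C$C) != mirror$n_actuators)
    stop("control matrix does not match the device actuator count")
  d <- drop(C$C %*% av)
  send(mirror, d)
  mirror$mode_request <- av
  list(d = d, saturated = mirror$saturated)
}

#' Adopt an externally produced control matrix
#'
#' Installs C as the device's active control matrix (used by [set_phase()]);
#' provenance is marked external.
#'
#' @param mirror the adaptive element.
#' @param C a [control_matrix()] or bare N x M matrix.
#' @param mode_indices Noll indices of C's columns when C is a bare matrix.
#' @return The adopted `control_matrix`, invisibly.
#' @export
set_control_matrix <- function(mirror, C, mode_indices = NULL) {
  if (!inherits(C, "control_matrix")) {
    C <- structure(list(C = as.matrix(C),
                        mode_indices = mode_indices %||% seq_len(ncol(as.matrix(C))),
                        entry_threshold = NA_real_, sv_cutoff = NA_real_,
                        source = "external"),
                   class = "control_matrix")
  } else {
    C$source <- "external"
  }
  if (nrow(C$C) != mirror$n_actuators)
    stop(sprintf("control matrix has %d rows but the device has %d actuators",
                 nrow(C$C), mirror$n_actuators))
  mirror$control_matrix <- C
  invisible(C)
}

#' Set Zernike mode amplitudes directly on the device
#'
#' Convenience composition of [apply_modes()] with the device's active
#' control matrix. Requests are absolute: each call replaces the previous
#' mode request rather than adding to it.
#'
#' @param a a [mode_vector()] (or numeric amplitudes over the active C's
#'   modes).
#' @param mirror the adaptive element; must have an active control matrix
#'   (see [set_control_matrix()]).
#' @return List with `d` and `saturated`, as [apply_modes()].
#' @export
set_phase <- function(a, mirror) {
  C <- mirror$control_matrix
  if (is.null(C))
    stop("no active control matrix; call set_control_matrix() first")
  apply_modes(C, a, mirror)
}
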