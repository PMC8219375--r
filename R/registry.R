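# Runtime registries for phase-acquisition methods and image-quality
# metrics. Both are plain named environments so users can plug in their own
# procedures by name at any time.

.registries <- new.env(parent = emptyenv())

registry_get <- function(kind) {
  reg <- .registries[[kind]]
  if (is.null(reg)) {
    reg <- new.env(parent = emptyenv())
    .registries[[kind]] <- reg
  }
  reg
}

#' Register a phase-acquisition method
#'
#' A method is a function `(raw_image, params)` returning a [phase_map()]
#' matching the raw image geometry.
#'
#' @param name method name used for dispatch.
#' @param fn the procedure.
#' @param overwrite replace an existing entry of the same name?
#' @return `name`, invisibly.
#' @export
register_phase_method <- function(name, fn, overwrite = FALSE) {
  reg <- registry_get("phase")
  if (!overwrite && !is.null(reg[[name]]))
    stop(sprintf("phase method '%s' is already registered", name))
  stopifnot(is.function(fn))
  reg[[name]] <- fn
  invisible(name)
}

#' Register an image-quality metric
#'
#' A metric is a function `(image, params)` returning a finite scalar that
#' increases as image quality improves.
#'
#' @inheritParams register_phase_method
#' @return `name`, invisibly.
#' @export
register_metric <- function(name, fn, overwrite = FALSE) {
  reg <- registry_get("metric")
  if (!overwrite && !is.null(reg[[name]]))
    stop(sprintf("metric '%s' is already registered", name))
  stopifnot(is.function(fn))
  reg[[name]] <- fn
  invisible(name)
}

#' Names of registered phase methods / metrics
#' @return character vector of registered names.
#' @export
phase_methods <- function() sort(ls(registry_get("phase")))

#' @rdname phase_methods
#' @export
metrics <- function() sort(ls(registry_get("metric")))

#' Acquire a phase map from a raw sensor image
#'
#' Dispatches to the named method in the phase-acquisition registry. The
#' active method is a runtime choice: pass a different `method` at any call.
#'
#' @param raw raw sensor image (numeric matrix).
#' @param method registered method name (`"direct"`, `"fourier_fringe"`,
#'   `"shack_hartmann"`, or user-registered).
#' @param params named list of method parameters.
#' @return A [phase_map()].
#' @export
acquire_phase <- function(raw, method = "direct", params = list()) {
  fn <- registry_get("phase")[[method]]
  if (is.null(fn))
    stop(sprintf("unknown phase method '%s'; registered: %s",
                 method, paste(phase_methods(), collapse = ", ")))
  out <- fn(raw, params)
  if (!inherits(out, "phase_map"))
    stop(sprintf("phase method '%s' did not return a phase_map", method))
  out
}

#' Evaluate an image-quality metric
#'
#' @param image image matrix.
#' @param metric registered metric name (`"fourier_power"`, `"contrast"`,
#'   `"sharpness"`, `"max_intensity"`, or user-registered).
#' @param params named list of metric parameters.
#' @return Scalar metric value (larger = better).
#' @export
compute_metric <- function(image, metric = "fourier_power", params = list()) {
  fn <- registry_get("metric")[[metric]]
  if (is.null(fn))
    stop(sprintf("unknown metric '%s'; registered: %s",
                 metric, paste(metrics(), collapse = ", ")))
  val <- fn(image, params)
  if (!is.numeric(val) || length(val) != 1 || !is.finite(val))
    stop(sprintf("metric '%s' did not return a finite scalar", metric))
  as.numeric(val)
}

register_builtins <- function() {
  reg_p <- registry_get("phase")
  if (is.null(reg_p[["direct"]])) {
    register_phase_method("direct", function(raw, params) {
      phase_map(raw, params$mask %||% pupil_mask(nrow(raw)))
    })
    register_phase_method("fourier_fringe", function(raw, params) {
      carrier <- params$carrier %||% 16
      g <- nrow(raw)
      sigma_f <- params$window_sigma %||% (carrier * 0.75)
      wrapped <- fourier_fringe_phase(raw, carrier, window_sigma = sigma_f)
      ph <- unwrap_phase(wrapped)
      # the sideband window smooths over ~g/(2 pi sigma_f) pixels; the
      # outermost ring of the pupil mixes with the (dark) outside and is
      # biased, so refit Zernike modes to an eroded interior and resynthesize
      erode <- params$erode_px %||% ceiling(2 * g / (2 * pi * sigma_f))
      modal <- params$modal_fit %||% 36L
      geom <- pupil_geometry(g)
      inner <- geom$rho <= 1 - 2 * erode / (g - 1)
      a <- decompose(phase_map(ph$values, ph$mask & inner), modal)
      amp <- a$amplitudes
      amp[1:3] <- 0  # piston/tip/tilt are arbitrary under a carrier
      synthesize(mode_vector(amp), g)
    })
    register_phase_method("shack_hartmann", function(raw, params) {
      shack_hartmann_phase(raw, params$reference, params$geometry)
    })
  }
  reg_m <- registry_get("metric")
  if (is.null(reg_m[["fourier_power"]])) {
    register_metric("fourier_power", function(image, params)
      metric_fourier_power(image, params$lo %||% 0.1, params$hi %||% 0.6))
    register_metric("contrast", function(image, params) {
      m <- mean(image)
      if (m <= 0) 0 else stats::sd(image) / m
    })
    register_metric("sharpness", function(image, params) {
      s <- sum(image)
      if (s <= 0) 0 else sum((image / s)^2)
    })
    register_metric("max_intensity", function(image, params) max(image))
  }
}

# fraction of spectral power in a mid/high-frequency annulus
metric_fourier_power <- function(image, lo, hi) {
  P <- Mod(stats::fft(image))^2
  g1 <- nrow(image); g2 <- ncol(image)
  f1 <- ifelse(seq_len(g1) - 1 > g1 / 2, seq_len(g1) - 1 - g1, seq_len(g1) - 1) / g1
  f2 <- ifelse(seq_len(g2) - 1 > g2 / 2, seq_len(g2) - 1 - g2, seq_len(g2) - 1) / g2
  r <- sqrt(outer(f1^2, f2^2, "+")) / 0.5  # fraction of Nyquist
  sum(P[r >= lo & r <= hi]) / sum(P)
}

# Subtract the least-squares fit of the given Noll modes from a phase map.
remove_modes <- function(phase, modes) {
  a <- decompose(phase, max(modes))
  amp <- a$amplitudes
  amp[setdiff(seq_along(amp), modes)] <- 0
  fit <- synthesize(mode_vector(amp), nrow(phase$values))
  phase_map(phase$values - fit$values, phase$mask, phase$pixel_scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.onLoad <- function(libname, pkgname) {
  register_builtins()
}
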