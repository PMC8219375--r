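# Simulated deformable mirror. A sim_mirror is an environment so that
# send() mutates device state in place, mirroring a hardware handle.

#' Construct a simulated deformable mirror
#'
#' Two influence-function models are available. `gaussian_bumps` gives each
#' actuator a Gaussian surface deflection whose width couples neighbouring
#' actuators, emulating a continuous membrane. `linear_zernike` gives each
#' actuator a fixed, known mixture of Zernike modes and records the exact
#' modes-per-signal matrix as `ground_truth_B`, so calibration can be checked
#' against an analytic answer.
#'
#' @param n_actuators number of actuators N (>= 1).
#' @param layout actuator arrangement: `"square_grid"` (N points of a square
#'   lattice closest to the pupil centre) or `"alpao69_like"` (9x9 lattice
#'   with 3 corner points removed per corner, 69 centres inside the pupil).
#' @param mode `"gaussian_bumps"` or `"linear_zernike"`.
#' @param seed integer seed controlling the reproducible random parts
#'   (ground-truth mode mixtures).
#' @param grid_size pupil sampling in pixels.
#' @param influence_sigma Gaussian influence width in pupil-radius units;
#'   default 0.7 x actuator pitch, giving ~40% deflection at the
#'   neighbouring actuator, the coupling regime of commercial membrane
#'   mirrors.
#' @param stroke_limit maximum |control signal|; requests beyond it clamp.
#' @param stroke_scale peak wavefront deflection in radians produced by one
#'   actuator at unit control signal. The default of 40 rad corresponds to
#'   ~3.5 um of mechanical stroke at 543 nm, typical of membrane mirrors.
#' @param n_modes number of Zernike modes in the `linear_zernike` ground
#'   truth (default `n_actuators`).
#' @return An environment of class `sim_mirror` with fields `n_actuators`,
#'   `actuator_centres`, `signals`, `stroke_limit`, `saturated`,
#'   `ground_truth_B` (linear_zernike mode) and the active `control_matrix`
#'   slot (initially `NULL`).
#' @export
make_sim_mirror <- function(n_actuators,
                            layout = c("square_grid", "alpao69_like"),
                            mode = c("gaussian_bumps", "linear_zernike"),
                            seed = 1L,
                            grid_size = 128L,
                            influence_sigma = NULL,
                            stroke_limit = 1,
                            stroke_scale = 40,
                            n_modes = n_actuators) {
  if (n_actuators < 1) stop("n_actuators must be >= 1")
  layout <- match.arg(layout)
  mode <- match.arg(mode)
  cl <- actuator_layout(n_actuators, layout)
  if (is.null(influence_sigma)) influence_sigma <- 0.7 * cl$pitch

  m <- new.env(parent = emptyenv())
  m$n_actuators <- as.integer(n_actuators)
  m$actuator_centres <- cl$centres
  m$influence_sigma <- influence_sigma
  m$stroke_limit <- stroke_limit
  m$stroke_scale <- stroke_scale
  m$signals <- numeric(n_actuators)
  m$saturated <- FALSE
  m$grid_size <- as.integer(grid_size)
  m$mode <- mode
  m$layout <- layout
  m$seed <- as.integer(seed)
  m$control_matrix <- NULL

  geom <- pupil_geometry(grid_size)
  if (mode == "gaussian_bumps") {
    # influence maps over the full grid, one column per actuator
    infl <- vapply(seq_len(n_actuators), function(h) {
      dx <- geom$x - cl$centres[h, 1]
      dy <- geom$y - cl$centres[h, 2]
      stroke_scale * exp(-(dx^2 + dy^2) / (2 * influence_sigma^2))
    }, numeric(grid_size^2))
    m$influence <- infl
    m$ground_truth_B <- NULL
  } else {
    # each actuator drives predominantly one mode plus weak coupling; the
    # stroke scale keeps unit-amplitude mode requests far from the clamp,
    # as on a real membrane mirror whose stroke spans many radians
    m$ground_truth_B <- with_seed(seed, {
      M <- as.integer(n_modes)
      B <- matrix(stats::rnorm(M * n_actuators, sd = 0.05), M, n_actuators)
      k <- seq_len(min(M, n_actuators))
      B[cbind(k, k)] <- B[cbind(k, k)] + stats::runif(length(k), 0.7, 1.3)
      stroke_scale * B
    })
    m$influence <- NULL
  }
  class(m) <- "sim_mirror"
  m
}

#' @export
print.sim_mirror <- function(x, ...) {
  cat(sprintf("<sim_mirror> %d actuators (%s, %s), stroke limit %.3g%s\n",
              x$n_actuators, x$layout, x$mode, x$stroke_limit,
              if (x$saturated) ", SATURATED" else ""))
  invisible(x)
}

actuator_layout <- function(n_actuators, layout) {
  if (layout == "alpao69_like") {
    if (n_actuators != 69)
      stop("alpao69_like layout requires 69 actuators")
    # 9x9 lattice minus 3 points per corner (81 - 12 = 69). The footprint
    # slightly overfills the pupil (outer centres beyond the rim), as on a
    # real bench where the beam underfills the mirror so the pupil edge
    # stays controllable.
    pitch <- 0.28
    pts <- as.matrix(expand.grid(x = (-4:4) * pitch, y = (-4:4) * pitch))
    keep <- !(abs(round(pts[, 1] / pitch)) + abs(round(pts[, 2] / pitch)) >= 7)
    pts <- pts[keep, , drop = FALSE]
    stopifnot(nrow(pts) == 69)
    list(centres = unname(pts), pitch = pitch)
  } else {
    side <- ceiling(sqrt(n_actuators))
    pitch <- 1.8 / max(side - 1, 1)
    ax <- (seq_len(side) - (side + 1) / 2) * pitch
    pts <- as.matrix(expand.grid(x = ax, y = ax))
    ord <- order(rowSums(pts^2), pts[, 1], pts[, 2])
    list(centres = unname(pts[ord[seq_len(n_actuators)], , drop = FALSE]),
         pitch = pitch)
  }
}

#' Send a control vector to a simulated mirror
#'
#' Signals are clamped to the stroke limit; any clamping sets the mirror's
#' `saturated` flag.
#'
#' @param mirror a [make_sim_mirror()] device.
#' @param d numeric control vector of length `n_actuators`.
#' @return The mirror, invisibly.
#' @export
send <- function(mirror, d) {
  if (length(d) != mirror$n_actuators)
    stop(sprintf("control vector has length %d but the mirror has %d actuators",
                 length(d), mirror$n_actuators))
  if (any(!is.finite(d))) stop("control signals must be finite")
  lim <- mirror$stroke_limit
  clamped <- pmin(pmax(d, -lim), lim)
  mirror$saturated <- any(clamped != d)
  mirror$signals <- clamped
  mirror$mode_request <- NULL   # raw signals supersede any modal request
  invisible(mirror)
}

#' Current surface of a simulated mirror
#'
#' Linear superposition of the per-actuator influence functions scaled by the
#' current control signals.
#'
#' @param mirror a [make_sim_mirror()] device.
#' @return A [phase_map()] of the mirror-induced wavefront (radians).
#' @export
mirror_surface <- function(mirror) {
  g <- mirror$grid_size
  if (mirror$mode == "gaussian_bumps") {
    vals <- matrix(drop(mirror$influence %*% mirror$signals), g, g)
    phase_map(vals, pupil_mask(g))
  } else {
    synthesize(mode_vector(drop(mirror$ground_truth_B %*% mirror$signals)), g)
  }
}

# Evaluate one actuator's influence function directly (unit signal).
influence_function <- function(mirror, h) {
  g <- mirror$grid_size
  if (mirror$mode == "gaussian_bumps") {
    phase_map(matrix(mirror$influence[, h], g, g), pupil_mask(g))
  } else {
    synthesize(mode_vector(mirror$ground_truth_B[, h]), g)
  }
}

# Run code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
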