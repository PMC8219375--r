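# Simulated wavefront sensors: direct phase readout, carrier-fringe
# interferometer and Shack-Hartmann spot camera.

#' Construct a simulated wavefront sensor
#'
#' @param mode `"direct_phase"` (phase readout plus optional noise),
#'   `"interferogram"` (carrier fringes along x) or `"shack_hartmann"`
#'   (grid of lenslet spots displaced by the local mean phase gradient).
#' @param carrier_frequency fringes per aperture (interferogram mode).
#' @param lenslet_count lenslets per side (shack_hartmann mode).
#' @param focal_scale spot displacement in pixels per rad/pixel of local
#'   phase gradient (shack_hartmann mode).
#' @param spot_sigma rendered spot width in pixels.
#' @param noise_sigma additive Gaussian noise level on the raw image.
#' @return An object of class `sim_sensor`.
#' @export
sim_sensor <- function(mode = c("direct_phase", "interferogram", "shack_hartmann"),
                       carrier_frequency = 16,
                       lenslet_count = 16L,
                       focal_scale = 20,
                       spot_sigma = 1.5,
                       noise_sigma = 0) {
  mode <- match.arg(mode)
  structure(list(mode = mode, carrier_frequency = carrier_frequency,
                 lenslet_count = as.integer(lenslet_count),
                 focal_scale = focal_scale, spot_sigma = spot_sigma,
                 noise_sigma = noise_sigma),
            class = "sim_sensor")
}

#' @export
print.sim_sensor <- function(x, ...) {
  cat(sprintf("<sim_sensor> %s (noise sigma %.3g)\n", x$mode, x$noise_sigma))
  invisible(x)
}

#' Acquire a raw sensor image of a wavefront
#'
#' @param sensor a [sim_sensor()].
#' @param total_phase a [phase_map()] of the wavefront reaching the sensor.
#' @param seed optional integer seed for the noise draw.
#' @return A numeric matrix: the raw sensor image. For `direct_phase` this is
#'   the phase itself (zero outside the pupil); for `interferogram` an
#'   intensity image `0.5 + 0.5 cos(2 pi f x + phase)` inside the pupil; for
#'   `shack_hartmann` a rendered spot image.
#' @export
sense <- function(sensor, total_phase, seed = NULL) {
  g <- nrow(total_phase$values)
  img <- switch(sensor$mode,
    direct_phase = {
      v <- total_phase$values
      v[!total_phase$mask] <- 0
      v
    },
    interferogram = {
      # carrier along x with an integer number of fringes across the grid,
      # so the sideband falls on an exact FFT bin
      xcol <- matrix((seq_len(g) - 1) / g, g, g, byrow = TRUE)
      carrier <- 2 * pi * sensor$carrier_frequency * xcol
      I <- 0.5 + 0.5 * cos(carrier + total_phase$values)
      I[!total_phase$mask] <- 0
      I
    },
    shack_hartmann = sh_spot_image(sensor, total_phase, reference = FALSE)
  )
  if (sensor$noise_sigma > 0) {
    img <- img + with_seed(seed,
      matrix(stats::rnorm(length(img), sd = sensor$noise_sigma), nrow(img)))
  }
  img
}

#' Reference (flat-wavefront) Shack-Hartmann spot image
#' @param sensor a shack_hartmann [sim_sensor()].
#' @param grid_size image side length in pixels.
#' @return Spot image matrix for a flat wavefront.
#' @export
sh_reference <- function(sensor, grid_size) {
  flat <- phase_map(matrix(0, grid_size, grid_size))
  sh_spot_image(sensor, flat, reference = TRUE)
}

# Lenslet partition of a grid: cell pixel ranges, centres, and validity
# (a cell is valid when at least half its pixels sit inside the pupil).
lenslet_cells <- function(grid_size, lenslet_count) {
  br <- floor(seq(0, grid_size, length.out = lenslet_count + 1))
  mask <- pupil_mask(grid_size)
  cells <- list()
  for (iy in seq_len(lenslet_count)) {
    for (ix in seq_len(lenslet_count)) {
      rows <- (br[iy] + 1):br[iy + 1]
      cols <- (br[ix] + 1):br[ix + 1]
      inmask <- mask[rows, cols]
      cells[[length(cells) + 1]] <- list(
        rows = rows, cols = cols,
        centre = c(mean(rows), mean(cols)),
        valid = mean(inmask) >= 0.5,
        inmask = inmask)
    }
  }
  cells
}

# Mean masked phase gradient (rad/pixel) per lenslet cell. Returns a matrix
# n_cells x 2 (d/dcol, d/drow); NA for invalid cells.
lenslet_gradients <- function(values, mask, cells) {
  g <- nrow(values)
  gx <- matrix(NA_real_, g, g)  # d/dcol
  gy <- matrix(NA_real_, g, g)  # d/drow
  gx[, 2:(g - 1)] <- (values[, 3:g] - values[, 1:(g - 2)]) / 2
  gy[2:(g - 1), ] <- (values[3:g, ] - values[1:(g - 2), ]) / 2
  okx <- matrix(FALSE, g, g); oky <- matrix(FALSE, g, g)
  okx[, 2:(g - 1)] <- mask[, 3:g] & mask[, 1:(g - 2)] & mask[, 2:(g - 1)]
  oky[2:(g - 1), ] <- mask[3:g, ] & mask[1:(g - 2), ] & mask[2:(g - 1), ]
  t(vapply(cells, function(cl) {
    if (!cl$valid) return(c(NA_real_, NA_real_))
    sx <- gx[cl$rows, cl$cols]; vx <- okx[cl$rows, cl$cols]
    sy <- gy[cl$rows, cl$cols]; vy <- oky[cl$rows, cl$cols]
    c(if (any(vx)) mean(sx[vx]) else NA_real_,
      if (any(vy)) mean(sy[vy]) else NA_real_)
  }, numeric(2)))
}

sh_spot_image <- function(sensor, total_phase, reference = FALSE) {
  g <- nrow(total_phase$values)
  cells <- lenslet_cells(g, sensor$lenslet_count)
  grads <- if (reference) NULL
           else lenslet_gradients(total_phase$values, total_phase$mask, cells)
  img <- matrix(0, g, g)
  X <- matrix(seq_len(g), g, g, byrow = TRUE)
  Y <- matrix(seq_len(g), g, g)
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    if (!cl$valid) next
    shift <- if (reference) c(0, 0) else sensor$focal_scale * c(grads[i, 2], grads[i, 1])
    if (any(!is.finite(shift))) next
    sy <- cl$centre[1] + shift[1]
    sx <- cl$centre[2] + shift[2]
    img <- img + exp(-((X - sx)^2 + (Y - sy)^2) / (2 * sensor$spot_sigma^2))
  }
  img
}
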