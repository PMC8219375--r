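# Zernike wavefront core: Noll indexing, mode synthesis, least-squares
# decomposition and RMS error over a circular pupil.

.zk_cache <- new.env(parent = emptyenv())

#' Phase map over a circular pupil
#'
#' A `phase_map` holds a 2D phase image in radians together with the boolean
#' pupil mask on which it is defined. All wavefront operations in the package
#' ignore values outside the mask.
#'
#' @param values numeric matrix of phase values (radians).
#' @param mask logical matrix of the same dimension marking pupil pixels.
#'   Defaults to the standard centred disc for the grid.
#' @param pixel_scale pupil-radius fraction per pixel. Defaults to
#'   `2 / (nrow(values) - 1)` (pupil diameter spans the grid).
#' @return An object of class `phase_map` with fields `values`, `mask`
#'   and `pixel_scale`.
#' @export
phase_map <- function(values, mask = NULL, pixel_scale = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- pupil_mask(nrow(values))
  if (!is.logical(mask) || !identical(dim(mask), dim(values)))
    stop("mask must be a logical matrix with the same dimensions as values")
  if (any(!is.finite(values[mask])))
    stop("phase values must be finite inside the mask")
  if (is.null(pixel_scale)) pixel_scale <- 2 / (nrow(values) - 1)
  structure(list(values = values, mask = mask, pixel_scale = pixel_scale),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map> %dx%d grid, %d pupil pixels, RMS %.4g rad\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              tryCatch(rms_error(x), error = function(e) NA_real_)))
  invisible(x)
}

#' @export
plot.phase_map <- function(x, main = "phase (rad)", ...) {
  v <- x$values
  v[!x$mask] <- NA
  graphics::image(t(v[nrow(v):1, ]), asp = 1, axes = FALSE, main = main, ...)
  invisible(x)
}

#' Noll-indexed Zernike amplitude vector
#'
#' @param amplitudes numeric vector of mode amplitudes in radians, contiguous
#'   in Noll order starting at `first_index`.
#' @param first_index lowest Noll index represented (default 1, piston).
#' @return An object of class `mode_vector`.
#' @export
mode_vector <- function(amplitudes, first_index = 1L) {
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) < 1) stop("mode_vector needs at least one amplitude")
  first_index <- as.integer(first_index)
  if (first_index < 1) stop("first_index must be >= 1")
  structure(list(amplitudes = amplitudes, first_index = first_index),
            class = "mode_vector")
}

#' @export
print.mode_vector <- function(x, ...) {
  j <- mode_indices(x)
  cat(sprintf("<mode_vector> Noll %d..%d, RMS amplitude %.4g rad\n",
              min(j), max(j), sqrt(sum(x$amplitudes[j > 1]^2))))
  invisible(x)
}

#' Noll indices covered by a mode vector
#' @param a a `mode_vector`.
#' @return integer vector of Noll indices.
#' @export
mode_indices <- function(a) {
  seq(a$first_index, length.out = length(a$amplitudes))
}

# Amplitudes of `a` re-indexed onto Noll indices 1..M (zeros elsewhere).
mode_amplitudes_full <- function(a, M) {
  out <- numeric(M)
  j <- mode_indices(a)
  keep <- j <= M
  out[j[keep]] <- a$amplitudes[keep]
  out
}

#' Convert a Noll index to radial degree and azimuthal frequency
#'
#' Standard Noll ordering: modes are sorted by radial degree n, within a
#' degree by increasing |m|; of the two modes with the same |m| the even
#' Noll index carries the cosine term (m > 0) and the odd index the sine
#' term (m < 0).
#'
#' @param j positive integer Noll index (scalar or vector).
#' @return A matrix with columns `n` and `m`, one row per index.
#' @export
noll_to_nm <- function(j) {
  if (length(j) < 1 || !is.numeric(j) || any(!is.finite(j)) ||
      any(j < 1) || any(j != round(j)))
    stop("Noll index must be a positive integer")
  jmax <- max(j)
  tab <- noll_table(jmax)
  out <- tab[j, , drop = FALSE]
  rownames(out) <- NULL
  out
}

noll_table <- function(jmax) {
  cached <- .zk_cache$noll
  if (!is.null(cached) && nrow(cached) >= jmax)
    return(cached[seq_len(jmax), , drop = FALSE])
  tab <- matrix(0L, jmax, 2, dimnames = list(NULL, c("n", "m")))
  k <- 0L
  n <- 0L
  while (k < jmax) {
    for (am in seq(n %% 2L, n, by = 2L)) {
      if (am == 0L) {
        k <- k + 1L
        if (k <= jmax) tab[k, ] <- c(n, 0L)
      } else {
        for (i in 1:2) {
          k <- k + 1L
          if (k <= jmax) tab[k, ] <- c(n, if (k %% 2L == 0L) am else -am)
        }
      }
    }
    n <- n + 1L
  }
  .zk_cache$noll <- tab
  tab
}

# Noll-normalised Zernike polynomial evaluated at polar coordinates.
# Unit coefficient <=> unit RMS phase over the continuous unit disc.
zernike_eval <- function(j, rho, theta) {
  nm <- noll_to_nm(j)
  n <- nm[1, "n"]; m <- nm[1, "m"]
  am <- abs(m)
  R <- numeric(length(rho))
  for (k in 0:((n - am) / 2)) {
    R <- R + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) * factorial((n - am) / 2 - k)) *
      rho^(n - 2 * k)
  }
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  if (m == 0) norm * R
  else if (m > 0) norm * R * cos(am * theta)
  else norm * R * sin(am * theta)
}

# Pixel-centre pupil geometry: pupil centred at (g-1)/2 with radius (g-1)/2.
pupil_geometry <- function(grid_size) {
  key <- paste0("geom", grid_size)
  g <- .zk_cache[[key]]
  if (!is.null(g)) return(g)
  r <- (grid_size - 1) / 2
  ax <- (seq_len(grid_size) - 1 - r) / r
  x <- matrix(ax, grid_size, grid_size, byrow = TRUE)   # column coordinate
  y <- matrix(ax, grid_size, grid_size)                 # row coordinate
  rho <- sqrt(x^2 + y^2)
  g <- list(x = x, y = y, rho = rho, theta = atan2(y, x), mask = rho <= 1)
  .zk_cache[[key]] <- g
  g
}

#' Standard centred pupil mask for a square grid
#' @param grid_size grid side length in pixels.
#' @return logical matrix marking the centred disc.
#' @export
pupil_mask <- function(grid_size) pupil_geometry(grid_size)$mask

# Masked Zernike basis (pupil pixels x M), grown lazily and cached per grid.
zernike_basis <- function(grid_size, M) {
  key <- paste0("basis", grid_size)
  b <- .zk_cache[[key]]
  if (is.null(b) || ncol(b) < M) {
    geom <- pupil_geometry(grid_size)
    rho <- geom$rho[geom$mask]
    theta <- geom$theta[geom$mask]
    have <- if (is.null(b)) 0L else ncol(b)
    add <- vapply(seq(have + 1L, M), function(j) zernike_eval(j, rho, theta),
                  numeric(length(rho)))
    b <- cbind(b, add)
    .zk_cache[[key]] <- b
  }
  b[, seq_len(M), drop = FALSE]
}

zernike_qr <- function(grid_size, M) {
  key <- paste0("qr", grid_size, "_", M)
  q <- .zk_cache[[key]]
  if (is.null(q)) {
    q <- qr(zernike_basis(grid_size, M))
    .zk_cache[[key]] <- q
  }
  q
}

#' Sample a single Zernike mode on the unit disc
#'
#' @param j Noll index (positive integer).
#' @param grid_size grid side length in pixels (>= 8).
#' @return A [phase_map()] of the Noll-normalised mode: unit coefficient
#'   gives unit RMS phase over the pupil.
#' @export
zernike_map <- function(j, grid_size) {
  if (grid_size < 8) stop("grid_size must be >= 8")
  a <- mode_vector(c(rep(0, j - 1), 1))
  synthesize(a, grid_size)
}

#' Synthesize a wavefront from Zernike amplitudes
#'
#' Linear superposition of Noll-normalised modes weighted by the amplitudes,
#' sampled on the standard centred pupil.
#'
#' @param a a [mode_vector()].
#' @param grid_size grid side length in pixels.
#' @return A [phase_map()]; values outside the pupil are zero.
#' @export
synthesize <- function(a, grid_size) {
  if (!inherits(a, "mode_vector")) a <- mode_vector(a)
  M <- max(mode_indices(a))
  B <- zernike_basis(grid_size, M)
  geom <- pupil_geometry(grid_size)
  vals <- matrix(0, grid_size, grid_size)
  vals[geom$mask] <- drop(B %*% mode_amplitudes_full(a, M))
  phase_map(vals, geom$mask)
}

#' Decompose a wavefront into Zernike modes
#'
#' Least-squares fit of Noll modes 1..M to the masked pixels of a phase map.
#' Truncation residual (out-of-range modes) is expected, not an error.
#'
#' @param phase a [phase_map()].
#' @param M number of modes to fit (Noll 1..M).
#' @return A [mode_vector()] of length M starting at Noll index 1.
#' @export
decompose <- function(phase, M) {
  if (M < 1) stop("M must be >= 1")
  npix <- sum(phase$mask)
  if (npix == 0) stop("phase mask is empty")
  if (npix < M) stop("underdetermined fit: mask has fewer pixels than modes")
  g <- nrow(phase$values)
  std <- nrow(phase$values) == ncol(phase$values) &&
    identical(phase$mask, pupil_geometry(g)$mask)
  y <- phase$values[phase$mask]
  if (std) {
    co <- qr.coef(zernike_qr(g, M), y)
  } else {
    geom <- mask_polar(phase$mask)
    Z <- vapply(seq_len(M), function(j) zernike_eval(j, geom$rho, geom$theta),
                numeric(npix))
    co <- qr.coef(qr(Z), y)
  }
  mode_vector(as.numeric(co))
}

# Polar coordinates of masked pixels for a non-standard mask, using the
# standard grid convention of the enclosing array.
mask_polar <- function(mask) {
  g <- nrow(mask)
  r <- (g - 1) / 2
  idx <- which(mask, arr.ind = TRUE)
  x <- (idx[, 2] - 1 - r) / r
  y <- (idx[, 1] - 1 - r) / r
  list(rho = sqrt(x^2 + y^2), theta = atan2(y, x))
}

#' RMS wavefront error
#'
#' Root-mean-square of the mean-subtracted phase over the pupil, optionally
#' restricted to a central sub-disc containing `central_fraction` of the
#' pupil area (radius scaled by `sqrt(central_fraction)`).
#'
#' @param phase a [phase_map()].
#' @param central_fraction fraction of pupil area to use, in (0, 1].
#'   `1` uses the full mask.
#' @return RMS error in radians.
#' @export
rms_error <- function(phase, central_fraction = 1) {
  if (central_fraction <= 0 || central_fraction > 1)
    stop("central_fraction must be in (0, 1]")
  eff <- phase$mask
  if (central_fraction < 1) {
    g <- nrow(phase$values)
    eff <- eff & (pupil_geometry(g)$rho <= sqrt(central_fraction))
  }
  if (!any(eff)) stop("effective mask is empty")
  v <- phase$values[eff]
  sqrt(mean((v - mean(v))^2))
}

# Elementwise sum of two phase maps sharing a grid (masks intersected).
phase_add <- function(p1, p2) {
  if (is.null(p1)) return(p2)
  if (is.null(p2)) return(p1)
  stopifnot(identical(dim(p1$values), dim(p2$values)))
  phase_map(p1$values + p2$values, p1$mask & p2$mask, p1$pixel_scale)
}
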