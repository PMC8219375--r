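# Carrier-fringe interferogram demodulation (Fourier method) and 2D phase
# unwrapping for centred circular pupils.

#' Demodulate a carrier-fringe interferogram
#'
#' Fourier fringe analysis: transform the interferogram, isolate the
#' positive-carrier sideband with a Gaussian window, shift it to the origin
#' and take the argument of the inverse transform. The DC term is suppressed
#' beforehand by subtracting the mean intensity over the pupil.
#'
#' @param interferogram raw intensity image (square matrix).
#' @param carrier carrier frequency in fringes per aperture (>= ~8 at grid
#'   256 so the sideband separates from DC).
#' @param window_sigma Gaussian window width in frequency bins; default
#'   half the carrier distance.
#' @param mask pupil mask; default the standard centred disc.
#' @return A [phase_map()] of wrapped phase in (-pi, pi].
#' @export
fourier_fringe_phase <- function(interferogram, carrier, window_sigma = NULL,
                                 mask = NULL) {
  g <- nrow(interferogram)
  if (is.null(mask)) mask <- pupil_mask(g)
  if (is.null(window_sigma)) window_sigma <- carrier / 2
  I <- interferogram
  I[!mask] <- 0
  I[mask] <- I[mask] - mean(I[mask])
  S <- stats::fft(I)
  # signed frequency bins along rows (kx varies along columns here since the
  # carrier runs along the x/column axis)
  kx <- ifelse(seq_len(g) - 1 > g / 2, seq_len(g) - 1 - g, seq_len(g) - 1)
  KX <- matrix(kx, g, g, byrow = TRUE)
  KY <- matrix(kx, g, g)
  band <- KX >= ceiling(carrier / 2) & KX <= min(2 * carrier, floor(g / 2) - 1)
  if (!any(band)) stop("carrier out of range for this grid")
  mag <- Mod(S)
  peak <- which(band & mag == max(mag[band]), arr.ind = TRUE)[1, ]
  px <- KX[peak[1], peak[2]]; py <- KY[peak[1], peak[2]]
  if (mag[peak[1], peak[2]] < 5 * mean(mag[band]))
    stop("demodulation error: carrier peak not found above background")
  W <- exp(-((KX - px)^2 + (KY - py)^2) / (2 * window_sigma^2))
  Ssb <- S * W
  # shift the sideband to the origin: circular roll by (-py rows, -px cols)
  Ssb <- roll_matrix(Ssb, -py, -px)
  wrapped <- Arg(stats::fft(Ssb, inverse = TRUE))
  phase_map(wrapped, mask)
}

roll_matrix <- function(x, dr, dc) {
  n1 <- nrow(x); n2 <- ncol(x)
  r <- ((seq_len(n1) - 1 - dr) %% n1) + 1
  c <- ((seq_len(n2) - 1 - dc) %% n2) + 1
  x[r, c]
}

#' Unwrap a wrapped phase map
#'
#' Removes 2-pi discontinuities inside the pupil. The centre row is
#' unwrapped first, then every column is unwrapped outward anchored on its
#' centre-row pixel; for a centred disc every masked column crosses the
#' centre row, so the result is continuous and equals the input modulo 2 pi
#' everywhere inside the mask.
#'
#' @param wrapped a [phase_map()] with values in (-pi, pi].
#' @return A [phase_map()] of continuous phase.
#' @export
unwrap_phase <- function(wrapped) {
  v <- wrapped$values
  mask <- wrapped$mask
  g <- nrow(v)
  out <- v
  rc <- which.max(rowSums(mask))  # centre row
  cols <- which(mask[rc, ])
  out[rc, cols] <- unwrap_1d(v[rc, cols])
  for (cc in which(colSums(mask) > 0)) {
    rows <- which(mask[, cc])
    r0 <- rows[1]; r1 <- rows[length(rows)]
    anchor_row <- if (mask[rc, cc]) rc else rows[which.min(abs(rows - rc))]
    seg <- v[r0:r1, cc]
    useg <- unwrap_1d(seg)
    # re-anchor so the centre-row pixel keeps its row-unwrapped value
    if (mask[rc, cc]) {
      k <- round((useg[anchor_row - r0 + 1] - out[rc, cc]) / (2 * pi))
    } else {
      k <- round((useg[anchor_row - r0 + 1] - v[anchor_row, cc]) / (2 * pi))
    }
    out[r0:r1, cc] <- useg - 2 * pi * k
  }
  phase_map(out, mask, wrapped$pixel_scale)
}

unwrap_1d <- function(v) {
  if (length(v) < 2) return(v)
  d <- diff(v)
  v + c(0, cumsum(-2 * pi * round(d / (2 * pi))))
}

#' Reconstruct a phase map from Shack-Hartmann spot images
#'
#' Per-lenslet intensity centroids are compared to the reference image; the
#' displacements give local wavefront gradients which are fitted modally to
#' Zernike gradients and re-synthesized into a phase map.
#'
#' @param spots spot image of the aberrated wavefront.
#' @param reference_spots spot image of a flat wavefront on the same lenslet
#'   grid (see [sh_reference()]).
#' @param geometry list with `lenslet_count`, `focal_scale`, and optionally
#'   `n_modes` (default 15) and `min_signal` (fraction of the strongest
#'   lenslet's summed intensity below which a lenslet is excluded,
#'   default 0.05).
#' @return A [phase_map()]; the fitted amplitudes are attached as attribute
#'   `"mode_vector"` and excluded lenslets as `"excluded"`.
#' @export
shack_hartmann_phase <- function(spots, reference_spots, geometry) {
  g <- nrow(spots)
  if (!identical(dim(spots), dim(reference_spots)))
    stop("spot and reference images must share a lenslet grid")
  nl <- geometry$lenslet_count
  fs <- geometry$focal_scale
  n_modes <- geometry$n_modes %||% 15L
  min_signal <- geometry$min_signal %||% 0.05
  cells <- lenslet_cells(g, nl)
  spot_sigma <- geometry$spot_sigma %||% 1.5
  # cell-bounded first guess, then an iterated Gaussian-weighted centroid:
  # the weight window tracks the estimate continuously, so a spot displaced
  # toward a cell edge is not biased by hard truncation, and neighbouring
  # spots are suppressed by the weight roll-off
  sw <- 2 * spot_sigma
  box <- ceiling(3 * sw)
  cent <- function(img, cl) {
    sub <- img[cl$rows, cl$cols]
    s <- sum(sub)
    if (s <= 0) return(c(NA_real_, NA_real_, 0))
    ry <- sum(sub * cl$rows) / s
    rx <- sum(t(sub) * cl$cols) / s
    for (pass in 1:4) {
      rows <- max(1, round(ry) - box):min(g, round(ry) + box)
      cols <- max(1, round(rx) - box):min(g, round(rx) + box)
      w <- img[rows, cols] *
        exp(-(outer((rows - ry)^2, (cols - rx)^2, "+")) / (2 * sw^2))
      s2 <- sum(w)
      if (s2 <= 0) break
      ry <- sum(w * rows) / s2
      rx <- sum(t(w) * cols) / s2
    }
    c(ry, rx, s)
  }
  valid <- vapply(cells, function(cl) cl$valid, logical(1))
  cm <- t(vapply(cells, function(cl) cent(spots, cl), numeric(3)))
  cr <- t(vapply(cells, function(cl) cent(reference_spots, cl), numeric(3)))
  smax <- max(cm[valid, 3], 0)
  ok <- valid & cm[, 3] > min_signal * smax & cr[, 3] > 0 &
    is.finite(cm[, 1]) & is.finite(cr[, 1])
  if (sum(ok) <= sum(valid) / 2)
    stop("reconstruction error: more than half of the lenslets have no signal")
  # gradients in rad/pixel: rows -> d/dy, cols -> d/dx
  gy <- (cm[ok, 1] - cr[ok, 1]) / fs
  gx <- (cm[ok, 2] - cr[ok, 2]) / fs
  # modal fit against per-lenslet mean gradients of the Zernike basis
  mask <- pupil_mask(g)
  G <- vapply(2:n_modes, function(j) {
    zm <- zernike_map(j, g)
    zg <- lenslet_gradients(zm$values, mask, cells)
    c(zg[ok, 1], zg[ok, 2])  # (d/dx, d/dy) stacked
  }, numeric(2 * sum(ok)))
  rhs <- c(gx, gy)
  use <- is.finite(rhs) & apply(is.finite(G), 1, all)
  co <- qr.coef(qr(G[use, , drop = FALSE]), rhs[use])
  co[!is.finite(co)] <- 0
  a <- mode_vector(c(0, co))
  out <- synthesize(a, g)
  attr(out, "mode_vector") <- a
  attr(out, "excluded") <- which(valid & !ok)
  out
}
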