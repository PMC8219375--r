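# Simulated incoherent microscope: Fourier-optics PSF from the pupil phase,
# convolution with a synthetic object, optional photon noise.

#' Construct a simulated microscope
#'
#' @param object non-negative 2D image of the sample (matrix). Its dimensions
#'   must match the pupil grid used for imaging.
#' @param photon_scale expected counts at the brightest pixel of the
#'   noiseless image.
#' @param poisson_noise logical; draw Poisson counts if `TRUE`.
#' @return An object of class `sim_scope`.
#' @export
sim_scope <- function(object, photon_scale = 1000, poisson_noise = FALSE) {
  object <- as.matrix(object)
  if (any(!is.finite(object)) || any(object < 0))
    stop("object must be finite and non-negative")
  g <- nrow(object)
  # fixed exposure: photon_scale counts at the brightest pixel of the
  # diffraction-limited (flat-pupil) image
  psf0 <- psf_from_phase(phase_map(matrix(0, g, ncol(object))))
  ref <- Re(stats::fft(stats::fft(object) * stats::fft(fft_shift(psf0)),
                       inverse = TRUE)) / length(psf0)
  structure(list(object = object, pupil_size = g,
                 photon_scale = photon_scale, poisson_noise = poisson_noise,
                 scale = photon_scale / max(ref)),
            class = "sim_scope")
}

#' Incoherent point-spread function of an aberrated pupil
#'
#' PSF = |inverse Fourier transform of (pupil mask x exp(i phase))|^2,
#' normalised to unit sum and centred in the array.
#'
#' @param pupil_phase a [phase_map()].
#' @return A numeric matrix summing to 1.
#' @export
psf_from_phase <- function(pupil_phase) {
  P <- pupil_phase$mask * exp(1i * pupil_phase$values)
  psf <- Mod(stats::fft(P, inverse = TRUE))^2
  psf <- fft_shift(psf)
  psf / sum(psf)
}

#' Image a synthetic object through an aberrated pupil
#'
#' The object is convolved (circularly) with the incoherent PSF of the given
#' pupil phase and scaled so the brightest pixel of the aberration-free image
#' equals `photon_scale`.
#'
#' @param scope a [sim_scope()].
#' @param pupil_phase a [phase_map()] with the same grid size as the object.
#' @param seed optional seed for the Poisson draw.
#' @return Image matrix (counts).
#' @export
image_object <- function(scope, pupil_phase, seed = NULL) {
  if (nrow(scope$object) != nrow(pupil_phase$values))
    stop("object and pupil grids must match")
  psf <- psf_from_phase(pupil_phase)
  img <- Re(stats::fft(stats::fft(scope$object) * stats::fft(fft_shift(psf)),
                       inverse = TRUE)) / length(psf)
  img[img < 0] <- 0
  img <- img * scope$scale
  if (scope$poisson_noise)
    img <- with_seed(seed, matrix(stats::rpois(length(img), img), nrow(img)))
  img
}

# Centre the zero-frequency / PSF peak of an FFT array.
fft_shift <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  s1 <- floor(n1 / 2); s2 <- floor(n2 / 2)
  x[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

#' Draw a reproducible random aberration with a prescribed RMS
#'
#' Amplitudes on the requested Noll modes are drawn from a standard normal
#' and rescaled so the synthesized wavefront has exactly the target RMS
#' (measured with [rms_error()] on the sampling grid).
#'
#' @param modes integer vector of Noll indices.
#' @param target_rms target RMS wavefront error in radians.
#' @param seed integer seed.
#' @param grid_size grid used to measure the RMS during rescaling.
#' @return A [mode_vector()] covering `min(modes)..max(modes)` (zeros on
#'   modes not requested).
#' @export
random_aberration <- function(modes, target_rms, seed = 1L, grid_size = 128L) {
  if (target_rms < 0) stop("target_rms must be >= 0")
  if (length(modes) == 0) {
    if (target_rms > 0) stop("empty mode list with positive target_rms")
    return(mode_vector(0))
  }
  modes <- sort(as.integer(modes))
  amp <- numeric(max(modes) - min(modes) + 1)
  if (target_rms > 0) {
    draw <- with_seed(seed, stats::rnorm(length(modes)))
    amp[modes - min(modes) + 1] <- draw
    a <- mode_vector(amp, first_index = min(modes))
    measured <- rms_error(synthesize(a, grid_size))
    amp <- amp * target_rms / measured
  }
  mode_vector(amp, first_index = min(modes))
}

#' Synthetic bead-field object for sensorless tests
#'
#' A reproducible scatter of Gaussian beads on a dark background.
#'
#' @param grid_size image side length in pixels.
#' @param n_beads number of beads.
#' @param bead_sigma bead width in pixels.
#' @param seed integer seed.
#' @return Non-negative image matrix with unit peak.
#' @export
bead_object <- function(grid_size = 64L, n_beads = 25L, bead_sigma = 1.2,
                        seed = 42L) {
  pos <- with_seed(seed,
    matrix(stats::runif(2 * n_beads, grid_size * 0.1, grid_size * 0.9), ncol = 2))
  X <- matrix(seq_len(grid_size), grid_size, grid_size, byrow = TRUE)
  Y <- matrix(seq_len(grid_size), grid_size, grid_size)
  img <- matrix(0, grid_size, grid_size)
  for (i in seq_len(n_beads))
    img <- img + exp(-((X - pos[i, 1])^2 + (Y - pos[i, 2])^2) / (2 * bead_sigma^2))
  img / max(img)
}
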