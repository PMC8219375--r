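# Shared fixtures: small simulated benches built in code.

# Small noiseless linear bench with an exact control matrix.
tiny_linear_bench <- function(n = 9, grid = 64, seed = 3) {
  mirror <- make_sim_mirror(n, "square_grid", "linear_zernike",
                            seed = seed, grid_size = grid)
  sensor <- sim_sensor("direct_phase")
  B <- calibrate(mirror, sensor, "direct", p = 5, M = n)
  C <- control_matrix(B, 0, 0)
  set_control_matrix(mirror, C)
  list(mirror = mirror, sensor = sensor, B = B, C = C, grid = grid,
       M = as.integer(n))
}

# Gaussian blur of an image by FFT (kernel sigma in pixels).
blur_image <- function(img, sigma) {
  g <- nrow(img)
  ax <- c(0:(g / 2), (-g / 2 + 1):(-1))
  K <- exp(-outer(ax^2, ax^2, "+") / (2 * sigma^2))
  K <- K / sum(K)
  Re(stats::fft(stats::fft(img) * stats::fft(K), inverse = TRUE)) / g^2
}
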