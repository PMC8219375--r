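# Influence-matrix calibration, control-matrix inversion, device control.

test_that("fit_influence matches a brute-force regression oracle", {
  # exact linear data recovers the generating slope
  pos <- seq(-0.8, 0.8, length.out = 5)
  A <- outer(pos, c(0.3, -1.2, 0)) + rep(c(0.1, -0.4, 2), each = 5)
  scan <- structure(list(A = A, positions = pos, actuator = 1L),
                    class = "actuator_scan")
  fit <- fit_influence(scan)
  expect_equal(fit$slopes, c(0.3, -1.2, 0), tolerance = 1e-12)
  expect_lt(max(fit$residuals), 1e-12)
  # random 5-point data vs explicit normal equations
  set.seed(13)
  An <- matrix(stats::rnorm(15), 5, 3)
  scan$A <- An
  X <- cbind(1, pos)
  oracle <- solve(t(X) %*% X, t(X) %*% An)[2, ]
  expect_equal(fit_influence(scan)$slopes, as.numeric(oracle),
               tolerance = 1e-10)
  scan$positions <- rep(0.2, 5)
  expect_error(fit_influence(scan), "degenerate")
})

test_that("measure_actuator rows respond linearly on the linear bench", {
  b <- tiny_linear_bench()
  scan <- measure_actuator(3, c(-1, 1), b$mirror, b$sensor, "direct", M = b$M)
  expect_equal(scan$A[2, ] - scan$A[1, ], 2 * b$mirror$ground_truth_B[, 3],
               tolerance = 1e-9)
  # all positions zero -> identical rows
  scan0 <- measure_actuator(2, c(0, 0, 0), b$mirror, b$sensor, "direct",
                            M = b$M)
  expect_lt(max(abs(sweep(scan0$A, 2, scan0$A[1, ]))), 1e-12)
  expect_error(measure_actuator(1, c(-2, 2), b$mirror, b$sensor, "direct",
                                M = b$M), "stroke")
})

test_that("calibration recovers the ground-truth influence matrix", {
  b <- tiny_linear_bench()
  expect_identical(dim(b$B$B), c(b$M, 9L))
  expect_lt(max(abs(b$B$B - b$mirror$ground_truth_B)), 1e-8)
  # works unchanged for a different actuator count (N from the device)
  b4 <- make_sim_mirror(4, "square_grid", "linear_zernike", seed = 9,
                        grid_size = 48)
  B4 <- calibrate(b4, sim_sensor("direct_phase"), "direct", p = 3, M = 4)
  expect_identical(dim(B4$B), c(4L, 4L))
  expect_lt(max(abs(B4$B - b4$ground_truth_B)), 1e-8)
})

test_that("control_matrix satisfies pseudo-inverse identities", {
  b <- tiny_linear_bench()
  C <- control_matrix(b$B, 0, 0)
  expect_lt(max(abs(C$C %*% b$B$B - diag(b$M))), 1e-8)
  expect_lt(max(abs(b$B$B %*% C$C %*% b$B$B - b$B$B)), 1e-8)
  # rectangular case: Moore-Penrose property still holds
  set.seed(3)
  Br <- matrix(stats::rnorm(7 * 4), 7, 4)
  Cr <- control_matrix(Br, 0, 0)
  expect_lt(max(abs(Br %*% Cr$C %*% Br - Br)), 1e-8)
  expect_error(control_matrix(Br, 1, 0), "thresholds")
  expect_error(control_matrix(matrix(1e-9, 3, 3) * 0, 0, 0), "zeroed")
})

test_that("entry thresholding suppresses demands for unsensed modes", {
  # an element that cannot drive its last modes at all: their B rows are
  # pure measurement noise, which unthresholded inversion turns into huge
  # actuator demands
  set.seed(5)
  B <- matrix(stats::rnorm(30 * 30, sd = 0.05), 30, 30)
  diag(B) <- diag(B) + stats::runif(30, 0.7, 1.3)
  B[26:30, ] <- 0
  Bn <- B + matrix(stats::rnorm(900, sd = 1e-3), 30, 30)
  C0 <- control_matrix(Bn, 0, 0)$C
  C1 <- control_matrix(Bn, 0.01, 0)$C
  expect_lt(max(abs(C1)), max(abs(C0)))
})

test_that("apply_modes, set_control_matrix and set_phase obey the contract", {
  b <- tiny_linear_bench()
  a <- mode_vector(c(0, 0.3, -0.2, 0.5))
  res <- apply_modes(b$C, a, b$mirror)
  # independent matrix-vector oracle
  av <- c(0, 0.3, -0.2, 0.5, rep(0, b$M - 4))
  expect_equal(res$d, as.numeric(b$C$C %*% av), tolerance = 1e-12)
  expect_false(res$saturated)
  # zero request, zero signals
  expect_true(all(apply_modes(b$C, numeric(b$M), b$mirror)$d == 0))
  # dimension mismatches error
  expect_error(apply_modes(b$C, numeric(b$M + 1), b$mirror), "amplitudes")
  wrongC <- control_matrix(matrix(stats::rnorm(25), 5, 5), 0, 0)
  expect_error(set_control_matrix(b$mirror, wrongC), "actuators")
  # an adopted external matrix drives subsequent set_phase calls
  ext <- b$C
  set_control_matrix(b$mirror, ext)
  expect_identical(b$mirror$control_matrix$source, "external")
  r1 <- set_phase(av, b$mirror)
  expect_equal(r1$d, res$d)
  # set_phase is absolute, not cumulative
  a2 <- numeric(b$M); a2[2] <- 1
  set_phase(a2, b$mirror)
  r3 <- set_phase(av, b$mirror)
  expect_equal(r3$d, res$d, tolerance = 1e-12)
  # large requests saturate
  big <- numeric(b$M); big[2] <- 1e4
  expect_true(set_phase(big, b$mirror)$saturated)
  m0 <- make_sim_mirror(4, "square_grid", "gaussian_bumps", grid_size = 32)
  expect_error(set_phase(numeric(4), m0), "no active control matrix")
})

test_that("closed-loop round trip reproduces requested modes exactly", {
  b <- tiny_linear_bench()
  set.seed(17)
  for (rep in 1:3) {
    a <- c(0, stats::rnorm(b$M - 1, sd = 0.5))
    set_phase(a, b$mirror)
    meas <- decompose(mirror_surface(b$mirror), b$M)
    expect_lt(max(abs(meas$amplitudes[-1] - a[-1])), 1e-6)
  }
})
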