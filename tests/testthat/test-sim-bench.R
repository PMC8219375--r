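# Simulated mirror, sensors and image formation.

test_that("mirror construction is reproducible and geometrically sane", {
  m1 <- make_sim_mirror(69, "alpao69_like", "gaussian_bumps", seed = 5,
                        grid_size = 64)
  m2 <- make_sim_mirror(69, "alpao69_like", "gaussian_bumps", seed = 5,
                        grid_size = 64)
  expect_equal(m1$actuator_centres, m2$actuator_centres)
  expect_identical(dim(m1$actuator_centres), c(69L, 2L))
  # footprint covers the pupil: actuators out to and beyond the rim
  radii <- sqrt(rowSums(m1$actuator_centres^2))
  expect_gt(max(radii), 1)
  expect_lt(min(radii), 0.2)
  expect_error(make_sim_mirror(68, "alpao69_like", "gaussian_bumps"),
               "requires 69")
  expect_error(make_sim_mirror(9, "hexagonal", "gaussian_bumps"))
})

test_that("mirror surface is the linear superposition of influence functions", {
  m <- make_sim_mirror(9, "square_grid", "gaussian_bumps", seed = 2,
                       grid_size = 48)
  send(m, numeric(9))
  expect_true(all(mirror_surface(m)$values == 0))
  d <- seq(-0.4, 0.4, length.out = 9)
  send(m, d)
  s1 <- mirror_surface(m)$values
  send(m, 2 * d)
  expect_equal(mirror_surface(m)$values, 2 * s1, tolerance = 1e-12)
  # single actuator at 0.5 equals half its influence function
  d0 <- numeric(9); d0[4] <- 0.5
  send(m, d0)
  infl <- aokit:::influence_function(m, 4)
  expect_equal(mirror_surface(m)$values, 0.5 * infl$values, tolerance = 1e-12)
})

test_that("send validates, clamps and reports saturation", {
  m <- make_sim_mirror(4, "square_grid", "gaussian_bumps", grid_size = 32)
  expect_error(send(m, c(0, 0)), "4 actuators")
  send(m, c(1.5, 0, 0, 0))
  expect_true(m$saturated)
  expect_equal(m$signals[1], 1)
  send(m, c(0.5, 0, 0, 0))
  expect_false(m$saturated)
})

test_that("linear_zernike mirror matches its ground-truth response exactly", {
  m <- make_sim_mirror(9, "square_grid", "linear_zernike", seed = 4,
                       grid_size = 64)
  set.seed(8)
  for (rep in 1:3) {
    d <- stats::runif(9, -1, 1)
    send(m, d)
    measured <- decompose(mirror_surface(m), 9)
    expect_lt(max(abs(measured$amplitudes - m$ground_truth_B %*% d)), 1e-10)
  }
})

test_that("direct and interferometric sensing behave as specified", {
  g <- 64
  ph <- synthesize(mode_vector(c(0, 0, 0, 0.7)), g)
  s <- sim_sensor("direct_phase")
  raw <- sense(s, ph)
  expect_equal(raw[ph$mask], ph$values[ph$mask])
  # flat phase gives straight fringes: intensity constant down each column
  si <- sim_sensor("interferogram", carrier_frequency = 8)
  I <- sense(si, phase_map(matrix(0, g, g)))
  for (cc in c(20, 32, 44)) {
    col <- I[, cc][ph$mask[, cc]]
    expect_lt(max(col) - min(col), 1e-12)
  }
  # noise is reproducible under a fixed seed
  sn <- sim_sensor("direct_phase", noise_sigma = 0.1)
  expect_identical(sense(sn, ph, seed = 9), sense(sn, ph, seed = 9))
  expect_false(identical(sense(sn, ph, seed = 9), sense(sn, ph, seed = 10)))
})

test_that("Shack-Hartmann spots shift uniformly under pure tilt", {
  g <- 128
  s <- sim_sensor("shack_hartmann", lenslet_count = 16, focal_scale = 20)
  amp <- 0.5
  tilt <- synthesize(mode_vector(c(0, amp)), g)
  ref <- sh_reference(s, g)
  # analytic: Z2 = 2x has gradient 2 amp / R rad/pixel along x, so every
  # spot shifts focal_scale * that many pixels; recover it from the images
  shift <- 20 * 2 * amp / ((g - 1) / 2)
  geo <- list(lenslet_count = 16, focal_scale = 20, n_modes = 10)
  rec <- shack_hartmann_phase(sense(s, tilt), ref, geo)
  a <- attr(rec, "mode_vector")$amplitudes
  expect_equal(a[2], amp, tolerance = 0.1)
  # and a synthetic uniform shift of the reference itself is pure tilt at
  # exactly the analytic slope (integer roll keeps centroids exact)
  shifted <- ref[, c(g, 1:(g - 1))]   # +1 pixel along x
  rec2 <- shack_hartmann_phase(shifted, ref, geo)
  a2 <- attr(rec2, "mode_vector")$amplitudes
  expect_equal(a2[2], (1 / 20) * (g - 1) / 2 / 2, tolerance = 0.05)
  expect_lt(max(abs(a2[-2])), 0.15 * abs(a2[2]))
})

test_that("PSF and image formation conserve flux and peak when unaberrated", {
  g <- 64
  flat <- phase_map(matrix(0, g, g))
  psf <- psf_from_phase(flat)
  expect_equal(sum(psf), 1, tolerance = 1e-12)
  obj <- bead_object(g)
  scope <- sim_scope(obj, photon_scale = 500)
  img0 <- image_object(scope, flat)
  expect_equal(max(img0), 500, tolerance = 1e-9)
  # circular convolution with a unit-sum PSF conserves total flux
  img1 <- image_object(scope, synthesize(mode_vector(c(0, 0, 0, 1)), g))
  expect_equal(sum(img1), sum(obj) * scope$scale, tolerance = 1e-6)
  expect_equal(sum(img0), sum(img1), tolerance = 1e-6)
  # the unaberrated image is the sharpest across single-mode aberrations
  s0 <- compute_metric(img0, "sharpness")
  for (j in 4:8) {
    a <- numeric(j); a[j] <- 1
    expect_lt(compute_metric(image_object(scope, synthesize(mode_vector(a), g)),
                             "sharpness"), s0)
  }
})

test_that("random aberrations hit the requested RMS reproducibly", {
  a1 <- random_aberration(5:29, 2.0, seed = 6)
  a2 <- random_aberration(5:29, 2.0, seed = 6)
  expect_identical(a1, a2)
  expect_equal(rms_error(synthesize(a1, 128)), 2.0, tolerance = 1e-6)
  expect_true(all(random_aberration(3:10, 0, seed = 1)$amplitudes == 0))
  expect_error(random_aberration(integer(0), 1), "empty mode list")
  # amplitudes only on the requested modes
  a3 <- random_aberration(c(4, 6, 9), 1.0, seed = 2)
  full <- aokit:::mode_amplitudes_full(a3, 9)
  expect_true(all(full[c(1:3, 5, 7, 8)] == 0))
})
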