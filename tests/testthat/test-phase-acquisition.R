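# Registry dispatch, fringe demodulation, unwrapping, Shack-Hartmann
# reconstruction.

test_that("registry dispatches by name and accepts user methods", {
  g <- 32
  ph <- synthesize(mode_vector(c(0, 0, 0, 0.5)), g)
  raw <- sense(sim_sensor("direct_phase"), ph)
  got <- acquire_phase(raw, "direct")
  expect_equal(got$values[got$mask], ph$values[ph$mask])
  expect_error(acquire_phase(raw, "nope"), "direct")
  register_phase_method("testmethod_halved",
                        function(raw, params) phase_map(raw / 2),
                        overwrite = TRUE)
  half <- acquire_phase(raw, "testmethod_halved")
  expect_equal(half$values, raw / 2)
  expect_true("testmethod_halved" %in% phase_methods())
  # dispatcher is pure routing
  direct_fn_result <- phase_map(raw, pupil_mask(g))
  expect_equal(acquire_phase(raw, "direct")$values, direct_fn_result$values)
})

test_that("fringe demodulation recovers a flat and wrapped phases", {
  g <- 128
  si <- sim_sensor("interferogram", carrier_frequency = 16)
  flat <- phase_map(matrix(0, g, g))
  w <- fourier_fringe_phase(sense(si, flat), 16)
  expect_lt(stats::sd(w$values[w$mask]), 0.05)
  expect_true(all(w$values >= -pi & w$values <= pi))
  # adding 2*pi to the phase leaves the wrapped output unchanged (up to the
  # floating-point identity cos(x + 2*pi) != cos(x), amplified at the rim)
  ph <- synthesize(mode_vector(c(0, 0, 0, 0.8)), g)
  ph2 <- phase_map(ph$values + 2 * pi, ph$mask)
  w1 <- fourier_fringe_phase(sense(si, ph), 16)
  w2 <- fourier_fringe_phase(sense(si, ph2), 16)
  inner <- aokit:::pupil_geometry(g)$rho < 0.9
  dd <- (w1$values - w2$values)[w1$mask & inner]
  expect_lt(max(abs(dd - 2 * pi * round(dd / (2 * pi)))), 1e-3)
})

test_that("unwrapping restores continuity and preserves values mod 2pi", {
  g <- 96
  # plane spanning 6*pi across the pupil
  plane <- synthesize(mode_vector(c(0, 3 * pi / 2)), g)
  wrapped <- phase_map(((plane$values + pi) %% (2 * pi)) - pi, plane$mask)
  un <- unwrap_phase(wrapped)
  # output mod 2pi equals input everywhere
  dd <- (un$values - wrapped$values)[un$mask]
  expect_lt(max(abs(dd - 2 * pi * round(dd / (2 * pi)))), 1e-9)
  # recovered surface is the plane up to a constant
  resid <- (un$values - plane$values)[un$mask]
  expect_lt(max(resid) - min(resid), 0.01)
  # an already-continuous map with range < 2pi is returned unchanged
  small <- synthesize(mode_vector(c(0, 0.4, 0.3)), g)
  expect_equal(unwrap_phase(small)$values[small$mask],
               small$values[small$mask], tolerance = 1e-12)
})

test_that("interferometric round trip recovers known aberrations", {
  g <- 256
  # the carrier must exceed the steepest phase slope, so it scales with the
  # aberration strength
  cases <- list(c(rms = 1, carrier = 16), c(rms = 2, carrier = 32),
                c(rms = 3, carrier = 48))
  for (cs in cases) {
    ab <- random_aberration(2:20, cs["rms"], seed = 21)
    truth <- synthesize(ab, g)
    si <- sim_sensor("interferogram", carrier_frequency = cs["carrier"])
    rec <- acquire_phase(sense(si, truth), "fourier_fringe",
                         list(carrier = cs["carrier"]))
    truth_pt <- aokit:::remove_modes(truth, 1:3)
    err <- phase_map(rec$values - truth_pt$values, rec$mask)
    expect_lt(rms_error(err), 0.05)
  }
})

test_that("Shack-Hartmann reconstruction handles flat, defocus and dropout", {
  g <- 128
  s <- sim_sensor("shack_hartmann", lenslet_count = 16, focal_scale = 20)
  ref <- sh_reference(s, g)
  geo <- list(lenslet_count = 16, focal_scale = 20, n_modes = 15)
  # identical images -> flat phase
  rec0 <- shack_hartmann_phase(ref, ref, geo)
  expect_lt(rms_error(rec0), 1e-6)
  # defocus recovered within 5%
  for (amp in c(0.5, 1)) {
    truth <- synthesize(mode_vector(c(0, 0, 0, amp)), g)
    rec <- shack_hartmann_phase(sense(s, truth), ref, geo)
    expect_equal(attr(rec, "mode_vector")$amplitudes[4], amp,
                 tolerance = 0.05 * amp)
  }
  # starved lenslets are excluded; too many starved is an error
  dark <- ref * 0
  expect_error(shack_hartmann_phase(dark, ref, geo), "half")
})
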