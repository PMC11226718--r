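test_that("reduced-unit conversions are exact and round-trip", {
  expect_identical(reduced_energy(0), 0)
  expect_equal(reduced_energy(0.51099895), 1)
  expect_equal(reduced_energy(51.099895), 100)
  E <- exp(seq(log(1e-3), log(1500), length.out = 50))
  expect_equal(from_reduced_energy(reduced_energy(E)), E,
               tolerance = 1e-14)
  expect_error(reduced_energy(-1), "non-negative")
})

test_that("velocity beta has the closed form, limits and monotonicity", {
  expect_identical(velocity_beta(0), 0)
  expect_equal(velocity_beta(1), sqrt(3) / 2, tolerance = 1e-14)
  expect_equal(velocity_beta(1e6), 1, tolerance = 1e-6)
  e <- exp(seq(log(1e-4), log(1e4), length.out = 200))
  b <- velocity_beta(e)
  expect_true(all(diff(b) > 0))
  expect_true(all(b < 1))
})

test_that("collisional stopping power matches a second coding of the closed form", {
  w <- material("water")
  ## independent second path: Bethe-Moller assembled term by term
  oracle <- function(E) {
    tau <- E / MEC2_T
    beta2 <- tau * (tau + 2) / (tau + 1)^2
    Ired <- w$I_eV * 1e-6 / MEC2_T
    Fm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
    0.153536 * w$ZA / beta2 *
      (2 * log(tau / Ired) + log(tau) + log(1 + 2 / tau) - log(2) + Fm -
         density_effect_delta(E, w))
  }
  for (E in c(0.1, 1, 10, 100, 1000))
    expect_equal(collisional_stopping_power(E, w), oracle(E),
                 tolerance = 1e-3)
})

test_that("macroscopic collisional stopping power is linear in density", {
  m1 <- material(composition = c(H = 0.111894, O = 0.888106), rho = 1,
                 I = 75)
  m2 <- material(composition = c(H = 0.111894, O = 0.888106), rho = 2,
                 I = 75)
  ## same delta: switch the density effect off for exact linearity
  s1 <- m1$rho * collisional_stopping_power(50, m1, density_effect = FALSE)
  s2 <- m2$rho * collisional_stopping_power(50, m2, density_effect = FALSE)
  expect_equal(s2, 2 * s1, tolerance = 1e-14)
})

test_that("switching off the density effect recovers the uncorrected form", {
  w <- material("water")
  E <- 100
  diff_s <- collisional_stopping_power(E, w, density_effect = FALSE) -
    collisional_stopping_power(E, w)
  expect_equal(diff_s, 0.153536 * w$ZA /
                 velocity_beta(reduced_energy(E))^2 *
                 density_effect_delta(E, w), tolerance = 1e-12)
  expect_gt(density_effect_delta(E, w), 0)
  expect_identical(density_effect_delta(0.01, w), 0)
})

test_that("bremsstrahlung kernel and radiative stopping power vanish at Z = 0", {
  expect_equal(berger_seltzer_ddcs(10, c(0.1, 1, 4), 0), rep(0, 3))
})

test_that("radiative/collisional ratio grows with energy in water", {
  w <- material("water")
  E <- c(10, 50, 200, 1000)
  r <- radiative_stopping_power(E, w) / collisional_stopping_power(E, w)
  expect_true(all(diff(r) > 0))
})

test_that("radiative stopping power agrees between quadrature orders", {
  w <- material("water")
  s96 <- radiative_stopping_power(100, w, nodes = 96)
  s192 <- radiative_stopping_power(100, w, nodes = 192)
  expect_equal(s96, s192, tolerance = 1e-6)
})

test_that("total stopping power is continuous over 1 keV .. 1.5 GeV", {
  w <- material("water")
  E <- exp(seq(log(1e-3), log(1500), length.out = 400))
  S <- collisional_stopping_power(E, w) + radiative_stopping_power(E, w)
  expect_true(all(S > 0))
  step_ratio <- abs(diff(log(S)))
  ## adjacent grid points are 3.6% apart in energy; a smooth curve moves
  ## much less than 5% per step and a fit-boundary jump would spike
  expect_lt(max(step_ratio), 0.05)
})

test_that("CSDA range integrates the reciprocal stopping power", {
  w <- material("water")
  expect_identical(csda_range(1e-3, w), 0)
  R <- csda_range(c(1, 10, 100), w)
  expect_true(all(diff(R) > 0))
  ## refinement oracle: 10x finer panels
  r1 <- csda_range(20, w)
  r2 <- csda_range(20, w, panels = 80L)
  expect_equal(r1, r2, tolerance = 1e-3)
})

test_that("group structures are log-spaced with exact bounds", {
  gs <- build_group_structure(300, E_max = 100)
  expect_length(gs$bounds, 301)
  expect_true(all(diff(gs$bounds) > 0))
  expect_equal(gs$bounds_MeV[301], 100)
  expect_equal(gs$bounds_MeV[1], 1e-3)
  r <- gs$bounds[-1] / gs$bounds[-301]
  expect_equal(max(r) / min(r) - 1, 0, tolerance = 1e-12)
  gs3 <- build_group_structure(3, E_max = 10)
  expect_length(gs3$bounds, 4)
  expect_true(all(gs3$width > 0))
  expect_error(build_group_structure(2, E_max = 10), "3 groups")
})

test_that("material construction validates fractions and applies Bragg additivity", {
  expect_error(material(composition = c(H = 0.5, O = 0.4), rho = 1),
               "sum to 1")
  w <- material("water")
  expect_equal(w$I_eV, 75)
  b <- material("bone")
  expect_gt(b$I_eV, 75)  # heavier constituents raise the mean excitation
  expect_error(material("unobtainium"), "unknown material")
})
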