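test_that("Elwert factor has the soft-photon, neutral and monotone properties", {
  expect_equal(elwert_factor(2, 1e-9, 29), 1, tolerance = 1e-6)
  expect_identical(elwert_factor(2, 0.5, 0), 1)
  k <- seq(0.01, 1.9, length.out = 100)
  f <- elwert_factor(2, k, 79)
  expect_true(all(diff(f) > 0))
})

test_that("Coulomb correction reproduces the series and the Z = 82 value", {
  expect_identical(coulomb_f(0), 0)
  Z <- 0:98
  expect_true(all(diff(coulomb_f(Z)) > 0))
  ## independent direct summation of the series
  a2 <- (82 / 137.035999084)^2
  ref <- a2 * (1 / (1 + a2) + 0.20206 - 0.0369 * a2 + 0.0083 * a2^2 -
                 0.002 * a2^3)
  expect_equal(coulomb_f(82), ref, tolerance = 1e-14)
  expect_equal(coulomb_f(82), 0.332, tolerance = 0.002)
  expect_error(coulomb_f(120), "0..99")
})

test_that("screening functions take the complete-screening constants and merge", {
  p0 <- screening_phis(0)
  expect_equal(p0$phi1, 20.867)
  expect_equal(p0$phi2, 20.029)
  p100 <- screening_phis(100)
  expect_equal(p100$phi1 - p100$phi2, 0, tolerance = 1e-12)
  ## continuity across the blended fit pieces
  z <- seq(0, 3, by = 1e-3)
  p <- screening_phis(z)
  expect_lt(max(abs(diff(p$phi1))), 1e-2)
  expect_lt(max(abs(diff(p$phi2))), 1e-2)
})

test_that("assembled cross section vanishes at the high-frequency limit", {
  el <- element_record("Cu")
  ep <- 50
  expect_equal(berger_seltzer_ddcs(ep, ep, el, e_gamma_max = ep), 0)
  near <- berger_seltzer_ddcs(ep, 0.9999 * ep, el, e_gamma_max = ep)
  mid <- berger_seltzer_ddcs(ep, 0.5 * ep, el, e_gamma_max = ep)
  expect_lt(near, 0.05 * mid)
})

test_that("assembled cross section scales as 1/e_gamma for soft photons", {
  el <- element_record("Cu")
  r <- berger_seltzer_ddcs(50, 1e-4, el) / berger_seltzer_ddcs(50, 2e-4, el)
  expect_equal(r, 2, tolerance = 0.02)
})

test_that("the omega-weighted assembly is a convex combination", {
  cmp <- bfpdose:::brems_components(100, c(1, 10, 50), 29)
  lo <- cmp$s1 + cmp$s2 - cmp$s3              # omega = 0
  hi <- cmp$s1 + cmp$s4 - cmp$s3              # omega = 1
  w <- bfpdose:::brems_omega(100)
  mid <- cmp$s1 + cmp$s2 - cmp$s3 + w * (cmp$s4 - cmp$s2)
  expect_true(all(mid <= pmax(lo, hi) + 1e-30))
  expect_true(all(mid >= pmin(lo, hi) - 1e-30))
})

test_that("screened and Coulomb-corrected kernels differ by the f(Z) term", {
  cmp <- bfpdose:::brems_components(40, c(2, 10, 30), 79)
  et <- 41; es <- et - c(2, 10, 30)
  r <- es / et
  pref <- 79 * 80 * (2.8179403262e-13)^2 / (137.035999084 * c(2, 10, 30))
  ident <- 4 * pref * coulomb_f(79) * (1 + r^2 - 2 / 3 * r)
  expect_equal(cmp$s2 - cmp$s4, ident, tolerance = 1e-12)
})

test_that("bremsstrahlung transfers obey the catastrophic rule and close in energy", {
  gs <- build_group_structure(14, E_max = 20)
  el <- element_record("Cu")
  tr <- build_brems_transfer(gs, 3L, el, nodes = 12L)
  for (gp in seq_len(gs$G))
    if (gp >= 2L) expect_equal(tr$b0[gp, (gp - 1L):gs$G],
                               rep(0, gs$G - gp + 2L))
  expect_true(tr$forward)
  expect_true(all(tr$b0 >= 0))
  expect_equal(tr$Egamma, tr$A1 - tr$Eout, tolerance = 1e-14)
  ## independent photon-energy quadrature for one emitting group
  gp <- 12L
  b <- gs$bounds
  f <- function(ep) {
    stats::integrate(function(ee)
      (ep - ee) * berger_seltzer_ddcs(ep, ep - ee, el,
                                      e_gamma_max = ep - b[2]),
      b[2], b[gp - 2L], rel.tol = 1e-9)$value
  }
  ref <- stats::integrate(Vectorize(f), b[gp], b[gp + 1L],
                          rel.tol = 1e-8)$value / gs$width[gp]
  expect_equal(tr$Egamma[gp], ref, tolerance = 1e-5)
})

test_that("transfer entries reproduce adaptive 2D quadrature", {
  gs <- build_group_structure(14, E_max = 20)
  el <- element_record("Cu")
  tr <- build_brems_transfer(gs, 3L, el, nodes = 16L)
  b <- gs$bounds
  set.seed(11)
  checked <- 0L
  for (k in 1:8) {
    gp <- sample(6:14, 1)
    g <- sample(seq_len(gp - 3L), 1)
    val <- tr$b0[gp, g]
    if (val == 0) next
    f <- function(ep, ee)
      berger_seltzer_ddcs(ep, ep - ee, el, e_gamma_max = ep - b[2])
    ref <- pracma::integral2(f, b[gp], b[gp + 1L],
                             max(b[g], b[2]), b[g + 1L],
                             reltol = 1e-10)$Q / gs$width[gp]
    expect_equal(val, ref, tolerance = 1e-6)
    checked <- checked + 1L
  }
  expect_gte(checked, 6L)
})
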