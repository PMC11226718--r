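test_that("Gauss-Legendre sets are normalised, symmetric and Galerkin-exact", {
  q <- gauss_legendre(16)
  expect_equal(sum(q$w), 2, tolerance = 1e-14)
  expect_equal(q$mu, -rev(q$mu), tolerance = 1e-14)
  q2 <- gauss_legendre(2)
  expect_equal(sort(q2$mu), c(-1, 1) / sqrt(3), tolerance = 1e-14)
  expect_equal(q2$w, c(1, 1), tolerance = 1e-14)
  ## discrete orthogonality for all retained orders with N = L + 1
  P <- bfpdose:::legendre_table(q$mu, 15L)
  Gm <- t(P) %*% (q$w * P)
  ref <- diag(2 / (2 * (0:15) + 1))
  expect_equal(Gm, ref, tolerance = 1e-13, ignore_attr = TRUE)
  expect_error(gauss_legendre(1), ">= 2")
})

test_that("single-cell solves reproduce the printed closed forms", {
  r <- sweep_cell(0, dx = 1, mu = 1, sigt = 1, Lsrc = 1, psi_in = 1)
  expect_equal(r$psi, 1)
  expect_equal(r$psi_out, 1)
  ## free streaming at any order
  for (M in 0:2) {
    r <- sweep_cell(M, 1, 0.5, 0, rep(0, M + 1), psi_in = 2)
    expect_equal(r$psi[1], 2, tolerance = 1e-14)
    expect_equal(r$psi_out, 2, tolerance = 1e-14)
  }
  ## M = 1 with zero first-moment source reduces to the M = 0 average
  r1 <- sweep_cell(1, 1, 1, 1, c(1, 0), psi_in = 1)
  expect_equal(r1$psi[1], 1, tolerance = 1e-14)
  ## mirror symmetry: mu < 0 equals the mirrored mu > 0 cell
  rp <- sweep_cell(1, 1, 0.7, 0.9, c(1.3, 0.4), psi_in = 0.8)
  rm <- sweep_cell(1, 1, -0.7, 0.9, c(1.3, -0.4), psi_in = 0.8)
  expect_equal(rm$psi, rp$psi * c(1, -1), tolerance = 1e-14)
  expect_equal(rm$psi_out, rp$psi_out, tolerance = 1e-14)
})

test_that("weighted-diamond energy propagation has the printed algebra", {
  expect_equal(energy_propagation(2, 2, 5, 3), 2 * 5 - 3)
  expect_equal(energy_propagation(1.3, 0.7, 4, 4), 4)
  expect_error(energy_propagation(0, 0, 1, 1), "cannot both vanish")
  expect_error(energy_propagation(1, 0, 1, 1), "absorbed")
})

test_that("scattering source reduces to Sigma0 phi / 2 for isotropic scatter", {
  q <- gauss_legendre(8)
  s <- scattering_source(c(3, 0, 0, 0), c(0.5, 0, 0, 0), q$mu)
  expect_equal(s, rep(0.5 * 3 / 2, 8))
  expect_equal(scattering_source(rep(0, 4), rep(1, 4), q$mu), rep(0, 8))
  withcsd <- scattering_source(c(0, 0), c(0, 0), q$mu,
                               csd = list(beta_plus = 2, dE = 0.5,
                                          psi_plus = rep(1, 8)))
  expect_equal(withcsd, rep(8, 8))
})

test_that("the discrete angular Fokker-Planck operator conserves and relaxes", {
  q <- gauss_legendre(8)
  expect_equal(angular_fp(0.3, rep(2, 8), q), rep(0, 8), tolerance = 1e-14)
  set.seed(5)
  psi <- runif(8)
  out <- angular_fp(0.4, psi, q)
  expect_equal(sum(q$w * out), 0, tolerance = 1e-13)
  ## pseudo-time relaxation toward isotropy, monotone in L2
  iso <- sum(q$w * psi) / 2
  d <- numeric(40)
  cur <- psi
  for (k in 1:40) {
    cur <- cur + 0.05 * angular_fp(1, cur, q)
    d[k] <- sqrt(sum(q$w * (cur - iso)^2))
  }
  expect_true(all(diff(d) < 1e-12))
  expect_lt(d[40], 0.05 * d[1])
})

test_that("pure absorber solves converge at the expected spatial orders", {
  gs <- build_group_structure(3, E_max = 10)
  q4 <- gauss_legendre(4)
  cellavg <- function(mu, sig, x0, x1)
    (exp(-sig * x0 / mu) - exp(-sig * x1 / mu)) * mu / sig / (x1 - x0)
  run <- function(M, nv) {
    pb <- slab_problem(list(list(material = "toy", thickness = 2)),
                       voxels = nv, N = 4, L = 3, M = M, tol = 1e-12,
                       max_inner = 500, beam = "boundary-flux")
    lib <- toy_library(gs, 3L, sigt = 1)
    sol <- solve_bfp(pb, setNames(list(lib), "toy"), source_group = 3)
    phi <- solution_phi(sol, 0)[3, ]
    mu <- q4$mu[4]
    x0 <- sol$mesh$x_mid - sol$mesh$dx / 2
    x1 <- sol$mesh$x_mid + sol$mesh$dx / 2
    ref <- q4$w[4] * cellavg(mu, 1, x0, x1) / (q4$w[4] * mu)
    max(abs(phi - ref) / max(ref))
  }
  e0 <- vapply(c(20, 40, 80), run, 0, M = 0)
  e1 <- vapply(c(20, 40), run, 0, M = 1)
  ## observed orders: ratio ~4 for M = 0 (2nd), >= 8 for M = 1 (>= 3rd)
  expect_gt(e0[1] / e0[2], 3.4)
  expect_gt(e0[2] / e0[3], 3.4)
  expect_gt(e1[1] / e1[2], 8)
})

test_that("a vacuum problem with no source stays identically zero", {
  gs <- build_group_structure(3, E_max = 10)
  lib <- toy_library(gs, 3L, sigt = 0.5)
  pb <- slab_problem(list(list(material = "toy", thickness = 1)),
                     voxels = 8, N = 4, L = 3, M = 1)
  sol <- solve_bfp(pb, setNames(list(lib), "toy"), source_group = 2)
  ## source in group 2: group 3 above it has no source at all
  expect_equal(max(abs(solution_phi(sol, 0)[3, ])), 0)
})

test_that("per-group particle balance holds at the sweep algebra level", {
  lib <- csd_only_water_library(40, 10)
  R <- cached_csda_water(10)
  pb <- slab_problem(list(list(material = "toy", thickness = 1.2 * R)),
                     voxels = 40, N = 8, L = 7, M = 1, tol = 1e-12,
                     max_inner = 2000)
  sol <- solve_bfp(pb, setNames(list(lib), "toy"))
  expect_lt(max(sol$balance), 1e-8)
})

test_that("slowing-down currents are conserved down the cascade", {
  ## uniform thick slab, constant-beta toy: each group passes the beam on
  gs <- build_group_structure(20, E_max = 10, E_min = 1)
  lib <- toy_library(gs, 3L, beta = 2)
  pb <- slab_problem(list(list(material = "toy", thickness = 40)),
                     voxels = 50, N = 4, L = 3, M = 1, tol = 1e-12,
                     max_inner = 1000)
  sol <- solve_bfp(pb, setNames(list(lib), "toy"))
  phi0 <- solution_phi(sol, 0)
  ## group-wise current beta * phi integrates to dE per group traversal
  dep <- as.vector(phi0 %*% sol$mesh$dx) * 2
  dE <- gs$width * MEC2_T
  expect_equal(dep[1:19] / dE[1:19], rep(1, 19), tolerance = 1e-6)
})

test_that("two-sided irradiation is the mirrored sum by linearity", {
  lib <- csd_only_water_library(30, 10)
  R <- cached_csda_water(10)
  mk <- function(bnd) {
    pb <- slab_problem(list(list(material = "toy", thickness = 1.2 * R)),
                       voxels = 40, N = 8, L = 7, M = 1, boundary = bnd,
                       tol = 1e-10, max_inner = 1000)
    sol <- solve_bfp(pb, setNames(list(lib), "toy"))
    dose_profile(sol, setNames(list(lib), "toy"))$dose_MeV_per_g
  }
  left <- mk("left")
  both <- mk("both")
  expect_equal(both, (left + rev(left)) / 2, tolerance = 1e-6)
})

test_that("problem validation enforces the Galerkin pairing and inputs", {
  expect_error(slab_problem(list(list(material = "w", thickness = 1)),
                            N = 8, L = 5), "N = L \\+ 1")
  expect_error(slab_problem(list(list(material = "w", thickness = -1))),
               "positive")
  expect_error(slab_problem(list(list(material = "w", thickness = 1)),
                            tol = 0), "tolerance")
  pb <- slab_problem(list(list(material = "w", thickness = 1)),
                     N = 8, L = 5, galerkin = FALSE)
  expect_s3_class(pb, "slab_problem")
})
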