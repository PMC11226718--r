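small_water_lib <- function() cached_water_library(40, 20, L = 3L, nodes = 10L)

test_that("total cross section is the printed channel sum", {
  G <- 6L
  z <- matrix(0, G, G)
  expect_equal(total_xs(z, z, rep(0, G)), rep(0, G))
  el0 <- c(1, 2, 3, 4, 5, 6)
  expect_equal(total_xs(z, z, el0), el0)
  set.seed(3)
  ee <- matrix(runif(G * G), G); b0 <- matrix(runif(G * G), G)
  ## independent second-path recomputation
  ref <- vapply(seq_len(G), function(g) sum(ee[g, ]) + sum(b0[g, ]) + el0[g], 0)
  expect_equal(total_xs(ee, b0, el0), ref, tolerance = 1e-12)
  expect_error(total_xs(ee, matrix(0, 3, 3), el0), "do not match")
})

test_that("assembled library satisfies the channel-sum identity exactly", {
  lib <- small_water_lib()
  ref <- rowSums(lib$ee[, , 1]) + rowSums(lib$b0) + lib$el[, 1]
  expect_equal(lib$Sigma_t, ref, tolerance = 1e-12)
})

test_that("soft plus catastrophic stopping power closes on the total", {
  lib <- small_water_lib()
  w <- material("water")
  Em <- lib$gs$mid * MEC2_T
  m <- lib$moments
  lhs_c <- lib$beta_c + MEC2_T * (m$A1_i - m$Eout_ee)
  expect_equal(lhs_c, w$rho * collisional_stopping_power(Em, w),
               tolerance = 1e-8)
  lhs_r <- lib$beta_r + MEC2_T * (m$A1_b - m$Eout_b)
  expect_equal(lhs_r, w$rho * radiative_stopping_power(Em, w),
               tolerance = 1e-8)
  ## catastrophic fraction strictly inside (0, 1) where channels are active
  big <- cached_water_library(150, 100)
  g100 <- big$gs$G
  frac <- MEC2_T * (big$moments$A1_i - big$moments$Eout_ee)[g100] /
    (material("water")$rho * collisional_stopping_power(100, w))
  expect_gt(frac, 0)
  expect_lt(frac, 1)
})

test_that("with no catastrophic channels the soft power equals the total", {
  ## G = 3: the two-adjacent-group skip leaves no catastrophic channel
  gs <- build_group_structure(3, E_max = 10)
  lib <- build_material_library(material("water"), gs, L = 1L, nodes = 6L)
  expect_equal(sum(lib$ee) + sum(lib$ed) + sum(lib$b0), 0)
  w <- material("water")
  expect_equal(lib$beta_c, w$rho * collisional_stopping_power(
    gs$mid * MEC2_T, w), tolerance = 1e-12)
})

test_that("deposition and photon production are a non-negative complement", {
  lib <- small_water_lib()
  expect_true(all(lib$Edep >= 0))
  expect_true(all(lib$Ephot >= 0))
  tot <- energy_deposition_xs(lib, "total")
  expect_equal(tot, energy_deposition_xs(lib, "electron") +
                 photon_production_xs(lib), tolerance = 1e-12)
  ## pure-CSD library deposits the soft stopping power only
  gs <- lib$gs
  toy <- toy_library(gs, 3L, beta = 2)
  expect_equal(energy_deposition_xs(toy, "electron"), rep(2, gs$G))
})

test_that("macroscopic mixing is number-density weighting", {
  w <- material("water")
  micro <- list(H = 2, O = 3)   # scalar per-atom stand-ins
  mixed <- mix_macroscopic(micro, w)
  NA_ <- 6.02214076e23
  ref <- 1.0 * 0.111894 * NA_ / 1.008 * 2 + 1.0 * 0.888106 * NA_ / 15.999 * 3
  expect_equal(mixed, ref, tolerance = 1e-12)
  ## 50/50 mass mix of identical elements equals the pure element
  half <- material(composition = c(O = 0.5, O = 0.5), rho = 1.3)
  pure <- material(composition = c(O = 1), rho = 1.3)
  expect_equal(mix_macroscopic(list(5, 5), half),
               mix_macroscopic(list(5), pure), tolerance = 1e-12)
  expect_error(mix_macroscopic(list(1), w), "per constituent")
})

test_that("library container round-trips bit-identically and is versioned", {
  lib <- small_water_lib()
  path <- tempfile(fileext = ".lib")
  write_library(lib, path)
  back <- read_library(path)
  expect_identical(back$ee, lib$ee)
  expect_identical(back$beta_edge, lib$beta_edge)
  expect_identical(back$gs$bounds, lib$gs$bounds)
  ## future schema version is refused
  payload <- readRDS(path)
  payload$version <- 99L
  saveRDS(payload, path)
  expect_error(read_library(path), "newer than supported")
  saveRDS(list(schema = "other"), path)
  expect_error(read_library(path), "not a bfpdose")
})

test_that("libraries on different group structures cannot be combined", {
  lib1 <- small_water_lib()
  gs2 <- build_group_structure(10, E_max = 20)
  lib2 <- toy_library(gs2, 3L)
  lib2$material$name <- "water"
  pb <- slab_problem(list(list(material = "water", thickness = 1),
                          list(material = "toy", thickness = 1)),
                     voxels = 10, N = 4, L = 3, M = 0)
  expect_error(solve_bfp(pb, list(water = lib1, toy = lib2)),
               "one group structure")
})
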