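test_that("benchmark compositions match the printed caption fractions", {
  th <- benchmark_spec("thorax")
  expect_identical(th$materials, c("muscle", "bone", "lung", "tissue"))
  expect_identical(th$fractions_printed, c(0.13, 0.07, 0.22, 0.58))
  io <- benchmark_spec("iort")
  expect_identical(io$materials, c("tumor", "aluminum", "steel", "tissue"))
  expect_identical(io$fractions_printed, c(0.40, 0.40, 0.15, 0.05))
  hh <- benchmark_spec("hh")
  expect_identical(hh$fractions_printed,
                   c(0.05, 0.07, 0.04, 0.04, 0.41, 0.06, 0.05, 0.08, 0.07,
                     0.06, 0.07))
  nm1 <- benchmark_spec("nm1")
  expect_identical(nm1$materials, c("Fe", "As", "C", "Zr"))
  expect_identical(nm1$fractions_printed, rep(0.25, 4))
  nm2 <- benchmark_spec("nm2")
  expect_identical(nm2$fractions_printed, c(rep(0.17, 5), 0.15))
  nm3 <- benchmark_spec("nm3")
  expect_identical(nm3$materials,
                   c("Au", "S", "Zn", "Sn", "Na", "Se", "K", "Sm", "V",
                     "Pd", "B", "Y", "In", "Yb", "Ti"))
  expect_identical(nm3$fractions_printed,
                   c(rep(0.10, 6), 0.30, rep(0.10, 8)))
  ## construction fractions always sum to one
  for (nm in c("water", "thorax", "iort", "hh", "nm1", "nm2", "nm3"))
    expect_equal(sum(benchmark_spec(nm)$fractions), 1, tolerance = 1e-12)
  expect_error(benchmark_spec("nope"), "unknown benchmark")
})

test_that("slab sizing scales with the mass range", {
  al <- build_benchmark("Al", 50, voxels = 10, N = 4, L = 3)
  au <- build_benchmark("Au", 50, voxels = 10, N = 4, L = 3)
  t_al <- sum(vapply(al$regions, `[[`, 0, "thickness"))
  t_au <- sum(vapply(au$regions, `[[`, 0, "thickness"))
  expect_lt(t_au, t_al)   # denser, higher-Z element: thinner slab
  ## high-Z assemblies default to two-sided irradiation
  expect_identical(build_benchmark("nm1", 100, voxels = 10, N = 4,
                                   L = 3)$boundary, "both")
  expect_identical(al$boundary, "left")
})

test_that("identical profiles give perfect metrics and zero KS", {
  x <- seq(0, 10, by = 0.25)
  d <- exp(-(x - 4)^2 / 4) + 0.05
  p <- data.frame(depth_cm = x, dose = d)
  cc <- compare_profiles(p, p)
  expect_equal(cc$eps1, 100)
  expect_equal(cc$eps2, 100)
  expect_equal(cc$eps_bar, 0)
  expect_equal(cc$ks_stat, 0)
  expect_false(cc$ks_reject)
})

test_that("a constructed 1.5% offset lands between the eps1 and eps2 gates", {
  x <- seq(0, 10, by = 0.25)
  d <- exp(-(x - 4)^2 / 4) + 0.05
  ref <- data.frame(depth_cm = x, dose = d)
  bfp <- data.frame(depth_cm = x, dose = 1.015 * d)
  cc <- compare_profiles(bfp, ref)
  expect_equal(cc$eps1, 0)
  expect_equal(cc$eps2, 100)
  expect_equal(cc$eps_bar, 1.5, tolerance = 1e-12)
})

test_that("a three-point toy pair matches hand-computed deviations", {
  bfp <- data.frame(depth_cm = c(0, 1, 2), dose = c(2.0, 1.0, 0.5))
  ref <- data.frame(depth_cm = c(0, 1, 2), dose = c(2.0, 1.1, 0.4))
  cc <- compare_profiles(bfp, ref)
  expect_equal(cc$eps_r, 100 * c(0, -0.1 / 1.1, 0.1 / 0.4),
               tolerance = 1e-12)
  expect_equal(cc$eps_bar, mean(abs(100 * c(0, -0.1 / 1.1, 0.1 / 0.4))),
               tolerance = 1e-12)
})

test_that("metric identities: ordering and scale invariance", {
  set.seed(21)
  x <- seq(0, 5, by = 0.1)
  a <- data.frame(depth_cm = x, dose = 1 + 0.03 * sin(x) + 0.01 * runif(length(x)))
  b <- data.frame(depth_cm = x, dose = rep(1, length(x)))
  c1 <- compare_profiles(a, b)
  expect_lte(c1$eps1, c1$eps2)
  c2 <- compare_profiles(transform(a, dose = 7 * dose),
                         transform(b, dose = 7 * dose))
  expect_equal(c1$eps_bar, c2$eps_bar, tolerance = 1e-12)
  expect_error(compare_profiles(a, transform(b, depth_cm = depth_cm + 99)),
               "overlap")
})

test_that("the tail floor excludes near-zero reference voxels", {
  x <- seq(0, 10, by = 0.5)
  ref <- data.frame(depth_cm = x, dose = c(rep(1, 15), rep(1e-6, 6)))
  bfp <- data.frame(depth_cm = x, dose = c(rep(1, 15), rep(5e-6, 6)))
  cc <- compare_profiles(bfp, ref)
  expect_equal(cc$n_excluded, 6)
  expect_equal(cc$eps_bar, 0)
})

test_that("reference profiles read with or without a header", {
  p1 <- tempfile(); p2 <- tempfile()
  writeLines(c("depth_cm dose", "0 1.0", "1 0.5"), p1)
  writeLines(c("0 1.0", "1 0.5"), p2)
  expect_equal(read_reference_profile(p1), read_reference_profile(p2))
})

test_that("dose scales linearly with the source and the audit reports components", {
  lib <- csd_only_water_library(30, 10)
  R <- cached_csda_water(10)
  pb <- slab_problem(list(list(material = "toy", thickness = 1.2 * R)),
                     voxels = 30, N = 8, L = 7, M = 1)
  sol <- solve_bfp(pb, setNames(list(lib), "toy"))
  prof <- dose_profile(sol, setNames(list(lib), "toy"))
  expect_true(all(prof$dose_MeV_per_g >= 0))
  aud <- energy_audit(sol, setNames(list(lib), "toy"))
  expect_named(aud, c("incident", "deposited", "photon", "leakage",
                      "subcutoff", "balance"))
  ## doubling every flux moment doubles every voxel dose exactly
  sol2 <- sol
  sol2$phi <- 2 * sol$phi
  prof2 <- dose_profile(sol2, setNames(list(lib), "toy"))
  expect_equal(prof2$dose_MeV_per_g, 2 * prof$dose_MeV_per_g,
               tolerance = 1e-14)
})

test_that("the element scan sizes slabs and self-compares cleanly", {
  refs <- NULL
  tab <- element_scan(c("Al", "Cu"), 30, groups = 24L, voxels = 24L,
                      N = 4L, L = 3L)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.na(tab$eps_bar)))      # no references supplied
  expect_lt(tab$thickness_cm[tab$element == "Cu"],
            tab$thickness_cm[tab$element == "Al"])
  profs <- attr(tab, "profiles")
  self <- compare_profiles(profs[["Al 30"]], profs[["Al 30"]])
  expect_equal(self$eps1, 100)
  expect_equal(self$eps_bar, 0)
})
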