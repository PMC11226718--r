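## Shared fixtures: cached material libraries (expensive to build) and a
## fully synthetic library constructor for solver tests.

.lib_cache <- new.env(parent = emptyenv())

cached_water_library <- function(G, E_max, L = 15L, nodes = 16L) {
  key <- paste("water", G, E_max, L, nodes, sep = "_")
  if (is.null(.lib_cache[[key]])) {
    gs <- build_group_structure(G, E_max = E_max)
    .lib_cache[[key]] <- build_material_library(material("water"), gs,
                                                L = L, nodes = nodes)
  }
  .lib_cache[[key]]
}

cached_csda_water <- function(E) {
  key <- paste("csda", E, sep = "_")
  if (is.null(.lib_cache[[key]]))
    .lib_cache[[key]] <- csda_range(E, material("water"))
  .lib_cache[[key]]
}

## synthetic single-material library with hand-set channels; every field a
## solver or audit touches is present
toy_library <- function(gs, L, sigt = 0, within_l = NULL, beta = 1e-12,
                        name = "toy") {
  G <- gs$G
  z <- function() rep(0, G)
  moments <- list(A1_i = z(), Eout_ee = z(), Eout_ed = z(), A1_b = z(),
                  Eout_b = z(), E_auger = z(), E_fluor = z(), E_local = z(),
                  Eout_ee_bal = z(), Eout_ed_bal = z(), Eout_b_bal = z(),
                  E_auger_bal = z(), Ein_i_bal = z(), Ein_b_bal = z())
  lib <- structure(list(
    gs = gs, L = as.integer(L),
    material = list(name = name, rho = 1, I_eV = 75, symbols = "X",
                    fractions = 1),
    options = list(rep_theta = 0.5),
    Sigma_t = rep(sigt, G),
    ee = array(0, c(G, G, L + 1L)), ed = array(0, c(G, G, L + 1L)),
    b0 = matrix(0, G, G), aug = matrix(0, G, G),
    el = if (is.null(within_l)) matrix(0, G, L + 1L) else within_l,
    beta_c = rep(beta, G), beta_r = z(),
    beta_c_edge = rep(beta, G + 1L), beta_r_edge = rep(1e-300, G + 1L),
    beta_edge = rep(beta, G + 1L),
    alpha = z(), moments = moments), class = "multigroup_library")
  lib$Edep <- lib$beta_c
  lib$Ephot <- lib$beta_r
  lib
}

## CSD-only water-like library: real stopping powers, catastrophic
## channels disabled (all loss through the slowing-down operator)
csd_only_water_library <- function(G, E_max, L = 7L, elastic = TRUE) {
  key <- paste("csdonly", G, E_max, L, elastic, sep = "_")
  if (!is.null(.lib_cache[[key]])) return(.lib_cache[[key]])
  w <- material("water")
  gs <- build_group_structure(G, E_max = E_max)
  lib <- toy_library(gs, L)
  Em <- gs$mid * 0.51099895
  bc <- w$rho * collisional_stopping_power(Em, w)
  br <- w$rho * radiative_stopping_power(Em, w)
  ll <- function(v) exp(approx(log(gs$mid), log(pmax(v, 1e-300)),
                               xout = log(gs$bounds), rule = 2)$y)
  lib$beta_c <- bc; lib$beta_r <- br
  lib$beta_c_edge <- ll(bc); lib$beta_r_edge <- ll(br)
  lib$beta_edge <- lib$beta_c_edge + lib$beta_r_edge
  if (elastic) {
    full <- build_material_library(w, gs, L = L, nodes = 8L)
    lib$el <- full$el
    lib$Sigma_t <- full$el[, 1L]
  }
  lib$Edep <- energy_deposition_xs(lib, "electron")
  lib$Ephot <- photon_production_xs(lib)
  .lib_cache[[key]] <- lib
  lib
}

MEC2_T <- 0.51099895
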