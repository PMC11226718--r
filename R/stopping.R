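## Analytic total stopping powers. Collisional: Berger-Seltzer (ICRU-37)
## closed form with the Sternheimer-Peierls density effect. Radiative: photon
## first moment of the package's own assembled bremsstrahlung cross section,
## which makes the soft/catastrophic radiative split internally consistent.

#' Collisional (electronic) total stopping power
#'
#' Berger-Seltzer closed form,
#' `S = 0.153536 (Z/A) / beta^2 [ ln( tau^2 (tau+2) / (2 (I/mc^2)^2) )
#'  + F(tau) - delta ]` MeV cm^2/g, with
#' `F = 1 - beta^2 + (tau^2/8 - (2 tau + 1) ln 2) / (tau + 1)^2` and `delta`
#' the material's density-effect correction.
#'
#' @param E kinetic energy in MeV (vectorised, `>=` the transport cutoff).
#' @param mat a [material()].
#' @param density_effect logical; set `FALSE` to recover the uncorrected
#'   Bethe-Moller form.
#' @return mass stopping power in MeV cm^2/g.
#' @export
collisional_stopping_power <- function(E, mat, density_effect = TRUE) {
  if (any(E <= 0)) stop("E must be positive")
  tau <- reduced_energy(E)
  beta2 <- velocity_beta(tau)^2
  Ired <- mat$I_eV * 1e-6 / MEC2
  Ftau <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  delta <- if (density_effect) density_effect_delta(E, mat) else 0
  0.153536 * mat$ZA / beta2 *
    (log(tau^2 * (tau + 2) / (2 * Ired^2)) + Ftau - delta)
}

## photon-energy first moment of the bremsstrahlung DDSC for one element,
## integral over the full spectrum [0, e'], in reduced-energy * cm^2.
## Composite Gauss-Legendre in log(e_gamma) plus the linear tip panel.
brems_energy_moment <- function(e_prime, elem, nodes = 32L) {
  if (e_prime <= 0) return(0)
  glq <- pracma::gaussLegendre(nodes, log(e_prime * 1e-5), log(0.99 * e_prime))
  k <- exp(glq$x)
  v <- berger_seltzer_ddcs(e_prime, k, elem, e_gamma_max = e_prime)
  main <- sum(glq$w * k^2 * v)   # extra k from the log substitution
  ## small-k analytic completion: k * ddcs ~ const below the first node
  v0 <- berger_seltzer_ddcs(e_prime, e_prime * 1e-5, elem,
                            e_gamma_max = e_prime) * e_prime * 1e-5
  low <- v0 * e_prime * 1e-5
  ## tip panel: ddcs linear to 0 over [0.99, 1] e'
  vtip <- berger_seltzer_ddcs(e_prime, 0.99 * e_prime, elem,
                              e_gamma_max = e_prime)
  tipw <- 0.01 * e_prime
  tip <- vtip * tipw * 0.995 * e_prime / 2
  main + low + tip
}

#' Radiative total stopping power
#'
#' Photon-energy first moment of the assembled bremsstrahlung differential
#' cross section ([berger_seltzer_ddcs()]) integrated over the full photon
#' spectrum, summed over constituents:
#' `S_r = sum_i (N_A w_i / A_i) m_e c^2 \int e_gamma sigma_b de_gamma`.
#' Using the same kernel as the transfer matrices guarantees that the soft
#' radiative stopping power (total minus catastrophic first moment) is
#' non-negative by construction.
#'
#' @param E kinetic energy in MeV (vectorised).
#' @param mat a [material()].
#' @param nodes quadrature nodes for the spectrum integral.
#' @return mass stopping power in MeV cm^2/g.
#' @export
radiative_stopping_power <- function(E, mat, nodes = 32L) {
  if (any(E <= 0)) stop("E must be positive")
  ep <- reduced_energy(E)
  out <- numeric(length(ep))
  for (j in seq_along(mat$elements)) {
    el <- mat$elements[[j]]
    coef <- N_AVO * mat$fractions[j] / el$A
    mom <- vapply(ep, brems_energy_moment, 0, elem = el, nodes = nodes)
    out <- out + coef * mom
  }
  out * MEC2
}

#' Total stopping power (collisional + radiative)
#' @inheritParams collisional_stopping_power
#' @return MeV cm^2/g.
#' @export
total_stopping_power <- function(E, mat) {
  collisional_stopping_power(E, mat) + radiative_stopping_power(E, mat)
}

#' CSDA range
#'
#' Continuous-slowing-down range `int_{cutoff}^{E} dE' / S_tot(E')` in
#' g/cm^2, by composite Gauss-Legendre quadrature on a logarithmic energy
#' grid (stopping powers are smooth in log E).
#'
#' @param E kinetic energy in MeV (scalar or vector).
#' @param mat a [material()].
#' @param cutoff lower limit in MeV (default 1 keV).
#' @param panels,nodes quadrature resolution per decade and per panel.
#' @return range in g/cm^2 (multiply by density for cm).
#' @export
csda_range <- function(E, mat, cutoff = 1e-3, panels = 8L, nodes = 8L) {
  if (any(E < cutoff)) stop("E must be >= cutoff")
  one <- function(Emax) {
    if (Emax == cutoff) return(0)
    np <- max(4L, ceiling(panels * log10(Emax / cutoff)))
    edges <- exp(seq(log(cutoff), log(Emax), length.out = np + 1L))
    tot <- 0
    for (i in seq_len(np)) {
      glq <- pracma::gaussLegendre(nodes, edges[i], edges[i + 1L])
      tot <- tot + sum(glq$w / total_stopping_power(glq$x, mat))
    }
    tot
  }
  vapply(E, one, 0)
}
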