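## Berger-Seltzer catastrophic bremsstrahlung: component kernels (unscreened
## Born, screened, non-relativistic Schiff, Olsen-Maximon Coulomb-corrected),
## Elwert factor, Butcher-Messel screening functions, and the
## surviving-electron transfer matrix. All kernels are per atom, in
## cm^2 / (reduced photon energy), vectorised over (e_prime, e_gamma).

.bfp_counters <- new.env(parent = emptyenv())
.bfp_counters$brems_clamped <- 0L

#' Elwert screening factor
#'
#' Coulomb-attraction correction to the Born bremsstrahlung cross section,
#' `(beta'/beta) (1 - exp(-2 pi Z alpha / beta')) / (1 - exp(-2 pi Z alpha /
#' beta))`, with `beta'` the incident and `beta` the post-emission electron
#' speed. Tends to 1 as the photon energy vanishes, and equals 1 exactly for
#' Z = 0; it diverges at the spectrum tip, which the assembled cross section
#' caps by its high-frequency extrapolation.
#'
#' @param e_prime incident reduced kinetic energy.
#' @param e_gamma reduced photon energy, `0 < e_gamma < e_prime`.
#' @param Z atomic number.
#' @return dimensionless factor (vectorised).
#' @export
elwert_factor <- function(e_prime, e_gamma, Z) {
  if (any(e_gamma <= 0) || any(e_gamma >= e_prime))
    stop("require 0 < e_gamma < e_prime")
  if (Z == 0) return(rep(1, length(e_prime + e_gamma)))
  b0 <- velocity_beta(e_prime)
  b1 <- velocity_beta(e_prime - e_gamma)
  a <- 2 * pi * Z * ALPHA_FS
  (b0 / b1) * (1 - exp(-a / b0)) / (1 - exp(-a / b1))
}

#' Coulomb correction f(Z)
#'
#' Davies-Bethe-Maximon series in `a = Z alpha`:
#' `f = a^2 [1/(1+a^2) + 0.20206 - 0.0369 a^2 + 0.0083 a^4 - 0.002 a^6]`.
#'
#' @param Z atomic number (0..99, vectorised).
#' @return dimensionless correction, 0 at Z = 0, monotone increasing.
#' @export
coulomb_f <- function(Z) {
  if (any(Z < 0) || any(Z > 99)) stop("Z must be in 0..99")
  a2 <- (Z * ALPHA_FS)^2
  a2 * (1 / (1 + a2) + 0.20206 - 0.0369 * a2 + 0.0083 * a2^2 - 0.002 * a2^3)
}

## Butcher-Messel screening-function fit. The quadratic (small-zeta) and
## logarithmic (large-zeta) branches are joined by a smoothstep blend over
## zeta in [0.8, 1.2], so each Phi is continuous (the raw fits jump by up to
## 0.3 at the conventional zeta = 1 switch).
.phi_log <- function(z) 21.12 - 4.184 * log(z + 0.952)
.PHI_BLEND <- c(0.8, 1.2)

#' Bremsstrahlung screening functions
#'
#' Butcher-Messel fits for the two screening functions entering the screened
#' and Coulomb-corrected kernels; at complete screening (`zeta = 0`) they take
#' the fit constants 20.867 and 20.029, and for large `zeta` both collapse
#' onto the same logarithmic branch (weak screening). The quadratic and
#' logarithmic fit pieces are blended smoothly across `zeta` in 0.8..1.2,
#' keeping both functions continuous.
#'
#' @param zeta screening argument (`>= 0`, vectorised).
#' @return list with components `phi1`, `phi2`.
#' @export
screening_phis <- function(zeta) {
  if (any(zeta < 0)) stop("zeta must be non-negative")
  t <- pmin(pmax((zeta - .PHI_BLEND[1L]) /
                   (.PHI_BLEND[2L] - .PHI_BLEND[1L]), 0), 1)
  s <- t * t * (3 - 2 * t)
  lg <- .phi_log(zeta)
  q1 <- 20.867 - 3.242 * zeta + 0.625 * zeta^2
  q2 <- 20.029 - 1.930 * zeta - 0.086 * zeta^2
  list(phi1 = (1 - s) * q1 + s * lg, phi2 = (1 - s) * q2 + s * lg)
}

## screening argument: zeta = 136 Z^{-1/3} e_gamma / (e_t e_s)
brems_zeta <- function(e_t, e_s, e_gamma, Z) {
  136 * Z^(-1 / 3) * e_gamma / (e_t * e_s)
}

## omega(e'): switches the Coulomb-corrected kernel on over 15..50 MeV total
## energy (smoothstep); below that range the Born screened kernel is kept.
brems_omega <- function(e_prime) {
  et_mev <- (e_prime + 1) * MEC2
  t <- pmin(pmax((et_mev - 15) / (50 - 15), 0), 1)
  t * t * (3 - 2 * t)
}

## The four component kernels (per atom). znuc: Z(Z+1) by default; the
## nuclear-field-only option replaces it by Z^2.
brems_components <- function(e_prime, e_gamma, Z, nuclear_only = FALSE) {
  et <- e_prime + 1
  es <- et - e_gamma
  p0 <- sqrt(pmax(et^2 - 1, 0))
  p1 <- sqrt(pmax(es^2 - 1, 0))
  k <- e_gamma
  zz <- if (nuclear_only) Z^2 else Z * (Z + 1)
  pref <- zz * R0_CM^2 * ALPHA_FS / k

  ## sigma1: Koch-Motz 3BN (Born, unscreened)
  Lf <- 2 * log(pmax((et * es + p0 * p1 - 1) / k, 1 + 1e-300))
  xi0 <- log((et + p0) / (et - p0))
  xi1 <- log((es + p1) / (es - p1))
  br <- 4 / 3 - 2 * et * es * (p1^2 + p0^2) / (p1^2 * p0^2) +
    xi0 * es / p0^3 + xi1 * et / p1^3 - xi1 * xi0 / (p1 * p0) +
    Lf * (8 / 3 * et * es / (p1 * p0) +
            k^2 * (et^2 * es^2 + p1^2 * p0^2) / (p1^3 * p0^3) +
            k / (2 * p1 * p0) *
              ((et * es + p0^2) * xi0 / p0^3 -
                 (et * es + p1^2) * xi1 / p1^3 +
                 2 * k * et * es / (p1^2 * p0^2)))
  s1 <- pref * (p1 / p0) * br

  ## sigma2/sigma3/sigma4: screened, Schiff non-relativistic, Coulomb-corrected
  r <- es / et
  ph <- screening_phis(brems_zeta(et, es, k, Z))
  lz3 <- log(Z) / 3
  s2 <- 4 * pref * ((1 + r^2) * (ph$phi1 / 4 - lz3) -
                      (2 / 3) * r * (ph$phi2 / 4 - lz3))
  s3 <- 4 * pref * (1 - (2 / 3) * r + r^2) * (log(2 * et * es / k) - 0.5)
  fz <- coulomb_f(Z)
  s4 <- 4 * pref * ((1 + r^2) * (ph$phi1 / 4 - lz3 - fz) -
                      (2 / 3) * r * (ph$phi2 / 4 - lz3 - fz))
  list(s1 = s1, s2 = s2, s3 = s3, s4 = s4)
}

#' Assembled Berger-Seltzer bremsstrahlung cross section
#'
#' Differential (in reduced photon energy) cross section per atom,
#' `xi_r * f_e * [sigma1 + sigma2 - sigma3 + omega (sigma4 - sigma2)]`,
#' where `f_e` is the [elwert_factor()], `omega` ramps the Coulomb-corrected
#' kernel in over 15-50 MeV total energy, and `xi_r` is an atomic correction
#' hook (default 1). Over the last 1% of the spectrum the assembly is
#' replaced by a linear extrapolation to zero at the high-frequency limit,
#' which keeps the spectrum integrable despite the Elwert divergence; the
#' kernels themselves vanish in the high-frequency limit. Negative assembled
#' values (possible far outside the fit range) are clamped to zero and
#' counted.
#'
#' @param e_prime incident reduced kinetic energy (scalar or vector).
#' @param e_gamma reduced photon energy (vectorised).
#' @param elem an [element_record()] (or atomic number).
#' @param e_gamma_max high-frequency limit in reduced units (default: the
#'   full kinetic energy `e_prime`).
#' @param xi_r atomic correction factor (default 1).
#' @param nuclear_only logical; replace `Z(Z+1)` by `Z^2`.
#' @return cross section in cm^2 per reduced photon energy.
#' @export
berger_seltzer_ddcs <- function(e_prime, e_gamma, elem,
                                e_gamma_max = NULL, xi_r = 1,
                                nuclear_only = FALSE) {
  Z <- if (inherits(elem, "element_record")) elem$Z else elem
  if (Z == 0) return(rep(0, length(e_gamma)))
  if (is.null(e_gamma_max)) e_gamma_max <- e_prime
  if (any(e_gamma < 0) || any(e_gamma > e_gamma_max + 1e-12 * e_gamma_max))
    stop("e_gamma outside [0, e_gamma_max]")
  ktip <- 0.99 * e_gamma_max
  k <- pmin(e_gamma, ktip)
  k <- pmax(k, 1e-300)
  cmp <- brems_components(e_prime, k, Z, nuclear_only)
  w <- brems_omega(e_prime)
  val <- elwert_factor(e_prime, k, Z) *
    (cmp$s1 + cmp$s2 - cmp$s3 + w * (cmp$s4 - cmp$s2)) * xi_r
  nneg <- sum(val < 0)
  if (nneg > 0) {
    .bfp_counters$brems_clamped <- .bfp_counters$brems_clamped + nneg
    val <- pmax(val, 0)
  }
  ## linear tip extrapolation: value at 0.99 e_gamma_max down to 0
  egm <- rep_len(e_gamma_max, length(val))
  ktipv <- rep_len(ktip, length(val))
  tip <- e_gamma > ktipv
  if (any(tip)) {
    frac <- (egm[tip] - e_gamma[tip]) / (egm[tip] - ktipv[tip])
    val[tip] <- val[tip] * pmax(frac, 0)
  }
  val
}

#' Build the bremsstrahlung surviving-electron transfer matrix
#'
#' Fixed-order Gauss-Legendre quadrature of the assembled Berger-Seltzer
#' cross section over each admissible (incident, destination) group panel.
#' The surviving electron keeps the incident direction, so every Legendre
#' order equals the zeroth (`P_l(1) = 1`) and only the l = 0 matrix is
#' stored with a `forward` flag. The same catastrophic-jump rule as
#' ionization applies (the electron lands at or below boundary `e^{g'-2}`),
#' and the high-frequency limit caps the photon at `e' - e^2` (the top
#' boundary of the lowest group). Photon-energy emission per incident group
#' is accumulated for the energy bookkeeping.
#'
#' @param gs a [build_group_structure()].
#' @param L maximum Legendre order carried by the library (stored for
#'   metadata; all orders share the l = 0 matrix).
#' @param elem an [element_record()] or atomic number.
#' @param nodes Gauss-Legendre points per panel dimension.
#' @param nuclear_only logical, passed to [berger_seltzer_ddcs()].
#' @return object of class `brems_transfer`: matrix `b0` of dimension
#'   `(G, G)` (incident, destination) in cm^2 with attribute `forward`;
#'   vectors `sig_cat`, `A1` (incident-energy first moment), `Eout`
#'   (surviving-electron first moment) and `Egamma` (photon energy emitted,
#'   reduced units * cm^2).
#' @export
build_brems_transfer <- function(gs, L, elem, nodes = 16L,
                                 nuclear_only = FALSE) {
  el <- if (inherits(elem, "element_record")) elem else element_record(elem)
  G <- gs$G
  b <- gs$bounds
  rule <- gl_rule(nodes)
  b0 <- matrix(0, G, G)
  sig_cat <- A1 <- Eout <- Egamma <- numeric(G)
  kern <- function(EP, X)
    berger_seltzer_ddcs(EP, EP - X, el, e_gamma_max = EP - b[2L],
                        nuclear_only = nuclear_only)
  mu1 <- function(EP, X) rep(1, length(EP))

  for (gp in seq_len(G)) {
    if (gp < 4L) next
    bc <- b[gp - 2L]
    outer_q <- gl_map(rule, b[gp], b[gp + 1L])
    epv <- outer_q$x
    wout <- outer_q$w / gs$width[gp]
    for (g in seq_len(gp - 3L)) {
      ## surviving electron in [max(e^g, e^2), e^{g+1}]
      res <- panel_quad(epv, wout, rep(max(b[g], b[2L]), length(epv)),
                        rep(min(b[g + 1L], bc), length(epv)),
                        rule, 0L, kern, mu1)
      if (is.null(res)) next
      b0[gp, g] <- res$moments[1L]
      Eout[gp] <- Eout[gp] + res$e1
      A1[gp] <- A1[gp] + res$ep1
    }
    sig_cat[gp] <- sum(b0[gp, ])
    Egamma[gp] <- A1[gp] - Eout[gp]
  }
  structure(list(gs = gs, L = L, Z = el$Z, b0 = b0, forward = TRUE,
                 sig_cat = sig_cat, A1 = A1, Eout = Eout, Egamma = Egamma),
            class = "brems_transfer")
}
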