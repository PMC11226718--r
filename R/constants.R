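#' @useDynLib bfpdose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx optimize setNames uniroot
#' @importFrom utils head modifyList read.table tail
NULL

## Physical constants (CODATA). Energies are carried internally in "reduced
## units" (kinetic energy divided by the electron rest energy); cross sections
## in cm^2, macroscopic quantities in cm^-1.
MEC2    <- 0.51099895      # electron rest energy, MeV
R0_CM   <- 2.8179403262e-13  # classical electron radius, cm
N_AVO   <- 6.02214076e23   # Avogadro constant, 1/mol
ALPHA_FS <- 1 / 137.035999084 # fine-structure constant

#' Convert kinetic energy from MeV to reduced units
#'
#' Reduced kinetic energy is `E / (m_e c^2)`; all cross-section kernels and
#' group structures in this package work in reduced units.
#'
#' @param E kinetic energy in MeV (vectorised, must be `>= 0`).
#' @return reduced kinetic energy (dimensionless).
#' @seealso [from_reduced_energy()]
#' @export
#' @examples
#' reduced_energy(0.51099895)  # 1
reduced_energy <- function(E) {
  if (any(E < 0)) stop("kinetic energy must be non-negative")
  E / MEC2
}

#' Convert reduced kinetic energy back to MeV
#' @param e reduced kinetic energy (dimensionless, `>= 0`).
#' @return kinetic energy in MeV.
#' @export
from_reduced_energy <- function(e) {
  if (any(e < 0)) stop("reduced energy must be non-negative")
  e * MEC2
}

#' Electron speed in units of the speed of light
#'
#' `beta = sqrt(e (e + 2)) / (e + 1)` for reduced kinetic energy `e`; strictly
#' increasing, bounded by 1.
#'
#' @param e reduced kinetic energy (vectorised, `>= 0`).
#' @return `beta` in `[0, 1)`.
#' @export
velocity_beta <- function(e) {
  if (any(e < 0)) stop("reduced energy must be non-negative")
  sqrt(e * (e + 2)) / (e + 1)
}

## momentum p = beta * gamma = sqrt(e(e+2)) in units of m_e c
reduced_momentum <- function(e) sqrt(e * (e + 2))

## Legendre polynomials P_0..P_lmax evaluated at mu (vector);
## returns matrix [length(mu), lmax+1]
legendre_table <- function(mu, lmax) {
  n <- length(mu)
  P <- matrix(0, n, lmax + 1L)
  P[, 1L] <- 1
  if (lmax >= 1L) P[, 2L] <- mu
  if (lmax >= 2L) {
    for (l in 1L:(lmax - 1L)) {
      P[, l + 2L] <- ((2 * l + 1) * mu * P[, l + 1L] - l * P[, l]) / (l + 1)
    }
  }
  P
}
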