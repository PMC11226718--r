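#' Depth-dose profile from a converged solution
#'
#' `D_i = sum_g E_dep(g) phi_{g,i} / rho_i` per source electron, with the
#' electron-only energy-deposition cross section (photons are eliminated at
#' birth and tallied separately).
#'
#' @param sol a [solve_bfp()] solution.
#' @param libs the library (or named list of libraries) used for the solve.
#' @return data.frame with columns `depth_cm` (voxel midpoints),
#'   `voxel_width_cm`, `dose_MeV_per_g` (per source electron) and
#'   `material`.
#' @export
dose_profile <- function(sol, libs) {
  if (inherits(libs, "multigroup_library"))
    libs <- setNames(list(libs), sol$lib_names)
  phi0 <- solution_phi(sol, 0L)               # G x nx
  nx <- nrow(sol$mesh)
  dose <- numeric(nx)
  rho <- numeric(nx)
  for (m in seq_along(libs)) {
    idx <- which(sol$matid == m)
    if (!length(idx)) next
    lb <- libs[[m]]
    dose[idx] <- as.vector(crossprod(phi0[, idx, drop = FALSE], lb$Edep)) /
      lb$material$rho / sol$n_source
    rho[idx] <- lb$material$rho
  }
  data.frame(depth_cm = sol$mesh$x_mid, voxel_width_cm = sol$mesh$dx,
             dose_MeV_per_g = dose, material = sol$mesh$material,
             stringsAsFactors = FALSE)
}

#' Global energy audit of a solve
#'
#' Checks that the incident beam energy is recovered as deposited electron
#' energy plus tallied radiative/fluorescence photon energy (photons are
#' killed at birth), plus boundary leakage and the sub-cutoff residual.
#'
#' @param sol a [solve_bfp()] solution.
#' @param libs library or named list of libraries.
#' @param E_MeV incident kinetic energy per source electron (default: the
#'   top boundary of the source group, which is exactly the energy the
#'   discrete beam carries under the energy-edge injection).
#' @return list with components `incident`, `deposited`, `photon`,
#'   `leakage`, `subcutoff` (MeV per source electron) and
#'   `balance` (relative closure error).
#' @export
energy_audit <- function(sol, libs, E_MeV = NULL) {
  if (inherits(libs, "multigroup_library"))
    libs <- setNames(list(libs), sol$lib_names)
  if (is.null(E_MeV)) E_MeV <- sol$gs$bounds_MeV[sol$source_group + 1L]
  phi0 <- solution_phi(sol, 0L)
  dep <- 0
  phot <- 0
  for (m in seq_along(libs)) {
    idx <- which(sol$matid == m)
    if (!length(idx)) next
    lb <- libs[[m]]
    wdx <- sol$mesh$dx[idx]
    dep <- dep + sum(as.vector(crossprod(phi0[, idx, drop = FALSE],
                                         lb$Edep)) * wdx)
    phot <- phot + sum(as.vector(crossprod(phi0[, idx, drop = FALSE],
                                           lb$Ephot)) * wdx)
  }
  inc <- E_MeV * sol$n_source
  total <- dep + phot + sol$leakage_E + sol$subcutoff_E
  list(incident = inc, deposited = dep, photon = phot,
       leakage = sol$leakage_E, subcutoff = sol$subcutoff_E,
       balance = (total - inc) / inc)
}
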