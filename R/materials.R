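## Built-in material compositions (mass fractions). Tissue-type compositions
## follow ICRU-44/ICRP reference media; steel is stainless 304; the tumor
## medium uses the soft-tissue composition at 1.04 g/cm^3.
BUILTIN_MATERIALS <- list(
  water    = list(rho = 1.000, I = 75.0,
                  comp = c(H = 0.111894, O = 0.888106)),
  tissue   = list(rho = 1.060, I = NA,
                  comp = c(H = 0.102, C = 0.143, N = 0.034, O = 0.708,
                           Na = 0.002, P = 0.003, S = 0.003, Cl = 0.002,
                           K = 0.003)),
  muscle   = list(rho = 1.050, I = NA,
                  comp = c(H = 0.102, C = 0.143, N = 0.034, O = 0.710,
                           Na = 0.001, P = 0.002, S = 0.003, Cl = 0.001,
                           K = 0.004)),
  bone     = list(rho = 1.920, I = NA,
                  comp = c(H = 0.034, C = 0.155, N = 0.042, O = 0.435,
                           Na = 0.001, Mg = 0.002, P = 0.103, S = 0.003,
                           Ca = 0.225)),
  lung     = list(rho = 0.260, I = NA,
                  comp = c(H = 0.103, C = 0.105, N = 0.031, O = 0.749,
                           Na = 0.002, P = 0.002, S = 0.003, Cl = 0.003,
                           K = 0.002)),
  adipose  = list(rho = 0.950, I = NA,
                  comp = c(H = 0.114, C = 0.598, N = 0.007, O = 0.278,
                           Na = 0.001, S = 0.001, Cl = 0.001)),
  tumor    = list(rho = 1.040, I = NA,
                  comp = c(H = 0.102, C = 0.143, N = 0.034, O = 0.708,
                           Na = 0.002, P = 0.003, S = 0.003, Cl = 0.002,
                           K = 0.003)),
  steel    = list(rho = 8.000, I = NA,
                  comp = c(Fe = 0.695, Cr = 0.190, Ni = 0.095, Mn = 0.020)),
  aluminum = list(rho = 2.699, I = NA, comp = c(Al = 1.0))
)

#' Material specification
#'
#' A material is a set of elements with mass fractions, a density, and the
#' Sternheimer density-effect parameters derived from its electron density and
#' mean excitation energy. Built-in names cover the benchmark media (`water`,
#' `tissue`, `muscle`, `bone`, `lung`, `adipose`, `tumor`, `steel`,
#' `aluminum`) and every embedded element symbol (pure slabs at the
#' condensed-phase reference density).
#'
#' @param name built-in material name or element symbol, ignored when
#'   `composition` is given.
#' @param composition named numeric vector of mass fractions by element
#'   symbol; must sum to 1 within `1e-12`.
#' @param rho mass density in g/cm^3 (required with `composition`).
#' @param I optional mean excitation energy override in eV; otherwise Bragg
#'   additivity over the constituents.
#' @return an object of class `material_spec` with fields `name`, `elements`
#'   (list of [element_record()]), `fractions`, `rho`, `I_eV`, `ZA` (mean
#'   Z/A), and `sternheimer` (density-effect fit parameters).
#' @export
#' @examples
#' w <- material("water")
#' w$I_eV
material <- function(name = NULL, composition = NULL, rho = NULL, I = NULL) {
  if (is.null(composition)) {
    stopifnot(is.character(name))
    if (name %in% names(BUILTIN_MATERIALS)) {
      b <- BUILTIN_MATERIALS[[name]]
      composition <- b$comp
      if (is.null(rho)) rho <- b$rho
      if (is.null(I) && !is.na(b$I)) I <- b$I
    } else if (name %in% ELEMENT_TABLE$sym) {
      el <- element_record(name)
      composition <- setNames(1, name)
      if (is.null(rho)) rho <- el$rho
    } else {
      stop("unknown material: ", name)
    }
  }
  if (is.null(name)) name <- "custom"
  if (abs(sum(composition) - 1) > 1e-12)
    stop("mass fractions must sum to 1 (got ", sum(composition), ")")
  if (is.null(rho) || rho <= 0) stop("density must be positive")
  elements <- lapply(names(composition), element_record)
  w <- unname(composition)
  ZA <- sum(w * vapply(elements, function(e) e$Z / e$A, 0))
  if (is.null(I)) {
    ## Bragg additivity: ln I = sum(w Z/A ln I) / sum(w Z/A)
    lnI <- sum(w * vapply(elements, function(e) e$Z / e$A * log(e$I), 0)) / ZA
    I <- exp(lnI)
  }
  obj <- list(name = name, elements = elements, fractions = w,
              rho = rho, I_eV = I, ZA = ZA,
              sternheimer = sternheimer_parameters(rho, ZA, I))
  class(obj) <- "material_spec"
  obj
}

#' @export
print.material_spec <- function(x, ...) {
  cat(sprintf("<material_spec> %s  rho=%.3f g/cm^3  I=%.1f eV\n",
              x$name, x$rho, x$I_eV))
  comp <- paste(sprintf("%s:%.4f",
                        vapply(x$elements, `[[`, "", "symbol"), x$fractions),
                collapse = " ")
  cat(" ", comp, "\n")
  invisible(x)
}

## Sternheimer-Peierls generic fit parameters from (rho, Z/A, I).
## Plasma energy hbar*omega_p = 28.816 sqrt(rho Z/A) eV; -C = 2 ln(I/hwp) + 1;
## condensed-media x0/x1 rules split at I = 100 eV, exponent m = 3.
sternheimer_parameters <- function(rho, ZA, I_eV) {
  hwp <- 28.816 * sqrt(rho * ZA)      # eV
  Cbar <- 2 * log(I_eV / hwp) + 1
  if (I_eV < 100) {
    x1 <- 2.0
    x0 <- if (Cbar < 3.681) 0.2 else 0.326 * Cbar - 1.0
  } else {
    x1 <- 3.0
    x0 <- if (Cbar < 5.215) 0.2 else 0.326 * Cbar - 1.5
  }
  a <- (Cbar - 2 * log(10) * x0) / (x1 - x0)^3
  list(hwp_eV = hwp, Cbar = Cbar, x0 = x0, x1 = x1, a = a, m = 3)
}

#' Sternheimer density-effect correction
#'
#' Evaluates the density-effect term `delta(E)` of the collisional stopping
#' power for a material, using generic Sternheimer-Peierls fit parameters
#' computed from the material's density, mean Z/A and mean excitation energy.
#'
#' @param E kinetic energy in MeV (vectorised).
#' @param mat a [material()].
#' @return `delta` (dimensionless, `>= 0`).
#' @export
density_effect_delta <- function(E, mat) {
  p <- mat$sternheimer
  x <- log10(reduced_momentum(reduced_energy(E)))
  delta <- ifelse(
    x >= p$x1, 2 * log(10) * x - p$Cbar,
    ifelse(x >= p$x0,
           2 * log(10) * x - p$Cbar + p$a * (p$x1 - x)^p$m,
           0)
  )
  pmax(delta, 0)
}

#' Read material definitions from a YAML file
#'
#' The file maps material names to `elements` (symbol: mass-fraction pairs),
#' `rho` (g/cm^3) and optionally `I` (eV).
#'
#' @param path YAML file path.
#' @return named list of [material()] objects.
#' @export
read_materials <- function(path) {
  defs <- yaml::read_yaml(path)
  out <- lapply(names(defs), function(nm) {
    d <- defs[[nm]]
    material(name = nm, composition = unlist(d$elements), rho = d$rho,
             I = d$I)
  })
  setNames(out, names(defs))
}
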