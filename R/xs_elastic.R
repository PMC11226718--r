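## Relativistic Moliere-screened Mott elastic scattering. The within-group
## Legendre cross sections are obtained semi-analytically from
## Goudsmit-Saunderson moments G_l = sigma_0 - sigma_l built out of Spencer
## integrals P_l^m = int (1 - P_l(mu)) (1 - mu + 2 eta)^m dmu: the screened
## Mott-Rutherford part in closed form (Legendre functions of the second
## kind), the McKinley-Feshbach Z-odd correction by a log-transformed
## composite quadrature that resolves the near-singular forward peak.

#' Moliere screening parameter
#'
#' Nigam's improved Moliere screening,
#' `eta = Z^(2/3) / (4 (0.885 / alpha)^2 p^2) * (1.13 + 3.76 (Z alpha /
#' beta)^2)` with `p = sqrt(e(e+2))` the reduced momentum. Decreasing in
#' energy, increasing in Z.
#'
#' @param e reduced kinetic energy (`> 0`, vectorised).
#' @param Z atomic number.
#' @return dimensionless screening parameter `eta > 0`.
#' @export
screening_eta <- function(e, Z) {
  if (any(e <= 0)) stop("e must be positive")
  p2 <- e * (e + 2)
  beta2 <- p2 / (e + 1)^2
  Z^(2 / 3) / (4 * (0.885 / ALPHA_FS)^2 * p2) *
    (1.13 + 3.76 * Z^2 * ALPHA_FS^2 / beta2)
}

#' Mott-Rutherford ratio (McKinley-Feshbach)
#'
#' Ratio of the Mott to the Rutherford cross section in the McKinley-Feshbach
#' closed form, `chi = 1 - beta^2 s^2 + pi Z alpha beta s (1 - s)` with
#' `s = sin(theta/2) = sqrt((1-mu)/2)`. Tends to 1 in the forward direction
#' and in the non-relativistic (Rutherford) limit. Known to degrade for
#' Z above roughly 30, where the exact Mott ratio departs from this low-Z
#' expansion.
#'
#' @param mu scattering cosine in `[-1, 1]` (vectorised).
#' @param e reduced kinetic energy (`> 0`).
#' @param Z atomic number.
#' @param nu_e empirical scaling of the Z-odd correction term (default 1).
#' @return dimensionless ratio.
#' @export
mott_ratio_chi <- function(mu, e, Z, nu_e = 1) {
  if (any(mu < -1) || any(mu > 1)) stop("mu must be in [-1, 1]")
  beta <- velocity_beta(e)
  s2 <- (1 - mu) / 2
  s <- sqrt(s2)
  1 - beta^2 * s2 + pi * Z * ALPHA_FS * beta * nu_e * s * (1 - s)
}

## Legendre functions of the second kind Q_0..Q_lmax at z > 1 (upward
## recurrence; stable here because z is barely above 1 and l stays small)
legendre_Q <- function(z, lmax) {
  Q <- numeric(lmax + 1L)
  Q[1L] <- 0.5 * log((z + 1) / (z - 1))
  if (lmax >= 1L) Q[2L] <- z * Q[1L] - 1
  if (lmax >= 2L) for (l in 1L:(lmax - 1L))
    Q[l + 2L] <- ((2 * l + 1) * z * Q[l + 1L] - l * Q[l]) / (l + 1)
  Q
}

## composite Gauss-Legendre in u = log(t), t = 1 + 2 eta - mu; integrates
## f(mu, t) * (1 - P_l(mu)) for all l = 0..lmax at once.
spencer_quad_table <- function(lmax, eta, f, nodes = 16L) {
  t0 <- 2 * eta
  t1 <- 2 + 2 * eta
  npan <- max(8L, ceiling((log(t1) - log(t0)) / 0.35))
  edges <- seq(log(t0), log(t1), length.out = npan + 1L)
  rule <- gl_rule(nodes)
  out <- numeric(lmax + 1L)
  for (i in seq_len(npan)) {
    q <- gl_map(rule, edges[i], edges[i + 1L])
    t <- exp(q$x)
    mu <- 1 + 2 * eta - t
    P <- legendre_table(mu, lmax)
    w <- q$w * t * f(mu, t)      # extra t from the log substitution
    out <- out + colSums(w * (1 - P))
  }
  out
}

## Spencer integrals for all l at once; closed forms for m = -1, -2,
## quadrature otherwise.
spencer_P_table <- function(lmax, m, eta, method = c("closed", "quadrature")) {
  method <- match.arg(method)
  z <- 1 + 2 * eta
  if (method == "closed" && m == -1) {
    Q <- legendre_Q(z, lmax)
    return(log((z + 1) / (z - 1)) - 2 * Q)
  }
  if (method == "closed" && m == -2) {
    Q <- legendre_Q(z, lmax)
    l <- seq_len(lmax)
    base <- 1 / (z - 1) - 1 / (z + 1)
    return(c(0, base + 2 * l * (z * Q[l + 1L] - Q[l]) / (z^2 - 1)))
  }
  spencer_quad_table(lmax, eta, function(mu, t) t^m)
}

#' Spencer integral for screened elastic kernels
#'
#' `P_l^m(eta) = int_{-1}^{1} (1 - mu + 2 eta)^m (1 - P_l(mu)) dmu`. The
#' order-0 integral vanishes for every `m`; for `l >= 1`, `m = 0` gives
#' exactly 2. Closed forms in terms of Legendre functions of the second kind
#' are used for `m = -1` and `m = -2` (the orders the screened Rutherford
#' part needs); other exponents, including half-integers, use a
#' log-transformed composite quadrature that resolves the `t = 2 eta`
#' forward peak. The semi-analytic and quadrature paths are
#' cross-validated in the test suite.
#'
#' @param l Legendre order (`>= 0`).
#' @param m exponent (any real).
#' @param eta screening parameter (`> 0`).
#' @param method `"auto"` (closed form when available), `"closed"`, or
#'   `"quadrature"`.
#' @return the integral value.
#' @export
spencer_P <- function(l, m, eta, method = c("auto", "closed", "quadrature")) {
  method <- match.arg(method)
  if (eta <= 0) stop("eta must be positive")
  if (l == 0) return(0)
  if (method == "quadrature" || (method != "quadrature" && !(m %in% c(-1, -2))))
    return(spencer_quad_table(l, eta, function(mu, t) t^m)[l + 1L])
  spencer_P_table(l, m, eta, method = "closed")[l + 1L]
}

#' Goudsmit-Saunderson moments of the screened Mott kernel
#'
#' `G_l = 2 pi r0^2 Z^2 ((e+1)/(e(e+2)))^2 int (1-P_l(mu)) chi(mu,e) /
#' (1 - mu + 2 eta)^2 dmu`, with `chi` the McKinley-Feshbach ratio. The
#' `"semianalytic"` path evaluates the screened-Rutherford part of `chi`
#' exactly through [spencer_P()] closed forms and only the Z-odd
#' correction term by quadrature; `"quadrature"` integrates the full kernel
#' numerically. `G_0 = 0` identically.
#'
#' @param e reduced kinetic energy (`> 0`; below 256 keV the same kernel is
#'   extended downward unless a user kernel is supplied to
#'   [elastic_moments()]).
#' @param Z atomic number.
#' @param L maximum order.
#' @param nu_e empirical correction factor on the Z-odd term (default 1).
#' @param method `"semianalytic"` or `"quadrature"`.
#' @return numeric vector `G_0..G_L` in cm^2.
#' @export
gs_moments_mott <- function(e, Z, L, nu_e = 1,
                            method = c("semianalytic", "quadrature")) {
  method <- match.arg(method)
  eta <- screening_eta(e, Z)
  beta <- velocity_beta(e)
  pref <- 2 * pi * R0_CM^2 * Z^2 * ((e + 1) / (e * (e + 2)))^2
  if (method == "quadrature") {
    G <- spencer_quad_table(L, eta, function(mu, t)
      mott_ratio_chi(mu, e, Z, nu_e) / t^2)
    return(pref * G)
  }
  P2 <- spencer_P_table(L, -2, eta)
  P1 <- spencer_P_table(L, -1, eta)
  ## chi/t^2 = [1 - beta^2 (1-mu)/2] / t^2 + pi Z alpha beta nu s(1-s)/t^2
  ## and (1-mu) = t - 2 eta, so the first part is closed-form in P1, P2.
  corr <- spencer_quad_table(L, eta, function(mu, t) {
    s <- sqrt((1 - mu) / 2)
    s * (1 - s) / t^2
  })
  pref * (P2 - beta^2 / 2 * (P1 - 2 * eta * P2) +
            pi * Z * ALPHA_FS * beta * nu_e * corr)
}

## total within-group elastic cross section sigma_0 (cm^2)
elastic_sigma0 <- function(e, Z, nu_e = 1) {
  eta <- screening_eta(e, Z)
  beta <- velocity_beta(e)
  z <- 1 + 2 * eta
  pref <- 2 * pi * R0_CM^2 * Z^2 * ((e + 1) / (e * (e + 2)))^2
  I2 <- 1 / (z - 1) - 1 / (z + 1)
  I1 <- log((z + 1) / (z - 1))
  rule <- gl_rule(16L)
  npan <- max(8L, ceiling((log(z + 1) - log(z - 1)) / 0.35))
  edges <- seq(log(z - 1), log(z + 1), length.out = npan + 1L)
  J <- 0
  for (i in seq_len(npan)) {
    q <- gl_map(rule, edges[i], edges[i + 1L])
    t <- exp(q$x)
    mu <- z - t
    s <- sqrt(pmin(pmax((1 - mu) / 2, 0), 1))
    J <- J + sum(q$w * t * s * (1 - s) / t^2)
  }
  pref * (I2 - beta^2 / 2 * (I1 - 2 * eta * I2) +
            pi * Z * ALPHA_FS * beta * nu_e * J)
}

#' Extended transport correction
#'
#' Subtracts the highest retained Legendre moment from every moment,
#' `sigma_l - sigma_L`, zeroing the L-th moment exactly and making the
#' highly forward-peaked elastic kernel representable at order L.
#'
#' @param sigma_l numeric vector of moments `sigma_0..sigma_L`.
#' @return corrected vector of the same length.
#' @export
transport_correction <- function(sigma_l) {
  sigma_l - sigma_l[length(sigma_l)]
}

#' Within-group elastic Legendre cross sections per group
#'
#' Evaluates `sigma_l = sigma_0 - G_l` at each group midpoint (elastic
#' scattering is within-group: no energy is exchanged). The kernel is the
#' Moliere-screened Mott cross section at all energies by default; a
#' user-supplied kernel (for instance built from a Riley coefficient table
#' via [riley_kernel()]) replaces it below `riley_below`.
#'
#' @param gs a [build_group_structure()].
#' @param L maximum Legendre order.
#' @param elem an [element_record()] or atomic number.
#' @param nu_e empirical Z-odd correction factor.
#' @param kernel optional `function(e, Z, L)` returning `sigma_0..sigma_L`
#'   (cm^2) used below `riley_below`.
#' @param riley_below energy (reduced units) below which `kernel` applies;
#'   default 256 keV.
#' @return matrix `(G, L+1)` of uncorrected within-group moments in cm^2
#'   (apply [transport_correction()] rowwise for transport use).
#' @export
elastic_moments <- function(gs, L, elem, nu_e = 1, kernel = NULL,
                            riley_below = reduced_energy(0.256)) {
  Z <- if (inherits(elem, "element_record")) elem$Z else elem
  out <- matrix(0, gs$G, L + 1L)
  for (g in seq_len(gs$G)) {
    e <- gs$mid[g]
    if (!is.null(kernel) && e <= riley_below) {
      out[g, ] <- kernel(e, Z, L)
    } else {
      out[g, ] <- elastic_sigma0(e, Z, nu_e) - gs_moments_mott(e, Z, L, nu_e)
    }
  }
  out
}

#' Read a Riley elastic-coefficient table
#'
#' Tabular dialect: whitespace-separated columns `energy_MeV D B A1 A2 A3 A4
#' C0 C1 C2 C3 C4 C5 C6` (one row per tabulated energy), `A_m` and `C_n` in
#' angstrom^2/sr, `D` dimensionless, `B` the screening parameter.
#'
#' @param path file path.
#' @return data.frame with the named columns.
#' @export
read_riley_table <- function(path) {
  df <- read.table(path, header = TRUE)
  need <- c("energy_MeV", "D", "B", paste0("A", 1:4), paste0("C", 0:6))
  if (!all(need %in% names(df))) stop("missing Riley columns")
  df
}

#' Elastic kernel from Riley fit coefficients
#'
#' Builds a `function(e, Z, L)` returning within-group Legendre moments from
#' the 12-parameter Riley representation: a screened small-angle sum
#' `D sum_m A_m (1 - mu + 2B)^{-m}` plus a Legendre tail `sum_n C_n P_n(mu)`,
#' with Goudsmit-Saunderson moments assembled through [spencer_P()]
#' integrals. Coefficients are interpolated log-linearly in energy.
#'
#' @param table a data.frame from [read_riley_table()].
#' @return kernel function suitable for [elastic_moments()].
#' @export
riley_kernel <- function(table) {
  ang2 <- 1e-16  # angstrom^2 in cm^2
  function(e, Z, L) {
    E <- from_reduced_energy(e)
    interp <- function(col) {
      if (nrow(table) == 1L) return(table[[col]])
      approx(log(table$energy_MeV), table[[col]], xout = log(E), rule = 2)$y
    }
    D <- interp("D"); B <- interp("B")
    A <- vapply(paste0("A", 1:4), interp, 0)
    Cn <- vapply(paste0("C", 0:6), interp, 0)
    ## sigma_0 = 2 pi [ D sum_m A_m I_m + 2 C_0 ]
    z <- 1 + 2 * B
    Im <- vapply(1:4, function(m) {
      if (m == 1) log((z + 1) / (z - 1))
      else ((z - 1)^(1 - m) - (z + 1)^(1 - m)) / (m - 1)
    }, 0)
    sig0 <- 2 * pi * (D * sum(A * Im) + 2 * Cn[1L]) * ang2
    Gl <- vapply(0:L, function(l) {
      if (l == 0) return(0)
      Pm <- vapply(1:4, function(m) spencer_P(l, -m, B), 0)
      Cl <- if (l <= 6) Cn[l + 1L] else 0
      2 * pi * (D * sum(A * Pm) + Cn[1L] - Cl) * ang2
    }, 0)
    sig0 - Gl
  }
}
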