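## Moller catastrophic ionization: free-electron two-body kinematics, the
## Lorence-Morel catastrophic-jump cutoff, and the primary (ee) and delta-ray
## (e-delta) multigroup transfer matrices. The delta ray is by convention the
## less energetic outgoing electron, so e_delta <= e'/2.

#' Moller differential cross section
#'
#' Free-electron ionization kernel per atomic electron,
#' `(r0/beta')^2 [ 1/e_d^2 + 1/e_e^2 + 1/(e'+1)^2
#'   - (2e'+1) / ((e'+1)^2 e_e e_d) ]` with `e_e = e' - e_d`, in cm^2 per
#' reduced energy. Symmetric under exchange of the two outgoing electrons
#' and singular as `1/e_d^2` for soft delta rays.
#'
#' @param e_prime incident reduced kinetic energy.
#' @param e_delta delta-ray reduced kinetic energy in `(0, e_prime/2]`.
#' @return cross section per atomic electron, cm^2 / reduced energy.
#' @export
moller_ddcs <- function(e_prime, e_delta) {
  if (any(e_delta <= 0) || any(e_delta > e_prime / 2 + 1e-12 * e_prime))
    stop("delta-ray energy must lie in (0, e_prime/2]")
  moller_kernel(e_prime, e_prime - e_delta)
}

## bare Moller bracket without the delta-convention domain check; e_out is
## the energy of either outgoing electron (the bracket is exchange-symmetric)
moller_kernel <- function(e_prime, e_out) {
  ed <- e_prime - e_out
  (R0_CM / velocity_beta(e_prime))^2 *
    (1 / ed^2 + 1 / e_out^2 + 1 / (e_prime + 1)^2 -
       (2 * e_prime + 1) / ((e_prime + 1)^2 * e_out * ed))
}

#' Two-body scattering cosine
#'
#' Laboratory direction cosine of an outgoing electron of reduced energy
#' `e_out` from an ionization event at incident energy `e_prime`:
#' `mu = sqrt( e_out (e' + 2) / ( e' (e_out + 2) ) )`. Both outgoing
#' electrons are forward peaked; `mu = 1` iff `e_out = e_prime`.
#'
#' @param e_prime incident reduced kinetic energy (`> 0`).
#' @param e_out outgoing reduced kinetic energy in `[0, e_prime]`.
#' @return cosine in `[0, 1]`.
#' @export
kinematic_cosine <- function(e_prime, e_out) {
  if (any(e_out < 0) || any(e_out > e_prime * (1 + 1e-12)))
    stop("e_out must lie in [0, e_prime]")
  sqrt(pmin(e_out * (e_prime + 2) / (e_prime * (e_out + 2)), 1))
}

#' Catastrophic cutoff energy
#'
#' Lowest delta-ray energy produced by a catastrophic ionization event: a
#' collision is catastrophic when the scattered primary skips the two
#' adjacent lower groups, i.e. lands at or below the boundary `e^{g'-2}`,
#' giving `e_c = e' - e^{g'-2}`. For incident groups without two full groups
#' below, the catastrophic channel is empty (all loss is soft) and `Inf` is
#' returned.
#'
#' @param gp incident group index.
#' @param gs a [build_group_structure()].
#' @param e_prime incident reduced energy (default: midpoint of group `gp`).
#' @return `e_c` in reduced units, or `Inf` for an empty channel.
#' @export
catastrophic_cutoff <- function(gp, gs, e_prime = gs$mid[gp]) {
  if (gp < 1 || gp > gs$G) stop("invalid group index")
  if (gp < 3) return(Inf)
  e_prime - gs$bounds[gp - 2L]
}

## Gauss-Legendre rule cache (reference interval [-1, 1])
.gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]])) .gl_cache[[key]] <- pracma::gaussLegendre(n, -1, 1)
  .gl_cache[[key]]
}
gl_map <- function(rule, a, b) {
  list(x = (a + b) / 2 + (b - a) / 2 * rule$x, w = (b - a) / 2 * rule$w)
}

## Vectorised 2D panel quadrature over one (incident group, destination)
## panel with outer nodes epv (weights wout, already 1/De-normalised) and
## per-outer-node inner bounds [lo, hi]. kernel(EP, X) and mu(EP, X) operate
## elementwise. Returns list(moments = length L+1, e1 = outgoing-energy
## first moment).
panel_quad <- function(epv, wout, lo, hi, rule, L, kernel, mu) {
  sel <- hi > lo
  if (!any(sel)) return(NULL)
  half <- pmax((hi - lo) / 2, 0)
  mid <- (hi + lo) / 2
  X <- outer(half, rule$x) + mid          # [outer, inner]
  W <- outer(half, rule$w) * wout         # includes outer weights
  EP <- matrix(epv, length(epv), length(rule$x))
  K <- kernel(EP, X)
  WK <- as.vector(W * K)
  P <- legendre_table(as.vector(mu(EP, X)), L)
  list(moments = colSums(WK * P), e1 = sum(WK * X), ep1 = sum(WK * EP))
}

#' Build the Moller ionization transfer matrices
#'
#' Populates the Legendre-resolved group-to-group transfer matrices for the
#' scattered primary (`ee`) and the delta ray (`ed`) by fixed-order
#' Gauss-Legendre quadrature of the Moller kernel over each admissible
#' (incident group, destination group) panel, with the Legendre polynomial
#' evaluated at the energy-dependent two-body cosine of the outgoing
#' particle. Incident-group weighting is flat (`1/De^{g'}`). Values are per
#' atom (scaled by Z). Energy first moments needed by the deposition cross
#' section are accumulated alongside: the incident-energy-weighted
#' catastrophic total `A1` and the outgoing-energy-weighted channel sums
#' `Eout_ee`, `Eout_ed` (all reduced units times cm^2).
#'
#' @param gs a [build_group_structure()].
#' @param L maximum Legendre order.
#' @param elem an [element_record()] (or atomic number).
#' @param nodes Gauss-Legendre points per panel dimension (default 16).
#' @return an object of class `ionization_transfer` with arrays `ee`, `ed`
#'   of dimension `(G, G, L+1)` (incident, destination, order) in cm^2, and
#'   vectors `sig_cat`, `A1`, `Eout_ee`, `Eout_ed`.
#' @export
build_ionization_transfer <- function(gs, L, elem, nodes = 16L) {
  Z <- if (inherits(elem, "element_record")) elem$Z else elem
  G <- gs$G
  b <- gs$bounds
  rule <- gl_rule(nodes)
  ee <- array(0, c(G, G, L + 1L))
  ed <- array(0, c(G, G, L + 1L))
  sig_cat <- A1 <- Eout_ee <- Eout_ed <- numeric(G)
  kern_out <- function(EP, X) Z * moller_kernel(EP, X)
  mu_out <- function(EP, X) kinematic_cosine(EP, X)

  for (gp in seq_len(G)) {
    if (gp < 4L) next  # primary must land at or below boundary g'-2
    bc <- b[gp - 2L]   # top admissible scattered-primary energy
    outer_q <- gl_map(rule, b[gp], b[gp + 1L])
    epv <- outer_q$x
    wout <- outer_q$w / gs$width[gp]
    ## ee channel: e_e in [max(e^g, e'/2), e^{g+1}], destinations g <= g'-3
    for (g in seq_len(gp - 3L)) {
      res <- panel_quad(epv, wout, pmax(b[g], epv / 2),
                        rep(min(b[g + 1L], bc), length(epv)),
                        rule, L, kern_out, mu_out)
      if (is.null(res)) next
      ee[gp, g, ] <- res$moments
      Eout_ee[gp] <- Eout_ee[gp] + res$e1
    }
    ## ed channel: e_d in [max(e^g, e_c), min(e^{g+1}, e'/2)]
    ec <- epv - bc
    for (g in seq_len(gp - 1L)) {
      res <- panel_quad(epv, wout, pmax(b[g], ec),
                        pmin(b[g + 1L], epv / 2),
                        rule, L, kern_out, mu_out)
      if (is.null(res)) next
      ed[gp, g, ] <- res$moments
      Eout_ed[gp] <- Eout_ed[gp] + res$e1
    }
    sig_cat[gp] <- sum(ee[gp, , 1L])
    ## incident-energy first moment of the catastrophic total
    lo <- ec
    hi <- epv / 2
    sel <- hi > lo
    if (any(sel)) {
      half <- pmax((hi - lo) / 2, 0)
      X <- outer(half, rule$x) + (hi + lo) / 2
      W <- outer(half, rule$w) * (wout * epv)
      EP <- matrix(epv, length(epv), nodes)
      A1[gp] <- sum(W * Z * moller_kernel(EP, EP - X))
    }
  }
  structure(list(gs = gs, L = L, Z = Z, ee = ee, ed = ed,
                 sig_cat = sig_cat, A1 = A1,
                 Eout_ee = Eout_ee, Eout_ed = Eout_ed),
            class = "ionization_transfer")
}
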