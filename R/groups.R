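#' Build a multigroup energy structure
#'
#' Boundaries are logarithmically spaced between the transport cutoff and the
#' maximum energy, stored in reduced units in ascending order: group `g` spans
#' `[e^g, e^{g+1}]`, the group index increases with energy, and the solver
#' sweeps from the highest group downward. The default cutoff is 1 keV, the
#' standard transport cutoff for condensed-history and multigroup electron
#' transport.
#'
#' @param G number of groups (`>= 3`; the catastrophic-jump rule needs at
#'   least two groups below the incident one).
#' @param E_max top boundary in MeV.
#' @param E_min transport cutoff in MeV (default 1 keV).
#' @return an object of class `group_structure` with fields `G`, `bounds`
#'   (length `G+1`, reduced units, strictly increasing), `mid` (arithmetic
#'   midpoints), `width`, and `bounds_MeV`.
#' @export
#' @examples
#' gs <- build_group_structure(300, E_max = 100)
#' length(gs$bounds)  # 301
build_group_structure <- function(G, E_max, E_min = 1e-3) {
  if (G < 3) stop("at least 3 groups are required")
  if (E_min <= 0 || E_max <= E_min) stop("need 0 < E_min < E_max")
  b <- exp(seq(log(reduced_energy(E_min)), log(reduced_energy(E_max)),
               length.out = G + 1L))
  b[G + 1L] <- reduced_energy(E_max)   # top boundary exact
  obj <- list(G = as.integer(G), bounds = b,
              mid = (b[-1L] + b[-(G + 1L)]) / 2,
              width = diff(b),
              bounds_MeV = b * MEC2)
  class(obj) <- "group_structure"
  obj
}

#' @export
print.group_structure <- function(x, ...) {
  cat(sprintf("<group_structure> %d groups, %.3g keV .. %.4g MeV (log-spaced)\n",
              x$G, x$bounds_MeV[1] * 1e3, x$bounds_MeV[x$G + 1L]))
  invisible(x)
}

## group index containing reduced energy e; exact boundary hits are assigned
## to the lower group (deterministic tie-break). 0 if below cutoff.
group_index <- function(gs, e) {
  idx <- findInterval(e, gs$bounds, rightmost.closed = TRUE)
  idx[e <= gs$bounds[1L]] <- ifelse(e[e <= gs$bounds[1L]] == gs$bounds[1L], 1L, 0L)
  ## exact interior boundary -> lower group
  on_bound <- match(e, gs$bounds, nomatch = 0L)
  sel <- on_bound > 1L & on_bound <= gs$G
  idx[sel] <- on_bound[sel] - 1L
  pmin(idx, gs$G)
}
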