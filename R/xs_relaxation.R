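## Gryzinski impact ionization of inner subshells and the Auger/fluorescence
## relaxation cascades. Cascade candidates follow the Z thresholds K: Z>10,
## L1: Z>27, L2/L3: Z>29, M: Z>51, N: Z>84; emitted energies are binding
## energy differences; a vacancy relaxes until it reaches the outermost
## subshell, and each complete path's probability is the product of its
## branch probabilities. Auger emission is isotropic (l = 0 only).

CASCADE_Z_MIN <- c(K = 10, L1 = 27, L2 = 29, L3 = 29, M = 51, N = 84)
MAX_SUBSHELLS <- 5L
MAX_LINES <- 28L

#' Gryzinski impact ionization cross section
#'
#' Group-averaged (flat weighting over the incident group) Gryzinski cross
#' section for one subshell of binding energy `e_b` (reduced units):
#' `sigma = (pi / De) int de' (r0/e_b)^2 (beta_j^2/beta_e^2)
#'   (beta_e^2 / (beta_e^2 + beta_j^2 - beta_e^2 beta_j^2))^{1/3}
#'   [1 + 2/3 (1 - e_b/(2e')) ln(2.7 + sqrt(e'/e_b - 1))]
#'   (1 - e_b/e')^{1/3}`,
#' with `beta_j = sqrt(e_b (e_b + 2)) / (e_b + 1)`. Vanishes at and below
#' threshold through the cube-root factor. Zero-binding (N-shell) subshells
#' degenerate; the binding energy is floored at the transport cutoff.
#'
#' @param e_prime incident reduced energy, or a length-2 numeric giving the
#'   group bounds to average over (flat weighting).
#' @param e_b subshell binding energy in reduced units (`>= 0`).
#' @param cutoff floor applied to `e_b` (reduced units; default 1 keV).
#' @param nodes quadrature nodes for the group average.
#' @return cross section in cm^2 (per subshell electron; multiply by the
#'   occupancy for the subshell total).
#' @export
gryzinski_sigma <- function(e_prime, e_b, cutoff = reduced_energy(1e-3),
                            nodes = 8L) {
  if (e_b < 0) stop("binding energy must be non-negative")
  eb <- max(e_b, cutoff)
  bj2 <- eb * (eb + 2) / (eb + 1)^2
  point <- function(ep) {
    if (ep <= eb) return(0)
    be2 <- ep * (ep + 2) / (ep + 1)^2
    (pi * R0_CM^2 / eb^2) * (bj2 / be2) *
      (be2 / (be2 + bj2 - be2 * bj2))^(1 / 3) *
      (1 + 2 / 3 * (1 - eb / (2 * ep)) * log(2.7 + sqrt(ep / eb - 1))) *
      (1 - eb / ep)^(1 / 3)
  }
  if (length(e_prime) == 2L) {
    q <- gl_map(gl_rule(nodes), e_prime[1L], e_prime[2L])
    sum(q$w * vapply(q$x, point, 0)) / diff(e_prime)
  } else {
    vapply(e_prime, point, 0)
  }
}

## default donor rules for the synthetic cascade: which shallower subshells
## fill a vacancy and which partner is ejected in an Auger event
.cascade_donors <- list(
  K  = list(fluor = "L3", auger = c("L2", "L3")),
  L1 = list(fluor = "M",  auger = c("M", "N")),
  L2 = list(fluor = "M",  auger = c("M", "N")),
  L3 = list(fluor = "M",  auger = c("M", "N")),
  M  = list(fluor = "N",  auger = c("N", "N")),
  N  = NULL
)

## recursive tree expansion: relax a single vacancy, returning a list of
## terminal outcomes, each with prob and a data.frame of emitted lines
relax_vacancy <- function(shell, eb, omega, donors = .cascade_donors) {
  rule <- donors[[shell]]
  avail <- names(eb)[eb > 0 | names(eb) == "N"]
  if (is.null(rule) || !all(c(rule$fluor, rule$auger) %in% avail) ||
      eb[[shell]] <= 0) {
    return(list(list(prob = 1,
                     lines = data.frame(type = character(), energy = numeric(),
                                        stringsAsFactors = FALSE))))
  }
  wf <- omega[[shell]]
  out <- list()
  ## fluorescence branch: photon e_j - e_donor, vacancy moves to donor
  if (wf > 0) {
    egam <- eb[[shell]] - eb[[rule$fluor]]
    sub <- relax_vacancy(rule$fluor, eb, omega, donors)
    for (s in sub) {
      out[[length(out) + 1L]] <- list(
        prob = wf * s$prob,
        lines = rbind(data.frame(type = "fluorescence", energy = egam,
                                 stringsAsFactors = FALSE), s$lines))
    }
  }
  ## Auger branch: electron e_j - e_d1 - e_d2, vacancies at both donors
  if (wf < 1) {
    d1 <- rule$auger[1L]; d2 <- rule$auger[2L]
    eaug <- max(eb[[shell]] - eb[[d1]] - eb[[d2]], 0)
    sub1 <- relax_vacancy(d1, eb, omega, donors)
    sub2 <- relax_vacancy(d2, eb, omega, donors)
    for (s1 in sub1) for (s2 in sub2) {
      out[[length(out) + 1L]] <- list(
        prob = (1 - wf) * s1$prob * s2$prob,
        lines = rbind(data.frame(type = "auger", energy = eaug,
                                 stringsAsFactors = FALSE),
                      s1$lines, s2$lines))
    }
  }
  out
}

#' Enumerate the relaxation cascade of an element
#'
#' Expands the full relaxation tree for each cascade-candidate subshell
#' (replicating de-excitations at every subshell call): each terminal path
#' carries the product of its branch probabilities, and path probabilities
#' sum to 1. Aggregated lines carry the expected number of emissions per
#' vacancy (`efficiency`) and the emitted energy (binding-energy
#' differences, reduced units). Elements below every Z threshold yield an
#' empty cascade. The subshell count and distinct-line count are capped at
#' 5 and 28; richer override data are rejected.
#'
#' @param elem an [element_record()].
#' @return an object of class `cascade_model`: list with `triggers` (per
#'   eligible subshell: `eb`, `occupancy`, `lines` data.frame with columns
#'   `type`, `energy`, `efficiency`, and `paths` with terminal
#'   probabilities), possibly empty.
#' @export
cascade_lines <- function(elem) {
  eb <- setNames(elem$subshells$eb, elem$subshells$shell)
  occ <- setNames(elem$subshells$occupancy, elem$subshells$shell)
  omega <- list(K = elem$yields$K, L1 = elem$yields$L, L2 = elem$yields$L,
                L3 = elem$yields$L, M = elem$yields$M, N = 0)
  eligible <- names(eb)[elem$Z > CASCADE_Z_MIN[names(eb)]]
  eligible <- setdiff(eligible, "N")  # N vacancies are terminal (e_b = 0)
  if (length(eligible) > MAX_SUBSHELLS)
    stop("at most ", MAX_SUBSHELLS, " cascade subshells are supported")
  triggers <- list()
  for (sh in eligible) {
    paths <- relax_vacancy(sh, eb, omega)
    probs <- vapply(paths, `[[`, 0, "prob")
    all_lines <- do.call(rbind, lapply(seq_along(paths), function(i) {
      df <- paths[[i]]$lines
      if (nrow(df)) df$prob <- probs[i]
      df
    }))
    if (is.null(all_lines) || nrow(all_lines) == 0L) next
    key <- paste(all_lines$type, signif(all_lines$energy, 12))
    agg <- lapply(split(all_lines, key), function(d)
      data.frame(type = d$type[1L], energy = d$energy[1L],
                 efficiency = sum(d$prob), stringsAsFactors = FALSE))
    lines <- do.call(rbind, agg)
    rownames(lines) <- NULL
    if (nrow(lines) > MAX_LINES)
      stop("cascade exceeds ", MAX_LINES, " transition lines")
    triggers[[sh]] <- list(eb = eb[[sh]], occupancy = occ[[sh]],
                           lines = lines, path_prob = probs)
  }
  structure(list(Z = elem$Z, triggers = triggers), class = "cascade_model")
}

#' Build the Auger transfer matrix and relaxation energy bookkeeping
#'
#' For each incident group, the Gryzinski subshell cross sections set the
#' vacancy production rate; each cascade line then either injects an
#' isotropic Auger electron into the group containing its energy (exact
#' boundary hits go to the lower group) or books fluorescence photon energy.
#' Lines below the transport cutoff are excluded from transport; their
#' energy stays in the local deposit. The per-vacancy energy balance
#' (emitted energy `<=` binding energy) holds line by line.
#'
#' @param gs a [build_group_structure()].
#' @param elem an [element_record()].
#' @param cascade a [cascade_lines()] model (default: built from `elem`).
#' @return an object of class `relaxation_transfer`: `aug` matrix `(G, G)`
#'   (incident, destination; l = 0 only, cm^2), `E_auger`, `E_fluor`,
#'   `E_local` vectors (reduced energy * cm^2 per incident group).
#' @export
build_relaxation_transfer <- function(gs, elem, cascade = cascade_lines(elem)) {
  G <- gs$G
  aug <- matrix(0, G, G)
  E_auger <- E_fluor <- E_local <- numeric(G)
  cutoff <- gs$bounds[1L]
  for (sh in names(cascade$triggers)) {
    tr <- cascade$triggers[[sh]]
    sig <- vapply(seq_len(G), function(gp)
      gryzinski_sigma(gs$bounds[gp + 0:1], tr$eb, cutoff = cutoff), 0) *
      tr$occupancy
    emitted <- 0
    for (k in seq_len(nrow(tr$lines))) {
      ln <- tr$lines[k, ]
      if (ln$energy < cutoff) next   # sub-cutoff emission stays local
      emitted <- emitted + ln$efficiency * ln$energy
      if (ln$type == "auger") {
        gk <- group_index(gs, ln$energy)
        if (gk >= 1L) aug[, gk] <- aug[, gk] + ln$efficiency * sig
        E_auger <- E_auger + ln$efficiency * ln$energy * sig
      } else {
        E_fluor <- E_fluor + ln$efficiency * ln$energy * sig
      }
    }
    if (emitted > tr$eb * (1 + 1e-9) + 1e-15)
      stop("cascade emits more energy than the vacancy binding energy")
    E_local <- E_local + (tr$eb - emitted) * sig
  }
  structure(list(gs = gs, aug = aug, E_auger = E_auger,
                 E_fluor = E_fluor, E_local = E_local),
            class = "relaxation_transfer")
}
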