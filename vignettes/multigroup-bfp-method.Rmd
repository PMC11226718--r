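---
title: "Multigroup electron cross sections and the 1D Boltzmann-Fokker-Planck depth-dose solver"
author: "bfpdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigroup electron cross sections and the 1D BFP depth-dose solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Very-high energy electron (VHEE, 50–300 MeV) and ultra-high energy
electron (UHEE, above 300 MeV) beams can reach deeply seated targets with
small lateral spread, and deterministic transport offers depth-dose answers
in seconds where Monte Carlo needs days. `bfpdose` implements the full
chain for the one-dimensional case: generation of multigroup electroatomic
cross-section libraries from analytic interaction models, and the
discrete-ordinates solution of the Boltzmann–Fokker–Planck (BFP) equation

$$\left[\mu_n \partial_x + \Sigma_{t,g}\right]\psi_{g,n}
 = \sum_x \sum_{l=0}^{L}\tfrac{2l+1}{2}P_l(\mu_n)\,
   \Sigma^{x}_{l,g'\to g}\,\psi^e_{l,g'}
 + \partial_E\left(\beta\,\psi\right)
 + \tfrac{\alpha}{2}\,\partial_\mu (1-\mu^2)\,\partial_\mu \psi + Q,$$

in which *catastrophic* collisions (energy transfers that skip at least the
two adjacent lower energy groups) are carried by explicit group-to-group
transfer matrices, while *soft* collisions are condensed into a restricted
continuous-slowing-down (CSD) stopping power $\beta_g$ and, optionally, an
angular Fokker–Planck momentum transfer $\alpha_g$.

Energies are carried in reduced units ($e = E/m_ec^2$) on a logarithmically
spaced group structure between a 1 keV transport cutoff (the standard
choice for condensed-history and multigroup electron transport) and the
beam energy. The group index increases with energy; the solver sweeps
downward. Log spacing gives uniform relative resolution over the six
decades between cutoff and UHEE energies.

# Interaction models

**Møller ionization** (`build_ionization_transfer`). Free-electron two-body
kinematics, no binding energy. The delta ray is the less energetic outgoing
electron ($e_\delta \le e'/2$); a collision is catastrophic when the
scattered primary lands at or below the boundary two groups down,
equivalently $e_\delta \ge e_c = e' - e^{g'-2}$. Both outgoing electrons
receive Legendre moments evaluated at the energy-dependent two-body cosine
$\mu = \sqrt{e_{out}(e'+2)/(e'(e_{out}+2))}$ inside the quadrature, and the
incident group is weighted flat ($1/\Delta e^{g'}$). Delta rays below the
transport cutoff are not produced; their energy stays in the soft channel.

**Bremsstrahlung** (`build_brems_transfer`). The Berger–Seltzer assembly
$\xi_r f_e [\sigma_1 + \sigma_2 - \sigma_3 + \omega(\sigma_4 - \sigma_2)]$:
the Koch–Motz Born kernel ($\sigma_1$), the Butcher–Messel screened kernel
($\sigma_2$), the non-relativistic Schiff kernel ($\sigma_3$) and the
Davies–Bethe–Maximon Coulomb-corrected kernel ($\sigma_4$), with the Elwert
factor $f_e$. The surviving electron keeps the incident direction
($P_l(1)=1$ for all orders). Choices left open by the formalism and made
here:

* $\omega(e')$ ramps smoothly from 0 at 15 MeV to 1 at 50 MeV total
  energy (a smoothstep), switching the Coulomb correction off where it is
  unreliable;
* the screening argument is $\zeta = 136\,Z^{-1/3} e_\gamma/(e_t e_s)$,
  and the two Butcher–Messel fit branches are blended smoothly over
  $\zeta \in [0.8, 1.2]$ (the raw pieces disagree by up to 0.3 at the
  conventional switch, and the assembly needs a continuous function);
* the high-frequency limit caps the photon at $e' - e^2$ (the top boundary
  of the lowest group) and the assembled spectrum is linearly extrapolated
  to zero over its last 1 %, which keeps it integrable despite the Elwert
  divergence at the tip;
* $\xi_r$ defaults to 1 with a per-element hook.

The radiative total stopping power is the photon-energy first moment of
this same assembled kernel, so the soft radiative stopping power (total
minus catastrophic moment) is non-negative by construction.

**Elastic scattering** (`elastic_moments`). Molière-screened Mott
scattering with Nigam's screening parameter and the McKinley–Feshbach
ratio, within-group only (no energy loss). Goudsmit–Saunderson moments
$\mathcal{G}_l = \sigma_0 - \sigma_l$ are evaluated semi-analytically: the
screened Rutherford part in closed form through Spencer integrals
$\mathcal{P}_l^m = \int (1-P_l)(1-\mu+2\eta)^m d\mu$ (Legendre functions of
the second kind for $m = -1, -2$), and the $Z$-odd McKinley–Feshbach
correction by a log-transformed composite quadrature that resolves the
forward peak at the scale of $\eta$ (down to $10^{-9}$ at VHEE energies; a
plain fixed-order rule cannot). A pure-quadrature path is kept as a
cross-check. The extended transport correction subtracts the $L$-th moment
from every moment, which removes a forward delta component (physically a
no-deflection term) and makes the kernel representable at order $L$.
The McKinley–Feshbach ratio is a low-$Z$ expansion; its accuracy degrades
for $Z \gtrsim 30$, which is a known limitation of this cross-section
family at high atomic number. Below 256 keV the same kernel is extended
downward by default; a tabulated low-energy (Riley-style) 12-parameter
kernel can be plugged in per element (`riley_kernel`).

**Impact ionization and relaxation** (`build_relaxation_transfer`).
Gryziński inner-shell ionization drives Auger/fluorescence cascades,
uncorrelated with the Møller channel. Cascade candidates follow the
thresholds K: $Z>10$, L1: $Z>27$, L2/L3: $Z>29$, M: $Z>51$, N: $Z>84$; the
full tree is expanded by replicating de-excitations at each vacancy, each
terminal path carrying the product of its branch probabilities (they sum
to 1). Auger emission is isotropic and binned to the group containing the
line energy (exact boundary hits go to the lower group); lines below the
cutoff deposit locally. Subshell binding energies and occupancies are a
screened-hydrogenic Dirac model with screening constants fitted to
measured K/L/M edges of O, Fe, Zn and Au — synthetic defaults, accurate to
roughly 10 %, fully overridable per element. Fluorescence yields use the
standard one-parameter $Z^4/(Z^4+A)$ fits. Because the Bethe collisional
stopping power already contains inner-shell losses, relaxation is booked
as a local redistribution: transported Auger electrons and tallied
fluorescence photons are subtracted from the local deposit, and the
remainder of the binding energy stays local.

# Library assembly

`build_material_library` mixes per-element microscopic channels by number
density, applies the transport correction, and derives:

* the total catastrophic cross section
  $\Sigma_t = \sum_g \Sigma^{ee} + \Sigma^{b} + \bar\Sigma^{el}_0$
  (delta-ray and Auger production do not remove the primary);
* restricted soft stopping powers: the analytic totals (Berger–Seltzer
  collisional with the Sternheimer–Peierls density effect computed from
  $\rho$, $Z/A$ and $I$; radiative by quadrature of the bremsstrahlung
  kernel) minus the catastrophic first-moment loss carried by the transfer
  matrices, evaluated at group midpoints and log-log interpolated to the
  boundaries;
* electron-only energy-deposition and photon-production cross sections
  (below).

The container written by `write_library` is a versioned R serialization of
the schema list; reading a newer schema version is refused and arrays
round-trip bit-identically.

# The solver and its numerical choices

`solve_bfp` runs one outer pass over groups from the source group downward
(upscatter is impossible), with plain source iteration of the within-group
scattering and a compiled diamond-difference spatial sweep at order
$M \in \{0, 1, 2\}$ (the printed closed forms for $\mu > 0$; negative
directions by mirror symmetry, which is algebraically identical). The
angular quadrature is Gauss–Legendre with $N = L + 1$ (a Galerkin pairing):
discrete orthogonality holds exactly for all retained orders, so a forward
delta kernel — the representation of the bremsstrahlung survivor and the
transport-corrected elastic remainder — is transported without deflection
to round-off.

**Slowing-down closure.** The group-to-group CSD handoff is carried as a
crossing rate $F = \beta\psi/\Delta E$, which is the quantity continuous
across boundaries of unequal width. The classic weighted-diamond closure
$\beta^+\psi^+ + \beta^-\psi^- = (\beta^+ + \beta^-)\psi$ is
non-dissipative and rings on the sharp spectral front that a monoenergetic
beam drags down the group cascade (an alternating mode that shows up as
several-percent dose oscillations). The solver therefore uses a
$\theta$-weighted closure — removal
$\sigma + (1+\theta)\bar\beta/\Delta E$, inflow source $(1+\theta)F^+$,
outflow $F^- = (1+\theta)\bar\beta\psi/\Delta E - \theta F^+$ — with
$\theta = 1$ the weighted diamond, $\theta = 0$ the upwind step, and the
default $\theta = 1/2$ damping the front mode geometrically at half the
upwind numerical straggling. The printed diamond algebra is available as
`csd_theta = 1` and through `energy_propagation()`.

**Discrete energy balance.** A particle injected into group $g$ is carried
by the $\theta$-closure from the representative energy
$b_g + \Delta E_g/(1+\theta)$ down to the lower edge. The deposition and
photon-production cross sections therefore debit removed primaries and
credit outgoing electrons at exactly these representative energies (the
analytic first moments remain stored and drive the restricted stopping
powers). With this bookkeeping the global audit — deposited electron
energy + tallied photon energy + boundary leakage + sub-cutoff residual
versus the incident energy — closes to better than 0.1 % at the
production discretisation; booking the analytic outgoing energies instead
leaves a 1–2 % gap at VHEE, because the transport scheme deposits group
representative rather than true energies downstream.

**Beam representation.** The beam is a boundary angular flux in the most
forward quadrature direction, normalised to unit incident current, and the
source group is solved with the upwind closure; the discrete beam then
enters carrying exactly the top boundary energy, independent of the group
count. Two-sided irradiation sums two such sources by linearity.

**Degenerate and edge cases.** Negative diamond fluxes are counted and
reported, not repaired (an optional set-to-zero fix-up exists); exact
boundary line energies bin to the lower group; zero-binding (N-shell)
subshells floor the Gryziński binding energy at the transport cutoff;
$\beta^- = 0$ would make the slowing-down outflow undefined and is
rejected. The momentum transfer $\alpha_g$ defaults to zero — elastic
scattering is fully catastrophic under the extended transport correction,
whose subtracted forward component carries no momentum transfer — and a
heuristic `sigma_L` mode reconstructs a diffusion coefficient from the
subtracted moment for sensitivity studies.

# Dose, audits and comparison metrics

The dose is strictly electronic: bremsstrahlung and fluorescence photons
are eliminated at the point of birth and only their energy is tallied, so
$D_i = \sum_g \mathcal{E}_g \phi_{g,i}/\rho$ with the electron-only
deposition cross section. `energy_audit` reports the full balance.
`compare_profiles` regrids two depth-dose curves by monotone
piecewise-cubic Hermite interpolation onto the union grid, computes
per-voxel relative deviations and the $\epsilon_1/\epsilon_2$ percentages
(voxels within 1 %/2 %), the mean absolute deviation $\bar\epsilon$, and a
two-sample Kolmogorov–Smirnov statistic on the normalised cumulative dose
distributions (decision at a 0.02 significance level by default). Voxels
whose reference dose is below 0.1 % of the profile maximum are excluded
from the deviation statistics — a deep-tail guard, configurable.

Benchmark phantoms are built from the layered fractional compositions of
the standard radiotherapy and high-$Z$ assemblies (water; thorax
muscle/bone/lung/tissue 13/7/22/58 %; the intra-operative tumor/Al/steel/
tissue 40/40/15/5 %; an 11-slab patient-like stack; and three non-medical
assemblies of mid- and high-$Z$ elements, irradiated from both sides). The
printed percentages of the 15-slab assembly sum to 170 %; they are kept
verbatim in `fractions_printed` and normalised for construction. The
total thickness consumes `kappa` (default 1.2) CSDA ranges distributed
over the layers, guaranteeing full beam attenuation.

# Problem sizes, verification scope and limitations

The production configuration mirrors the standard deterministic scheme for
this energy range: 150–300 groups, $S_{16}$ with $P_{15}$ anisotropy,
at least 100 voxels, inner tolerance $10^{-5}$. The test suite verifies,
at these and smaller sizes:

* every transfer-matrix builder against adaptive 2D quadrature of its
  defining integrals (to $10^{-6}$ relative on sampled entries), and the
  Spencer closed forms against composite direct quadrature (to
  $10^{-10}$);
* the channel-sum identity ($10^{-12}$), the soft+catastrophic
  stopping-power closure ($10^{-8}$) and the exact zero of the
  transport-corrected top moment;
* pure-absorber attenuation at the expected spatial orders (2nd at
  $M=0$, at least 3rd at $M=1$), the CSDA extinction depth of a
  slowing-down-only beam, and the Galerkin delta-transport property
  ($10^{-10}$);
* the global energy audit at 10/100/300 MeV on water within 0.5 %;
* group-count (150 vs 300) and mesh (100 vs 200 voxels) self-convergence
  of the 100 MeV water profile below 1 % mean absolute deviation.

What these checks do not establish: agreement with measured dose or with
Monte Carlo reference transport, which requires externally supplied
reference profiles (`compare_profiles`, `element_scan` accept them); the
accuracy of the McKinley–Feshbach ratio at high $Z$; the synthetic
relaxation data beyond their stated fidelity; photon transport (out of
scope by design — photons are killed at birth); and lateral (2D/3D)
transport. The low-energy elastic domain below 256 keV uses the
relativistic kernel unless a tabulated kernel is supplied. Beyond roughly
1.5 GeV the analytic assemblies leave their validated range and no claim
is made.
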