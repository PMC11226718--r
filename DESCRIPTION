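Package: bfpdose
Title: Multigroup Electron Cross Sections and 1D Boltzmann-Fokker-Planck
    Depth-Dose Calculation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates multigroup electroatomic cross-section libraries for
    electron beams from the conventional radiotherapy range up to very-high
    and ultra-high energies (1 MeV to 1.5 GeV): Moller catastrophic
    ionization with delta-ray production, Berger-Seltzer catastrophic
    bremsstrahlung with Elwert and Coulomb corrections, Moliere-screened
    Mott elastic scattering through Goudsmit-Saunderson moments with an
    extended transport correction, and Gryzinski impact ionization with
    Auger/fluorescence relaxation cascades. Assembles per-material
    macroscopic libraries with restricted (soft) stopping powers and
    energy-deposition cross sections, and solves the one-dimensional
    multigroup discrete-ordinates Boltzmann-Fokker-Planck equation with
    high-order diamond-difference spatial sweeps and weighted-diamond
    continuous-slowing-down energy propagation to produce depth-dose curves
    in heterogeneous slab phantoms. Includes standard radiotherapy and
    high-Z benchmark phantoms and dose-comparison metrics against reference
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
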