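Package: xrvib
Title: Vibronic X-Ray Absorption and Photoelectron Spectra from Harmonic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates vibronically resolved X-ray absorption (XANES) and
    photoelectron (XPS) spectra of molecules from ground-state harmonic data
    and per-state electronic inputs (vertical energies, Cartesian gradients,
    transition dipoles or Dyson norms, core-hole lifetimes). Implements the
    displaced harmonic oscillator (DHO) model via gradient projection onto
    mass-weighted normal modes, multi-mode Franck-Condon progressions by both
    sum-over-states and time-domain (FFT) routes, and beyond-DHO corrections:
    Duschinsky mode mixing with recursive multidimensional Franck-Condon
    overlaps and linear Herzberg-Teller intensity borrowing. Assembles full
    spectra with ionization-threshold rendering, lifetime and instrumental
    broadening, Boltzmann conformer averaging and normalization, and provides
    an iterative chunked virtual-orbital accumulation scheme for building
    core-excited state manifolds over a pluggable electronic-structure
    backend. Includes Molden frequency-file I/O, a YAML interchange bundle
    format, and seeded synthetic-model generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
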