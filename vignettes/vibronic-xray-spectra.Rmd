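---
title: "Vibronic X-ray spectra from harmonic models: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibronic X-ray spectra from harmonic models: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrvib)
```

# The problem

Core-level spectra (XANES absorption, XPS photoemission) of small molecules
show vibrational fine structure because removing or promoting a core electron
suddenly changes the forces on the nuclei. `xrvib` turns the minimal set of
quantum-chemical inputs — ground-state frequencies and normal modes, plus
per-state vertical energies, Cartesian gradients, transition dipoles or Dyson
norms, and core-hole lifetimes — into stick and broadened spectra. The
electronic-structure calculation itself is *not* part of the package: it is
consumed as data (a YAML "bundle"), or emulated by the synthetic generators.

# The displaced harmonic oscillator (DHO)

The baseline model assumes the final-state potential surface is the same
harmonic well as the ground state, rigidly displaced. All coupling
information then lives in the final-state gradient at the ground-state
minimum. With the mass-weighted gradient projected on mode $k$ (frequency
$\omega_k$, atomic units, $\hbar = 1$):

$$
\Delta_k = -\frac{g_k}{\omega_k^{3/2}}, \qquad
S_k = \frac{\Delta_k^2}{2} = \frac{g_k^2}{2\omega_k^3}, \qquad
\lambda_k = S_k\,\hbar\omega_k, \qquad
E_{00} = E_\mathrm{vert} - \textstyle\sum_k \lambda_k .
$$

$S_k$ is the Huang–Rhys factor, $\lambda_k$ the mode reorganization energy.
The sign convention (negative gradient $\to$ positive displacement) matters
only once Herzberg–Teller cross terms enter; it is fixed here and used
consistently by the synthetic generator.

At 0 K the Franck–Condon progression is a product of Poisson factors:
a line at $E_{00} + \sum_k n_k \hbar\omega_k$ with relative intensity
$\prod_k e^{-S_k} S_k^{n_k}/n_k!$. Two exact sum rules follow, and the test
suite asserts both: the intensity-weighted mean equals $E_\mathrm{vert}$ and
the variance equals $\sum_k S_k (\hbar\omega_k)^2$.

Two independent evaluation routes are implemented. `fc_sticks()` enumerates
the progression explicitly; `timedomain_spectrum()` evaluates the exact
cumulant expression

$$
\sigma(E) \propto \mathrm{Re}\!\int_0^\infty \! dt\;
e^{i(E - E_{00})t/\hbar}\,
\exp\!\Big[-\sum_k S_k\big(1 - e^{-i\omega_k t}\big)\Big] D(t),
$$

with damping $D(t) = e^{-\Gamma t/2\hbar} e^{-\sigma_G^2 t^2/2\hbar^2}$, by
FFT. Their pointwise agreement (relative $L_\infty < 10^{-3}$, in practice
$\sim 10^{-6}$) is a structural cross-check: the two routes share no code
beyond the constants table.

## Numerical choices

* **Truncation.** Per-mode ladders are cut when the per-mode cumulative
  Poisson weight reaches $(1-\varepsilon)^{1/M}$ (so the retained total is
  $\ge 1-\varepsilon$; default $\varepsilon = 10^{-4}$), then extended by
  three quanta so the truncation bias in the moment sum rules stays orders of
  magnitude below $\varepsilon$; a hard cap of 50 quanta per mode applies.
  Enumeration is lexicographic, making outputs deterministic.
* **FFT discretization.** The internal energy axis oversamples the requested
  grid (step $\le$ width/40) and pads the window by 20 widths plus the
  progression extent; the span is then stretched $8\times$ because the time
  step $dt = 2\pi\hbar/\mathrm{span}$ controls the trapezoid bias of the
  half-line Fourier integral. The result is cubic-spline interpolated onto
  the user grid. A grid step above one fifth of the smallest width is
  rejected rather than silently under-resolved.
* **Voigt profile.** Evaluated through the Faddeeva function
  $w(z)$ (Weideman's 64-term rational approximation) rather than numerical
  convolution, giving grid-independent accuracy near machine precision; the
  degenerate widths reduce exactly to the pure Gaussian/Lorentzian forms.
* **Lifetime broadening.** $\Gamma = \hbar/\tau$ with
  $\hbar = 0.6582120$ eV fs. Core-hole lifetimes of 1–4 fs (typical for
  second-row K edges) give 0.66–0.16 eV Lorentzian widths. Gaussian
  (instrumental) widths are configurable and not derived from any reference
  dataset.

# Beyond the DHO: Duschinsky rotation and Herzberg–Teller terms

When final-state harmonic data are available, the identical-well assumption
is dropped. Final-state normal coordinates are related to ground-state ones
by $Q' = J Q + \text{shift}$ with $J = L'^{\mathsf T} L$ in mass-weighted
coordinates, after Eckart (Kabsch) alignment of the two geometries — whether
to axis-align before building $J$ is a genuine design choice; we align,
because an unremoved rigid rotation would masquerade as mode mixing. The
shift is stored as $K$, the final-state minimum expressed in *dimensionless
ground-state* coordinates, which makes the DHO the exact special case
$J = I$, $\omega' = \omega$, $K = \Delta$.

Multidimensional overlaps $\langle 0 | n' \rangle$ are generated by a
ladder-operator recursion that consumes only final-state quanta:

$$
u(n) = (I + CC^{\mathsf T})^{-1}\big(d\,f_n + CC^{\mathsf T} v(n)\big),\quad
f_{n+e_l} = \sqrt{\tfrac{2}{n_l+1}}\,u_l(n) -
\sqrt{\tfrac{n_l}{n_l+1}}\,f_{n-e_l},
$$

where $C = \Omega'^{1/2} J\, \Omega^{-1/2}$, $d = -CK$,
$v_l(n) = \sqrt{2 n_l}\, f_{n-e_l}$, and the seed $f_0$ is the closed-form
Gaussian overlap. The same pass yields the coordinate matrix elements
$\langle 0 | q_m | n' \rangle = [C^{\mathsf T}(v-u)]_m$ used for
Herzberg–Teller intensities

$$
I(n') = \big|\,\mu_0 \langle 0|n'\rangle + \textstyle\sum_k
\partial_k\mu \,\langle 0| q_k |n'\rangle\,\big|^2 .
$$

**Conventions in one place** (the classic source of silent $\sqrt2$ bugs):
both $K$ and the dipole derivatives $\partial_k\mu$ are expressed per unit
*dimensionless ground-state* coordinate $q_k = \sqrt{\omega_k}\,Q_k$; the
dipole expansion is linear (Condon limit at $\partial_k\mu = 0$); quadratic
dipole terms are out of scope. The recursion is validated not against
another recursion but against explicit quadrature of harmonic-oscillator
wavefunctions (20001-point grids in 1-D, $400^2$ in 2-D), plus three exact
limits: the Poisson reduction, the one-mode frequency-mismatch overlap
$|\langle 0|0'\rangle|^2 = 2\sqrt2/3$ at $\omega' = 2\omega$, and the pure-HT
fundamental $|\partial\mu|^2/2$. A hard cap of 10 coupled modes keeps the
table size sane; larger systems must block-diagonalize $J$.

The qualitative benchmark is a two-mode carbonyl fixture
(`fixture_preset("formaldehyde-like")`): a C=O stretch at 1753 cm$^{-1}$
carrying $S \approx 1.1$ and a C–H stretch at 2970 cm$^{-1}$ that is almost
undisplaced. On core excitation the carbonyl mode softens to
$\approx 1190$ cm$^{-1}$ (scale 0.68, matching the well-known bond-order
loss when a $\pi^*$ orbital is filled) and the modes mix by 25°. At the DHO
level the third vibronic band is a single peak; with the frequency change and
mode mixing the nearly degenerate $2\nu_1'$ and $\nu_2'$ levels separate and
the band splits into two sub-peaks. The analysis broadening used for this
check (0.02 eV Lorentzian + 0.025 eV Gaussian) is chosen to resolve that
structure, as an experiment with vibronic resolution would.

# Spectrum assembly

`assemble_xanes()` renders states below the ionization threshold as
broadened envelopes (each with its own lifetime Lorentzian) and states above
it as sticks only — bound states have discrete lineshapes, continuum
resonances are left unbroadened since their widths are not predicted by this
model. `assemble_xps()` scales each cation envelope by its Dyson norm
(sudden approximation), optionally adds the zero-point shift
$\tfrac12\sum_k \hbar(\omega_k' - \omega_k)$ when final-state frequencies
exist (positive when bonds stiffen, as for carbon core ionization), and by
default normalizes the strongest band to 1 — the convention used when
matching measured photoemission intensities. XANES output is left
unnormalized by default.

Conformer averaging uses $r_i = \exp(-\Delta G_i / RT)$ with
$R = 8.314462$ J mol$^{-1}$ K$^{-1}$. Both the raw ratio and the normalized
fraction are returned: for a free-energy gap of 6.535 kJ/mol at 473 K the
ratio is 0.190 ("about 20%") while the two-conformer fraction is 0.160 —
quoting one number hides the convention, so the package reports both.

# The chunked active-space iteration

For larger molecules the manifold of core-excited states is accumulated
chunk by chunk: a minimal active space (core, a few occupied orbitals,
the LUMO) is augmented with $n$ virtual orbitals at a time in energy order;
each step's states are computed by a pluggable backend, tagged, and merged.
States recomputed at every step (the minimal-space transitions and their
shake-up satellites) are removed by label + energy-tolerance matching
(defaults: $10^{-6}$ eV for the exact toy backend; $\sim 0.05$ eV is a
realistic preset for multireference data, where duplicate identity is
genuinely ambiguous — we match on the dominant-configuration label and flag
nothing else). Convergence is declared when an iteration adds no new state
inside the energy window of interest.

The scheme neglects interactions between states computed in different
chunks. The packaged `toy_electronic_model` makes that caveat exact and
testable: when its coupling matrix is block-diagonal with respect to the
chunking, chunked accumulation plus deduplication reproduces single-shot
full-space diagonalization to machine precision, and with couplings across
chunks the difference is bounded by the coupling norm. Orbital
rotation/locking is treated as pure set bookkeeping — in a real
quantum-chemistry code that step belongs to the backend.

# What the synthetic generator does and does not emulate

`make_bundle()` solves the inverse problem: given target Huang–Rhys factors
it constructs the Cartesian gradient $M^{1/2} \sum_k l_k
(-\omega_k^{3/2}\sqrt{2 S_k})$ on a unit-mass pseudo-molecule (a slightly
bent chain, so the full 6-dimensional translation/rotation space exists and
3N−6 bookkeeping is unambiguous) with seeded random orthonormal modes. All
mode-space quantities — projections, progressions, transforms — behave
exactly as for a real molecule, which is what every downstream algorithm
consumes. What it does *not* emulate: real electronic-structure energetics,
anharmonicity, dissociative surfaces, symmetry, or realistic Cartesian
force fields. Tests passing on these fixtures therefore validate the
spectroscopy pipeline, not any electronic-structure method.

Randomness is confined to the generators and fully determined by explicit
seeds; every science-facing function is deterministic.

# Known limitations

* 0 K initial state only: no hot bands. Core-relevant modes
  (> 1000 cm$^{-1}$) are thermally unpopulated at the temperatures where
  gas-phase core spectra are measured, but low-frequency modes at high
  temperature are outside the model.
* The DHO cannot describe dissociative or strongly anharmonic final states
  (the classic failure at fluorine K edges); `flag_dho_suspect()` marks
  modes with per-mode reorganization energies above a threshold (default
  0.5 eV) instead of pretending to treat them.
* Above-threshold states get sticks, not physical continuum lineshapes; no
  edge-jump or semicontinuum background is modelled.
* Herzberg–Teller terms are linear; Duschinsky treatment caps at 10 coupled
  modes.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run 200 random Franck–Condon
fixtures with up to 4 modes, 5 three-mode route-equivalence fixtures,
2-mode quadrature oracles on $400^2$ grids with quanta up to 4–8, and toy
models with 7 virtual orbitals. These sizes make every check exact or
near-exact while completing in well under a minute each; the algorithms
themselves accept larger inputs up to the documented caps.
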