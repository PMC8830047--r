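# xrvib — vibronic X-ray absorption and photoelectron spectra

`xrvib` simulates vibrationally resolved core-level spectra — XANES
(X-ray absorption near-edge structure) and XPS (X-ray photoelectron
spectroscopy) — of molecules, for spectroscopists and theorists who already
have quantum-chemical data and need the vibronic lineshape step. The inputs
are ground-state harmonic data (geometry, masses, frequencies, normal modes;
Molden format or a YAML bundle) plus, per electronic state, a vertical
energy, the Cartesian gradient at the ground-state minimum, a transition
dipole (absorption) or Dyson norm (photoemission), and a core-hole lifetime.
The electronic-structure computation itself is consumed as data, never
performed.

## The model

**Displaced harmonic oscillator (DHO).** The final-state surface is assumed
to be the ground-state well rigidly displaced; projecting the final-state
gradient on mass-weighted mode *k* gives (atomic units, ħ = 1)

    Δ_k = −g_k / ω_k^{3/2}     S_k = Δ_k²/2      λ_k = S_k ħω_k
    E_00 = E_vert − Σ_k λ_k

where `S_k` is the Huang–Rhys factor and `λ_k` the mode reorganization
energy. At 0 K the Franck–Condon progression is a product of Poisson
factors, `I(n) ∝ Π_k e^{−S_k} S_k^{n_k}/n_k!`, evaluated both by explicit
enumeration (`fc_sticks()`) and by the exact time-domain cumulant expression
via FFT (`timedomain_spectrum()`); the two routes cross-check each other.

**Beyond the DHO.** With final-state harmonic data, `build_duschinsky()`
forms the mode-mixing matrix `J = L′ᵀL` and shift `K`, and `fc_integrals()`
generates multidimensional overlaps ⟨0|n′⟩ by a ladder-operator recursion
(validated against explicit wavefunction quadrature). `fcht_sticks()` adds
linear Herzberg–Teller terms, `|μ₀⟨0|n′⟩ + Σ_k ∂μ_k⟨0|q_k|n′⟩|²`.

**Assembly.** Lifetime Lorentzian (Γ = ħ/τ) plus instrumental Gaussian
broadening (Voigt via the Faddeeva function); states above the ionization
threshold are rendered as sticks; Dyson-norm-scaled XPS envelopes with
optional zero-point shift; Boltzmann conformer averaging; max-to-1
normalization and rigid shifts. An iterative chunked virtual-orbital scheme
(`iterate_active_space()`) accumulates core-excited states over a pluggable
backend with duplicate removal and window-convergence detection.

## Worked example

A two-mode carbonyl-like core-excited state with known ground truth
(C=O stretch 1753 cm⁻¹, C–H stretch 2970 cm⁻¹):

```r
library(xrvib)
bundle <- make_bundle(fixture_preset("formaldehyde-like", seed = 3))
state  <- bundle$states[[1]]

dho <- dho_from_state(state, bundle$harmonic)
print(dho)
#> dho_parameters: 2 modes; E_vert = 286 eV; lambda = 0.246443 eV; E_00 = 285.7536 eV
#>  freq_cm1    S lambda_eV
#>      1753 1.10  0.239100
#>      2970 0.02  0.007365
```

The gradient projection recovers the generator's Huang–Rhys factors
(S = 1.10, 0.02) exactly; the reorganization energy 0.246 eV places the 0-0
line at 285.75 eV. The strongest Franck–Condon lines:

```r
sticks <- fc_sticks(dho, intensity0 = sum(state$tdm^2), epsilon = 1e-6)
head(sticks[order(-sticks$intensity), ], 4)
#>      energy  intensity label
#> 8  285.9709 0.35890777 n=1,0
#> 1  285.7536 0.32627979 n=0,0
#> 15 286.1882 0.19739928 n=2,0
#> 22 286.4056 0.07237973 n=3,0
```

Beyond the DHO, the state's own harmonic data give the mode-mixing matrix
(25° rotation) and a softened carbonyl stretch; the nearly degenerate
2ν₁′ and ν₂′ levels then split the third vibronic band into the peak pair
at 286.010/286.070 eV:

```r
tr  <- build_duschinsky(bundle$harmonic, state$es_harmonic)
round(tr$J, 3)
#>       [,1]   [,2]
#> [1,] 0.906 -0.423
#> [2,] 0.423  0.906

e00   <- dho$adiabatic_energy + zpe_shift(bundle$harmonic, state$es_harmonic)
dusch <- fcht_sticks(tr, ht_expansion(state$tdm, NULL, 2), e00, nmax = 10)
br    <- broadening_spec(lorentzian_fwhm = 0.02, gaussian_fwhm = 0.025)
find_peaks(broaden_sticks(dusch, br, energy_grid("285.2:287.6:0.002")),
           threshold = 0.05)
#>    energy intensity
#> 1 285.714 6.8420186
#> 2 285.862 5.0278653
#> 3 286.010 0.9962770
#> 4 286.070 2.5065960
#> 5 286.218 2.5558350
#> ...
```

Conformer weighting — a 6.535 kJ/mol free-energy gap at 473 K gives a
secondary-conformer ratio of 0.19 ("about 20%"), fraction 0.16:

```r
boltzmann_weights(c(0, 6.535), 473)
#> $ratios
#> [1] 1.0000000 0.1898177
#> $fractions
#> [1] 0.8404649 0.1595351
```

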