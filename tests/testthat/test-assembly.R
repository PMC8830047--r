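make_two_state_bundle <- function(ip = NULL, s2_energy = 296) {
  m <- synthetic_harmonic_model(c(800, 1500), seed = 4)
  n3 <- 3L * length(m$atom_symbols)
  s1 <- electronic_state("1s->pi*", "core-excited", 287, rep(0, n3),
                         tdm = c(1, 0, 0), lifetime = 4)
  s2 <- electronic_state("1s->sigma*", "core-excited", s2_energy, rep(0, n3),
                         tdm = c(0, 0.5, 0), lifetime = 1)
  calculation_bundle(m, list(s1, s2), ip_threshold = ip)
}

test_that("states straddling the IP threshold partition into envelope + sticks", {
  b <- make_two_state_bundle(ip = 291)
  res <- assemble_xanes(b, "dho", "283:299:0.01", gaussian_fwhm = 0.2)
  # envelope holds exactly the sub-IP state's intensity (|tdm|^2 = 1)
  expect_equal(spectral_moments(res$grid)$m0, 1, tolerance = 0.01)
  expect_equal(spectral_moments(res$grid)$mean, 287, tolerance = 1e-3)
  # stick list holds exactly the supra-IP line
  expect_equal(nrow(res$sticks), 1L)
  expect_equal(res$sticks$energy, 296)
  expect_equal(res$sticks$intensity, 0.25)
  expect_match(res$sticks$label, "sigma")

  # single S = 0 state below IP: one symmetric line at E_00 = E_vert
  b1 <- calculation_bundle(b$harmonic, b$states[1], ip_threshold = 291)
  r1 <- assemble_xanes(b1, "dho", "283:299:0.01")
  expect_equal(r1$grid$grid[which.max(r1$grid$intensity)], 287)

  expect_error(assemble_xanes(
    calculation_bundle(b$harmonic, list(
      electronic_state("cat", "core-cation", 294,
                       rep(0, 3 * length(b$harmonic$atom_symbols)),
                       dyson_norm = 1, lifetime = 2))),
    "dho", "283:299:0.01"), "no core-excited states")
})

test_that("assembly is additive over states", {
  b <- make_bundle(fixture_preset("three-mode-dho", seed = 2))
  st <- b$states[[1]]
  twice <- calculation_bundle(b$harmonic, list(st, st))
  grid <- "283:292:0.01"
  one <- assemble_xanes(b, "dho", grid)$grid$intensity
  two <- assemble_xanes(twice, "dho", grid)$grid$intensity
  expect_equal(two, 2 * one, tolerance = 1e-12)
})

test_that("XPS envelopes scale with Dyson norms and keep the moment rule", {
  m <- synthetic_harmonic_model(c(1000, 1600), seed = 4)
  b <- make_bundle(fixture_spec(c(1000, 1600), c(0.4, 0.2),
                                vertical_energy = 294, kind = "core-cation",
                                dyson_norm = 1, seed = 4))
  grid <- "290:298:0.01"
  sp <- assemble_xps(b, grid, gaussian_fwhm = 0.3)
  expect_equal(max(sp$intensity), 1)                  # normalized
  expect_equal(normalize_spectrum(sp)$intensity, sp$intensity)

  # envelope mean equals the vertical ionization potential
  expect_equal(spectral_moments(sp)$mean, 294, tolerance = 1e-3)

  # two states 1.0 vs 0.5 Dyson: 2:1 peak ratio before normalization
  st <- b$states[[1]]
  half <- electronic_state("half", "core-cation", 291, st$gradient,
                           dyson_norm = 0.5, lifetime = st$lifetime)
  b2 <- calculation_bundle(b$harmonic, list(st, half))
  raw <- assemble_xps(b2, "288:298:0.01", gaussian_fwhm = 0.3,
                      normalize = FALSE)
  pk <- find_peaks(raw, threshold = 0.2)
  expect_equal(nrow(pk), 2L)
  expect_equal(max(pk$intensity) / min(pk$intensity), 2, tolerance = 1e-2)
  expect_equal(max(assemble_xps(b2, "288:298:0.01")$intensity), 1)

  expect_error(assemble_xps(make_two_state_bundle(), grid),
               "no core-cation states")
})

test_that("ZPE shift moves the XPS band origin when ES data are present", {
  spec <- fixture_spec(c(1000, 1600), c(0, 0), vertical_energy = 294,
                       kind = "core-cation",
                       es_frequency_scale = c(1.2, 1.2), seed = 6)
  b <- make_bundle(spec)
  dz <- zpe_shift(b$harmonic, b$states[[1]]$es_harmonic)
  expect_gt(dz, 0)  # stiffened cation frequencies: positive shift
  with_z <- assemble_xps(b, "292:296:0.005", gaussian_fwhm = 0.15)
  no_z <- assemble_xps(b, "292:296:0.005", gaussian_fwhm = 0.15,
                       apply_zpe = FALSE)
  shift <- with_z$grid[which.max(with_z$intensity)] -
    no_z$grid[which.max(no_z$intensity)]
  expect_lt(abs(shift - dz), 0.011)  # two grid steps
})

test_that("Boltzmann weights reproduce the published conformer ratio", {
  w <- boltzmann_weights(c(0, 6.535), 473)
  expect_equal(w$ratios[1], 1)
  expect_equal(w$ratios[2], 0.190, tolerance = 1e-2)
  expect_equal(round(w$ratios[2] * 100 / 10) * 10, 20)   # "about 20%"
  expect_equal(w$fractions[2], w$ratios[2] / (1 + w$ratios[2]),
               tolerance = 1e-12)
  expect_equal(boltzmann_weights(c(0, 0), 300)$fractions, c(0.5, 0.5))
  expect_equal(boltzmann_weights(c(0, 50), 1e9)$fractions, c(0.5, 0.5),
               tolerance = 1e-5)
  expect_error(boltzmann_weights(c(0, 1), -10), "positive")
})

test_that("conformer combination is a pointwise weighted sum", {
  b <- make_bundle(fixture_preset("three-mode-dho", seed = 2))
  grid <- "283:292:0.01"
  sp1 <- assemble_xanes(b, "dho", grid)$grid
  sp2 <- grid_spectrum(sp1$grid, rev(sp1$intensity))
  expect_equal(combine_conformers(list(sp1, sp2), c(1, 0))$intensity,
               sp1$intensity)
  expect_equal(combine_conformers(list(sp1, sp1), c(0.3, 0.7))$intensity,
               sp1$intensity, tolerance = 1e-12)
  w <- boltzmann_weights(c(0, 6.535), 473)$fractions
  comb <- combine_conformers(list(sp1, sp2), w)
  expect_equal(spectral_moments(comb)$m0,
               w[1] * spectral_moments(sp1)$m0 +
                 w[2] * spectral_moments(sp2)$m0, tolerance = 1e-12)
  expect_error(combine_conformers(list(sp1, sp2), c(0.6, 0.6)), "sum to 1")
  other <- grid_spectrum(sp1$grid + 0.5, sp1$intensity)
  expect_error(combine_conformers(list(sp1, other), c(0.5, 0.5)),
               "grid mismatch")
})

test_that("rigid shifts translate energies only and invert exactly", {
  st <- stick_spectrum(c(285, 287), c(1, 2), c("a", "b"))
  expect_equal(apply_shift(st, 0), st)
  sh <- apply_shift(st, 0.1)
  expect_equal(sh$energy, st$energy + 0.1)
  expect_identical(sh$intensity, st$intensity)
  expect_equal(apply_shift(sh, -0.1), st)

  g <- broaden_sticks(st, broadening_spec(0.2, 0), "282:290:0.01")
  g2 <- apply_shift(apply_shift(g, 0.1), -0.1)
  expect_equal(g2$grid, g$grid, tolerance = 1e-12)
  expect_equal(g2$intensity, g$intensity)
  expect_equal(apply_shift(g, 0.1)$metadata$shift, 0.1)
})
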