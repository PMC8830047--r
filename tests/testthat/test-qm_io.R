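test_that("Molden frequency files round-trip through write and read", {
  m <- synthetic_harmonic_model(c(600, 1200, 1800), seed = 9)
  path <- withr::local_tempfile(fileext = ".molden")
  write_molden_frequencies(m, path)
  m2 <- read_molden_frequencies(path, masses = m$masses)
  expect_equal(length(m2$frequencies), 3L)
  expect_equal(length(m2$atom_symbols), 5L)
  expect_equal(m2$geometry, m$geometry, tolerance = 1e-10)
  expect_equal(m2$frequencies, m$frequencies, tolerance = 1e-10)
  expect_equal(m2$mw_modes, m$mw_modes, tolerance = 1e-10)
  # re-orthonormalization on read is idempotent
  write_molden_frequencies(m2, path)
  m3 <- read_molden_frequencies(path, masses = m$masses)
  expect_equal(m3$mw_modes, m2$mw_modes, tolerance = 1e-12)
})

test_that("Molden reader rejects malformed files and imaginary modes", {
  m <- synthetic_harmonic_model(c(600, 1200), seed = 2)
  path <- withr::local_tempfile(fileext = ".molden")
  write_molden_frequencies(m, path)
  lines <- readLines(path)

  no_freq <- withr::local_tempfile()
  writeLines(lines[!grepl("FREQ", lines)][-(2:3)], no_freq)
  expect_error(read_molden_frequencies(no_freq), "missing section")

  imag <- withr::local_tempfile()
  bad <- lines
  bad[grep("\\[FREQ\\]", bad) + 1L] <- "-5.0e+01"
  writeLines(bad, imag)
  expect_error(read_molden_frequencies(imag, masses = m$masses),
               "nonpositive frequency")
  dropped <- read_molden_frequencies(imag, masses = m$masses,
                                     drop_nonpositive = TRUE)
  expect_equal(length(dropped$frequencies), 1L)

  mism <- withr::local_tempfile()
  bad2 <- lines[-length(lines)]  # truncate last mode component
  writeLines(bad2, mism)
  expect_error(read_molden_frequencies(mism, masses = m$masses),
               "consistency")
})

test_that("harmonic model enforces its invariants", {
  m <- synthetic_harmonic_model(c(500, 900), seed = 1)
  expect_lt(max(abs(crossprod(m$mw_modes) - diag(2))), 1e-12)
  expect_error(harmonic_model("X", 1, matrix(0, 1, 3), 500,
                              matrix(1, 3, 1)), "too many modes")
  expect_error(harmonic_model(c("X", "X"), c(1, -1),
                              matrix(rnorm(6), 2, 3), 500,
                              matrix(1, 6, 1)), "masses")
  skewed <- m$mode_vectors
  skewed[, 2] <- skewed[, 1] + 1e-3 * skewed[, 2]
  expect_error(harmonic_model(m$atom_symbols, m$masses, m$geometry,
                              m$frequencies, skewed), "orthonormal")
})

test_that("bundles round-trip through YAML with units normalized", {
  b <- make_bundle(fixture_preset("formaldehyde-like", seed = 3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_bundle(b, path)
  b2 <- read_bundle(path)
  s <- b$states[[1]]; s2 <- b2$states[[1]]
  expect_equal(s2$gradient, s$gradient, tolerance = 1e-10)
  expect_equal(s2$vertical_energy, s$vertical_energy, tolerance = 1e-12)
  expect_equal(s2$tdm, s$tdm)
  expect_equal(s2$es_harmonic$frequencies, s$es_harmonic$frequencies,
               tolerance = 1e-10)
  expect_equal(s2$tdm_derivatives, s$tdm_derivatives, tolerance = 1e-10)

  # Hartree-declared energies convert to the same bundle
  doc <- yaml::read_yaml(path)
  doc$units$energy <- "hartree"
  doc$states[[1]]$vertical_energy <-
    doc$states[[1]]$vertical_energy / 27.211386
  hpath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, hpath, precision = 15)
  b3 <- read_bundle(hpath)
  expect_equal(b3$states[[1]]$vertical_energy, s$vertical_energy,
               tolerance = 1e-9)

  doc$units$energy <- "furlong"
  upath <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc, upath, precision = 15)
  expect_error(read_bundle(upath), "unknown energy unit")
})

test_that("bundle validation rejects inconsistent state records", {
  m <- synthetic_harmonic_model(c(800, 1500), seed = 4)
  expect_error(
    electronic_state("bad", "core-excited", 287, rep(0, 12),
                     dyson_norm = 0.9, lifetime = 2),
    "tdm and no dyson_norm")
  expect_error(
    electronic_state("bad", "core-cation", 294, rep(0, 12),
                     tdm = c(1, 0, 0), lifetime = 2),
    "dyson_norm and no tdm")
  short <- electronic_state("ok", "core-excited", 287, rep(0, 9),
                            tdm = c(1, 0, 0), lifetime = 2)
  expect_error(calculation_bundle(m, list(short)), "gradient length")
  ok <- electronic_state("ok", "core-excited", 287,
                         rep(0, 3 * length(m$atom_symbols)),
                         tdm = c(1, 0, 0), lifetime = 2)
  expect_error(calculation_bundle(m, list(ok), ip_threshold = 600),
               "outside the state-energy span")
  b <- calculation_bundle(m, list(ok))
  expect_null(b$ip_threshold)
})

test_that("spectra round-trip through TSV, labels verbatim", {
  st <- fc_sticks(dho_from_displacements(c(700, 1400), c(1, 0.4), 287), 0.8,
                  label_prefix = "1s_C -> pi* ")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(st, path)
  st2 <- read_spectrum(path)
  expect_equal(st2$energy, st$energy, tolerance = 1e-12)
  expect_equal(st2$intensity, st$intensity, tolerance = 1e-12)
  expect_identical(st2$label, st$label)

  g <- broaden_sticks(st, broadening_spec(0.1, 0.1), "284:290:0.01")
  gpath <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(g, gpath)
  g2 <- read_spectrum(gpath)
  expect_equal(g2$intensity, g$intensity, tolerance = 1e-12)
  expect_equal(g2$grid, g$grid, tolerance = 1e-12)

  epath <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(stick_spectrum(), epath)
  expect_equal(length(readLines(epath)), 1L)  # header only
})
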