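test_that("identical states give the identity transform", {
  m <- synthetic_harmonic_model(c(900, 1600), seed = 11)
  tr <- build_duschinsky(m, m)
  expect_equal(tr$J, diag(2), tolerance = 1e-10)
  expect_equal(tr$K, c(0, 0), tolerance = 1e-10)
  expect_lt(attr(tr, "orthogonality_deviation"), 1e-10)
})

test_that("a pure shift along mode 1 appears as K = (Delta, 0)", {
  b <- make_bundle(fixture_spec(c(900, 1600), c(0.405, 0),
                                es_frequency_scale = c(1, 1), seed = 11))
  tr <- build_duschinsky(b$harmonic, b$states[[1]]$es_harmonic)
  expect_equal(tr$J, diag(2), tolerance = 1e-8)
  expect_equal(tr$K, c(sqrt(2 * 0.405), 0), tolerance = 1e-8)
})

test_that("a planned 30-degree mode mixing is recovered exactly", {
  b <- make_bundle(fixture_spec(c(900, 1600), c(0.405, 0.08),
                                duschinsky_angle = 30 * pi / 180,
                                es_frequency_scale = c(0.78, 1.16),
                                seed = 11))
  tr <- build_duschinsky(b$harmonic, b$states[[1]]$es_harmonic)
  angle <- atan2(tr$J[2, 1], tr$J[1, 1])
  expect_equal(angle, 30 * pi / 180, tolerance = 1e-8)
  expect_lt(attr(tr, "orthogonality_deviation"), 1e-8)
  expect_equal(tr$K, sqrt(2 * c(0.405, 0.08)), tolerance = 1e-8)
  expect_error(build_duschinsky(b$harmonic,
                                synthetic_harmonic_model(900, seed = 1)),
               "atom mismatch")
})

test_that("overlaps reduce to Poisson factors for J = I, equal frequencies", {
  tr <- duschinsky_transform(diag(2), c(1.0, 0.6), c(800, 1500),
                             c(800, 1500))
  tab <- fc_integrals(tr, nmax = 10)
  s <- c(0.5, 0.18)
  pois <- apply(tab$qn, 1L, function(n) prod(dpois(n, s)))
  expect_equal(tab$overlap^2, pois, tolerance = 1e-12)
  expect_gte(tab$completeness, 0.999)
})

test_that("frequency-mismatch overlap matches the 1-D closed form", {
  # omega' = 2 omega, no shift: |<0|0'>|^2 = 2 sqrt(2) / 3
  tr <- duschinsky_transform(matrix(1), 0, 1000, 2000)
  tab <- fc_integrals(tr, nmax = 8)
  expect_equal(tab$overlap[1]^2, 2 * sqrt(2) / 3, tolerance = 1e-12)
  # odd levels vanish by parity
  odd <- tab$qn[, 1] %% 2 == 1
  expect_lt(max(abs(tab$overlap[odd])), 1e-14)
})

test_that("every overlap and q-element matches 1-D quadrature", {
  tr <- duschinsky_transform(matrix(1), 0.8, 1000, 1400)
  tab <- fc_integrals(tr, nmax = 8)
  for (i in seq_len(nrow(tab$qn))) {
    n <- tab$qn[i, 1]
    expect_equal(tab$overlap[i], quad_overlap_1d(n, 1000, 1400, 0.8),
                 tolerance = 1e-8)
    expect_equal(tab$q_elements[i, 1],
                 quad_overlap_1d(n, 1000, 1400, 0.8, with_q = TRUE),
                 tolerance = 1e-8)
  }
})

test_that("two-mode mixed overlaps match the 400^2 quadrature oracle", {
  th <- 30 * pi / 180
  J <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  K <- c(0.9, -0.4)
  tr <- duschinsky_transform(J, K, c(900, 1600), c(700, 1850))
  tab <- fc_integrals(tr, nmax = 4)
  oracle <- quad_overlap_2d(tab$qn, J, K, c(900, 1600), c(700, 1850))
  expect_equal(tab$overlap, unname(oracle[, "overlap"]), tolerance = 1e-8)
  expect_equal(tab$q_elements[, 1], unname(oracle[, "q1"]), tolerance = 1e-8)
  expect_equal(tab$q_elements[, 2], unname(oracle[, "q2"]), tolerance = 1e-8)
})

test_that("overlap completeness is monotone in nmax and near-complete", {
  tr <- duschinsky_transform(
    matrix(c(cos(0.4), sin(0.4), -sin(0.4), cos(0.4)), 2),
    c(1.1, 0.3), c(900, 1600), c(720, 1750))
  comp <- sapply(2:9, function(nm) fc_integrals(tr, nm)$completeness)
  expect_true(all(diff(comp) >= -1e-14))
  expect_gte(fc_integrals(tr, 8)$completeness, 0.999)
  expect_error(fc_integrals(duschinsky_transform(diag(11), rep(0, 11),
                                                 rep(1000, 11),
                                                 rep(1000, 11)), 2),
               "at most 10")
})

test_that("Condon limit of fcht_sticks reproduces fc_sticks line for line", {
  d <- dho_from_displacements(c(800, 1400), c(0.9, -0.5), 287)
  tr <- duschinsky_transform(diag(2), c(0.9, -0.5), c(800, 1400),
                             c(800, 1400))
  stF <- fcht_sticks(tr, ht_expansion(c(1, 0, 0), NULL, 2),
                     d$adiabatic_energy, nmax = 12)
  stP <- fc_sticks(d, 1, epsilon = 1e-12, nmax = 12)
  common <- intersect(label_qn(stF), label_qn(stP))
  expect_gte(length(common), nrow(stP) - 1L)
  iF <- match(common, label_qn(stF)); iP <- match(common, label_qn(stP))
  expect_equal(stF$energy[iF], stP$energy[iP], tolerance = 1e-10)
  expect_equal(stF$intensity[iF], stP$intensity[iP], tolerance = 1e-10)
})

test_that("pure Herzberg-Teller line carries |dmu|^2/2 in the fundamental", {
  tr <- duschinsky_transform(matrix(1), 0, 1200, 1200)
  ht <- ht_expansion(c(0, 0, 0), matrix(c(0.3, 0, 0), 3, 1))
  st <- fcht_sticks(tr, ht, 280, nmax = 6)
  nz <- st[st$intensity > 1e-20, ]
  expect_equal(nrow(nz), 1L)
  expect_equal(label_qn(nz), "1")
  expect_equal(nz$intensity, 0.3^2 / 2, tolerance = 1e-12)
  expect_equal(nz$energy, 280 + 1200 / 8065.544, tolerance = 1e-12)
})

test_that("generic 1-mode FC+HT intensities match quadrature of mu(q)", {
  tr <- duschinsky_transform(matrix(1), 0.7, 1000, 1300)
  ht <- ht_expansion(c(0.8, 0, 0), matrix(c(0.25, 0, 0), 3, 1))
  st <- fcht_sticks(tr, ht, 280, nmax = 8)
  ord <- order(as.integer(label_qn(st)))
  oracle <- sapply(0:8, function(n)
    (0.8 * quad_overlap_1d(n, 1000, 1300, 0.7) +
       0.25 * quad_overlap_1d(n, 1000, 1300, 0.7, with_q = TRUE))^2)
  expect_equal(st$intensity[ord], oracle, tolerance = 1e-8)
})

test_that("frequency change plus mode mixing splits the third vibronic band", {
  b <- make_bundle(fixture_preset("formaldehyde-like", seed = 3))
  st <- b$states[[1]]
  gs <- b$harmonic
  dho <- dho_from_state(st, gs)
  tr <- build_duschinsky(gs, st$es_harmonic)
  e00_d <- dho$adiabatic_energy + zpe_shift(gs, st$es_harmonic)
  br <- broadening_spec(0.02, 0.025, "voigt")
  grid <- energy_grid("285.2:287.6:0.002")

  sp_dho <- broaden_sticks(fc_sticks(dho, 1, epsilon = 1e-8), br, grid)
  sp_dus <- broaden_sticks(
    fcht_sticks(tr, ht_expansion(st$tdm, NULL, 2), e00_d, nmax = 10),
    br, grid)

  sp_co <- cm1_to_ev(1753)
  w_dho <- dho$adiabatic_energy + c(1.5, 2.5) * sp_co
  w_dus <- e00_d + c(1.5, 2.5) * cm1_to_ev(1753 * 0.68)
  expect_equal(nrow(find_peaks(sp_dho, 0.05, w_dho)), 1L)
  expect_equal(nrow(find_peaks(sp_dus, 0.05, w_dus)), 2L)

  # the Herzberg-Teller level keeps the split pair
  sp_ht <- broaden_sticks(
    fcht_sticks(tr, ht_expansion(st$tdm, st$tdm_derivatives), e00_d,
                nmax = 10), br, grid)
  expect_equal(nrow(find_peaks(sp_ht, 0.05, w_dus)), 2L)
})
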