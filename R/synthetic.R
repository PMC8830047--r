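# Synthetic models with known ground truth. All randomness in the package is
# confined to this file and is fully determined by explicit seeds; the RNG
# state of the caller is saved and restored.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Synthetic harmonic model with prescribed frequencies
#'
#' Builds a unit-mass pseudo-molecule (a slightly bent chain of `M + 2`
#' placeholder atoms, so 3N - 6 >= M) carrying `M` vibrational modes with the
#' requested frequencies. Mode vectors are a seeded random orthonormal set in
#' the complement of the translation/rotation subspace, so all mode-space
#' quantities behave exactly as for a real molecule while the Cartesian
#' embedding stays trivially bookkeepable. Non-physical by construction:
#' only mode-space quantities are meaningful downstream.
#'
#' @param frequencies cm^-1, one per mode.
#' @param seed integer seed controlling geometry jitter and mode orientation.
#' @return a [harmonic_model()] with atom symbol "X" and unit masses.
#' @export
synthetic_harmonic_model <- function(frequencies, seed = 1L) {
  m <- length(frequencies)
  n <- m + 2L
  .with_seed(seed, {
    # bent chain: nonlinear so the full 6-dimensional trans/rot space exists
    geom <- cbind(seq_len(n) * 1.2,
                  0.3 * sin(seq_len(n)) + stats::runif(n, -0.05, 0.05),
                  0.2 * cos(2 * seq_len(n)) + stats::runif(n, -0.05, 0.05))
    model0 <- list(atom_symbols = rep("X", n), masses = rep(1, n),
                   geometry = geom)
    tr <- trans_rot_basis(structure(model0, class = "harmonic_model"))
    proj <- diag(3L * n) - tcrossprod(tr)
    raw <- matrix(stats::rnorm(3L * n * m), 3L * n, m)
    basis <- qr.Q(qr(proj %*% raw))[, seq_len(m), drop = FALSE]
    harmonic_model(rep("X", n), rep(1, n), geom, frequencies,
                   basis)  # unit masses: Cartesian = mass-weighted
  })
}

#' Fixture specification for synthetic bundles
#'
#' Declares the ground truth a synthetic [calculation_bundle()] must encode:
#' target Huang-Rhys factors (recovered exactly by the DHO pipeline),
#' optional Herzberg-Teller transition-dipole derivatives, pairwise
#' Duschinsky mixing and excited-state frequency scaling.
#'
#' @param frequencies cm^-1 per mode (> 0).
#' @param target_huang_rhys dimensionless, >= 0, per mode.
#' @param vertical_energy eV.
#' @param lifetime fs.
#' @param kind `"core-excited"` or `"core-cation"`.
#' @param dyson_norm used when `kind = "core-cation"`.
#' @param ht_derivatives optional per-mode TDM derivative magnitudes (a.u.
#'   per dimensionless coordinate, applied along the x axis).
#' @param duschinsky_angle optional mixing angle in radians between modes 1
#'   and 2 of the excited state.
#' @param es_frequency_scale optional per-mode excited-state frequency
#'   factors.
#' @param seed integer.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(frequencies, target_huang_rhys,
                         vertical_energy = 287, lifetime = 4,
                         kind = c("core-excited", "core-cation"),
                         dyson_norm = 1,
                         ht_derivatives = NULL, duschinsky_angle = NULL,
                         es_frequency_scale = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (any(frequencies <= 0)) stop("frequencies must be positive")
  if (any(target_huang_rhys < 0)) stop("target_huang_rhys must be >= 0")
  if (length(target_huang_rhys) != length(frequencies))
    stop("one Huang-Rhys factor per mode required")
  if (!is.null(duschinsky_angle) && length(frequencies) < 2L)
    stop("duschinsky_angle needs at least two modes")
  structure(list(frequencies = as.numeric(frequencies),
                 target_huang_rhys = as.numeric(target_huang_rhys),
                 vertical_energy = vertical_energy, lifetime = lifetime,
                 kind = kind, dyson_norm = dyson_norm,
                 ht_derivatives = ht_derivatives,
                 duschinsky_angle = duschinsky_angle,
                 es_frequency_scale = es_frequency_scale,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Build a calculation bundle from a fixture specification
#'
#' Inverse-problem construction: the Cartesian gradient is assembled as
#' `grad = M^{1/2} sum_k l_k g_k` with `g_k = -omega_k^{3/2} sqrt(2 S_k)`
#' (atomic units), so that [project_gradient()] followed by
#' [dho_parameters()] recovers `S_k` (and a positive displacement
#' `Delta_k = +sqrt(2 S_k)`) to machine precision. When Duschinsky options
#' are present, an excited-state harmonic model is attached whose geometry
#' is displaced by exactly `Delta`, whose frequencies are scaled, and whose
#' modes 1-2 are mixed by the requested angle, so [build_duschinsky()]
#' recovers the planned transform. Deterministic given `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @return a [calculation_bundle()] with one state labelled by its origin.
#' @export
make_bundle <- function(spec) {
  model <- synthetic_harmonic_model(spec$frequencies, spec$seed)
  m <- length(spec$frequencies)
  omega <- .cm1_to_au(spec$frequencies)
  g_mode <- -omega^1.5 * sqrt(2 * spec$target_huang_rhys)
  sqm_me <- rep(sqrt(model$masses * .const$me_per_amu), each = 3L)
  gradient <- sqm_me * as.numeric(model$mw_modes %*% g_mode)

  es_harm <- NULL
  if (!is.null(spec$duschinsky_angle) || !is.null(spec$es_frequency_scale)) {
    scale <- if (is.null(spec$es_frequency_scale)) rep(1, m)
             else rep_len(spec$es_frequency_scale, m)
    rot <- diag(m)
    if (!is.null(spec$duschinsky_angle)) {
      a <- spec$duschinsky_angle
      rot[1:2, 1:2] <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
    }
    # ES modes: GS modes mixed pairwise; ES minimum displaced by Delta along
    # GS modes (mass-weighted shift Delta_k / sqrt(omega_k), a.u.)
    delta <- sqrt(2 * spec$target_huang_rhys)
    dq_mw <- as.numeric(model$mw_modes %*% (delta / sqrt(omega)))
    dx_ang <- dq_mw / sqm_me / .const$bohr_per_angstrom
    es_geom <- model$geometry + matrix(dx_ang, ncol = 3L, byrow = TRUE)
    es_modes <- model$mw_modes %*% t(rot)   # unit masses: Cartesian == mw
    es_harm <- harmonic_model(model$atom_symbols, model$masses, es_geom,
                              spec$frequencies * scale, es_modes)
  }

  tdm_der <- NULL
  if (!is.null(spec$ht_derivatives)) {
    tdm_der <- matrix(0, 3L, m)
    tdm_der[1L, ] <- rep_len(spec$ht_derivatives, m)
  }

  state <- electronic_state(
    label = paste0("synthetic ", spec$kind),
    kind = spec$kind,
    vertical_energy = spec$vertical_energy,
    gradient = gradient,
    tdm = if (spec$kind == "core-excited") c(1, 0, 0) else NULL,
    dyson_norm = if (spec$kind == "core-cation") spec$dyson_norm else NULL,
    lifetime = spec$lifetime,
    es_harmonic = es_harm,
    tdm_derivatives = tdm_der
  )
  calculation_bundle(model, list(state),
                     conformer_label = paste0("synthetic-seed", spec$seed))
}

#' Named fixture presets
#'
#' `"three-mode-dho"`: a generic three-mode displaced oscillator
#' (500/1100/1753 cm^-1, S = 0.3/0.6/0.9). `"formaldehyde-like"`: the
#' two-mode C=O + symmetric C-H stretch system (1753 and 2970 cm^-1) with a
#' strongly displaced carbonyl mode, excited-state softening of the C=O
#' stretch and 25 degrees of mode mixing - the configuration whose third
#' vibronic band splits into two sub-peaks once Duschinsky rotation is
#' enabled. `"toy-ci"`: a six-virtual toy configuration model for the
#' active-space iterator (see [make_toy_model()]).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @return a [fixture_spec()] (or, for `"toy-ci"`, a `toy_electronic_model`).
#' @export
fixture_preset <- function(name = c("three-mode-dho", "formaldehyde-like",
                                    "toy-ci"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "three-mode-dho" = fixture_spec(
      frequencies = c(500, 1100, 1753),
      target_huang_rhys = c(0.3, 0.6, 0.9),
      vertical_energy = 287, lifetime = 4, seed = seed),
    "formaldehyde-like" = fixture_spec(
      frequencies = c(1753, 2970),
      target_huang_rhys = c(1.1, 0.02),
      vertical_energy = 286, lifetime = 4,
      ht_derivatives = c(0.08, 0.03),
      duschinsky_angle = 25 * pi / 180,
      es_frequency_scale = c(0.68, 0.97), seed = seed),
    "toy-ci" = make_toy_model(6L, coupling_scale = 0.3, seed = seed))
}

#' Toy configuration-interaction model
#'
#' A synthetic stand-in for a multiconfigurational electronic-structure
#' backend: one configuration per core -> virtual excitation (plus an
#' optional shake-up configuration attached to the lowest virtual), diagonal
#' energies `core_energy + orbital_energy`, a symmetric coupling matrix, and
#' per-configuration transition-dipole magnitudes. Exact states of any
#' configuration subset are obtained by dense diagonalization, which makes
#' the chunked active-space iteration exactly checkable. With
#' `coupling_scale = 0` the state energies equal the diagonal configuration
#' energies.
#'
#' @param n_virtuals number of virtual orbitals (>= 1).
#' @param coupling_scale magnitude of off-diagonal couplings, eV.
#' @param seed integer.
#' @param core_energy core-level transition offset, eV.
#' @param block_size optional integer: couplings are zeroed between blocks of
#'   this size (blocks taken over virtuals 2, 3, ... in energy order, with
#'   the lowest virtual kept uncoupled), producing a model whose chunked
#'   iteration is exactly equivalent to a full-space computation.
#' @param shake_up logical: add a dark shake-up configuration 1.5 eV above
#'   the lowest virtual transition, recomputed at every iteration.
#' @return object of class `toy_electronic_model` with fields
#'   `orbital_energies`, `core_energy`, `occupied_ids`, `couplings`,
#'   `tdm_rule`, `window`, `labels`, `config_energies`, `config_virtual`.
#' @export
make_toy_model <- function(n_virtuals, coupling_scale = 0, seed = 1L,
                           core_energy = 290, block_size = NULL,
                           shake_up = TRUE) {
  if (n_virtuals < 1L) stop("n_virtuals must be >= 1")
  .with_seed(seed, {
    orb <- sort(stats::runif(n_virtuals, 1, 12))
    tdm <- stats::runif(n_virtuals, 0.2, 1)
    labels <- paste0("core->v", seq_len(n_virtuals))
    energies <- core_energy + orb
    virt <- seq_len(n_virtuals)
    if (shake_up) {
      labels <- c(labels, "core->v1+shake")
      energies <- c(energies, core_energy + orb[1] + 1.5)
      tdm <- c(tdm, 0.05)
      virt <- c(virt, 1L)
    }
    nc <- length(labels)
    cpl <- matrix(stats::runif(nc * nc, -1, 1), nc, nc)
    cpl <- coupling_scale * (cpl + t(cpl)) / 2
    diag(cpl) <- 0
    if (!is.null(block_size)) {
      blk <- integer(nc)
      blk[virt == 1L] <- 0L                       # minimal-space block
      rest <- which(virt > 1L)
      blk[rest] <- (seq_along(rest) - 1L) %/% block_size + 1L
      cpl[outer(blk, blk, "!=")] <- 0
      cpl[virt == 1L, ] <- 0                      # keep v1 states uncoupled
      cpl[, virt == 1L] <- 0
    }
    structure(list(
      orbital_energies = orb, core_energy = core_energy,
      occupied_ids = "HOMO", couplings = cpl, tdm_rule = tdm,
      window = c(core_energy + orb[1] - 1,
                 core_energy + orb[max(1L, ceiling(n_virtuals / 2))] + 0.5),
      labels = labels, config_energies = energies, config_virtual = virt
    ), class = "toy_electronic_model")
  })
}
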