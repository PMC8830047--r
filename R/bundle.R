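#' Per-state electronic record
#'
#' One core-excited or core-ionized electronic state as consumed by the
#' vibronic engine: vertical energy, Cartesian gradient at the ground-state
#' minimum, an intensity carrier (transition dipole for absorption, Dyson
#' norm for photoemission), and a core-hole lifetime.
#'
#' @param label free-text state tag, e.g. `"1s_C -> pi*"`.
#' @param kind `"core-excited"` (needs `tdm`) or `"core-cation"` (needs
#'   `dyson_norm`).
#' @param vertical_energy vertical excitation/ionization energy in eV (> 0),
#'   relative to the neutral ground state.
#' @param gradient Cartesian energy gradient of this state at the ground-state
#'   minimum, Hartree/Bohr, length 3N (atom-major x,y,z).
#' @param tdm transition dipole moment 3-vector, atomic units.
#' @param dyson_norm Dyson orbital norm in \[0, 1\].
#' @param lifetime core-hole lifetime in fs (> 0); sets the Lorentzian width
#'   via Gamma = hbar/tau.
#' @param es_harmonic optional [harmonic_model()] of this state (enables
#'   Duschinsky/zero-point corrections).
#' @param tdm_derivatives optional 3 x M matrix of transition-dipole
#'   derivatives along the ground-state dimensionless normal coordinates
#'   (a.u. per unit coordinate), for Herzberg-Teller corrections.
#' @return object of class `electronic_state`.
#' @export
electronic_state <- function(label, kind, vertical_energy, gradient,
                             tdm = NULL, dyson_norm = NULL, lifetime,
                             es_harmonic = NULL, tdm_derivatives = NULL) {
  kind <- match.arg(kind, c("core-excited", "core-cation"))
  if (!is.finite(vertical_energy) || vertical_energy <= 0)
    stop("vertical_energy must be positive (eV)")
  if (!is.finite(lifetime) || lifetime <= 0)
    stop("lifetime must be positive (fs)")
  if (kind == "core-excited") {
    if (is.null(tdm) || !is.null(dyson_norm))
      stop("core-excited states carry a tdm and no dyson_norm")
    if (length(tdm) != 3L || any(!is.finite(tdm)))
      stop("tdm must be a finite 3-vector")
  } else {
    if (is.null(dyson_norm) || !is.null(tdm))
      stop("core-cation states carry a dyson_norm and no tdm")
    if (!is.finite(dyson_norm) || dyson_norm < 0 || dyson_norm > 1)
      stop("dyson_norm must lie in [0, 1]")
  }
  if (!is.null(es_harmonic) && !inherits(es_harmonic, "harmonic_model"))
    stop("es_harmonic must be a harmonic_model")
  if (!is.null(tdm_derivatives)) {
    tdm_derivatives <- as.matrix(tdm_derivatives)
    if (nrow(tdm_derivatives) != 3L)
      stop("tdm_derivatives must be 3 x n_modes")
  }
  structure(list(
    label = as.character(label), kind = kind,
    vertical_energy = vertical_energy,
    gradient = as.numeric(gradient),
    tdm = if (is.null(tdm)) NULL else as.numeric(tdm),
    dyson_norm = dyson_norm, lifetime = lifetime,
    es_harmonic = es_harmonic, tdm_derivatives = tdm_derivatives
  ), class = "electronic_state")
}

#' Calculation bundle: one molecule or conformer
#'
#' Couples a ground-state harmonic model with its electronic-state records
#' plus optional ionization threshold and thermochemistry metadata. This is
#' the unit of input for spectrum assembly and the object serialized by
#' [write_bundle()].
#'
#' @param harmonic ground-state [harmonic_model()].
#' @param states list of [electronic_state()] records (non-empty).
#' @param ip_threshold core-ionization potential in eV (optional); states
#'   above it are rendered as sticks by [assemble_xanes()].
#' @param conformer_label text label.
#' @param delta_g Gibbs free energy in kJ/mol relative to the reference
#'   conformer (optional).
#' @param temperature temperature in K (optional).
#' @return object of class `calculation_bundle`.
#' @export
calculation_bundle <- function(harmonic, states, ip_threshold = NULL,
                               conformer_label = "", delta_g = NULL,
                               temperature = NULL) {
  if (!inherits(harmonic, "harmonic_model"))
    stop("harmonic must be a harmonic_model")
  if (inherits(states, "electronic_state")) states <- list(states)
  if (length(states) == 0L) stop("states must be non-empty")
  if (!all(vapply(states, inherits, TRUE, "electronic_state")))
    stop("states must be electronic_state records")
  n3 <- 3L * n_atoms(harmonic)
  for (s in states)
    if (length(s$gradient) != n3)
      stop("state '", s$label, "': gradient length ", length(s$gradient),
           " != 3N = ", n3)
  if (!is.null(ip_threshold)) {
    ev <- vapply(states, `[[`, 0, "vertical_energy")
    if (ip_threshold < min(ev) - 50 || ip_threshold > max(ev) + 50)
      stop("ip_threshold ", ip_threshold,
           " eV lies outside the state-energy span +/- 50 eV")
  }
  structure(list(
    harmonic = harmonic, states = states, ip_threshold = ip_threshold,
    conformer_label = as.character(conformer_label),
    delta_g = delta_g, temperature = temperature
  ), class = "calculation_bundle")
}

#' @export
print.calculation_bundle <- function(x, ...) {
  cat("calculation_bundle", if (nzchar(x$conformer_label))
    paste0("'", x$conformer_label, "'") else "", ":",
    length(x$states), "states,", n_modes(x$harmonic), "modes\n")
  invisible(x)
}

# ---- YAML serialization (schema version 1) ---------------------------------

.harmonic_to_list <- function(m) {
  list(atom_symbols = m$atom_symbols, masses = m$masses,
       geometry = apply(m$geometry, 1L, identity, simplify = FALSE),
       frequencies = m$frequencies,
       mode_vectors = apply(m$mode_vectors, 2L, identity, simplify = FALSE),
       linear = m$linear)
}

.harmonic_from_list <- function(l) {
  harmonic_model(
    atom_symbols = unlist(l$atom_symbols),
    masses = unlist(l$masses),
    geometry = do.call(rbind, l$geometry),
    frequencies = unlist(l$frequencies),
    mode_vectors = do.call(cbind, l$mode_vectors),
    linear = isTRUE(l$linear)
  )
}

#' Write a calculation bundle to a YAML file
#'
#' Serializes the bundle under schema `xrvib_bundle: 1`. All energies are
#' written in eV, geometries in Angstrom, gradients in Hartree/Bohr,
#' lifetimes in fs; the unit tags are recorded in the file and checked on
#' read. Numeric precision is 15 significant digits, so write/read round
#' trips preserve values to better than 1e-10 relative.
#'
#' @param bundle a [calculation_bundle()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bundle <- function(bundle, path) {
  st <- lapply(bundle$states, function(s) {
    out <- list(label = s$label, kind = s$kind,
                vertical_energy = s$vertical_energy,
                gradient = s$gradient, lifetime = s$lifetime)
    if (!is.null(s$tdm)) out$tdm <- s$tdm
    if (!is.null(s$dyson_norm)) out$dyson_norm <- s$dyson_norm
    if (!is.null(s$tdm_derivatives))
      out$tdm_derivatives <-
        apply(s$tdm_derivatives, 2L, identity, simplify = FALSE)
    if (!is.null(s$es_harmonic))
      out$es_harmonic <- .harmonic_to_list(s$es_harmonic)
    out
  })
  doc <- list(
    xrvib_bundle = 1L,
    units = list(energy = "eV", gradient = "hartree_bohr",
                 length = "angstrom", lifetime = "fs"),
    conformer_label = bundle$conformer_label,
    harmonic = .harmonic_to_list(bundle$harmonic),
    states = st
  )
  if (!is.null(bundle$ip_threshold)) doc$ip_threshold <- bundle$ip_threshold
  if (!is.null(bundle$delta_g)) doc$delta_g <- bundle$delta_g
  if (!is.null(bundle$temperature)) doc$temperature <- bundle$temperature
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read a calculation bundle from a YAML file
#'
#' Accepts energies in `eV` or `hartree` (declared in the file's `units`
#' block); everything is normalized to the package's spectroscopic units on
#' read. Unknown unit tags are an error, as are gradients whose length does
#' not match the harmonic model.
#'
#' @param path YAML file written by [write_bundle()] or following the same
#'   schema.
#' @return a validated [calculation_bundle()].
#' @export
read_bundle <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$xrvib_bundle))
    stop("not an xrvib bundle (missing 'xrvib_bundle' schema tag)")
  e_unit <- if (is.null(doc$units$energy)) "eV" else doc$units$energy
  e_scale <- switch(tolower(e_unit),
                    "ev" = 1, "hartree" = .const$ev_per_hartree,
                    stop("unknown energy unit tag: ", e_unit))
  g_unit <- if (is.null(doc$units$gradient)) "hartree_bohr"
            else doc$units$gradient
  if (!tolower(g_unit) %in% "hartree_bohr")
    stop("unknown gradient unit tag: ", g_unit)

  harm <- .harmonic_from_list(doc$harmonic)
  states <- lapply(doc$states, function(s) {
    electronic_state(
      label = s$label, kind = s$kind,
      vertical_energy = s$vertical_energy * e_scale,
      gradient = unlist(s$gradient),
      tdm = if (is.null(s$tdm)) NULL else unlist(s$tdm),
      dyson_norm = s$dyson_norm,
      lifetime = s$lifetime,
      es_harmonic = if (is.null(s$es_harmonic)) NULL
                    else .harmonic_from_list(s$es_harmonic),
      tdm_derivatives = if (is.null(s$tdm_derivatives)) NULL
                        else do.call(cbind, s$tdm_derivatives)
    )
  })
  calculation_bundle(
    harmonic = harm, states = states,
    ip_threshold = if (is.null(doc$ip_threshold)) NULL
                   else doc$ip_threshold * e_scale,
    conformer_label = if (is.null(doc$conformer_label)) ""
                      else doc$conformer_label,
    delta_g = doc$delta_g, temperature = doc$temperature
  )
}
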