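#' Project a Cartesian gradient onto mass-weighted normal modes
#'
#' Converts a Cartesian energy gradient (Hartree/Bohr) of an excited or
#' ionized state, evaluated at the ground-state minimum, into per-mode
#' gradients in mass-weighted atomic units. Rigid translation and rotation
#' components are removed with the Eckart projector before projection, so
#' small contaminations from finite-difference gradients do not leak into
#' the vibrational analysis.
#'
#' @param gradient numeric vector of length 3N, Hartree/Bohr, atom-major.
#' @param model ground-state [harmonic_model()].
#' @return numeric vector `g` of per-mode gradients (atomic units), one per
#'   mode, `g[k] = <mode_k | M^{-1/2} grad>`.
#' @export
project_gradient <- function(gradient, model) {
  n3 <- 3L * n_atoms(model)
  if (length(gradient) != n3)
    stop("gradient length ", length(gradient), " != 3N = ", n3)
  sqm_me <- rep(sqrt(model$masses * .const$me_per_amu), each = 3L)
  g_mw <- as.numeric(gradient) / sqm_me        # Hartree / (Bohr sqrt(me))
  g_mw <- as.numeric(eckart_projector(model) %*% g_mw)
  as.numeric(crossprod(model$mw_modes, g_mw))
}

#' Displaced-harmonic-oscillator parameters from per-mode gradients
#'
#' Maps mode-space gradients to the DHO quantities governing vibronic
#' structure (atomic units internally, hbar = 1):
#' dimensionless displacement `Delta_k = -g_k / omega_k^{3/2}`, Huang-Rhys
#' factor `S_k = Delta_k^2 / 2 = g_k^2 / (2 omega_k^3)`, mode reorganization
#' energy `lambda_k = S_k hbar omega_k = g_k^2 / (2 omega_k^2)` (reported in
#' eV), total `lambda = sum lambda_k`, and adiabatic origin
#' `E_00 = E_vert - lambda`. The sign convention makes a downhill (negative)
#' gradient along a mode correspond to a positive displacement.
#'
#' @param g per-mode gradients from [project_gradient()] (mass-weighted
#'   atomic units).
#' @param model ground-state [harmonic_model()].
#' @param e_vert vertical transition energy in eV.
#' @return object of class `dho_parameters` with fields `frequencies`
#'   (cm^-1), `displacements`, `huang_rhys`, `lambda_k` (eV),
#'   `lambda` (eV), `vertical_energy` (eV), `adiabatic_energy` (eV).
#' @export
#' @examples
#' m <- synthetic_harmonic_model(1753, seed = 1)
#' g <- -(.0079878)^1.5 * sqrt(2 * 0.5)  # one mode, S = 0.5
#' dho_parameters(g, m, e_vert = 287)
dho_parameters <- function(g, model, e_vert) {
  if (length(g) != n_modes(model))
    stop("per-mode gradient length must equal the number of modes")
  omega <- .cm1_to_au(model$frequencies)
  if (any(omega <= 0)) stop("nonpositive frequency")
  delta <- -g / omega^1.5
  s <- delta^2 / 2
  lambda_k <- s * omega * .const$ev_per_hartree
  lambda <- sum(lambda_k)
  structure(list(
    frequencies = model$frequencies,
    displacements = delta,
    huang_rhys = s,
    lambda_k = lambda_k,
    lambda = lambda,
    vertical_energy = e_vert,
    adiabatic_energy = e_vert - lambda
  ), class = "dho_parameters")
}

#' @export
print.dho_parameters <- function(x, ...) {
  cat("dho_parameters:", length(x$frequencies), "modes; E_vert =",
      signif(x$vertical_energy, 8), "eV; lambda =",
      signif(x$lambda, 6), "eV; E_00 =",
      signif(x$adiabatic_energy, 8), "eV\n")
  df <- data.frame(freq_cm1 = signif(x$frequencies, 6),
                   S = signif(x$huang_rhys, 4),
                   lambda_eV = signif(x$lambda_k, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Build DHO parameters directly from a bundle state
#'
#' Convenience wrapper: [project_gradient()] then [dho_parameters()].
#'
#' @param state an [electronic_state()].
#' @param model ground-state [harmonic_model()].
#' @return a `dho_parameters` object.
#' @export
dho_from_state <- function(state, model) {
  g <- project_gradient(state$gradient, model)
  dho_parameters(g, model, state$vertical_energy)
}

#' Construct a DHO directly from mode data
#'
#' For synthetic work and fixtures: build a `dho_parameters` object from
#' frequencies and signed dimensionless displacements without a Cartesian
#' embedding.
#'
#' @param frequencies cm^-1 per mode (> 0).
#' @param displacements signed dimensionless displacements Delta_k.
#' @param e_vert vertical energy, eV.
#' @return a `dho_parameters` object.
#' @export
dho_from_displacements <- function(frequencies, displacements, e_vert) {
  if (length(frequencies) != length(displacements))
    stop("frequencies and displacements lengths differ")
  if (any(frequencies <= 0)) stop("nonpositive frequency")
  omega <- .cm1_to_au(frequencies)
  s <- displacements^2 / 2
  lambda_k <- s * omega * .const$ev_per_hartree
  structure(list(
    frequencies = as.numeric(frequencies),
    displacements = as.numeric(displacements),
    huang_rhys = s, lambda_k = lambda_k, lambda = sum(lambda_k),
    vertical_energy = e_vert, adiabatic_energy = e_vert - sum(lambda_k)
  ), class = "dho_parameters")
}

#' Zero-point-energy shift between two harmonic models
#'
#' `dZPE = 1/2 sum_k hbar (omega'_k - omega_k)` in eV, positive when the
#' excited-state frequencies stiffen (as for carbon core ionization, where
#' orbital contraction strengthens the bond). Modes are paired by
#' maximum-overlap assignment of mass-weighted mode vectors when atom counts
#' agree, falling back to sorted-frequency order; pairings with overlap
#' below 0.5 trigger a warning.
#'
#' @param gs ground-state [harmonic_model()].
#' @param es excited/ionized-state [harmonic_model()] with the same number
#'   of modes.
#' @return shift in eV.
#' @export
#' @examples
#' gs <- synthetic_harmonic_model(1000, seed = 1)
#' es <- synthetic_harmonic_model(1100, seed = 1)
#' zpe_shift(gs, es)  # +50 cm^-1 = 6.199e-3 eV
zpe_shift <- function(gs, es) {
  if (n_modes(gs) != n_modes(es))
    stop("mode-count mismatch: ", n_modes(gs), " vs ", n_modes(es))
  perm <- .match_modes(gs, es)
  sum(.cm1_to_ev(es$frequencies[perm] - gs$frequencies)) / 2
}

# Pair ES modes to GS modes. Greedy maximum-overlap assignment on the
# |l_gs . l_es| matrix when geometries are compatible; otherwise (or when
# any pairing is ambiguous) sorted-frequency order.
.match_modes <- function(gs, es) {
  m <- n_modes(gs)
  if (n_atoms(gs) == n_atoms(es)) {
    ov <- abs(crossprod(gs$mw_modes, es$mw_modes))  # m x m
    perm <- integer(m); taken <- rep(FALSE, m); ok <- TRUE
    for (step in seq_len(m)) {
      ov_masked <- ov
      ov_masked[, taken] <- -1
      idx <- which(ov_masked == max(ov_masked), arr.ind = TRUE)[1, ]
      if (ov[idx[1], idx[2]] < 0.5) { ok <- FALSE; break }
      perm[idx[1]] <- idx[2]
      taken[idx[2]] <- TRUE
      ov[idx[1], ] <- -1
    }
    if (ok) return(perm)
    warning("ambiguous mode overlap (< 0.5); falling back to ",
            "sorted-frequency pairing")
  }
  order(es$frequencies)[rank(gs$frequencies, ties.method = "first")]
}

#' Core-hole lifetime to Lorentzian FWHM
#'
#' `Gamma = hbar / tau` with hbar = 0.6582120 eV fs. Core-hole lifetimes of
#' 1-4 fs (typical of second-row K edges) give widths of 0.66-0.16 eV.
#'
#' @param tau lifetime in fs (> 0).
#' @return Lorentzian full width at half maximum, eV.
#' @export
#' @examples
#' lifetime_to_fwhm(4)
lifetime_to_fwhm <- function(tau) {
  if (any(!is.finite(tau) & !is.infinite(tau)) || any(tau <= 0))
    stop("lifetime must be positive")
  .const$hbar_ev_fs / tau
}

#' Flag modes whose reorganization energy exceeds a threshold
#'
#' Large per-mode reorganization energies signal strong excited-state
#' distortion along that coordinate, where the identical-well assumption is
#' least trustworthy (the regime where dissociative or strongly anharmonic
#' surfaces appear, e.g. fluorine K-edge C-F stretching). The DHO cannot
#' describe such modes; this diagnostic marks them as suspect rather than
#' attempting an anharmonic treatment.
#'
#' @param dho a `dho_parameters` object.
#' @param lambda_tol per-mode reorganization-energy threshold in eV
#'   (default 0.5 eV).
#' @return logical vector, TRUE where `lambda_k > lambda_tol`.
#' @export
flag_dho_suspect <- function(dho, lambda_tol = 0.5) {
  dho$lambda_k > lambda_tol
}
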