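#' Ground- or excited-state harmonic model
#'
#' Container for the harmonic description of one electronic state: geometry,
#' atomic masses, vibrational frequencies and Cartesian normal-mode vectors.
#' Mode vectors are re-orthonormalized in the mass-weighted metric on
#' construction, so downstream projections can treat them as an orthonormal
#' basis of the vibrational subspace.
#'
#' @param atom_symbols character vector of element labels, length N.
#' @param masses atomic masses in amu, length N, all positive.
#' @param geometry N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param frequencies vibrational frequencies in cm^-1, one per mode.
#' @param mode_vectors 3N x M matrix; column k is the Cartesian displacement
#'   vector of mode k (atom-major layout: x1, y1, z1, x2, ...).
#' @param linear logical; TRUE for a linear molecule (3N-5 modes allowed).
#' @param mass_weighted logical; set TRUE when `mode_vectors` are already
#'   mass-weighted displacements (some Molden writers emit these). They are
#'   converted to Cartesian convention before validation.
#' @param drop_nonpositive logical; drop zero/imaginary (negative) frequencies
#'   and their modes instead of erroring.
#'
#' @return An object of class `harmonic_model` with elements `atom_symbols`,
#'   `masses`, `geometry`, `frequencies`, `mode_vectors` (Cartesian, as given,
#'   rescaled), `mw_modes` (orthonormal mass-weighted mode matrix), `linear`.
#' @export
#' @examples
#' m <- synthetic_harmonic_model(c(1000, 1500), seed = 1)
#' round(crossprod(m$mw_modes), 10)  # identity: mass-weighted orthonormal
harmonic_model <- function(atom_symbols, masses, geometry, frequencies,
                           mode_vectors, linear = FALSE,
                           mass_weighted = FALSE, drop_nonpositive = FALSE) {
  n_atom <- length(atom_symbols)
  geometry <- as.matrix(geometry)
  mode_vectors <- as.matrix(mode_vectors)
  if (length(masses) != n_atom)
    stop("masses must have one entry per atom")
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("all masses must be positive and finite")
  if (!identical(dim(geometry), c(n_atom, 3L)) &&
      !identical(dim(geometry), as.integer(c(n_atom, 3))))
    stop("geometry must be an N x 3 matrix")
  if (nrow(mode_vectors) != 3L * n_atom)
    stop("mode vectors must have 3N rows (atom count mismatch)")
  if (ncol(mode_vectors) != length(frequencies))
    stop("number of mode vectors must match number of frequencies")

  keep <- rep(TRUE, length(frequencies))
  if (any(frequencies <= 0)) {
    if (!drop_nonpositive)
      stop("nonpositive frequency encountered (",
           paste(signif(frequencies[frequencies <= 0], 6), collapse = ", "),
           " cm^-1); use drop_nonpositive = TRUE to discard such modes")
    keep <- frequencies > 0
  }
  frequencies <- frequencies[keep]
  mode_vectors <- mode_vectors[, keep, drop = FALSE]

  max_modes <- 3L * n_atom - if (linear) 5L else 6L
  if (length(frequencies) > max_modes)
    stop("too many modes: ", length(frequencies), " > 3N-",
         if (linear) 5 else 6, " = ", max_modes)

  sqm <- rep(sqrt(masses), each = 3L)
  if (mass_weighted) mode_vectors <- mode_vectors / sqm

  # mass-weighted orthonormalization (rescale only, then verify)
  mw <- mode_vectors * sqm
  norms <- sqrt(colSums(mw^2))
  if (any(norms == 0)) stop("zero-norm mode vector")
  mw <- sweep(mw, 2L, norms, "/")
  gram <- crossprod(mw)
  off <- max(abs(gram - diag(ncol(gram))))
  if (off > 1e-6)
    stop("mode vectors are not orthonormal in the mass-weighted metric ",
         "(max deviation ", signif(off, 3), " > 1e-6)")

  structure(list(
    atom_symbols = as.character(atom_symbols),
    masses = as.numeric(masses),
    geometry = geometry,
    frequencies = as.numeric(frequencies),
    mode_vectors = mw / sqm,   # Cartesian convention, mass-weight-normalized
    mw_modes = mw,
    linear = isTRUE(linear)
  ), class = "harmonic_model")
}

#' @export
print.harmonic_model <- function(x, ...) {
  cat("harmonic_model:", length(x$atom_symbols), "atoms,",
      length(x$frequencies), "modes\n")
  cat("  frequencies (cm^-1):",
      paste(signif(x$frequencies, 6), collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(model) length(model$atom_symbols)
n_modes <- function(model) length(model$frequencies)

# Orthonormal basis of mass-weighted translation/rotation vectors.
# Returns a 3N x k matrix (k <= 6); used by the Eckart projector.
trans_rot_basis <- function(model) {
  n <- n_atoms(model)
  sqm <- sqrt(model$masses)
  com <- colSums(model$geometry * model$masses) / sum(model$masses)
  xyz <- sweep(model$geometry, 2L, com)
  vecs <- matrix(0, 3L * n, 6L)
  for (a in 1:3) vecs[seq(a, 3L * n, by = 3L), a] <- sqm  # translations
  for (i in seq_len(n)) {                                  # rotations
    r <- xyz[i, ]
    rows <- (3L * i - 2L):(3L * i)
    vecs[rows, 4L] <- sqm[i] * c(0, -r[3], r[2])
    vecs[rows, 5L] <- sqm[i] * c(r[3], 0, -r[1])
    vecs[rows, 6L] <- sqm[i] * c(-r[2], r[1], 0)
  }
  qr_d <- qr(vecs)
  rank <- qr_d$rank
  qr.Q(qr_d)[, seq_len(rank), drop = FALSE]
}

#' Eckart translation/rotation projector
#'
#' Projector onto the internal (vibrational) subspace in mass-weighted
#' coordinates: applied to a mass-weighted gradient it removes the rigid
#' translation and rotation components that contaminate finite-difference
#' gradients.
#'
#' @param model a [harmonic_model()].
#' @return 3N x 3N symmetric projector matrix.
#' @export
eckart_projector <- function(model) {
  tr <- trans_rot_basis(model)
  diag(3L * n_atoms(model)) - tcrossprod(tr)
}
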