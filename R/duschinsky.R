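#' Duschinsky transform between two harmonic states
#'
#' Linear relation `Q' = J Q + shift` between excited-state and ground-state
#' mass-weighted normal coordinates, stored with both frequency sets. The
#' shift is kept as `K`, the position of the excited-state minimum expressed
#' in *dimensionless ground-state* normal coordinates; for a pure
#' displacement (J = I, equal frequencies) `K` equals the DHO displacement
#' vector Delta and the Franck-Condon factors reduce to Poisson factors of
#' `S = K^2/2`.
#'
#' @param J M x M mode-mixing matrix (ES modes in terms of GS modes).
#' @param K length-M shift, dimensionless GS-mode coordinates.
#' @param gs_frequencies,es_frequencies cm^-1, length M each, positive.
#' @return object of class `duschinsky_transform`. The attribute
#'   `orthogonality_deviation` records `max |J'J - I|` when set by
#'   [build_duschinsky()].
#' @export
duschinsky_transform <- function(J, K, gs_frequencies, es_frequencies) {
  J <- as.matrix(J)
  m <- length(gs_frequencies)
  if (!all(dim(J) == m) || length(K) != m || length(es_frequencies) != m)
    stop("inconsistent dimensions in Duschinsky transform")
  if (any(gs_frequencies <= 0) || any(es_frequencies <= 0))
    stop("nonpositive frequency")
  if (any(!is.finite(K)) || any(!is.finite(J))) stop("non-finite transform")
  structure(list(J = J, K = as.numeric(K),
                 gs_frequencies = as.numeric(gs_frequencies),
                 es_frequencies = as.numeric(es_frequencies)),
            class = "duschinsky_transform")
}

#' Build a Duschinsky transform from two harmonic models
#'
#' Eckart-aligns the excited-state geometry onto the ground state (mass
#' weighted Kabsch rotation, applied to geometry and mode vectors), then
#' forms `J = L'^T L` in mass-weighted coordinates and the shift `K` from
#' the mass-weighted geometry difference projected onto ground-state modes
#' and nondimensionalized with the ground-state frequencies. The deviation
#' of J from orthogonality (nonzero when the two mode sets span different
#' internal subspaces) is reported as an attribute.
#'
#' @param gs,es [harmonic_model()] objects with identical atom ordering and
#'   masses and equal mode counts.
#' @return a [duschinsky_transform()].
#' @export
build_duschinsky <- function(gs, es) {
  if (n_atoms(gs) != n_atoms(es))
    stop("atom mismatch between ground- and excited-state models")
  if (max(abs(gs$masses - es$masses)) > 1e-8)
    stop("mass mismatch between ground- and excited-state models")
  if (n_modes(gs) != n_modes(es))
    stop("mode-count mismatch: ", n_modes(gs), " vs ", n_modes(es))

  m_me <- gs$masses * .const$me_per_amu
  com <- function(x) colSums(x * m_me) / sum(m_me)
  xg <- sweep(gs$geometry, 2L, com(gs$geometry)) * .const$bohr_per_angstrom
  xe <- sweep(es$geometry, 2L, com(es$geometry)) * .const$bohr_per_angstrom

  # Kabsch: rotation R minimizing the mass-weighted geometry mismatch
  a_mat <- crossprod(xe * m_me, xg)
  sv <- svd(a_mat)
  d_fix <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  rot <- sv$v %*% d_fix %*% t(sv$u)
  xe_rot <- xe %*% t(rot)

  # rotate ES mode vectors atom-wise
  lp <- es$mw_modes
  n <- n_atoms(gs)
  lp_rot <- lp
  for (i in seq_len(n)) {
    rows <- (3L * i - 2L):(3L * i)
    lp_rot[rows, ] <- rot %*% lp[rows, , drop = FALSE]
  }

  j_mat <- crossprod(lp_rot, gs$mw_modes)
  orth_dev <- max(abs(crossprod(j_mat) - diag(n_modes(gs))))

  # shift of the ES minimum in dimensionless GS coordinates
  dx_mw <- sqrt(rep(m_me, each = 3L)) * as.numeric(t(xe_rot - xg))
  q_shift <- as.numeric(crossprod(gs$mw_modes, dx_mw))   # mass-weighted a.u.
  k_dimless <- sqrt(.cm1_to_au(gs$frequencies)) * q_shift

  out <- duschinsky_transform(j_mat, k_dimless,
                              gs$frequencies, es$frequencies)
  attr(out, "orthogonality_deviation") <- orth_dev
  out
}

#' Herzberg-Teller expansion of the transition dipole
#'
#' Linear expansion `mu(q) = mu0 + sum_k dmu_k q_k` in the dimensionless
#' ground-state normal coordinates (the same convention as the Duschinsky
#' shift `K`); `dmu = 0` recovers the Condon approximation.
#'
#' @param mu0 3-vector, atomic units.
#' @param dmu 3 x M matrix of per-mode derivative vectors (a.u. per unit
#'   dimensionless coordinate), or NULL for pure Condon.
#' @param n_modes number of modes (needed when `dmu` is NULL).
#' @return object of class `ht_expansion`.
#' @export
ht_expansion <- function(mu0, dmu = NULL, n_modes = NULL) {
  if (length(mu0) != 3L || any(!is.finite(mu0)))
    stop("mu0 must be a finite 3-vector")
  if (is.null(dmu)) {
    if (is.null(n_modes)) stop("n_modes required when dmu is NULL")
    dmu <- matrix(0, 3L, n_modes)
  }
  dmu <- as.matrix(dmu)
  if (nrow(dmu) != 3L || any(!is.finite(dmu)))
    stop("dmu must be a finite 3 x M matrix")
  structure(list(mu0 = as.numeric(mu0), dmu = dmu), class = "ht_expansion")
}

# Internal engine: vibrational overlaps of the GS vibrational ground state
# with ES levels |n'> under q' = C q + d (dimensionless coordinates,
# C = W'^{1/2} J W^{-1/2}, d = -C K), evaluated by a ladder-operator
# recursion that consumes only final-state quanta:
#   u(n)        = (I + C C^T)^{-1} (d f_n + C C^T v(n)),
#   v_l(n)      = sqrt(2 n_l) f_{n - e_l},
#   f_{n + e_l} = sqrt(2/(n_l+1)) u_l(n) - sqrt(n_l/(n_l+1)) f_{n - e_l},
# with the closed-form Gaussian overlap <0|0'> as the seed. The same pass
# yields the Herzberg-Teller matrix elements <0| q_m |n'> = [C^T (v - u)]_m.

#' Multidimensional Franck-Condon overlaps with Duschinsky rotation
#'
#' Tabulates `<0|n'>` for all excited-state quantum-number vectors with
#' `n'_k <= nmax` (per mode), together with the coordinate matrix elements
#' `<0|q_k|n'>` (dimensionless ground-state coordinates) used for
#' Herzberg-Teller intensities. As `nmax` grows,
#' `sum |<0|n'>|^2 -> 1`.
#'
#' @param transform a [duschinsky_transform()].
#' @param nmax per-mode quantum cap (scalar or per-mode vector).
#' @return list with `qn` (rows of quantum numbers, lexicographic order),
#'   `overlap` (`<0|n'>`), `q_elements` (matrix, column k = `<0|q_k|n'>`),
#'   `energies_ev` (vibrational energy above the ES zero level),
#'   `completeness` (`sum overlap^2`).
#' @export
fc_integrals <- function(transform, nmax = 8L) {
  m <- length(transform$gs_frequencies)
  if (m > 10L)
    stop("fc_integrals supports at most 10 coupled modes; block-diagonalize ",
         "the Duschinsky matrix for larger systems")
  nmax <- rep_len(as.integer(nmax), m)
  w_g <- .cm1_to_au(transform$gs_frequencies)
  w_e <- .cm1_to_au(transform$es_frequencies)
  j_mat <- transform$J

  c_mat <- diag(sqrt(w_e), m) %*% j_mat %*% diag(1 / sqrt(w_g), m)
  d_vec <- as.numeric(-c_mat %*% transform$K)

  # seed <0|0'>: Gaussian overlap in mass-weighted coordinates
  kappa <- as.numeric(-j_mat %*% (transform$K / sqrt(w_g)))
  a_mat <- diag(w_g, m) + t(j_mat) %*% diag(w_e, m) %*% j_mat
  b_vec <- as.numeric(-t(j_mat) %*% (w_e * kappa))
  log_pref <- (m / 2) * log(2) + sum(log(w_g) + log(w_e)) / 4 -
    determinant(a_mat, logarithm = TRUE)$modulus / 2
  expo <- -sum(w_e * kappa^2) / 2 + sum(b_vec * solve(a_mat, b_vec)) / 2
  f00 <- exp(as.numeric(log_pref) + expo)

  cct <- tcrossprod(c_mat)
  w_inv <- solve(diag(m) + cct)

  dims <- nmax + 1L
  n_states <- prod(dims)
  qn <- as.matrix(rev(expand.grid(rev(lapply(dims - 1L, seq.int, from = 0L)))))
  colnames(qn) <- NULL
  ord <- do.call(order, as.data.frame(qn))
  qn <- qn[ord, , drop = FALSE]
  lookup <- new.env(hash = TRUE, size = n_states)
  for (i in seq_len(n_states))
    assign(paste(qn[i, ], collapse = ","), i, envir = lookup)
  gi <- function(n) get(paste(n, collapse = ","), envir = lookup)

  f <- numeric(n_states)
  qel <- matrix(0, n_states, m)
  tot <- rowSums(qn)
  f[gi(rep(0L, m))] <- f00

  for (level in 0:max(tot)) {
    for (i in which(tot == level)) {
      n <- qn[i, ]
      fn <- f[i]
      v <- numeric(m)
      for (l in seq_len(m)) if (n[l] > 0L)
        v[l] <- sqrt(2 * n[l]) * f[gi(n - (seq_len(m) == l))]
      u <- as.numeric(w_inv %*% (d_vec * fn + cct %*% v))
      qel[i, ] <- as.numeric(crossprod(c_mat, v - u))
      for (l in seq_len(m)) {
        if (n[l] + 1L > nmax[l]) next
        tgt <- n + (seq_len(m) == l)
        # assign only from the canonical parent (first raised index) so each
        # target is written exactly once
        first_raise <- which(tgt > 0L)[1]
        if (l != first_raise) next
        fm <- if (n[l] > 0L) f[gi(n - (seq_len(m) == l))] else 0
        f[gi(tgt)] <- sqrt(2 / (n[l] + 1)) * u[l] -
          sqrt(n[l] / (n[l] + 1)) * fm
      }
    }
  }
  list(qn = qn, overlap = f, q_elements = qel,
       energies_ev = as.numeric(qn %*% .cm1_to_ev(transform$es_frequencies)),
       completeness = sum(f^2))
}

#' Vibronic sticks with Duschinsky rotation and Herzberg-Teller terms
#'
#' Line intensity
#' `|mu0 <0|n'> + sum_k dmu_k <0|q_k|n'>|^2` at energy
#' `E_00 + sum_k n'_k hbar omega'_k`. With `dmu = 0` this is the Condon
#' limit `|mu0|^2 |<0|n'>|^2`; with `J = I` and equal frequencies it
#' reproduces [fc_sticks()] line for line.
#'
#' @param transform a [duschinsky_transform()].
#' @param ht an [ht_expansion()].
#' @param e00 adiabatic 0-0 energy, eV.
#' @param nmax per-mode quantum cap passed to [fc_integrals()].
#' @return a [stick_spectrum()] with quantum-number labels; attribute
#'   `completeness` carries the FC sum.
#' @export
fcht_sticks <- function(transform, ht, e00, nmax = 8L) {
  tab <- fc_integrals(transform, nmax)
  amp <- outer(ht$mu0, tab$overlap) + ht$dmu %*% t(tab$q_elements)  # 3 x n
  inten <- colSums(amp^2)
  out <- stick_spectrum(e00 + tab$energies_ev, inten,
                        paste0("n'=", apply(tab$qn, 1L, paste, collapse = ",")))
  attr(out, "completeness") <- tab$completeness
  out
}
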