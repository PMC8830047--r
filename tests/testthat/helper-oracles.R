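# Independent oracles used across the suite. These deliberately avoid the
# package's recursion/FFT code paths: harmonic-oscillator wavefunctions are
# evaluated explicitly and integrals done by quadrature or enumeration.

cm1_to_au <- function(f) f / (27.211386 * 8065.544)
cm1_to_ev <- function(f) f / 8065.544

# dimensionless harmonic-oscillator eigenfunction by Hermite recurrence
ho_wf <- function(n, x) {
  h <- matrix(0, length(x), n + 1L)
  h[, 1] <- 1
  if (n >= 1) h[, 2] <- 2 * x
  if (n >= 2) for (k in 2:n) h[, k + 1] <- 2 * x * h[, k] - 2 * (k - 1) * h[, k - 1]
  h[, n + 1] * exp(-x^2 / 2) / sqrt(2^n * factorial(n) * sqrt(pi))
}

# 1-D overlap <0 | n'> and <0 | q | n'> by trapezoid quadrature in the
# mass-weighted coordinate; q is the dimensionless GS coordinate.
quad_overlap_1d <- function(n, w_cm, wp_cm, K, with_q = FALSE) {
  w <- cm1_to_au(w_cm); wp <- cm1_to_au(wp_cm)
  Q <- seq(-9 / sqrt(w), 9 / sqrt(w), length.out = 20001L)
  dQ <- Q[2] - Q[1]
  psi0 <- (w / pi)^0.25 * exp(-w * Q^2 / 2)
  qp <- sqrt(wp) * (Q - K / sqrt(w))
  phin <- ho_wf(n, qp) * wp^0.25
  if (with_q) sum(psi0 * sqrt(w) * Q * phin) * dQ
  else sum(psi0 * phin) * dQ
}

# 2-D overlaps and q-matrix elements on a 400 x 400 grid for a general
# two-mode Duschinsky transform (J rotation, K dimensionless GS shift).
quad_overlap_2d <- function(qn, J, K, wg_cm, we_cm) {
  wg <- cm1_to_au(wg_cm); we <- cm1_to_au(we_cm)
  g1 <- seq(-9 / sqrt(wg[1]), 9 / sqrt(wg[1]), length.out = 400L)
  g2 <- seq(-9 / sqrt(wg[2]), 9 / sqrt(wg[2]), length.out = 400L)
  d12 <- (g1[2] - g1[1]) * (g2[2] - g2[1])
  Q1 <- matrix(g1, 400, 400); Q2 <- matrix(g2, 400, 400, byrow = TRUE)
  psi0 <- (wg[1] / pi)^0.25 * exp(-wg[1] * Q1^2 / 2) *
    (wg[2] / pi)^0.25 * exp(-wg[2] * Q2^2 / 2)
  qmin <- K / sqrt(wg)
  qp1 <- sqrt(we[1]) * (J[1, 1] * (Q1 - qmin[1]) + J[1, 2] * (Q2 - qmin[2]))
  qp2 <- sqrt(we[2]) * (J[2, 1] * (Q1 - qmin[1]) + J[2, 2] * (Q2 - qmin[2]))
  t(apply(qn, 1L, function(n) {
    phin <- ho_wf(n[1], c(qp1)) * we[1]^0.25 * ho_wf(n[2], c(qp2)) * we[2]^0.25
    c(overlap = sum(c(psi0) * phin) * d12,
      q1 = sum(c(psi0) * sqrt(wg[1]) * c(Q1) * phin) * d12,
      q2 = sum(c(psi0) * sqrt(wg[2]) * c(Q2) * phin) * d12)
  }))
}

# quantum numbers encoded in stick labels ("... n=2,0" / "... n'=2,0")
label_qn <- function(sticks) sub(".*n'?=", "", sticks$label)

# random 3-D rotation matrix (deterministic under the caller's seed)
random_rotation <- function() {
  q <- qr(matrix(rnorm(9), 3))
  r <- qr.Q(q)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# apply a rigid rotation to geometry, mode vectors and a Cartesian gradient
rotate_frame <- function(model, gradient, rot) {
  n <- length(model$atom_symbols)
  geom <- model$geometry %*% t(rot)
  modes <- model$mode_vectors
  grad <- gradient
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    modes[rows, ] <- rot %*% modes[rows, , drop = FALSE]
    grad[rows] <- rot %*% grad[rows]
  }
  list(model = harmonic_model(model$atom_symbols, model$masses, geom,
                              model$frequencies, modes),
       gradient = grad)
}
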