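#' Broadening specification
#'
#' Combines the lifetime (Lorentzian) and instrumental/unresolved (Gaussian)
#' widths. `profile = "voigt"` convolves both; degenerate widths reduce it to
#' the pure profile.
#'
#' @param lorentzian_fwhm Lorentzian FWHM in eV (>= 0), typically
#'   `lifetime_to_fwhm(tau)`.
#' @param gaussian_fwhm Gaussian FWHM in eV (>= 0).
#' @param profile `"voigt"`, `"lorentzian"` or `"gaussian"`.
#' @return object of class `broadening_spec`.
#' @export
broadening_spec <- function(lorentzian_fwhm = 0, gaussian_fwhm = 0,
                            profile = c("voigt", "lorentzian", "gaussian")) {
  profile <- match.arg(profile)
  if (lorentzian_fwhm < 0 || gaussian_fwhm < 0)
    stop("widths must be nonnegative")
  if (profile == "lorentzian") gaussian_fwhm <- 0
  if (profile == "gaussian") lorentzian_fwhm <- 0
  structure(list(lorentzian_fwhm = lorentzian_fwhm,
                 gaussian_fwhm = gaussian_fwhm, profile = profile),
            class = "broadening_spec")
}

.broadening_width <- function(b) {
  w <- max(b$lorentzian_fwhm, b$gaussian_fwhm)
  if (w <= 0) stop("broadening requires at least one positive width")
  w
}

# ---- Faddeeva function ------------------------------------------------------
# w(z) = exp(-z^2) erfc(-iz) for Im(z) >= 0, via Weideman's rational
# approximation (SIAM Rev. 36, 1994), N = 64 terms: uniform accuracy near
# machine precision in the upper half plane. Used for the Voigt profile.
.faddeeva_coef <- local({
  cache <- NULL
  function(N = 64L) {
    if (!is.null(cache)) return(cache)
    M <- 2L * N; M2 <- 2L * M
    k <- seq(-M + 1L, M - 1L)
    L <- sqrt(N / sqrt(2))
    theta <- k * pi / M
    t <- L * tan(theta / 2)
    f <- c(0, exp(-t^2) * (L^2 + t^2))
    # fftshift then FFT to obtain polynomial coefficients
    f_shift <- c(f[(M + 1L):M2], f[1:M])
    a <- Re(stats::fft(f_shift)) / M2
    cache <<- list(L = L, a = rev(a[2:(N + 1L)]))  # descending powers
    cache
  }
})

.faddeeva <- function(z) {
  cf <- .faddeeva_coef()
  L <- cf$L; a <- cf$a
  Z <- (L + 1i * z) / (L - 1i * z)
  p <- rep(0 + 0i, length(z))
  for (ak in a) p <- p * Z + ak          # Horner, descending coefficients
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}

# Area-normalized profiles centered at 0, per eV.
.profile_lorentz <- function(x, fwhm) {
  g2 <- fwhm / 2
  (g2 / pi) / (x^2 + g2^2)
}
.profile_gauss <- function(x, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  stats::dnorm(x, sd = sigma)
}
.profile_voigt <- function(x, l_fwhm, g_fwhm) {
  if (g_fwhm <= 0) return(.profile_lorentz(x, l_fwhm))
  if (l_fwhm <= 0) return(.profile_gauss(x, g_fwhm))
  sigma <- g_fwhm / (2 * sqrt(2 * log(2)))
  gamma <- l_fwhm / 2
  z <- (x + 1i * gamma) / (sigma * sqrt(2))
  Re(.faddeeva(z)) / (sigma * sqrt(2 * pi))
}

.profile_eval <- function(x, b) {
  switch(b$profile,
         lorentzian = .profile_lorentz(x, b$lorentzian_fwhm),
         gaussian = .profile_gauss(x, b$gaussian_fwhm),
         voigt = .profile_voigt(x, b$lorentzian_fwhm, b$gaussian_fwhm))
}

# ---- Franck-Condon sticks ---------------------------------------------------

#' Franck-Condon stick spectrum of a displaced harmonic oscillator
#'
#' Zero-temperature multi-mode Poisson progression: a line at
#' `E_00 + sum_k n_k hbar omega_k` for every retained quantum-number vector,
#' with intensity `intensity0 * prod_k exp(-S_k) S_k^{n_k} / n_k!`.
#' Per-mode ladders are truncated at the smallest depth whose per-mode
#' cumulative weight reaches `(1 - epsilon)^{1/M}` (so the retained total is
#' at least `1 - epsilon`), with a hard per-mode cap; enumeration order is
#' lexicographic in the quantum numbers, making output deterministic.
#'
#' @param dho a `dho_parameters` object.
#' @param intensity0 electronic intensity carrier (`|mu|^2` or Dyson norm).
#' @param epsilon cumulative Franck-Condon weight tolerance (default 1e-4).
#' @param nmax per-mode quantum cap (default 50).
#' @param label_prefix prefix for per-line labels.
#' @return a [stick_spectrum()]; labels record the quantum numbers, and the
#'   attribute `retained_weight` the kept fraction of the FC sum rule.
#' @export
#' @examples
#' d <- dho_from_displacements(1753, sqrt(2 * 0.5), e_vert = 287)
#' head(fc_sticks(d, 1))
fc_sticks <- function(dho, intensity0, epsilon = 1e-4, nmax = 50L,
                      label_prefix = "") {
  s <- dho$huang_rhys
  m <- length(s)
  hw <- .cm1_to_ev(dho$frequencies)
  per_mode_target <- (1 - epsilon)^(1 / m)
  ladders <- lapply(seq_len(m), function(k) {
    if (s[k] == 0) return(list(n = 0L, p = 1))
    n_hi <- 0L
    repeat {
      cum <- stats::ppois(n_hi, s[k])
      if (cum >= per_mode_target || n_hi >= nmax) break
      n_hi <- n_hi + 1L
    }
    # three extra quanta beyond the weight threshold: keeps the truncation
    # bias in the moment sum rules far below the retained-weight tolerance
    n_hi <- min(n_hi + 3L, nmax)
    list(n = 0:n_hi, p = stats::dpois(0:n_hi, s[k]))
  })
  sizes <- vapply(ladders, function(l) length(l$n), 0L)
  if (prod(sizes) > 2e6)
    stop("FC enumeration would exceed 2e6 lines; reduce modes or epsilon")
  # lexicographic: first mode slowest
  qn <- as.matrix(rev(expand.grid(rev(lapply(ladders, `[[`, "n")))))
  ord <- do.call(order, as.data.frame(qn))
  qn <- qn[ord, , drop = FALSE]
  wt <- rep(1, nrow(qn))
  en <- rep(dho$adiabatic_energy, nrow(qn))
  for (k in seq_len(m)) {
    wt <- wt * ladders[[k]]$p[qn[, k] + 1L]
    en <- en + qn[, k] * hw[k]
  }
  labels <- paste0(label_prefix, "n=", apply(qn, 1L, paste, collapse = ","))
  out <- stick_spectrum(en, intensity0 * wt, labels)
  attr(out, "retained_weight") <- sum(wt)
  out
}

#' Convolve a stick spectrum with a broadening profile
#'
#' Each stick contributes an area-normalized Lorentzian, Gaussian or Voigt
#' profile times its intensity; the result is evaluated on the supplied
#' uniform grid. With a grid spanning +/- 20 widths around the sticks the
#' zeroth moment is preserved to better than 1e-6 relative.
#'
#' @param sticks a [stick_spectrum()].
#' @param broadening a [broadening_spec()].
#' @param grid uniform energy axis (numeric vector or `"start:stop:step"`).
#' @return a [grid_spectrum()].
#' @export
broaden_sticks <- function(sticks, broadening, grid) {
  grid <- energy_grid(grid)
  width <- .broadening_width(broadening)
  step <- grid[2] - grid[1]
  if (step > width / 5)
    stop("grid too coarse for requested widths: step ", signif(step, 3),
         " > width/5 = ", signif(width / 5, 3))
  y <- numeric(length(grid))
  for (i in seq_len(nrow(sticks))) {
    if (sticks$intensity[i] == 0) next
    y <- y + sticks$intensity[i] *
      .profile_eval(grid - sticks$energy[i], broadening)
  }
  grid_spectrum(grid, y, metadata = list(broadening = broadening))
}

# ---- time-domain route ------------------------------------------------------

#' Time-domain DHO absorption spectrum via FFT
#'
#' Evaluates the zero-temperature DHO lineshape from its exact cumulant
#' expression,
#' `sigma(E) = intensity0/(pi hbar) Re int_0^inf dt e^{i(E-E_00)t/hbar}
#'  exp[-sum_k S_k (1 - e^{-i omega_k t})] D(t)`,
#' with damping `D(t) = exp(-Gamma t / 2 hbar) exp(-sigma_G^2 t^2 / 2 hbar^2)`
#' (`Gamma` the Lorentzian FWHM, `sigma_G = gaussian_fwhm / 2.3548`). The
#' half-line Fourier integral is computed by FFT on an internal grid that
#' oversamples the requested one (step at most width/40, span padded by 20
#' widths plus the progression extent, trapezoidal end correction at t = 0)
#' and cubic-spline interpolated onto `grid`. This route is the
#' cross-validation partner of `broaden_sticks(fc_sticks(...))`; the two
#' agree pointwise to better than 1e-3 relative on few-mode fixtures.
#'
#' @inheritParams broaden_sticks
#' @param dho a `dho_parameters` object.
#' @param intensity0 electronic intensity carrier.
#' @return a [grid_spectrum()]; the area under the full line integrates to
#'   `intensity0`.
#' @export
timedomain_spectrum <- function(dho, intensity0, broadening, grid) {
  grid <- energy_grid(grid)
  width <- .broadening_width(broadening)
  step <- grid[2] - grid[1]
  if (step > width / 5)
    stop("grid too coarse for requested widths: step ", signif(step, 3),
         " > width/5 = ", signif(width / 5, 3))
  hbar <- .const$hbar_ev_fs
  s <- dho$huang_rhys
  omega <- .cm1_to_ev(dho$frequencies) / hbar   # rad/fs
  gamma <- broadening$lorentzian_fwhm
  sig_g <- broadening$gaussian_fwhm / (2 * sqrt(2 * log(2)))

  # internal energy window: requested grid padded by 20 widths and the
  # Franck-Condon progression extent on the high side
  extent <- sum((s + 5 * sqrt(pmax(s, 1))) * .cm1_to_ev(dho$frequencies))
  e_lo <- min(grid) - 20 * width
  e_hi <- max(grid) + 20 * width + extent
  # pad the span 8x: the time step dt = 2*pi*hbar/span sets the trapezoid
  # bias of the half-line Fourier integral, which falls as dt^2
  e_hi <- e_lo + 8 * (e_hi - e_lo)
  de <- min(step, width / 40)
  n_fft <- 2^ceiling(log2((e_hi - e_lo) / de + 1))
  n_fft <- max(n_fft, 16384L)
  de <- (e_hi - e_lo) / n_fft
  dt <- 2 * pi * hbar / (n_fft * de)

  t <- (0:(n_fft - 1L)) * dt
  logc <- -outer(t, omega, function(tt, om) 1 - exp(-1i * om * tt)) %*% s
  damp <- -gamma * t / (2 * hbar) - (sig_g * t)^2 / (2 * hbar^2)
  # shift the transform origin to e_lo so FFT bin m maps to e_lo + m*de
  phase <- 1i * (e_lo - dho$adiabatic_energy) * t / hbar
  integrand <- exp(drop(logc) + damp + phase)
  integrand[1] <- integrand[1] / 2            # trapezoid at t = 0
  ft <- stats::fft(integrand, inverse = TRUE) # sum_j z_j exp(+2pi i jm/n)
  e_int <- e_lo + (0:(n_fft - 1L)) * de
  sig <- intensity0 * dt / (pi * hbar) * Re(ft)
  keep <- e_int >= min(grid) - 10 * width & e_int <= max(grid) + 10 * width
  y <- stats::spline(e_int[keep], sig[keep], xout = grid, method = "natural")$y
  grid_spectrum(grid, pmax(y, 0),
                metadata = list(broadening = broadening, route = "timedomain"))
}
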