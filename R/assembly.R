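# Composition of per-state vibronic spectra into full XANES / XPS traces.

.state_sticks <- function(state, harmonic, model_level, epsilon, nmax) {
  dho <- dho_from_state(state, harmonic)
  intensity0 <- if (state$kind == "core-excited") sum(state$tdm^2)
                else state$dyson_norm
  if (model_level == "dho")
    return(fc_sticks(dho, intensity0, epsilon = epsilon,
                     label_prefix = paste0(state$label, " ")))
  if (is.null(state$es_harmonic))
    stop("state '", state$label, "': model level '", model_level,
         "' needs es_harmonic data")
  tr <- build_duschinsky(harmonic, state$es_harmonic)
  e00 <- dho$adiabatic_energy + zpe_shift(harmonic, state$es_harmonic)
  ht <- if (model_level == "fcht" && !is.null(state$tdm_derivatives))
    ht_expansion(state$tdm, state$tdm_derivatives)
  else ht_expansion(state$tdm, NULL, n_modes(harmonic))
  st <- fcht_sticks(tr, ht, e00, nmax = nmax)
  st$label <- paste0(state$label, " ", st$label)
  st
}

#' Assemble a XANES spectrum from a calculation bundle
#'
#' Every core-excited state contributes its vibronic progression at the
#' requested model level (`"dho"`: gradient-only displaced oscillator;
#' `"duschinsky"`: rotated Franck-Condon integrals from the state's harmonic
#' data; `"fcht"`: additionally linear Herzberg-Teller terms). States below
#' the ionization threshold are broadened - each with the Lorentzian width of
#' its own lifetime plus the common Gaussian width - while states above the
#' threshold are returned as sticks only, mirroring the bound/continuum
#' rendering convention. With no `ip_threshold` all states are broadened.
#'
#' @param bundle a [calculation_bundle()] containing core-excited states.
#' @param model_level `"dho"`, `"duschinsky"` or `"fcht"`.
#' @param grid energy axis (numeric or `"start:stop:step"`, eV).
#' @param gaussian_fwhm common instrumental Gaussian FWHM, eV.
#' @param normalize logical, scale the grid maximum to 1 (default FALSE).
#' @param shift rigid energy shift in eV applied to the result (default 0).
#' @param epsilon Franck-Condon truncation for the DHO route.
#' @param nmax per-mode cap for the Duschinsky route.
#' @return list of class `assembled_spectrum`: `grid` ([grid_spectrum()]),
#'   `sticks` (supra-threshold lines), `per_state` (named list of per-state
#'   stick spectra).
#' @export
assemble_xanes <- function(bundle, model_level = c("dho", "duschinsky",
                                                   "fcht"),
                           grid, gaussian_fwhm = 0.2, normalize = FALSE,
                           shift = 0, epsilon = 1e-6, nmax = 8L) {
  model_level <- match.arg(model_level)
  grid <- energy_grid(grid)
  states <- Filter(function(s) s$kind == "core-excited", bundle$states)
  if (length(states) == 0L)
    stop("bundle contains no core-excited states")
  ip <- bundle$ip_threshold
  total <- numeric(length(grid))
  supra <- stick_spectrum()
  per_state <- list()
  any_below <- FALSE
  for (s in states) {
    st <- .state_sticks(s, bundle$harmonic, model_level, epsilon, nmax)
    per_state[[s$label]] <- st
    if (is.null(ip) || s$vertical_energy < ip) {
      any_below <- TRUE
      b <- broadening_spec(lifetime_to_fwhm(s$lifetime), gaussian_fwhm,
                           "voigt")
      total <- total + broaden_sticks(st, b, grid)$intensity
    } else {
      supra <- stick_spectrum(c(supra$energy, st$energy),
                              c(supra$intensity, st$intensity),
                              c(supra$label, st$label))
    }
  }
  if (!any_below && nrow(supra) == 0L)
    stop("empty spectrum: no states below the threshold and no sticks")
  gs <- grid_spectrum(grid, total,
                      metadata = list(model_level = model_level,
                                      gaussian_fwhm = gaussian_fwhm))
  out <- list(grid = gs, sticks = supra, per_state = per_state)
  class(out) <- "assembled_spectrum"
  if (normalize) out$grid <- normalize_spectrum(out$grid)
  if (shift != 0) {
    out$grid <- apply_shift(out$grid, shift)
    out$sticks <- apply_shift(out$sticks, shift)
  }
  out
}

#' Assemble an XPS spectrum from a calculation bundle
#'
#' Each core-cation state contributes a DHO vibronic envelope scaled by its
#' Dyson norm (sudden-approximation intensity), broadened with its lifetime
#' Lorentzian plus the common Gaussian. When a state carries excited-state
#' harmonic data, the zero-point-energy shift
#' `dZPE = 1/2 sum hbar (omega' - omega)` is added to its band origin.
#' By default the output is normalized so the most intense band has height 1,
#' the convention used when matching measured photoemission intensities.
#'
#' @inheritParams assemble_xanes
#' @param apply_zpe logical, add the zero-point shift where ES data exist.
#' @param normalize logical (default TRUE), maximum scaled to 1.
#' @return a [grid_spectrum()].
#' @export
assemble_xps <- function(bundle, grid, gaussian_fwhm = 0.3,
                         normalize = TRUE, apply_zpe = TRUE,
                         epsilon = 1e-6) {
  grid <- energy_grid(grid)
  states <- Filter(function(s) s$kind == "core-cation", bundle$states)
  if (length(states) == 0L)
    stop("bundle contains no core-cation states (missing dyson_norm)")
  total <- numeric(length(grid))
  for (s in states) {
    dho <- dho_from_state(s, bundle$harmonic)
    st <- fc_sticks(dho, s$dyson_norm, epsilon = epsilon,
                    label_prefix = paste0(s$label, " "))
    if (apply_zpe && !is.null(s$es_harmonic))
      st$energy <- st$energy + zpe_shift(bundle$harmonic, s$es_harmonic)
    b <- broadening_spec(lifetime_to_fwhm(s$lifetime), gaussian_fwhm,
                         "voigt")
    total <- total + broaden_sticks(st, b, grid)$intensity
  }
  out <- grid_spectrum(grid, total,
                       metadata = list(kind = "xps",
                                       gaussian_fwhm = gaussian_fwhm))
  if (normalize) normalize_spectrum(out) else out
}

#' Boltzmann conformer weights
#'
#' Raw ratios `r_i = exp(-dG_i / RT)` relative to the reference conformer
#' (`dG = 0`) and normalized fractions `r_i / sum r_j`, with
#' R = 8.314462 J mol^-1 K^-1. For two conformers the fraction equals
#' `ratio / (1 + ratio)`; a free-energy gap of 6.535 kJ/mol at 473 K gives a
#' ratio close to 0.19, i.e. a secondary-conformer weight of about 20%.
#'
#' @param delta_g kJ/mol per conformer (reference at 0).
#' @param temperature K (> 0).
#' @return list with `ratios` and `fractions`.
#' @export
#' @examples
#' boltzmann_weights(c(0, 6.535), 473)
boltzmann_weights <- function(delta_g, temperature) {
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive")
  ratios <- exp(-delta_g * 1000 / (.const$gas_constant_j_mol_k * temperature))
  list(ratios = ratios, fractions = ratios / sum(ratios))
}

#' Combine per-conformer spectra with weights
#'
#' Pointwise weighted sum of grid spectra defined on identical grids.
#'
#' @param spectra list of [grid_spectrum()] objects.
#' @param weights numeric weights summing to 1.
#' @return a [grid_spectrum()].
#' @export
combine_conformers <- function(spectra, weights) {
  if (length(spectra) != length(weights))
    stop("one weight per spectrum required")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  g0 <- spectra[[1]]$grid
  for (sp in spectra[-1])
    if (length(sp$grid) != length(g0) || max(abs(sp$grid - g0)) > 1e-9)
      stop("grid mismatch between conformer spectra")
  total <- Reduce(`+`, Map(function(sp, w) w * sp$intensity, spectra,
                           weights))
  grid_spectrum(g0, total, metadata = list(weights = weights))
}

#' Rigid energy shift
#'
#' Translates a spectrum along the energy axis; intensities are untouched
#' and the shift is logged in grid-spectrum metadata. Default pipelines use
#' no shift.
#'
#' @param spectrum [grid_spectrum()] or [stick_spectrum()].
#' @param shift eV.
#' @return shifted spectrum of the same class.
#' @export
apply_shift <- function(spectrum, shift) {
  if (inherits(spectrum, "grid_spectrum")) {
    md <- spectrum$metadata
    md$shift <- (if (is.null(md$shift)) 0 else md$shift) + shift
    grid_spectrum(spectrum$grid + shift, spectrum$intensity, md)
  } else if (inherits(spectrum, "stick_spectrum")) {
    stick_spectrum(spectrum$energy + shift, spectrum$intensity,
                   spectrum$label)
  } else stop("unsupported spectrum type")
}

#' Scale a spectrum so its maximum is 1
#'
#' Idempotent and invariant under any prior positive scaling.
#'
#' @param spectrum [grid_spectrum()] or [stick_spectrum()].
#' @return normalized spectrum.
#' @export
normalize_spectrum <- function(spectrum) {
  if (inherits(spectrum, "grid_spectrum")) {
    m <- max(spectrum$intensity)
    if (m <= 0) stop("cannot normalize an all-zero spectrum")
    grid_spectrum(spectrum$grid, spectrum$intensity / m, spectrum$metadata)
  } else if (inherits(spectrum, "stick_spectrum")) {
    m <- max(spectrum$intensity)
    if (m <= 0) stop("cannot normalize an all-zero spectrum")
    stick_spectrum(spectrum$energy, spectrum$intensity / m, spectrum$label)
  } else stop("unsupported spectrum type")
}

#' @export
print.assembled_spectrum <- function(x, ...) {
  cat("assembled_spectrum:", length(x$per_state), "state(s);",
      nrow(x$sticks), "supra-threshold stick(s)\n")
  print(x$grid)
  invisible(x)
}
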