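#' Discrete vibronic stick spectrum
#'
#' @param energy line positions, eV (finite).
#' @param intensity nonnegative line intensities (dimensionless).
#' @param label per-line parent labels (recycled).
#' @return object of class `stick_spectrum`: a data frame with columns
#'   `energy`, `intensity`, `label`.
#' @export
stick_spectrum <- function(energy = numeric(), intensity = numeric(),
                           label = character()) {
  if (length(energy) != length(intensity))
    stop("energy and intensity lengths differ")
  if (any(!is.finite(energy)) || any(!is.finite(intensity)))
    stop("stick energies and intensities must be finite")
  if (any(intensity < 0)) stop("stick intensities must be nonnegative")
  if (length(label) == 0L && length(energy) > 0L) label <- ""
  df <- data.frame(energy = as.numeric(energy),
                   intensity = as.numeric(intensity),
                   label = if (length(energy)) rep_len(as.character(label),
                                                       length(energy))
                           else character())
  class(df) <- c("stick_spectrum", "data.frame")
  df
}

#' Uniform-grid broadened spectrum
#'
#' @param grid strictly increasing, uniformly spaced energy axis (eV).
#' @param intensity nonnegative intensity per grid point.
#' @param metadata list recording the broadening and any shift applied.
#' @return object of class `grid_spectrum`.
#' @export
grid_spectrum <- function(grid, intensity, metadata = list()) {
  grid <- as.numeric(grid); intensity <- as.numeric(intensity)
  if (length(grid) < 2L) stop("grid needs at least two points")
  if (length(grid) != length(intensity))
    stop("grid and intensity lengths differ")
  d <- diff(grid)
  if (any(d <= 0)) stop("grid must be strictly increasing")
  if (max(d) - min(d) > 1e-9 * mean(d)) stop("grid must be uniform")
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  if (any(intensity < -1e-12 * max(abs(intensity), 1)))
    stop("intensities must be nonnegative")
  structure(list(grid = grid, intensity = pmax(intensity, 0),
                 metadata = metadata),
            class = "grid_spectrum")
}

#' @export
print.grid_spectrum <- function(x, ...) {
  cat("grid_spectrum:", length(x$grid), "points,",
      signif(min(x$grid), 8), "to", signif(max(x$grid), 8), "eV, step",
      signif(x$grid[2] - x$grid[1], 6), "eV\n")
  invisible(x)
}

#' Parse an energy-grid specification
#'
#' Accepts a `"start:stop:step"` string (eV) or a numeric vector, returning
#' a uniform increasing grid.
#'
#' @param spec grid specification.
#' @return numeric vector of grid energies.
#' @export
#' @examples
#' energy_grid("280:290:0.05")[1:3]
energy_grid <- function(spec) {
  if (is.numeric(spec)) return(as.numeric(spec))
  parts <- as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]])
  if (length(parts) != 3L || any(is.na(parts)) || parts[3] <= 0 ||
      parts[2] <= parts[1])
    stop("grid spec must be 'start:stop:step' with stop > start, step > 0")
  seq(parts[1], parts[2], by = parts[3])
}

#' Write a spectrum to a tab-separated text file
#'
#' Grid spectra become two columns (`energy`, `intensity`); stick spectra
#' three (`energy`, `intensity`, `label`, labels verbatim). 15 significant
#' digits are kept, so [read_spectrum()] recovers values to better than
#' 1e-12 relative.
#'
#' @param spectrum a [stick_spectrum()] or [grid_spectrum()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_spectrum <- function(spectrum, path) {
  if (inherits(spectrum, "grid_spectrum")) {
    df <- data.frame(energy = formatC(spectrum$grid, format = "e", digits = 15),
                     intensity = formatC(spectrum$intensity, format = "e",
                                         digits = 15))
  } else if (inherits(spectrum, "stick_spectrum")) {
    if (any(!is.finite(spectrum$intensity)))
      stop("non-finite intensities cannot be written")
    df <- data.frame(energy = formatC(spectrum$energy, format = "e",
                                      digits = 15),
                     intensity = formatC(spectrum$intensity, format = "e",
                                         digits = 15),
                     label = spectrum$label)
  } else stop("spectrum must be a stick_spectrum or grid_spectrum")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path TSV file; two columns are read back as a grid spectrum,
#'   three as a stick spectrum.
#' @return a [stick_spectrum()] or [grid_spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) == 2L)
    grid_spectrum(as.numeric(df[[1]]), as.numeric(df[[2]]))
  else if (ncol(df) == 3L)
    stick_spectrum(as.numeric(df[[1]]), as.numeric(df[[2]]),
                   as.character(df[[3]]))
  else stop("unrecognized spectrum file layout: ", ncol(df), " columns")
}

#' Intensity-weighted spectral moments
#'
#' Zeroth moment, mean energy and variance of a stick or grid spectrum.
#' For the Franck-Condon progression of a displaced harmonic oscillator
#' these obey the sum rules mean = E_00 + lambda = E_vert and
#' variance = sum_k S_k (hbar omega_k)^2.
#'
#' @param x a [stick_spectrum()] or [grid_spectrum()]; grid spectra are
#'   integrated by the trapezoidal rule.
#' @return list with `m0`, `mean`, `variance`.
#' @export
spectral_moments <- function(x) {
  if (inherits(x, "stick_spectrum")) {
    w <- x$intensity; e <- x$energy
    m0 <- sum(w)
  } else if (inherits(x, "grid_spectrum")) {
    e <- x$grid
    h <- e[2] - e[1]
    w <- x$intensity * h
    w[c(1, length(w))] <- w[c(1, length(w))] / 2
    m0 <- sum(w)
  } else stop("x must be a stick_spectrum or grid_spectrum")
  if (m0 <= 0) stop("all-zero spectrum has no moments")
  mu <- sum(w * e) / m0
  list(m0 = m0, mean = mu, variance = sum(w * (e - mu)^2) / m0)
}

#' Locate peaks of a broadened spectrum
#'
#' Simple local-maximum finder: a grid point is a peak when it exceeds both
#' neighbours and rises above `threshold` times the global maximum.
#'
#' @param spectrum a [grid_spectrum()].
#' @param threshold relative height floor (default 0.01).
#' @param window optional `c(lo, hi)` energy interval restricting the search.
#' @return data frame with columns `energy`, `intensity`.
#' @export
find_peaks <- function(spectrum, threshold = 0.01, window = NULL) {
  y <- spectrum$intensity; e <- spectrum$grid
  n <- length(y)
  is_pk <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                    y[2:(n - 1)] > y[3:n], FALSE)
  is_pk <- is_pk & y >= threshold * max(y)
  if (!is.null(window)) is_pk <- is_pk & e >= window[1] & e <= window[2]
  data.frame(energy = e[is_pk], intensity = y[is_pk])
}
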