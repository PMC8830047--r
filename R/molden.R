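# Molden frequency-format I/O ([FREQ], [FR-COORD], [FR-NORM-COORD]).
# Molden stores coordinates in Bohr and carries no masses; masses are
# assigned from a standard atomic-weight table (overridable).

.atomic_masses <- c(
  H = 1.00794, D = 2.014102, He = 4.002602,
  Li = 6.941, Be = 9.012182, B = 10.811, C = 12.0107, N = 14.0067,
  O = 15.9994, F = 18.9984032, Ne = 20.1797,
  Na = 22.98977, Mg = 24.305, Al = 26.981538, Si = 28.0855,
  P = 30.973761, S = 32.065, Cl = 35.453, Ar = 39.948,
  K = 39.0983, Ca = 40.078, X = 1.0  # X: unit-mass pseudo-atom
)

.mass_from_symbol <- function(symbols) {
  key <- sub("[0-9]+$", "", symbols)        # tolerate "C1", "O2" labels
  key <- paste0(toupper(substr(key, 1, 1)), tolower(substring(key, 2)))
  m <- .atomic_masses[key]
  if (any(is.na(m)))
    stop("unknown element symbol(s): ",
         paste(unique(symbols[is.na(m)]), collapse = ", "),
         "; supply masses explicitly")
  unname(m)
}

.molden_sections <- function(lines) {
  tag_idx <- grep("^\\s*\\[", lines)
  tags <- toupper(gsub("[^A-Z-]", "", toupper(lines[tag_idx])))
  out <- list()
  for (i in seq_along(tag_idx)) {
    from <- tag_idx[i] + 1L
    to <- if (i < length(tag_idx)) tag_idx[i + 1L] - 1L else length(lines)
    body <- lines[seq(from, length.out = max(0L, to - from + 1L))]
    out[[tags[i]]] <- body[nzchar(trimws(body))]
  }
  out
}

#' Read a Molden frequency file
#'
#' Parses the `[FREQ]`, `[FR-COORD]` and `[FR-NORM-COORD]` sections of a
#' Molden file into a validated [harmonic_model()]. Coordinates and mode
#' vectors are converted from Bohr to Angstrom; masses are looked up from
#' element symbols unless supplied. Mode vectors are re-orthonormalized in
#' the mass-weighted metric (idempotent for files the package writes).
#'
#' @param path file path.
#' @param masses optional numeric vector of masses (amu) overriding the
#'   element lookup.
#' @param linear logical; molecule is linear.
#' @param mass_weighted logical; the file's normal coordinates are
#'   mass-weighted rather than Cartesian displacements (writer dialect flag).
#' @param drop_nonpositive logical; drop zero/imaginary modes instead of
#'   erroring.
#' @return a [harmonic_model()].
#' @export
read_molden_frequencies <- function(path, masses = NULL, linear = FALSE,
                                    mass_weighted = FALSE,
                                    drop_nonpositive = FALSE) {
  lines <- readLines(path, warn = FALSE)
  sec <- .molden_sections(lines)
  need <- c("FREQ", "FR-COORD", "FR-NORMCOORD")
  have <- c("FREQ" %in% names(sec), "FR-COORD" %in% names(sec),
            any(c("FR-NORMCOORD", "FRNORM-COORD", "FR-NORM-COORD") %in% names(sec)))
  if (!all(have))
    stop("Molden format error: missing section(s) ",
         paste(c("[FREQ]", "[FR-COORD]", "[FR-NORM-COORD]")[!have],
               collapse = ", "))

  freqs <- as.numeric(sec[["FREQ"]])
  if (any(is.na(freqs))) stop("Molden format error: non-numeric [FREQ] entry")

  coord_tok <- strsplit(trimws(sec[["FR-COORD"]]), "\\s+")
  symbols <- vapply(coord_tok, `[`, "", 1L)
  geom_bohr <- t(vapply(coord_tok,
                        function(t) as.numeric(t[2:4]), numeric(3)))
  if (any(is.na(geom_bohr))) stop("Molden format error: bad [FR-COORD] line")
  n_atom <- length(symbols)

  nm_name <- intersect(c("FR-NORMCOORD", "FRNORM-COORD", "FR-NORM-COORD"),
                       names(sec))[1]
  body <- sec[[nm_name]]
  vib_idx <- grep("^\\s*[Vv]ibration", body)
  if (length(vib_idx) != length(freqs))
    stop("Molden consistency error: ", length(vib_idx),
         " vibration blocks for ", length(freqs), " frequencies")
  modes <- matrix(0, 3L * n_atom, length(freqs))
  for (k in seq_along(vib_idx)) {
    from <- vib_idx[k] + 1L
    to <- if (k < length(vib_idx)) vib_idx[k + 1L] - 1L else length(body)
    vals <- as.numeric(unlist(strsplit(trimws(body[from:to]), "\\s+")))
    if (length(vals) != 3L * n_atom || any(is.na(vals)))
      stop("Molden consistency error: vibration ", k, " has ",
           length(vals), " components, expected ", 3L * n_atom)
    modes[, k] <- vals
  }

  if (is.null(masses)) masses <- .mass_from_symbol(symbols)
  harmonic_model(
    atom_symbols = symbols, masses = masses,
    geometry = geom_bohr / .const$bohr_per_angstrom,
    frequencies = freqs,
    mode_vectors = modes / .const$bohr_per_angstrom,
    linear = linear, mass_weighted = mass_weighted,
    drop_nonpositive = drop_nonpositive
  )
}

#' Write a harmonic model as a Molden frequency file
#'
#' Writes `[FREQ]`, `[FR-COORD]` and `[FR-NORM-COORD]` sections (coordinates
#' in Bohr, Cartesian displacement normal coordinates). Numeric fields carry
#' 12 significant digits so a write/read round trip preserves the model.
#'
#' @param model a [harmonic_model()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_molden_frequencies <- function(model, path) {
  fmt <- function(x) formatC(x, format = "e", digits = 12)
  out <- c("[Molden Format]", "[FREQ]", fmt(model$frequencies), "[FR-COORD]")
  geom_bohr <- model$geometry * .const$bohr_per_angstrom
  out <- c(out, vapply(seq_len(n_atoms(model)), function(i) {
    paste(model$atom_symbols[i], paste(fmt(geom_bohr[i, ]), collapse = " "))
  }, ""))
  out <- c(out, "[FR-NORM-COORD]")
  modes_bohr <- model$mode_vectors * .const$bohr_per_angstrom
  for (k in seq_len(n_modes(model))) {
    out <- c(out, paste("vibration", k),
             vapply(seq_len(n_atoms(model)), function(i) {
               paste(fmt(modes_bohr[(3 * i - 2):(3 * i), k]), collapse = " ")
             }, ""))
  }
  writeLines(out, path)
  invisible(path)
}
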