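#' Physical constants used throughout xrvib
#'
#' All computations run internally in Hartree atomic units (hbar = 1);
#' user-facing quantities are spectroscopic (eV, cm^-1, fs, Angstrom, amu).
#' Every conversion in the package goes through this single table so that
#' each number produced by the package is reproducible from it.
#'
#' @return Named list of constants:
#' \describe{
#'   \item{ev_per_hartree}{27.211386 eV per Hartree}
#'   \item{cm1_per_ev}{8065.544 cm^-1 per eV}
#'   \item{cm1_per_hartree}{product of the two above}
#'   \item{hbar_ev_fs}{0.6582120 eV fs (lifetime broadening Gamma = hbar/tau)}
#'   \item{bohr_per_angstrom}{1.8897261}
#'   \item{me_per_amu}{1822.888486 electron masses per unified amu}
#'   \item{gas_constant_j_mol_k}{8.314462 J mol^-1 K^-1}
#' }
#' @export
#' @examples
#' xrvib_constants()$hbar_ev_fs
xrvib_constants <- function() {
  ev_per_hartree <- 27.211386
  cm1_per_ev <- 8065.544
  list(
    ev_per_hartree = ev_per_hartree,
    cm1_per_ev = cm1_per_ev,
    cm1_per_hartree = ev_per_hartree * cm1_per_ev,
    hbar_ev_fs = 0.6582120,
    bohr_per_angstrom = 1.8897261,
    me_per_amu = 1822.888486,
    gas_constant_j_mol_k = 8.314462
  )
}

# internal shorthand (fixed copy; xrvib_constants() is the public view)
.const <- list(
  ev_per_hartree = 27.211386,
  cm1_per_ev = 8065.544,
  cm1_per_hartree = 27.211386 * 8065.544,
  hbar_ev_fs = 0.6582120,
  bohr_per_angstrom = 1.8897261,
  me_per_amu = 1822.888486,
  gas_constant_j_mol_k = 8.314462
)

# cm^-1 -> angular frequency in atomic units (hbar = 1)
.cm1_to_au <- function(freq_cm1) freq_cm1 / .const$cm1_per_hartree

# cm^-1 -> eV photon/vibrational quantum
.cm1_to_ev <- function(freq_cm1) freq_cm1 / .const$cm1_per_ev
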