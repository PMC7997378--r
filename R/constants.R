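#' Physical constants and unit conventions
#'
#' All coordinates are in Angstrom, scattering vectors q in 1/Angstrom,
#' energies in kJ/mol, masses in Da, temperatures in K and times in ps.
#' One conversion layer exists at I/O only.
#'
#' @name units
#' @keywords internal
NULL

## Boltzmann constant, kJ/mol/K
KB <- 0.008314463

## kJ/mol -> Da * A^2 / ps^2 (dynamics units)
ENERGY_TO_DYN <- 100

## Coulomb constant e^2/(4 pi eps0), kJ * A / mol, for unit charges in e
COULOMB_KE <- 1389.35457644382

#' Boltzmann constant in kJ/mol/K
#' @return Numeric scalar, 0.008314463 kJ/mol/K.
#' @export
kB <- function() KB

## Atomic masses (Da) for elements that occur in protein heavy atoms plus H
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305
)

element_mass <- function(element) {
  m <- ATOMIC_MASSES[toupper(element)]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("unknown element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}

## Guess element from a PDB atom name (heavy-atom biased; first letter after
## stripping digits, with two-letter cases handled explicitly).
element_from_atom_name <- function(atom_name) {
  nm <- toupper(gsub("[ 0-9']", "", atom_name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("SE", "FE", "ZN", "MG"), two, substr(nm, 1, 1))
  el
}
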