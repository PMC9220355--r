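#' Energy unit conversion
#'
#' Converts quantum-chemistry energies to the package's working unit,
#' kJ/mol. The hartree conversion uses the CODATA value
#' 1 Eh = 2625.4996394799 kJ/mol; 1 kcal = 4.184 kJ (thermochemical).
#'
#' @param value Numeric vector of energies.
#' @param unit One of `"hartree"`, `"kJ/mol"`, `"kcal/mol"`.
#' @return Numeric vector in kJ/mol.
#' @examples
#' convert_energy(1, "hartree")
#' convert_energy(-255, "kJ/mol")
#' @export
convert_energy <- function(value, unit) {
  stopifnot(is.numeric(value))
  unit <- as.character(unit)
  if (length(unit) == 1L) unit <- rep(unit, length(value))
  if (length(unit) != length(value))
    stop("`unit` must have length 1 or length(value)")
  known <- c("hartree", "kJ/mol", "kcal/mol")
  bad <- setdiff(unique(unit), known)
  if (length(bad))
    stop("unknown energy unit: ", paste(bad, collapse = ", "))
  fac <- c("hartree" = HARTREE_KJMOL, "kJ/mol" = 1, "kcal/mol" = 4.184)
  unname(value * fac[unit])
}

#' @rdname convert_energy
#' @param to Target unit for the reverse conversion.
#' @export
convert_energy_from_kjmol <- function(value, to) {
  stopifnot(is.numeric(value))
  known <- c("hartree", "kJ/mol", "kcal/mol")
  if (!(is.character(to) && length(to) == 1L && to %in% known))
    stop("unknown energy unit: ", paste(to, collapse = ", "))
  fac <- c("hartree" = HARTREE_KJMOL, "kJ/mol" = 1, "kcal/mol" = 4.184)
  unname(value / fac[to])
}

# CODATA 2018
HARTREE_KJMOL <- 2625.4996394799
# molar gas constant, J mol^-1 K^-1 (exact, SI 2019)
GAS_CONSTANT <- 8.314462618
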