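#' Physical constants registry
#'
#' Single source of the physical constants and unit-conversion factors used
#' throughout the package. Energies are carried internally in kcal/mol; the
#' conversion factors here are the 2018 CODATA values.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_to_kcal}{627.509474 kcal/mol per hartree}
#'   \item{ev_to_kcal}{23.060547830619026 kcal/mol per eV}
#'   \item{kj_to_kcal}{1/4.184 kcal per kJ (thermochemical calorie)}
#'   \item{k_boltzmann}{Boltzmann constant, 1.380649e-23 J/K}
#'   \item{h_planck}{Planck constant, 6.62607015e-34 J s}
#'   \item{r_gas_kcal}{molar gas constant, 1.98720425e-3 kcal/(mol K)}
#'   \item{t_default}{default thermodynamic temperature, 298.15 K}
#'   \item{wigner_coeff_printed}{1.44, the literal coefficient of the Wigner
#'     tunneling expression as commonly printed}
#'   \item{wigner_coeff_physical}{hc/k_B = 1.4387768775 cm K, the physical
#'     second radiation constant}
#'   \item{std_state_printed}{24.3, the 1 atm -> 1 M standard-state factor as
#'     commonly printed}
#'   \item{std_state_physical}{24.465, the ideal-gas molar volume in L/mol at
#'     298.15 K and 1 atm}
#' }
#' @export
kyn_constants <- list(
  hartree_to_kcal = 627.509474,
  ev_to_kcal      = 23.060547830619026,
  kj_to_kcal      = 1 / 4.184,
  k_boltzmann     = 1.380649e-23,
  h_planck        = 6.62607015e-34,
  r_gas_kcal      = 1.98720425e-3,
  t_default       = 298.15,
  wigner_coeff_printed  = 1.44,
  wigner_coeff_physical = 1.4387768775,
  std_state_printed     = 24.3,
  std_state_physical    = 24.465
)

#' Supported energy units
#' @keywords internal
.energy_units <- c("hartree", "kcal_per_mol", "kJ_per_mol", "eV")

# factors to kcal/mol
.unit_to_kcal <- c(
  hartree      = 627.509474,
  kcal_per_mol = 1,
  kJ_per_mol   = 1 / 4.184,
  eV           = 23.060547830619026
)

#' Convert an energy value between units
#'
#' Exact linear conversion between hartree, kcal/mol, kJ/mol and eV.
#' Round trips satisfy `convert_energy(convert_energy(x, a, b), b, a) == x`
#' to better than 1e-12 relative.
#'
#' @param value numeric vector of energies.
#' @param from_unit,to_unit one of `"hartree"`, `"kcal_per_mol"`,
#'   `"kJ_per_mol"`, `"eV"`.
#' @return numeric vector in `to_unit`.
#' @examples
#' convert_energy(1, "hartree", "kcal_per_mol")  # 627.509474
#' @export
convert_energy <- function(value, from_unit, to_unit) {
  from_unit <- match_unit(from_unit)
  to_unit <- match_unit(to_unit)
  if (from_unit == to_unit) {
    return(value)
  }
  value * .unit_to_kcal[[from_unit]] / .unit_to_kcal[[to_unit]]
}

match_unit <- function(unit) {
  if (length(unit) != 1L || !is.character(unit) || !(unit %in% .energy_units)) {
    stop("unknown energy unit: ", paste(unit, collapse = ", "),
         " (expected one of ", paste(.energy_units, collapse = ", "), ")",
         call. = FALSE)
  }
  unit
}
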