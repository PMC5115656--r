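# Reaction energetics and conventional TST rate constants with Wigner
# tunneling for hydrogen transfer from an antioxidant O-H group to a free
# radical's O atom.

#' Activation energetics of a hydrogen-transfer step
#'
#' From the reagent complex and the transition structure:
#' `dE_TS-R = E_TS - E_R` (electronic), `dG_TS-R = G_TS - G_R` (the
#' difference of thermal free-energy corrections at 298.15 K), and the
#' corrected barrier `dE_TS-R/COR = dE_TS-R + dG_TS-R` that enters the
#' rate expression.
#'
#' @param reagents,ts `species_record`s with `energy` and `g_corr`, sharing
#'   level and phase.
#' @return list with `de_ts_r`, `dg_ts_r`, `de_ts_r_cor` (kcal/mol).
#' @export
activation_energy <- function(reagents, ts) {
  check_same_level_phase(reagents, ts)
  for (r in list(reagents, ts)) {
    if (is.null(r$g_corr)) {
      stop("record '", r$label, "' lacks g_corr (thermal free-energy correction)",
           call. = FALSE)
    }
  }
  de <- ts$energy - reagents$energy
  dg <- ts$g_corr - reagents$g_corr
  list(de_ts_r = de, dg_ts_r = dg, de_ts_r_cor = de + dg)
}

#' Reaction energetics of a hydrogen-transfer step
#'
#' `dE_P-R = E_P - E_R`, the corresponding free-energy-correction
#' difference `dG_P-R`, their sum `dE_P-R/COR`, and (when the transition
#' structure is supplied) the reverse barrier `dE_TS-P = E_TS - E_P`.
#'
#' @param reagents,products `species_record`s sharing level and phase.
#' @param ts optional transition-structure `species_record`.
#' @return list with `de_p_r`, `dg_p_r`, `de_p_r_cor`, `de_ts_p`
#'   (kcal/mol; `NULL` where ingredients are absent).
#' @export
reaction_energy <- function(reagents, products, ts = NULL) {
  check_same_level_phase(reagents, products)
  de <- products$energy - reagents$energy
  dg <- if (!is.null(reagents$g_corr) && !is.null(products$g_corr)) {
    products$g_corr - reagents$g_corr
  } else NULL
  list(
    de_p_r = de,
    dg_p_r = dg,
    de_p_r_cor = if (is.null(dg)) NULL else de + dg,
    de_ts_p = if (is.null(ts)) NULL else ts$energy - products$energy
  )
}

#' Wigner tunneling factor
#'
#' `A(T) = 1 + (1/24) * (coeff * nu_i / T)^2`, the leading-order quantum
#' tunneling correction built from the transition structure's imaginary
#' frequency. The default coefficient is the literal 1.44 of the printed
#' expression; the physical value hc/k_B = 1.4387768775 cm K is available
#' via `coeff = kyn_constants$wigner_coeff_physical`.
#'
#' @param nu_imag imaginary-frequency magnitude, cm^-1 (>= 0).
#' @param temperature K (> 0).
#' @param coeff coefficient in cm K (default 1.44).
#' @return dimensionless factor >= 1.
#' @export
wigner_factor <- function(nu_imag, temperature = kyn_constants$t_default,
                          coeff = kyn_constants$wigner_coeff_printed) {
  if (any(nu_imag < 0)) stop("nu_imag must be >= 0", call. = FALSE)
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  1 + (1 / 24) * (coeff * nu_imag / temperature)^2
}

#' TST rate constant with Wigner tunneling
#'
#' Conventional transition-state theory for a bimolecular hydrogen
#' transfer:
#' `k(T) = I * (k_B T / h) * exp(-dE_cor / (R T)) * std_state_factor * A(T)`
#' with `A(T)` the Wigner factor. The standard-state factor (default 24.3)
#' converts from the 1 atm to the 1 M reference state; the ideal-gas molar
#' volume at 298.15 K (24.465 L/mol) is available via
#' `kyn_constants$std_state_physical`.
#'
#' @param de_cor corrected activation energy `dE_TS-R/COR`, kcal/mol.
#' @param nu_imag imaginary-frequency magnitude, cm^-1.
#' @param temperature K.
#' @param degeneracy reaction pathway degeneracy I (>= 1).
#' @param std_state_factor 1 atm -> 1 M conversion multiplier.
#' @param wigner_coeff coefficient passed to [wigner_factor()].
#' @return list of class `rate_result` with `rate` (M^-1 s^-1),
#'   `tunneling_factor`, `temperature`, `degeneracy`, `std_state_factor`.
#' @export
rate_constant <- function(de_cor, nu_imag,
                          temperature = kyn_constants$t_default,
                          degeneracy = 1L,
                          std_state_factor = kyn_constants$std_state_printed,
                          wigner_coeff = kyn_constants$wigner_coeff_printed) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  if (degeneracy < 1) stop("degeneracy must be >= 1", call. = FALSE)
  if (nu_imag < 0) stop("nu_imag must be >= 0", call. = FALSE)
  a_t <- wigner_factor(nu_imag, temperature, coeff = wigner_coeff)
  prefactor <- kyn_constants$k_boltzmann * temperature / kyn_constants$h_planck
  boltz <- exp(-de_cor / (kyn_constants$r_gas_kcal * temperature))
  rate <- degeneracy * prefactor * boltz * std_state_factor * a_t
  structure(list(rate = rate, tunneling_factor = a_t,
                 temperature = temperature, degeneracy = as.integer(degeneracy),
                 std_state_factor = std_state_factor),
            class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("<rate_result> k(%.2f K) = %.4g M^-1 s^-1  [A(T) = %.4f, I = %d, f_std = %.3f]\n",
              x$temperature, x$rate, x$tunneling_factor, x$degeneracy,
              x$std_state_factor))
  invisible(x)
}

#' Rate constant of a reaction system
#'
#' Convenience wrapper assembling the corrected barrier from the system's
#' reagent and transition-structure records and evaluating
#' [rate_constant()]. Following the hybrid recipe used for refined single
#' points, `dG_TS-R` and the imaginary frequency may be carried over from
#' a lower level of theory than the electronic energies: pass `dg_override`
#' and/or `nu_override` and the result is annotated with a provenance note.
#'
#' @param system a `reaction_system`.
#' @param temperature K.
#' @param dg_override optional `dG_TS-R` (kcal/mol) from another level.
#' @param nu_override optional imaginary frequency (cm^-1) from another
#'   level.
#' @param ... passed to [rate_constant()].
#' @return a `rate_result` with additional elements `de_ts_r_cor` and
#'   `provenance`.
#' @export
system_rate <- function(system, temperature = kyn_constants$t_default,
                        dg_override = NULL, nu_override = NULL, ...) {
  de <- system$ts$energy - system$reagents$energy
  dg <- if (!is.null(dg_override)) dg_override else
    activation_energy(system$reagents, system$ts)$dg_ts_r
  nu <- if (!is.null(nu_override)) nu_override else system$ts$nu_imag
  res <- rate_constant(de + dg, nu, temperature,
                       degeneracy = system$degeneracy, ...)
  res$de_ts_r_cor <- de + dg
  res$provenance <- if (!is.null(dg_override) || !is.null(nu_override)) {
    "dG_TS-R and/or nu_i carried over from another level of theory"
  } else "all ingredients from the system's own records"
  res
}

#' Enthalpy of radical addition to an antioxidant radical
#'
#' Energetics of a peroxyl radical adding to the aromatic ring of an
#' antioxidant radical (para to the O* atom): `dE_P-R` between the adduct
#' and the separated-pair (or pre-complex) reference, plus the corrected
#' value when free-energy corrections are available.
#'
#' @param pair `species_record` for the separated antioxidant-radical +
#'   radical reference.
#' @param adduct `species_record` for the addition product.
#' @param g_available if `TRUE`, require `g_corr` on both and return the
#'   corrected value.
#' @return list with `de_p_r` and `de_p_r_cor` (the latter `NULL` when not
#'   requested).
#' @export
radical_addition_energy <- function(pair, adduct, g_available = FALSE) {
  check_same_level_phase(pair, adduct)
  de <- adduct$energy - pair$energy
  cor <- NULL
  if (g_available) {
    if (is.null(pair$g_corr) || is.null(adduct$g_corr)) {
      stop("free-energy corrections requested but absent on '",
           if (is.null(pair$g_corr)) pair$label else adduct$label, "'",
           call. = FALSE)
    }
    cor <- de + (adduct$g_corr - pair$g_corr)
  }
  list(de_p_r = de, de_p_r_cor = cor)
}
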