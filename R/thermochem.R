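# Antioxidant descriptors: BDE, IP, frontier orbitals, spin and charge
# descriptors of the hydrogen-donation (HAT/PCET) machinery.

check_same_level_phase <- function(...) {
  recs <- list(...)
  lv <- unique(vapply(recs, `[[`, character(1), "level"))
  ph <- unique(vapply(recs, `[[`, character(1), "phase"))
  if (length(lv) != 1L || length(ph) != 1L) {
    stop("records must share level and phase (got levels ",
         paste(lv, collapse = "/"), ", phases ", paste(ph, collapse = "/"), ")",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Homolytic bond dissociation enthalpy
#'
#' `BDE = E_RAD + E_H - E_W`: the electronic energy cost of splitting an
#' X-H bond of the whole molecule (`whole`) into its radical (`radical`)
#' and a free hydrogen atom (`h_atom`). All inputs must share level and
#' phase.
#'
#' @param whole,radical,h_atom `species_record`s.
#' @return BDE in kcal/mol.
#' @export
bde <- function(whole, radical, h_atom) {
  check_same_level_phase(whole, radical, h_atom)
  radical$energy + h_atom$energy - whole$energy
}

#' Thermal correction to the bond dissociation enthalpy
#'
#' `H_T = H_RAD + H_H - H_W`, the difference of thermal enthalpy
#' corrections (298.15 K, unscaled frequencies) between the fragments and
#' the whole molecule.
#'
#' @inheritParams bde
#' @return H_T in kcal/mol.
#' @export
thermal_correction <- function(whole, radical, h_atom) {
  for (r in list(whole, radical, h_atom)) {
    if (is.null(r$h_corr)) {
      stop("record '", r$label, "' lacks h_corr (thermal enthalpy correction)",
           call. = FALSE)
    }
  }
  radical$h_corr + h_atom$h_corr - whole$h_corr
}

#' Thermally corrected bond dissociation enthalpy
#'
#' `BDE_COR = BDE + H_T`.
#'
#' @param bde_value electronic BDE, kcal/mol.
#' @param h_t thermal correction from [thermal_correction()], kcal/mol.
#' @return BDE_COR in kcal/mol.
#' @export
bde_cor <- function(bde_value, h_t) {
  bde_value + h_t
}

#' Adiabatic ionization potential
#'
#' `IP = E_CAT - E_W`, the energy of the relaxed one-electron-abstracted
#' species minus the parent. For parents with an ionized carboxylic group
#' the electron-abstracted form is the neutral molecule; the operation
#' therefore keys on the charge difference (+1), not on absolute charge.
#'
#' @param neutral_or_parent parent `species_record`.
#' @param electron_abstracted `species_record` with charge `parent + 1`.
#' @return IP in kcal/mol.
#' @export
ip <- function(neutral_or_parent, electron_abstracted) {
  check_same_level_phase(neutral_or_parent, electron_abstracted)
  if (electron_abstracted$charge - neutral_or_parent$charge != 1L) {
    stop("electron-abstracted record must have charge = parent + 1 (got ",
         neutral_or_parent$charge, " -> ", electron_abstracted$charge, ")",
         call. = FALSE)
  }
  electron_abstracted$energy - neutral_or_parent$energy
}

#' Frontier-orbital gap
#'
#' `H-L gap = E_HOMO - E_LUMO`; negative for every compound studied here
#' (the HOMO lies below the LUMO).
#'
#' @param species `species_record` with both orbital energies.
#' @return gap in kcal/mol.
#' @export
homo_lumo_gap <- function(species) {
  if (is.null(species$e_homo) || is.null(species$e_lumo)) {
    stop("record '", species$label, "' lacks an orbital energy", call. = FALSE)
  }
  species$e_homo - species$e_lumo
}

#' Deviation from the Koopmans limit
#'
#' `IP - (-E_HOMO)`: zero when Koopmans' theorem holds exactly. B3LYP
#' systematically underestimates |E_HOMO|, giving positive values of
#' roughly 37 kcal/mol in the gas phase for this compound set.
#'
#' @param ip_value adiabatic IP, kcal/mol.
#' @param e_homo HOMO energy, kcal/mol.
#' @return kcal/mol.
#' @export
koopmans_delta <- function(ip_value, e_homo) {
  ip_value + e_homo
}

#' Spin delocalization of a radical
#'
#' The dispersion of per-atom Mulliken spin densities is used as an
#' estimator of electron delocalization: evenly spread spin (low standard
#' deviation) marks a stabilized radical and hence a weaker parent X-H
#' bond. The default is the population convention over all atoms, treating
#' the radical's atom set as the complete population rather than a sample.
#'
#' @param radical `species_record` with per-atom `mulliken_spin`.
#' @param named_atoms named integer vector mapping roles (e.g. `"O*"`,
#'   `"C_PARA"`) to atom indices; their spin densities are reported
#'   individually.
#' @param convention `"population"` (divide by N) or `"sample"` (divide by
#'   N-1).
#' @param heavy_only if `TRUE`, hydrogens are excluded from the dispersion.
#' @return list with `delta_sd` (the dispersion) and `sd_by_role` (named
#'   spin densities).
#' @export
spin_delocalization <- function(radical, named_atoms = integer(),
                                convention = c("population", "sample"),
                                heavy_only = FALSE) {
  convention <- match.arg(convention)
  at <- radical$atoms
  if (is.null(at)) stop("record '", radical$label, "' has no atoms", call. = FALSE)
  if (any(is.na(at$mulliken_spin))) {
    stop("record '", radical$label, "' lacks Mulliken spin density on some atoms",
         call. = FALSE)
  }
  if (length(named_atoms) > 0 &&
      (any(named_atoms < 1L) || any(named_atoms > nrow(at)))) {
    stop("atom index out of range in named_atoms", call. = FALSE)
  }
  spins <- at$mulliken_spin
  pool <- if (heavy_only) spins[at$element != "H"] else spins
  n <- length(pool)
  delta_sd <- if (convention == "population") {
    sqrt(sum((pool - mean(pool))^2) / n)
  } else {
    stats::sd(pool)
  }
  list(delta_sd = delta_sd,
       sd_by_role = setNames(spins[named_atoms], names(named_atoms)))
}

#' PCET charge descriptors of a hydrogen-transfer transition structure
#'
#' Mulliken-charge descriptors distinguishing proton-coupled electron
#' transfer from plain hydrogen-atom transfer: the charge on the
#' transferred H in the transition structure, its change relative to the
#' reagent complex, and the oxygen charge displacement
#' `dQ(O) = Q(O2) - Q(O1)` for a phenoxyl acceptor or
#' `Q(O2) + Q(O3) - Q(O1)` for a methyl-peroxy acceptor (O1 the donor
#' oxygen of the antioxidant, O2/O3 the acceptor oxygens), together with
#' its TS-minus-reagent difference.
#'
#' @param system a `reaction_system`.
#' @param atom_map named list with elements `reagents` and `ts`, each a
#'   named integer vector with roles `H`, `O1`, `O2` (and `O3` for a
#'   methyl-peroxy radical).
#' @return list with `q_h`, `delta_q_h`, `dq_o`, `delta_dq_ts_r` (all in e).
#' @export
charge_descriptors <- function(system, atom_map) {
  need <- c("H", "O1", "O2", if (system$radical == "methyl_peroxy") "O3")
  q_of <- function(rec, map, role) {
    if (!(role %in% names(map))) {
      stop("atom_map for '", rec$label, "' lacks role '", role,
           "' required for a ", system$radical, " radical", call. = FALSE)
    }
    idx <- map[[role]]
    at <- rec$atoms
    if (is.null(at) || idx < 1L || idx > nrow(at)) {
      stop("atom index out of range for role '", role, "' in '", rec$label, "'",
           call. = FALSE)
    }
    q <- at$mulliken_charge[idx]
    if (is.na(q)) stop("missing Mulliken charge for role '", role, "' in '",
                       rec$label, "'", call. = FALSE)
    q
  }
  dq_o <- function(rec, map) {
    if (system$radical == "methyl_peroxy") {
      q_of(rec, map, "O2") + q_of(rec, map, "O3") - q_of(rec, map, "O1")
    } else {
      q_of(rec, map, "O2") - q_of(rec, map, "O1")
    }
  }
  for (role in need) {
    q_of(system$ts, atom_map$ts, role)
    q_of(system$reagents, atom_map$reagents, role)
  }
  q_h_ts <- q_of(system$ts, atom_map$ts, "H")
  q_h_r <- q_of(system$reagents, atom_map$reagents, "H")
  dq_ts <- dq_o(system$ts, atom_map$ts)
  dq_r <- dq_o(system$reagents, atom_map$reagents)
  list(q_h = q_h_ts, delta_q_h = q_h_ts - q_h_r,
       dq_o = dq_ts, delta_dq_ts_r = dq_ts - dq_r)
}

#' Assemble a descriptor table from species records
#'
#' Looks up, for each recipe entry, the whole molecule, its H-abstracted
#' radical, and its electron-abstracted form among `records` (all at one
#' level/phase) and computes every descriptor whose ingredients are
#' present: BDE, H_T, BDE_COR, IP, E_HOMO, E_LUMO, H-L gap, and the
#' Koopmans deviation. Absent ingredients yield `NA` fields, never zeros.
#'
#' @param records list of `species_record`s.
#' @param recipe data frame with columns `compound`, `whole`, `radical`,
#'   `cation` (label strings; `NA` allowed for radical/cation), and
#'   optionally `h_atom` (defaults to the label `"H_atom"`).
#' @return data frame with one row per recipe entry.
#' @export
build_descriptor_table <- function(records, recipe) {
  labels <- vapply(records, `[[`, character(1), "label")
  find <- function(lab) {
    if (is.null(lab) || is.na(lab)) return(NULL)
    hit <- which(labels == lab)
    if (length(hit) == 0) return(NULL)
    if (length(hit) > 1) {
      stop("ambiguous label '", lab, "': ", length(hit), " records match",
           call. = FALSE)
    }
    records[[hit]]
  }
  if (nrow(recipe) == 0) {
    return(data.frame(compound = character(), level = character(),
                      phase = character(), bde = numeric(), h_t = numeric(),
                      bde_cor = numeric(), ip = numeric(), e_homo = numeric(),
                      e_lumo = numeric(), hl_gap = numeric(),
                      koopmans_delta = numeric(), stringsAsFactors = FALSE))
  }
  if (is.null(recipe$h_atom)) recipe$h_atom <- "H_atom"
  rows <- lapply(seq_len(nrow(recipe)), function(i) {
    w <- find(recipe$whole[i])
    r <- find(recipe$radical[i])
    cat_ <- find(recipe$cation[i])
    h <- find(recipe$h_atom[i])
    if (is.null(w)) stop("recipe row ", i, ": whole-molecule label '",
                         recipe$whole[i], "' not found", call. = FALSE)
    bde_v <- if (!is.null(r) && !is.null(h)) bde(w, r, h) else NA_real_
    h_t <- if (!is.null(r) && !is.null(h) &&
               !is.null(w$h_corr) && !is.null(r$h_corr) && !is.null(h$h_corr)) {
      thermal_correction(w, r, h)
    } else NA_real_
    ip_v <- if (!is.null(cat_)) ip(w, cat_) else NA_real_
    e_homo <- if (is.null(w$e_homo)) NA_real_ else w$e_homo
    e_lumo <- if (is.null(w$e_lumo)) NA_real_ else w$e_lumo
    gap <- if (!is.na(e_homo) && !is.na(e_lumo)) homo_lumo_gap(w) else NA_real_
    data.frame(
      compound = recipe$compound[i], level = w$level, phase = w$phase,
      bde = bde_v, h_t = h_t, bde_cor = bde_v + h_t,
      ip = ip_v, e_homo = e_homo, e_lumo = e_lumo, hl_gap = gap,
      koopmans_delta = if (!is.na(ip_v) && !is.na(e_homo))
        koopmans_delta(ip_v, e_homo) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
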