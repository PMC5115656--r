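#' @importFrom stats sd setNames splinefun optimize cor pt rnorm runif
#' @importFrom utils read.csv write.csv head
NULL

# element symbol -> nuclear charge, H..Kr (ample for organic antioxidants)
.element_z <- c(
  H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8, F = 9, Ne = 10,
  Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16, Cl = 17, Ar = 18,
  K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24, Mn = 25, Fe = 26,
  Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32, As = 33, Se = 34,
  Br = 35, Kr = 36
)

.phase_vocab <- c("gas", "water")
.level_vocab <- c("I", "II", "III", "III_LC_BLYP", "IV", "V")

#' Create a table of atom records
#'
#' Atoms are represented as a data frame with one row per atom. Optional
#' Mulliken columns are `NA` when absent.
#'
#' @param element character vector of element symbols.
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param nuclear_charge integer nuclear charges; derived from `element`
#'   when omitted.
#' @param mulliken_charge,mulliken_spin optional per-atom Mulliken partial
#'   charge and spin density (e).
#' @return data frame of class `kyn_atoms`.
#' @export
atom_table <- function(element, x, y, z, nuclear_charge = NULL,
                       mulliken_charge = NULL, mulliken_spin = NULL) {
  n <- length(element)
  if (length(x) == 1L) x <- rep(x, n)
  if (length(y) == 1L) y <- rep(y, n)
  if (length(z) == 1L) z <- rep(z, n)
  stopifnot(length(x) == n, length(y) == n, length(z) == n)
  unknown <- setdiff(unique(element), names(.element_z))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  z_expected <- unname(.element_z[element])
  if (is.null(nuclear_charge)) {
    nuclear_charge <- z_expected
  } else {
    bad <- which(as.integer(round(nuclear_charge)) != z_expected)
    if (length(bad) > 0) {
      stop("nuclear charge does not match element symbol at atom(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))) {
    stop("atom coordinates must be finite", call. = FALSE)
  }
  df <- data.frame(
    element = element,
    nuclear_charge = as.integer(round(nuclear_charge)),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    mulliken_charge = if (is.null(mulliken_charge)) NA_real_ else as.numeric(mulliken_charge),
    mulliken_spin = if (is.null(mulliken_spin)) NA_real_ else as.numeric(mulliken_spin),
    stringsAsFactors = FALSE
  )
  class(df) <- c("kyn_atoms", "data.frame")
  df
}

#' Create a species record
#'
#' One chemical species at one level of theory and phase: the unit of input
#' for every thermochemical and kinetic computation in the package. All
#' energy-like fields are in kcal/mol; `nu_imag` is the magnitude of the
#' imaginary frequency in cm^-1 (transition structures only). Optional fields
#' left `NULL` are treated as absent, never as zero.
#'
#' @param label unique species label, e.g. `"3HAA"` or `"3HAA_rad"`.
#' @param energy total electronic (or electronic-plus-solvation) energy,
#'   kcal/mol.
#' @param charge total charge (integer).
#' @param multiplicity spin multiplicity (positive integer).
#' @param level level-of-theory tag, one of `r paste(.level_vocab, collapse = ", ")`.
#' @param phase `"gas"` or `"water"`.
#' @param h_corr,g_corr thermal corrections to enthalpy / free energy at
#'   298.15 K, kcal/mol.
#' @param e_homo,e_lumo frontier-orbital energies, kcal/mol.
#' @param nu_imag imaginary-frequency magnitude, cm^-1.
#' @param atoms optional `kyn_atoms` table (see [atom_table()]).
#' @param extra named list of unknown fields preserved verbatim by the
#'   readers and writers.
#' @return object of class `species_record`.
#' @export
species_record <- function(label, energy, charge = 0L, multiplicity = 1L,
                           level = "II", phase = "gas",
                           h_corr = NULL, g_corr = NULL,
                           e_homo = NULL, e_lumo = NULL,
                           nu_imag = NULL, atoms = NULL, extra = list()) {
  rec <- structure(list(
    label = label, charge = as.integer(charge),
    multiplicity = as.integer(multiplicity),
    level = level, phase = phase, energy = as.numeric(energy),
    h_corr = h_corr, g_corr = g_corr,
    e_homo = e_homo, e_lumo = e_lumo,
    nu_imag = nu_imag, atoms = atoms, extra = extra
  ), class = "species_record")
  validate_species_record(rec)
  rec
}

#' Validate a species record
#'
#' Checks the structural invariants: vocabulary membership of level and
#' phase tags, positive multiplicity, finite energies, positive stored
#' imaginary-frequency magnitude, zero Mulliken spin for singlets, and
#' element/nuclear-charge consistency of the atom table.
#'
#' @param rec a `species_record`.
#' @return `rec`, invisibly; raises an error naming the record and field on
#'   violation.
#' @export
validate_species_record <- function(rec) {
  fail <- function(field, msg) {
    stop(sprintf("species record '%s', field '%s': %s", rec$label, field, msg),
         call. = FALSE)
  }
  if (!is.character(rec$label) || length(rec$label) != 1L || !nzchar(rec$label)) {
    stop("species record must have a non-empty label", call. = FALSE)
  }
  if (!(rec$phase %in% .phase_vocab)) {
    fail("phase", paste0("'", rec$phase, "' not in {", paste(.phase_vocab, collapse = ", "), "}"))
  }
  if (!(rec$level %in% .level_vocab)) {
    fail("level", paste0("'", rec$level, "' not in {", paste(.level_vocab, collapse = ", "), "}"))
  }
  if (is.na(rec$multiplicity) || rec$multiplicity < 1L) {
    fail("multiplicity", "must be a positive integer")
  }
  if (!is.finite(rec$energy)) fail("energy", "must be finite")
  for (f in c("h_corr", "g_corr", "e_homo", "e_lumo")) {
    v <- rec[[f]]
    if (!is.null(v) && (length(v) != 1L || !is.finite(v))) {
      fail(f, "must be a finite scalar when present")
    }
  }
  if (!is.null(rec$nu_imag)) {
    if (!is.finite(rec$nu_imag) || rec$nu_imag <= 0) {
      fail("nu_imag", "stored as a magnitude, must be > 0 when present")
    }
  }
  if (!is.null(rec$atoms)) {
    at <- rec$atoms
    if (!is.data.frame(at)) fail("atoms", "must be an atom table")
    z_expected <- unname(.element_z[at$element])
    if (anyNA(z_expected)) fail("atoms", "unknown element symbol")
    if (any(at$nuclear_charge != z_expected)) {
      fail("atoms", "nuclear charge inconsistent with element symbol")
    }
    if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z))) {
      fail("atoms", "coordinates must be finite")
    }
    if (rec$multiplicity == 1L && any(!is.na(at$mulliken_spin)) &&
        any(abs(at$mulliken_spin[!is.na(at$mulliken_spin)]) > 1e-6)) {
      fail("atoms", "singlet species must have zero Mulliken spin density")
    }
  }
  invisible(rec)
}

#' Bundle reagent, transition structure and product into a reaction system
#'
#' @param name system name, e.g. `"3HAA--PhO"`.
#' @param reagents,ts,products `species_record`s sharing level and phase;
#'   `ts` must carry an imaginary frequency.
#' @param radical `"phenoxyl"`, `"methyl_peroxy"` or `"other"`; selects the
#'   oxygen charge-displacement formula in [charge_descriptors()].
#' @param degeneracy reaction pathway degeneracy (1 for all systems studied
#'   here).
#' @return object of class `reaction_system`.
#' @export
reaction_system <- function(name, reagents, ts, products,
                            radical = c("phenoxyl", "methyl_peroxy", "other"),
                            degeneracy = 1L) {
  radical <- match.arg(radical)
  for (r in list(reagents, ts, products)) validate_species_record(r)
  if (is.null(ts$nu_imag)) {
    stop("transition structure '", ts$label, "' must carry an imaginary frequency",
         call. = FALSE)
  }
  lv <- unique(c(reagents$level, ts$level, products$level))
  ph <- unique(c(reagents$phase, ts$phase, products$phase))
  if (length(lv) != 1L || length(ph) != 1L) {
    stop("reagents, ts and products must share level and phase tags", call. = FALSE)
  }
  if (degeneracy < 1L) stop("degeneracy must be a positive integer", call. = FALSE)
  structure(list(name = name, radical = radical, reagents = reagents,
                 ts = ts, products = products,
                 degeneracy = as.integer(degeneracy)),
            class = "reaction_system")
}

# ---- serialization ---------------------------------------------------------

.scalar_fields <- c("label", "charge", "multiplicity", "level", "phase",
                    "energy", "h_corr", "g_corr", "e_homo", "e_lumo", "nu_imag")
.energy_fields <- c("energy", "h_corr", "g_corr", "e_homo", "e_lumo")

record_to_plain <- function(rec) {
  out <- list()
  for (f in .scalar_fields) if (!is.null(rec[[f]])) out[[f]] <- rec[[f]]
  if (!is.null(rec$atoms)) {
    at <- as.data.frame(rec$atoms)
    keep <- c("element", "nuclear_charge", "x", "y", "z")
    if (any(!is.na(at$mulliken_charge))) keep <- c(keep, "mulliken_charge")
    if (any(!is.na(at$mulliken_spin))) keep <- c(keep, "mulliken_spin")
    out$atoms <- at[, keep, drop = FALSE]
  }
  if (length(rec$extra) > 0) out <- c(out, rec$extra)
  out
}

plain_to_record <- function(obj, default_unit = "kcal_per_mol") {
  lab <- if (is.null(obj$label)) "<unnamed>" else obj$label
  unit <- if (is.null(obj$energy_unit)) default_unit else obj$energy_unit
  if (!(unit %in% .energy_units)) {
    stop("species record '", lab, "': unknown unit tag '", unit, "'", call. = FALSE)
  }
  num <- function(field, required = FALSE) {
    v <- obj[[field]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      if (required) stop("species record '", lab, "': malformed or missing field '",
                         field, "'", call. = FALSE)
      return(NULL)
    }
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 1L || is.na(v)) {
      stop("species record '", lab, "': malformed field '", field, "'", call. = FALSE)
    }
    v
  }
  energies <- lapply(setNames(.energy_fields, .energy_fields), function(f) {
    v <- num(f, required = (f == "energy"))
    if (is.null(v)) NULL else convert_energy(v, unit, "kcal_per_mol")
  })
  atoms <- NULL
  if (!is.null(obj$atoms)) {
    at <- as.data.frame(obj$atoms)
    atoms <- atom_table(
      element = as.character(at$element),
      x = at$x, y = at$y, z = at$z,
      nuclear_charge = if ("nuclear_charge" %in% names(at)) at$nuclear_charge else NULL,
      mulliken_charge = if ("mulliken_charge" %in% names(at)) at$mulliken_charge else NULL,
      mulliken_spin = if ("mulliken_spin" %in% names(at)) at$mulliken_spin else NULL
    )
  }
  known <- c(.scalar_fields, "atoms", "energy_unit")
  extra <- obj[setdiff(names(obj), known)]
  species_record(
    label = lab, energy = energies$energy,
    charge = if (is.null(num("charge"))) 0L else num("charge"),
    multiplicity = if (is.null(num("multiplicity"))) 1L else num("multiplicity"),
    level = if (is.null(obj$level)) "II" else obj$level,
    phase = if (is.null(obj$phase)) "gas" else obj$phase,
    h_corr = energies$h_corr, g_corr = energies$g_corr,
    e_homo = energies$e_homo, e_lumo = energies$e_lumo,
    nu_imag = num("nu_imag"), atoms = atoms, extra = extra
  )
}

#' Read species records from JSON or CSV
#'
#' The JSON document is a list of species objects; the CSV carries scalar
#' fields only (one row per species, mandatory header). A per-record
#' `energy_unit` tag (`hartree`, `kcal_per_mol`, `kJ_per_mol`, `eV`) is
#' honoured and all energy-like fields are converted to kcal/mol on read.
#' Unknown fields are preserved in the record's `extra` list.
#'
#' @param source file path.
#' @param format `"json"` or `"csv"`; inferred from the extension when
#'   omitted.
#' @return list of `species_record`s.
#' @export
read_species_records <- function(source, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") {
    doc <- jsonlite::read_json(source, simplifyVector = FALSE)
    objs <- lapply(doc, function(o) {
      if (!is.null(o$atoms)) {
        o$atoms <- do.call(rbind, lapply(o$atoms, function(a) as.data.frame(a)))
      }
      o
    })
  } else {
    df <- read.csv(source, stringsAsFactors = FALSE)
    objs <- lapply(seq_len(nrow(df)), function(i) {
      row <- as.list(df[i, , drop = FALSE])
      row[vapply(row, function(v) is.na(v) || identical(v, ""), logical(1))] <- NULL
      row
    })
  }
  lapply(objs, plain_to_record)
}

#' Write species records to JSON or CSV
#'
#' Inverse of [read_species_records()]: `read(write(x))` is field-for-field
#' identity on all defined fields. Energies are written in kcal/mol at full
#' precision. The CSV format carries scalar fields only; writing a record
#' with atoms to CSV is an error.
#'
#' @param records list of `species_record`s.
#' @param sink file path.
#' @param format `"json"` or `"csv"`.
#' @return `sink`, invisibly.
#' @export
write_species_records <- function(records, sink, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", sink, ignore.case = TRUE)) "csv" else "json"
  }
  for (r in records) validate_species_record(r)
  if (format == "json") {
    jsonlite::write_json(lapply(records, record_to_plain), sink,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    if (any(vapply(records, function(r) !is.null(r$atoms), logical(1)))) {
      stop("CSV format carries scalar fields only; use JSON for records with atoms",
           call. = FALSE)
    }
    rows <- lapply(records, function(r) {
      vals <- lapply(setNames(.scalar_fields, .scalar_fields),
                     function(f) if (is.null(r[[f]])) NA else r[[f]])
      as.data.frame(vals, stringsAsFactors = FALSE)
    })
    write.csv(do.call(rbind, rows), sink, row.names = FALSE, na = "")
  }
  invisible(sink)
}

#' Read an XYZ-style coordinate block
#'
#' Each non-blank line is `symbol  nuclear_charge  x  y  z` (whitespace
#' separated, coordinates in Angstrom), the layout of plain-text optimized
#' structure dumps. Lines are validated against the element table.
#'
#' @param source file path, or a character vector of lines.
#' @return a `kyn_atoms` table in file order.
#' @export
read_xyz_block <- function(source) {
  lines <- if (length(source) == 1L && file.exists(source)) readLines(source) else source
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) stop("empty coordinate block", call. = FALSE)
  parsed <- lapply(keep, function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:],]+")[[1]]
    if (length(tok) != 5L) {
      stop("line ", i, ": expected 'symbol charge x y z', got ", length(tok),
           " fields", call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(tok[2:5]))
    if (anyNA(num)) stop("line ", i, ": non-numeric field", call. = FALSE)
    sym <- tok[1]
    if (!(sym %in% names(.element_z))) {
      stop("line ", i, ": unknown element symbol '", sym, "'", call. = FALSE)
    }
    if (as.integer(round(num[1])) != .element_z[[sym]]) {
      stop("line ", i, ": nuclear charge ", num[1],
           " does not match element '", sym, "'", call. = FALSE)
    }
    list(sym = sym, z = num[1], xyz = num[2:4])
  })
  atom_table(
    element = vapply(parsed, `[[`, character(1), "sym"),
    x = vapply(parsed, function(p) p$xyz[1], numeric(1)),
    y = vapply(parsed, function(p) p$xyz[2], numeric(1)),
    z = vapply(parsed, function(p) p$xyz[3], numeric(1))
  )
}

#' @export
print.species_record <- function(x, ...) {
  cat(sprintf("<species_record> %s  [level %s, %s, q=%+d, mult=%d]\n",
              x$label, x$level, x$phase, x$charge, x$multiplicity))
  cat(sprintf("  energy: %.6f kcal/mol\n", x$energy))
  opt <- c("h_corr", "g_corr", "e_homo", "e_lumo", "nu_imag")
  for (f in opt) if (!is.null(x[[f]])) cat(sprintf("  %s: %.6f\n", f, x[[f]]))
  if (!is.null(x$atoms)) cat(sprintf("  atoms: %d\n", nrow(x$atoms)))
  invisible(x)
}
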