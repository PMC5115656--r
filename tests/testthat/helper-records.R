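# terse builders for test species
sp <- function(label, energy, ...) species_record(label, energy, ...)

# reference hydrogen atom used by planted thermochemistry fixtures
h_ref <- function(level = "II", phase = "gas") {
  species_record("H_atom", energy = convert_energy(-0.5, "hartree", "kcal_per_mol"),
                 multiplicity = 2L, level = level, phase = phase, h_corr = 1.481)
}

# random valid species record for round-trip property tests
random_record <- function(i, with_atoms = FALSE) {
  atoms <- NULL
  if (with_atoms) {
    n <- sample(2:6, 1)
    el <- sample(c("C", "O", "N", "H"), n, replace = TRUE)
    mult <- 2L
    atoms <- atom_table(el, rnorm(n), rnorm(n), rnorm(n),
                        mulliken_charge = round(rnorm(n, 0, 0.3), 4),
                        mulliken_spin = round(abs(rnorm(n, 0, 0.2)), 4))
  }
  species_record(
    label = paste0("cmp", i),
    energy = rnorm(1, -5e4, 1e3),
    charge = sample(-1:1, 1),
    multiplicity = if (with_atoms) 2L else sample(1:2, 1),
    level = sample(c("II", "III", "IV"), 1),
    phase = sample(c("gas", "water"), 1),
    h_corr = if (runif(1) < 0.7) rnorm(1, 80, 5) else NULL,
    g_corr = if (runif(1) < 0.7) rnorm(1, 60, 5) else NULL,
    e_homo = if (runif(1) < 0.7) rnorm(1, -130, 10) else NULL,
    e_lumo = if (runif(1) < 0.7) rnorm(1, -10, 10) else NULL,
    nu_imag = if (runif(1) < 0.3) abs(rnorm(1, 1400, 200)) else NULL,
    atoms = atoms
  )
}

expect_record_equal <- function(a, b) {
  for (f in c("label", "charge", "multiplicity", "level", "phase")) {
    expect_identical(a[[f]], b[[f]], info = f)
  }
  for (f in c("energy", "h_corr", "g_corr", "e_homo", "e_lumo", "nu_imag")) {
    if (is.null(a[[f]])) expect_null(b[[f]]) else
      expect_equal(a[[f]], b[[f]], tolerance = 1e-12, info = f)
  }
  if (is.null(a$atoms)) {
    expect_null(b$atoms)
  } else {
    expect_equal(as.data.frame(a$atoms), as.data.frame(b$atoms),
                 tolerance = 1e-10)
  }
}
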