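test_that("energy conversions use the CODATA factors and compose exactly", {
  expect_equal(convert_energy(1, "hartree", "kcal_per_mol"), 627.509474)
  expect_equal(convert_energy(627.509474, "kcal_per_mol", "hartree"), 1.0)
  expect_identical(convert_energy(13.7, "eV", "eV"), 13.7)
  x <- c(-1.5, 0, 2.25, 1e3)
  for (a in c("hartree", "kcal_per_mol", "kJ_per_mol", "eV")) {
    for (b in c("hartree", "kcal_per_mol", "kJ_per_mol", "eV")) {
      expect_equal(convert_energy(convert_energy(x, a, b), b, a), x,
                   tolerance = 1e-12)
      # composition through an intermediate unit
      expect_equal(convert_energy(convert_energy(x, a, "eV"), "eV", b),
                   convert_energy(x, a, b), tolerance = 1e-10)
    }
  }
  expect_error(convert_energy(1, "joule", "eV"), "unknown energy unit")
})

test_that("record validation enforces the structural invariants", {
  expect_error(species_record("x", 0, phase = "vacuum"), "phase")
  expect_error(species_record("x", 0, level = "VII"), "level")
  expect_error(species_record("x", NaN), "finite")
  expect_error(species_record("x", 0, nu_imag = -5), "magnitude")
  # singlet with nonzero spin density rejected
  at <- atom_table(c("O", "H"), c(0, 1), c(0, 0), c(0, 0),
                   mulliken_spin = c(0.5, 0.5))
  expect_error(species_record("x", 0, multiplicity = 1L, atoms = at),
               "zero Mulliken spin")
  # same atoms fine on a doublet
  expect_s3_class(species_record("x", 0, multiplicity = 2L, atoms = at),
                  "species_record")
  expect_error(atom_table("O", 0, 0, 0, nuclear_charge = 7), "nuclear charge")
  expect_error(atom_table("Xx", 0, 0, 0), "unknown element")
})

test_that("a hartree-tagged energy is converted to kcal/mol on read", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"label":"mol","energy":-100.0,"energy_unit":"hartree"}]', f)
  recs <- read_species_records(f)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$energy, -62750.9474, tolerance = 1e-9)
  # unknown unit tag is an error naming the record
  writeLines('[{"label":"mol","energy":-100.0,"energy_unit":"furlong"}]', f)
  expect_error(read_species_records(f), "unknown unit tag")
  # malformed field names record and field
  writeLines('[{"label":"mol","energy":"abc"}]', f)
  expect_error(read_species_records(f), "mol.*energy")
})

test_that("an empty document reads as an empty list and writes back", {
  f <- withr::local_tempfile(fileext = ".json")
  write_species_records(list(), f)
  expect_identical(read_species_records(f), list())
})

test_that("JSON round trip is field-for-field identity on randomized records", {
  set.seed(101)
  recs <- lapply(1:12, function(i) random_record(i, with_atoms = i %% 3 == 0))
  f <- withr::local_tempfile(fileext = ".json")
  write_species_records(recs, f)
  back <- read_species_records(f)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) expect_record_equal(recs[[i]], back[[i]])
})

test_that("CSV round trip preserves scalar records and rejects atom records", {
  set.seed(202)
  recs <- lapply(1:8, function(i) random_record(i, with_atoms = FALSE))
  f <- withr::local_tempfile(fileext = ".csv")
  write_species_records(recs, f)
  back <- read_species_records(f)
  for (i in seq_along(recs)) expect_record_equal(recs[[i]], back[[i]])
  with_at <- random_record(99, with_atoms = TRUE)
  expect_error(write_species_records(list(with_at), f), "scalar fields only")
})

test_that("records differing only in phase stay distinguishable through IO", {
  a <- sp("twin", -100, phase = "gas")
  b <- sp("twin", -100, phase = "water")
  f <- withr::local_tempfile(fileext = ".json")
  write_species_records(list(a, b), f)
  back <- read_species_records(f)
  expect_setequal(vapply(back, `[[`, character(1), "phase"), c("gas", "water"))
})

test_that("unknown fields survive a write/read cycle in the extra map", {
  r <- species_record("x", -10, extra = list(s_squared = 0.761, source = "run7"))
  f <- withr::local_tempfile(fileext = ".json")
  write_species_records(list(r), f)
  back <- read_species_records(f)[[1]]
  expect_equal(back$extra$s_squared, 0.761)
  expect_identical(back$extra$source, "run7")
})

test_that("xyz blocks parse in order and reject malformed lines", {
  one <- read_xyz_block("O 8.0 0.0 0.0 0.0")
  expect_identical(one$element, "O")
  expect_identical(one$nuclear_charge, 8L)
  expect_equal(unlist(one[, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))

  water <- read_xyz_block(c(
    "O 8.0  0.000  0.000  0.117",
    "H 1.0  0.000  0.757 -0.469",
    "H 1.0  0.000 -0.757 -0.469"
  ))
  expect_identical(water$element, c("O", "H", "H"))
  expect_equal(water$z, c(0.117, -0.469, -0.469))

  expect_error(read_xyz_block("O 8.0 0.0 0.0"), "line 1")
  expect_error(read_xyz_block(c("O 8.0 0 0 0", "H 8.0 1 0 0")),
               "line 2.*does not match")
})

test_that("reaction systems require a ts frequency and shared tags", {
  r <- sp("r", -10, g_corr = 1, multiplicity = 2L)
  t_ <- sp("t", -8, g_corr = 0.5, multiplicity = 2L, nu_imag = 1300)
  p <- sp("p", -20, g_corr = 1.2, multiplicity = 2L)
  expect_s3_class(reaction_system("ok", r, t_, p), "reaction_system")
  no_nu <- sp("t2", -8, g_corr = 0.5, multiplicity = 2L)
  expect_error(reaction_system("bad", r, no_nu, p), "imaginary frequency")
  wrong_phase <- sp("p2", -20, g_corr = 1.2, multiplicity = 2L, phase = "water")
  expect_error(reaction_system("bad", r, t_, wrong_phase), "share level and phase")
})
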