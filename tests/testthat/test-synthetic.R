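test_that("identical seeds give byte-identical serialized species sets", {
  spec <- data.frame(label = c("A", "B"), target_bde = c(73.166, 80),
                     target_ip = c(165.428, 170), target_gap = c(-92.118, -100))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_species_records(generate_species_set(42, spec)$records, f1)
  write_species_records(generate_species_set(42, spec)$records, f2)
  expect_identical(readLines(f1), readLines(f2))
  write_species_records(generate_species_set(43, spec)$records, f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("generators leave the global random stream untouched", {
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(generate_species_set(9, data.frame(
    label = "A", target_bde = 70, target_ip = 160, target_gap = -90)))
  invisible(generate_geometry_fixture(9))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("planted thermochemistry targets are realized exactly", {
  spec <- data.frame(label = "L3HOK", target_bde = 73.166,
                     target_ip = 165.428, target_gap = -92.118)
  gen <- generate_species_set(42, spec)
  labs <- vapply(gen$records, `[[`, character(1), "label")
  w <- gen$records[[which(labs == "L3HOK")]]
  r <- gen$records[[which(labs == "L3HOK_rad")]]
  h <- gen$records[[which(labs == "H_atom")]]
  cat_ <- gen$records[[which(labs == "L3HOK_cat")]]
  expect_equal(bde(w, r, h), 73.166, tolerance = 1e-9)
  expect_equal(ip(w, cat_), 165.428, tolerance = 1e-9)
  expect_equal(homo_lumo_gap(w), -92.118, tolerance = 1e-9)
  expect_equal(thermal_correction(w, r, h), gen$truth$targets$L3HOK$h_t,
               tolerance = 1e-9)
  # zero-BDE plant: whole and fragments cancel exactly
  gen0 <- generate_species_set(1, data.frame(label = "Z", target_bde = 0,
                                             target_ip = 1, target_gap = -1))
  labs0 <- vapply(gen0$records, `[[`, character(1), "label")
  expect_equal(bde(gen0$records[[which(labs0 == "Z")]],
                   gen0$records[[which(labs0 == "Z_rad")]],
                   gen0$records[[which(labs0 == "H_atom")]]), 0,
               tolerance = 1e-9)
  # every generated record passes validation
  for (rec in gen$records) expect_silent(validate_species_record(rec))
})

test_that("planted kinetics targets are realized exactly", {
  gen <- generate_reaction_system(5, target_de_cor = 0.600,
                                  target_nu = 1295.9,
                                  target_de_p_r = -11.514)
  act <- activation_energy(gen$system$reagents, gen$system$ts)
  expect_equal(act$de_ts_r_cor, 0.600, tolerance = 1e-9)
  expect_equal(gen$system$ts$nu_imag, 1295.9)
  re <- reaction_energy(gen$system$reagents, gen$system$products)
  expect_equal(re$de_p_r, -11.514, tolerance = 1e-9)
  expect_equal(system_rate(gen$system)$rate,
               rate_constant(0.600, 1295.9)$rate, tolerance = 1e-6)
  # barrierless plant reduces to prefactor times tunneling
  gen0 <- generate_reaction_system(2, 0, 1000, -20)
  expect_equal(system_rate(gen0$system)$rate,
               rate_constant(0, 1000)$rate, tolerance = 1e-9)
})

test_that("full-pipeline parameter recovery holds across many seeds", {
  set.seed(990)
  seeds <- sample.int(1e6, 100)
  for (s in seeds) {
    tb <- runif(1, 60, 120)
    ti <- runif(1, 80, 260)
    tg <- -runif(1, 60, 300)
    gen <- generate_species_set(s, data.frame(label = "X", target_bde = tb,
                                              target_ip = ti, target_gap = tg))
    tab <- build_descriptor_table(
      gen$records, data.frame(compound = "X", whole = "X", radical = "X_rad",
                              cation = "X_cat"))
    expect_equal(tab$bde, tb, tolerance = 1e-9)
    expect_equal(tab$ip, ti, tolerance = 1e-9)
    expect_equal(tab$hl_gap, tg, tolerance = 1e-9)

    de <- runif(1, -1, 10); nu <- runif(1, 300, 2000); dpr <- runif(1, -20, 5)
    k <- generate_reaction_system(s, de, nu, dpr)
    expect_equal(activation_energy(k$system$reagents, k$system$ts)$de_ts_r_cor,
                 de, tolerance = 1e-9)
    expect_equal(reaction_energy(k$system$reagents, k$system$products)$de_p_r,
                 dpr, tolerance = 1e-9)
  }
})

test_that("tuning and geometry plants are recovered over seeds", {
  set.seed(991)
  for (i in 1:20) {
    s <- sample.int(1e6, 1)
    # interior optima: the natural end condition biases the interpolant by
    # up to ~5e-3 inside the outermost grid intervals
    mu_star <- runif(1, 0.15, 0.75)
    tc <- generate_tuning_curve(s, mu_star, curvature = runif(1, 20, 200))
    expect_lt(abs(find_optimal_mu(build_curve(tc$per_mu_records)) - mu_star), 2e-3)
    geo <- generate_geometry_fixture(s, runif(1, 2.4, 2.9), runif(1, 150, 179),
                                     runif(1, 5, 85), runif(1, 1, 359))
    rep_ <- geometry_report(geo$atoms, geo$roles)
    tg <- geo$truth$targets
    expect_equal(rep_$oho_length, tg$oho_length, tolerance = 1e-6)
    expect_equal(rep_$oho_angle, tg$oho_angle, tolerance = 1e-6)
    expect_equal(rep_$plane_angle, tg$plane_angle, tolerance = 1e-6)
    expect_equal(rep_$torsion, tg$torsion, tolerance = 1e-6)
  }
})

test_that("the packaged reference tables pass their integrity checksum", {
  st <- study_tables()
  expect_s3_class(st, "study_tables")
  # spot values straight from the printed tables
  expect_equal(st$table3$nu_i[st$table3$compound == "3HAA" &
                                st$table3$radical == "PhO"], 1295.9)
  expect_equal(st$table1$II_e_homo[st$table1$compound == "Phenol"], -137.424)
  expect_equal(st$bde_exp[["ASC"]], 81.0)
  expect_equal(st$table6$de_p_r_II[st$table6$radical == "Phenoxyl"], -49.289)
  expect_equal(st$table2$gas_ip[st$table2$compound == "DTBP"], 174.788)
  # a corrupted cell breaks the checksum
  broken <- st
  broken$table1$II_bde[1] <- broken$table1$II_bde[1] + 0.001
  expect_gt(abs(study_checksum_value(broken) - study_checksum_value(st)), 0)
})
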