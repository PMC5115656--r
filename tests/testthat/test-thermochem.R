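test_that("bde is the radical-plus-H minus whole energy difference", {
  w <- sp("w", -100.0); r <- sp("r", -99.5, multiplicity = 2L)
  h <- sp("h", -0.5, multiplicity = 2L)
  expect_equal(bde(w, r, h), 0.0)
  # independent arithmetic: -62313.0 + (-313.7547) - (-62750.9474)
  w2 <- sp("w2", -62750.9474)
  r2 <- sp("r2", -62313.0, multiplicity = 2L)
  h2 <- sp("h2", -313.7547, multiplicity = 2L)
  expect_equal(bde(w2, r2, h2), 124.1927, tolerance = 1e-9)
  r_wat <- sp("rw", -99.5, multiplicity = 2L, phase = "water")
  expect_error(bde(w, r_wat, h), "share level and phase")
})

test_that("thermal correction combines enthalpy corrections of the fragments", {
  mk <- function(lab, h) sp(lab, -1, h_corr = h)
  expect_equal(thermal_correction(mk("w", 0), mk("r", 0), mk("h", 0)), 0)
  expect_equal(thermal_correction(mk("w", 80.0), mk("r", 72.0), mk("h", 1.48)),
               -6.52, tolerance = 1e-12)
  no_h <- sp("r", -1)
  expect_error(thermal_correction(mk("w", 80), no_h, mk("h", 1.48)), "'r' lacks h_corr")
})

test_that("bde_cor adds the thermal correction (printed-table differences)", {
  # phenol level II: 106.394 + (99.481 - 106.394) = 99.481
  expect_equal(bde_cor(106.394, -6.913), 99.481)
  # L-3HOK level III
  expect_equal(bde_cor(77.190, -5.717), 71.473)
  expect_identical(bde_cor(42, 0), 42)
})

test_that("ip keys on a +1 charge difference, not absolute charge", {
  w <- sp("w", -1000.0)
  cat_ <- sp("cat", -834.572, charge = 1L, multiplicity = 2L)
  expect_equal(ip(w, cat_), 165.428)
  same_e <- sp("cat2", -1000.0, charge = 1L, multiplicity = 2L)
  expect_equal(ip(w, same_e), 0)
  # anionic parent, neutral abstracted form
  an <- sp("an", -500, charge = -1L)
  ne <- sp("ne", -420, charge = 0L, multiplicity = 2L)
  expect_equal(ip(an, ne), 80)
  expect_error(ip(w, sp("x", -900)), "charge")
})

test_that("frontier gap matches printed table rows", {
  expect_equal(homo_lumo_gap(sp("phenol", -1, e_homo = -137.424, e_lumo = 0.816)),
               -138.240)
  expect_equal(homo_lumo_gap(sp("kyna", -1, e_homo = -151.606, e_lumo = -49.448)),
               -102.158)
  expect_equal(homo_lumo_gap(sp("x", -1, e_homo = -5, e_lumo = -5)), 0)
  expect_error(homo_lumo_gap(sp("x", -1, e_homo = -5)), "orbital energy")
})

test_that("koopmans deviation is IP + E_HOMO", {
  expect_equal(koopmans_delta(174.788, -138.366), 36.422)  # DTBP gas
  expect_equal(koopmans_delta(165.428, -128.702), 36.726)  # L-3HOK gas
  expect_equal(koopmans_delta(100, -100), 0)
})

test_that("spin delocalization uses the chosen dispersion convention", {
  at <- atom_table(c("O", "C", "C"), 1:3, 0, 0, mulliken_spin = c(0.9, 0.05, 0.05))
  rad <- sp("rad", -1, multiplicity = 2L, atoms = at)
  res_pop <- spin_delocalization(rad, c("O*" = 1L))
  # closed form: mean 1/3, squared deviations (0.56667^2, 2 x 0.28333^2)
  expect_equal(res_pop$delta_sd, sqrt(sum((c(0.9, 0.05, 0.05) - 1 / 3)^2) / 3),
               tolerance = 1e-12)
  expect_equal(res_pop$delta_sd, 0.40069, tolerance = 1e-4)
  expect_equal(spin_delocalization(rad, convention = "sample")$delta_sd,
               0.49075, tolerance = 1e-4)
  expect_equal(res_pop$sd_by_role[["O*"]], 0.9)

  uniform <- sp("u", -1, multiplicity = 2L,
                atoms = atom_table(rep("C", 4), 1:4, 0, 0,
                                   mulliken_spin = rep(0.25, 4)))
  expect_equal(spin_delocalization(uniform)$delta_sd, 0)

  expect_error(spin_delocalization(rad, c("O*" = 9L)), "out of range")
  no_spin <- sp("n", -1, multiplicity = 2L,
                atoms = atom_table("O", 0, 0, 0))
  expect_error(spin_delocalization(no_spin), "spin density")
})

test_that("spin delocalization is permutation invariant and scales linearly", {
  set.seed(33)
  for (i in 1:20) {
    n <- sample(4:12, 1)
    spins <- rnorm(n, 0.1, 0.3)
    at <- atom_table(rep("C", n), seq_len(n), 0, 0, mulliken_spin = spins)
    rad <- sp("r", -1, multiplicity = 2L, atoms = at)
    perm <- sample(n)
    at_p <- atom_table(rep("C", n), seq_len(n), 0, 0, mulliken_spin = spins[perm])
    rad_p <- sp("rp", -1, multiplicity = 2L, atoms = at_p)
    expect_equal(spin_delocalization(rad)$delta_sd,
                 spin_delocalization(rad_p)$delta_sd, tolerance = 1e-12)
    c_ <- rnorm(1, 0, 2)
    at_s <- atom_table(rep("C", n), seq_len(n), 0, 0, mulliken_spin = c_ * spins)
    rad_s <- sp("rs", -1, multiplicity = 2L, atoms = at_s)
    expect_equal(spin_delocalization(rad_s)$delta_sd,
                 abs(c_) * spin_delocalization(rad)$delta_sd, tolerance = 1e-10)
  }
})

make_charge_system <- function(radical, q_reag, q_ts) {
  n <- length(q_ts)
  at <- function(q) atom_table(c("O", "H", "O", "O")[seq_len(n)], seq_len(n), 0, 0,
                               mulliken_charge = q)
  r <- species_record("r", -10, multiplicity = 2L, atoms = at(q_reag))
  t_ <- species_record("t", -8, multiplicity = 2L, nu_imag = 1300, atoms = at(q_ts))
  p <- species_record("p", -12, multiplicity = 2L)
  reaction_system("sys", r, t_, p, radical = radical)
}

test_that("charge descriptors follow the radical-specific oxygen formula", {
  # phenoxyl: dQ(O) = Q(O2) - Q(O1)
  sys <- make_charge_system("phenoxyl", q_reag = c(-0.40, 0.45, -0.20),
                            q_ts = c(-0.35, 0.65, -0.30))
  m <- list(reagents = c(O1 = 1L, H = 2L, O2 = 3L),
            ts = c(O1 = 1L, H = 2L, O2 = 3L))
  cd <- charge_descriptors(sys, m)
  expect_equal(cd$q_h, 0.65)
  expect_equal(cd$delta_q_h, 0.20)
  expect_equal(cd$dq_o, -0.30 - (-0.35))
  expect_equal(cd$delta_dq_ts_r, 0.05 - (-0.20 - (-0.40)))

  # methyl peroxy: dQ(O) = Q(O2) + Q(O3) - Q(O1)
  sys2 <- make_charge_system("methyl_peroxy",
                             q_reag = c(-0.30, 0.50, -0.10, -0.15),
                             q_ts = c(-0.30, 0.55, -0.20, -0.25))
  m2 <- list(reagents = c(O1 = 1L, H = 2L, O2 = 3L, O3 = 4L),
             ts = c(O1 = 1L, H = 2L, O2 = 3L, O3 = 4L))
  cd2 <- charge_descriptors(sys2, m2)
  expect_equal(cd2$dq_o, -0.20 + -0.25 - -0.30)
  expect_equal(cd2$dq_o, -0.15)
  # all-zero charges give all-zero descriptors
  sys0 <- make_charge_system("phenoxyl", rep(0, 3), rep(0, 3))
  cd0 <- charge_descriptors(sys0, m)
  expect_true(all(unlist(cd0) == 0))
  # O3 mandatory for methyl peroxy
  m_no3 <- list(reagents = c(O1 = 1L, H = 2L, O2 = 3L),
                ts = c(O1 = 1L, H = 2L, O2 = 3L))
  expect_error(charge_descriptors(sys2, m_no3), "O3")
})

test_that("descriptor tables fill what resolves and never invent zeros", {
  expect_equal(nrow(build_descriptor_table(
    list(), data.frame(compound = character(), whole = character(),
                       radical = character(), cation = character()))), 0L)

  gen <- generate_species_set(42, data.frame(
    label = "L3HOK", target_bde = 73.166, target_ip = 165.428,
    target_gap = -92.118))
  recipe <- data.frame(compound = "L3HOK", whole = "L3HOK",
                       radical = "L3HOK_rad", cation = "L3HOK_cat")
  tab <- build_descriptor_table(gen$records, recipe)
  expect_equal(tab$bde, 73.166, tolerance = 1e-9)
  expect_equal(tab$ip, 165.428, tolerance = 1e-9)
  expect_equal(tab$hl_gap, -92.118, tolerance = 1e-9)

  recipe_nocat <- data.frame(compound = "L3HOK", whole = "L3HOK",
                             radical = "L3HOK_rad", cation = "missing")
  tab2 <- build_descriptor_table(gen$records, recipe_nocat)
  expect_false(is.na(tab2$bde))
  expect_true(is.na(tab2$ip))

  dup <- c(gen$records, gen$records[2])
  expect_error(build_descriptor_table(dup, recipe), "ambiguous")
})

test_that("descriptors are gauge invariant and the enthalpy identity holds", {
  set.seed(7)
  for (i in 1:10) {
    e <- rnorm(3, -1e4, 100)
    h <- rnorm(3, 50, 5)
    w <- sp("w", e[1], h_corr = h[1])
    r <- sp("r", e[2], multiplicity = 2L, h_corr = h[2])
    ha <- sp("h", e[3], multiplicity = 2L, h_corr = h[3])
    shift <- rnorm(1, 0, 500)
    # shifting a compound's own records (whole + radical) by a constant
    # leaves BDE unchanged: absolute energy origins are gauge freedom
    ws <- sp("w", e[1] + shift, h_corr = h[1])
    rs <- sp("r", e[2] + shift, multiplicity = 2L, h_corr = h[2])
    expect_equal(bde(w, r, ha), bde(ws, rs, ha), tolerance = 1e-9)
    # assembled enthalpy identity
    lhs <- bde_cor(bde(w, r, ha), thermal_correction(w, r, ha))
    rhs <- (e[2] + h[2]) + (e[3] + h[3]) - (e[1] + h[1])
    expect_equal(lhs, rhs, tolerance = 1e-9)
    # IP gauge invariance under a constant shift of both records
    cat_ <- sp("c", e[1] + 160, charge = 1L, multiplicity = 2L)
    cat_s <- sp("c", e[1] + 160 + shift, charge = 1L, multiplicity = 2L)
    expect_equal(ip(w, cat_), ip(ws, cat_s), tolerance = 1e-9)
  }
})
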