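test_that("side-reaction coefficient and conditional constants behave as chemistry requires", {
  # no pKa -> identity
  plain <- chelator("x", 1, 20, ligand_molar_mass = 100)
  expect_identical(effective_betas(plain, 7.4), 20)

  # deferiprone at pH 7.4: direct arithmetic evaluation
  expect_equal(side_reaction_coefficient(c(3.68, 9.77), 7.4), ORACLE_ALPHA_74,
               tolerance = 1e-12)
  expect_equal(effective_betas(deferiprone(), 7.4), ORACLE_LOGB_COND,
               tolerance = 1e-12)

  # far above the largest pKa the correction vanishes
  b13 <- effective_betas(deferiprone(), 13)
  expect_equal(10^b13, 10^deferiprone()$log_beta, tolerance = 0.01)

  # correction can only weaken binding, at any pH
  for (ph in c(2, 5, 7.4, 9, 12)) {
    expect_true(all(effective_betas(deferiprone(), ph) <=
                      deferiprone()$log_beta))
  }
  expect_error(side_reaction_coefficient(c(3.68, 9.77), -1),
               class = "ferrispec_validation_error")
})

test_that("equilibrium with no iron is trivial and exact", {
  st <- solve_equilibrium(medium(tf_total = 13e-6, ligand_total = 156e-6),
                          chelator = deferiprone())
  expect_identical(st$free_fe, 0)
  expect_identical(st$tf0, 13e-6)
  expect_identical(st$free_ligand, 156e-6)
  expect_true(all(st$complexes == 0))
  expect_equal(st$frac_apo, 1)
})

test_that("chelator-free solve matches the bisection oracle and frozen reference", {
  st <- solve_equilibrium(medium(tf_total = 1.3e-6, fe_total = 2.6e-6))
  expect_equal(st$free_fe, ORACLE_EX2_FREE_FE, tolerance = 1e-6)
  expect_equal(st$frac_holo, ORACLE_EX2_FRAC_HOLO, tolerance = 1e-9)
  orc <- oracle_solve(2.6e-6, 1.3e-6, 0)
  expect_equal(st$free_fe, orc$free_fe, tolerance = 1e-6)
  expect_equal(st$tf0, orc$tf0, tolerance = 1e-6)
  expect_equal(st$tf1, orc$tf1, tolerance = 1e-6)
  expect_equal(st$tf2, orc$tf2, tolerance = 1e-6)
})

test_that("apotransferrin reloading equilibrium matches the reference solution", {
  st <- solve_equilibrium(medium(tf_total = 13e-6, fe_total = 52e-6,
                                 ligand_total = 156e-6),
                          chelator = deferiprone())
  expect_equal(st$frac_apo, ORACLE_RELOAD_FRAC[["apo"]], tolerance = 1e-6)
  expect_equal(st$frac_mono, ORACLE_RELOAD_FRAC[["mono"]], tolerance = 1e-6)
  expect_equal(st$frac_holo, ORACLE_RELOAD_FRAC[["holo"]], tolerance = 1e-6)
  # the substance of the gel observation: most transferrin ends up
  # iron-loaded, and uncorrected constants would leave it stripped
  expect_gt(1 - st$frac_apo, 0.9)
  raw <- solve_equilibrium(medium(tf_total = 13e-6, fe_total = 52e-6,
                                  ligand_total = 156e-6),
                           chelator = deferiprone(),
                           correct_protonation = FALSE)
  expect_lt(raw$frac_holo, 0.01)
})

test_that("mass balances and mass-action laws hold over random compositions", {
  set.seed(42)
  lb <- effective_betas(deferiprone(), 7.4)
  for (i in 1:200) {
    rc <- random_composition()
    st <- solve_equilibrium(rc$comp, chelator = rc$chelator)
    expect_lt(max(st$residuals), 1e-10)
    # mass-action laws, reconstructed independently of the solver
    k1 <- 7e22; k2 <- 3.6e21
    expect_equal(st$tf1, k1 * st$tf0 * st$free_fe, tolerance = 1e-12)
    expect_equal(st$tf2, k2 * st$tf1 * st$free_fe, tolerance = 1e-12)
    if (!is.null(rc$chelator)) {
      expect_equal(unname(st$complexes),
                   10^lb * st$free_fe * st$free_ligand^(1:3),
                   tolerance = 1e-12)
    }
    expect_true(all(c(st$free_fe, st$free_ligand, st$tf0, st$tf1, st$tf2,
                      st$complexes) >= 0))
    if (rc$comp$tf_total > 0)
      expect_equal(st$frac_apo + st$frac_mono + st$frac_holo, 1,
                   tolerance = 1e-9)
  }
})

test_that("solver agrees with the nested bisection oracle on random subsystems", {
  set.seed(7)
  for (i in 1:40) {
    # chelator-free subsystem
    tf_t <- 10^runif(1, -7, -4.5); fe_t <- 10^runif(1, -7, -4)
    st <- solve_equilibrium(medium(tf_total = tf_t, fe_total = fe_t))
    orc <- oracle_solve(fe_t, tf_t, 0)
    expect_equal(st$free_fe, orc$free_fe, tolerance = 1e-6)
    expect_equal(st$tf2, orc$tf2, tolerance = 1e-6)
    # transferrin-free subsystem
    l_t <- 10^runif(1, -6, -3.5); fe2 <- 10^runif(1, -7, -4.5)
    st2 <- solve_equilibrium(medium(fe_total = fe2, ligand_total = l_t),
                             chelator = deferiprone())
    orc2 <- oracle_solve(fe2, 0, l_t, log_beta = ORACLE_LOGB_COND)
    expect_equal(st2$free_fe, orc2$free_fe, tolerance = 1e-6)
    expect_equal(st2$free_ligand, orc2$free_ligand, tolerance = 1e-6)
  }
})

test_that("equilibrium responds monotonically to iron and ligand pools", {
  fe_grid <- c(2, 5, 10, 20, 30, 50) * 1e-6
  holo <- vapply(fe_grid, function(fe)
    solve_equilibrium(medium(tf_total = 13e-6, fe_total = fe))$frac_holo, 0)
  expect_true(all(diff(holo) >= -1e-12))  # non-decreasing up to float noise

  lig_grid <- c(10, 30, 100, 300, 1000) * 1e-6
  free_fe <- vapply(lig_grid, function(l)
    solve_equilibrium(medium(tf_total = 1.3e-6, fe_total = 10e-6,
                             ligand_total = l),
                      chelator = deferiprone())$free_fe, 0)
  expect_true(all(diff(free_fe) <= 1e-12 * free_fe[1]))
})

test_that("two identical solves are bit-identical", {
  comp <- medium(tf_total = 13e-6, fe_total = 52e-6, ligand_total = 156e-6)
  a <- solve_equilibrium(comp, chelator = deferiprone())
  b <- solve_equilibrium(comp, chelator = deferiprone())
  expect_identical(a, b)
})

test_that("tf_fractions reports loading and refuses an empty pool", {
  st <- solve_equilibrium(medium(tf_total = 1.3e-6, fe_total = 1e-4))
  fr <- tf_fractions(st)
  expect_equal(unname(fr[c("frac_apo", "frac_mono")]), c(0, 0), tolerance = 1e-6)
  expect_equal(fr[["frac_holo"]], 1, tolerance = 1e-6)
  expect_equal(fr[["tf_site_saturation"]], 1, tolerance = 1e-6)

  st0 <- solve_equilibrium(medium(tf_total = 1.3e-6, fe_total = 0))
  fr0 <- tf_fractions(st0)
  expect_equal(unname(fr0), c(1, 0, 0, 0))

  st_free <- solve_equilibrium(medium(fe_total = 1e-6, ligand_total = 1e-5),
                               chelator = deferiprone())
  expect_error(tf_fractions(st_free), class = "ferrispec_validation_error")
})

test_that("pFe reproduces the reference values and limiting behavior", {
  # non-binding 1:1 ligand: essentially all iron stays free
  weak <- chelator("weak", 1, 0, ligand_molar_mass = 100)
  expect_equal(compute_pfe(weak), 6, tolerance = 1e-4)

  expect_equal(compute_pfe(deferiprone(), correct_protonation = FALSE),
               ORACLE_PFE_DEF_RAW, tolerance = 1e-6)
  expect_equal(compute_pfe(deferiprone()), ORACLE_PFE_DEF_CORR,
               tolerance = 1e-6)
  expect_equal(compute_pfe(transferrin()), ORACLE_PFE_TF, tolerance = 1e-6)

  # protonation correction weakens binding, so corrected pFe is lower
  expect_lt(compute_pfe(deferiprone()),
            compute_pfe(deferiprone(), correct_protonation = FALSE))
  # corrected deferiprone is in the 19-22 window, below transferrin
  expect_gt(compute_pfe(deferiprone()), 19)
  expect_lt(compute_pfe(deferiprone()), 22)
})

test_that("invalid inputs raise typed validation errors", {
  expect_error(medium(tf_total = -1e-6), class = "ferrispec_validation_error")
  expect_error(medium(ph = 15), class = "ferrispec_validation_error")
  expect_error(chelator("x", 2, c(10), ligand_molar_mass = 100),
               class = "ferrispec_validation_error")
  expect_error(transferrin(k1 = 1e20, k2 = 1e21),
               class = "ferrispec_validation_error")
  expect_error(solve_equilibrium(medium(fe_total = 1e-6, ligand_total = 1e-5)),
               class = "ferrispec_validation_error")
})
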