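scenario_htf1000 <- function() medium(tf_total = 13e-6, fe_total = 26e-6)

test_that("zero uptake leaves every state identical to the initial state", {
  tc <- simulate_timecourse(scenario_htf1000(), uptake = uptake_model(0),
                            t_end = 10, dt = 2)
  df <- as.data.frame(tc)
  first <- unname(unlist(df[1, -1]))
  for (i in seq_len(nrow(tc)))
    expect_identical(unname(unlist(df[i, -1])), first)
})

test_that("total iron depletes linearly and other pools are conserved", {
  r <- medium_from_recipe(htf_ug_per_ml = 100, complex_umol_per_l = 26)
  tc <- simulate_timecourse(r$medium, chelator = r$chelator,
                            t_end = 96, dt = 4)
  expect_equal(tc$fe_total, pmax(r$medium$fe_total - 1.7e-7 * tc$time, 0),
               tolerance = 1e-12)
  # implied transferrin and ligand pools constant across time
  tf_pool <- tc$tf0 + tc$tf1 + tc$tf2
  lig_pool <- tc$free_ligand + tc$FeL1 + 2 * tc$FeL2 + 3 * tc$FeL3
  expect_equal(tf_pool, rep(r$medium$tf_total, nrow(tc)), tolerance = 1e-9)
  expect_equal(lig_pool, rep(r$medium$ligand_total, nrow(tc)), tolerance = 1e-9)
})

test_that("96 h depleted state matches the chelator-free oracle", {
  tc <- simulate_timecourse(scenario_htf1000(), t_end = 96, dt = 8)
  expect_equal(tc$frac_holo[nrow(tc)], ORACLE_96H_HTF_FRAC_HOLO,
               tolerance = 1e-6)
  orc <- oracle_solve(26e-6 - 96 * 1.7e-7, 13e-6, 0)
  expect_equal(tc$frac_holo[nrow(tc)], orc$frac_holo, tolerance = 1e-6)
})

test_that("states agree exactly at shared grid times for different dt", {
  r <- medium_from_recipe(htf_ug_per_ml = 100, complex_umol_per_l = 52)
  coarse <- simulate_timecourse(r$medium, chelator = r$chelator,
                                t_end = 48, dt = 8)
  fine <- simulate_timecourse(r$medium, chelator = r$chelator,
                              t_end = 48, dt = 4)
  shared <- match(coarse$time, fine$time)
  expect_false(anyNA(shared))
  cf <- as.data.frame(coarse)[, -1]
  ff <- as.data.frame(fine)[shared, -1]
  rownames(cf) <- rownames(ff) <- NULL
  expect_identical(cf, ff)
})

test_that("iron exhaustion is clamped at zero with a warning and a recorded time", {
  comp <- medium(tf_total = 1.3e-6, fe_total = 5e-6)
  expect_warning(
    tc <- simulate_timecourse(comp, t_end = 96, dt = 4),
    "exhausted")
  expect_true(all(tc$fe_total >= 0))
  expect_equal(attr(tc, "exhausted_at"), 32)  # 5e-6 / 1.7e-7 = 29.4 h
  expect_equal(tc$fe_total[tc$time >= 32], rep(0, sum(tc$time >= 32)))
})

test_that("scenario comparison reproduces the holotransferrin advantage of the chelator dose", {
  rA <- medium_from_recipe(htf_ug_per_ml = 1000, complex_umol_per_l = 0,
                           label = "1000 ug/mL hTf")
  rB <- medium_from_recipe(htf_ug_per_ml = 100, complex_umol_per_l = 26,
                           label = "100 ug/mL hTf + 26 uM Def3Fe")
  rC <- medium_from_recipe(htf_ug_per_ml = 100, complex_umol_per_l = 52,
                           label = "100 ug/mL hTf + 52 uM Def3Fe")
  tcs <- list(
    simulate_timecourse(rA$medium, chelator = rA$chelator, t_end = 96, dt = 8,
                        scenario_label = rA$label),
    simulate_timecourse(rB$medium, chelator = rB$chelator, t_end = 96, dt = 8,
                        scenario_label = rB$label),
    simulate_timecourse(rC$medium, chelator = rC$chelator, t_end = 96, dt = 8,
                        scenario_label = rC$label)
  )
  cmp <- compare_scenarios(tcs)
  expect_equal(nrow(cmp$table), 3 * nrow(tcs[[1]]))

  at96 <- function(tc) as.data.frame(tc)[tc$time == 96, ]
  expect_gt(at96(tcs[[3]])$frac_holo, at96(tcs[[1]])$frac_holo)
  expect_lt(at96(tcs[[3]])$frac_apo, at96(tcs[[1]])$frac_apo)
  expect_gt(at96(tcs[[2]])$frac_holo, at96(tcs[[1]])$frac_holo)
  last <- cmp$summary[cmp$summary$time == 96, ]
  expect_equal(last$best_holo, rC$label)
  expect_equal(last$best_apo, rC$label)
  expect_false(last$holo_tie)
})

test_that("identical scenarios compare as ties at every time", {
  comp <- scenario_htf1000()
  a <- simulate_timecourse(comp, t_end = 24, dt = 8, scenario_label = "a")
  b <- simulate_timecourse(comp, t_end = 24, dt = 8, scenario_label = "b")
  cmp <- compare_scenarios(list(a, b))
  expect_true(all(cmp$summary$holo_tie))
  expect_true(all(cmp$summary$apo_tie))
  expect_true(all(cmp$summary$best_holo == "a/b"))
})

test_that("mismatched grids are rejected", {
  comp <- scenario_htf1000()
  a <- simulate_timecourse(comp, t_end = 24, dt = 8)
  b <- simulate_timecourse(comp, t_end = 24, dt = 6)
  expect_error(compare_scenarios(list(a, b)),
               class = "ferrispec_validation_error")
})

test_that("the recomputed uptake rate from stoichiometric basis is ~2.1e-7 mol/L/h", {
  r <- uptake_rate_from_basis()
  expect_equal(r, 1e10 * 1.2e9 / 6.02214076e23 / 96, tolerance = 1e-12)
  expect_equal(r, 2.08e-7, tolerance = 0.005)
})
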