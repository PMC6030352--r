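test_that("named scenarios carry the published multipliers", {
  po <- build_scenario("pressure_overload")
  expect_equal(po$pvr_mult, 1.96)
  expect_equal(po$cpa_mult, 0.70)
  rvf <- build_scenario("rvf_full")
  expect_equal(rvf$passive_force_target_ratio, 2.7)
  expect_equal(rvf$fmax_target_ratio, 0.64)
  expect_equal(rvf$metadata$published_kstiff2_factor, 0.46)
  expect_equal(rvf$metadata$published_con_collagen_factor, 1.69)
  base <- build_scenario("baseline")
  expect_equal(base$pvr_mult, 1)
  expect_equal(base$cpa_mult, 1)
  expect_equal(base$fmax_target_ratio, 1)
  fm <- build_scenario("po_fmax_only")
  expect_equal(fm$passive_force_target_ratio, 1)
  expect_equal(fm$fmax_target_ratio, 0.64)
  a6 <- build_scenario("a6_rescue")
  expect_equal(a6$fmax_target_ratio, 0.78)
  expect_equal(a6$metadata$published_kstiff2_factor, 0.22)
  expect_error(build_scenario("nonsense"), "unknown scenario")
})

test_that("scenarios perturb only the circulation and the RV free wall", {
  m0 <- test_model()
  for (nm in c("pressure_overload", "rvf_full", "a6_rescue")) {
    m <- apply_scenario(m0, build_scenario(nm))
    expect_identical(m$walls$L, m0$walls$L)
    expect_identical(m$walls$S, m0$walls$S)
  }
  m <- apply_scenario(m0, build_scenario("rvf_full"))
  expect_equal(m$circ$PVR, m0$circ$PVR * 1.96)
  expect_equal(m$circ$C_PA, m0$circ$C_PA * 0.70)
  expect_equal(isometric_fmax_closed_form(m$walls$R$sarcomere) /
                 isometric_fmax_closed_form(m0$walls$R$sarcomere),
               0.64, tolerance = 1e-9)
  expect_equal(passive_stress(2.2, m$walls$R$sarcomere)$total /
                 passive_stress(2.2, m0$walls$R$sarcomere)$total,
               2.7, tolerance = 1e-9)
})

test_that("random scenario generation is seeded, bounded, and validated", {
  s1 <- generate_random_scenarios(123, 5)
  s2 <- generate_random_scenarios(123, 5)
  expect_identical(s1, s2)
  s3 <- generate_random_scenarios(124, 5)
  expect_false(identical(s1, s3))
  for (sc in s1) {
    expect_true(sc$pvr_mult >= 1 && sc$pvr_mult <= 3)
    expect_true(sc$cpa_mult >= 0.5 && sc$cpa_mult <= 1)
    expect_true(sc$passive_force_target_ratio >= 1 &&
                  sc$passive_force_target_ratio <= 3)
    expect_true(sc$fmax_target_ratio >= 0.4 && sc$fmax_target_ratio <= 1)
  }
  expect_error(generate_random_scenarios(1, 0), "n must")
  expect_error(generate_random_scenarios(1, 2, ranges = list(pvr_mult = c(2, 1))),
               "ranges|invalid")
})

test_that("randomly perturbed scenarios integrate with conserved volume", {
  hs <- get_baseline()
  scs <- generate_random_scenarios(77, 3,
                                   ranges = list(pvr_mult = c(1, 2.2),
                                                 cpa_mult = c(0.6, 1),
                                                 passive_ratio = c(1, 2.7),
                                                 fmax_ratio = c(0.6, 1)))
  for (sc in scs) {
    m <- hs$model
    m$circ$PVR <- m$circ$PVR * sc$pvr_mult
    m$circ$C_PA <- m$circ$C_PA * sc$cpa_mult
    m$walls$R$sarcomere <- calibrate_fibrosis(
      m$walls$R$sarcomere, sc$passive_force_target_ratio)
    m$walls$R$sarcomere <- calibrate_contractility(
      m$walls$R$sarcomere, sc$fmax_target_ratio)
    run <- run_to_convergence(m, state = hs$run$state, warm = hs$run$warm)
    tr <- run$trajectory
    tot <- rowSums(tr[, c("V_Ao", "V_SV", "V_PA", "V_PV",
                          "V_LA", "V_RA", "V_LV", "V_RV")])
    expect_lt(max(abs(tot - m$circ$V_total)), 1e-6 * m$circ$V_total)
    expect_true(all(tr$q_av >= 0 & tr$q_pval >= 0))
  }
})

test_that("embedded reference tables load with the published values", {
  ref <- reference_tables()
  hemo <- ref$hemodynamics
  expect_equal(as.numeric(hemo$control[hemo$parameter == "RV systolic pressure"]), 20.9)
  expect_equal(as.numeric(hemo$disease[hemo$parameter == "RV systolic pressure"]), 42.9)
  expect_equal(as.numeric(hemo$control[hemo$parameter == "Arterial elastance (Ea)"]), 0.91)
  expect_equal(as.numeric(hemo$control[hemo$parameter == "Ejection fraction (EF)"]), 69.6)
  par <- ref$parameters
  expect_equal(par$printed_factor_disease[par$symbol == "PVR"], 1.96)
  expect_equal(par$printed_factor_disease[par$symbol == "CPA"], 0.70)
  expect_equal(par$printed_factor_disease[par$symbol == "k_stiff2"], 0.46)
  expect_equal(par$printed_factor_treated[par$symbol == "k_stiff2"], 0.22)
})
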