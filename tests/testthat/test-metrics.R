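test_that("beat metrics satisfy their defining identities on a converged beat", {
  hs <- get_baseline()
  b <- beat_metrics(hs$run$trajectory)
  expect_equal(b$EF, b$SV / b$EDV)
  expect_equal(b$CO, b$SV * b$HR)
  expect_equal(b$RVSP, max(hs$run$trajectory$P_RV))
  expect_gt(b$EDV, b$ESV)
  expect_gt(b$EF, 0); expect_lt(b$EF, 1)
  expect_gt(b$LV_EF, 0); expect_lt(b$LV_EF, 1)
})

test_that("arterial elastance is end-systolic pressure over stroke volume", {
  expect_equal(arterial_elastance(25, 25), 1)
  expect_equal(arterial_elastance(25, 50), 0.5)
  expect_error(arterial_elastance(25, 0), "SV")
})

test_that("ESPVR fitting recovers exact and noisy synthetic slopes", {
  # collinear points recover the slope exactly
  V <- c(10, 20, 30, 40)
  P <- 5 + 2.5 * V
  f <- fit_espvr_points(V, P)
  expect_equal(f$Ees, 2.5, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  expect_equal(f$V0, -2, tolerance = 1e-9)
  # two points define the line
  expect_equal(fit_espvr_points(c(20, 30), c(10, 35))$Ees, 2.5)
  # recovery oracle: slope m* with 1% noise at 5 levels
  set.seed(11)
  ok <- replicate(20, {
    m_star <- runif(1, 1, 4)
    V <- seq(15, 35, length.out = 5)
    P <- m_star * (V - 5) * (1 + rnorm(5, 0, 0.01))
    abs(fit_espvr_points(V, P)$Ees / m_star - 1) < 0.05
  })
  expect_true(all(ok))
  expect_error(fit_espvr_points(c(10, 10, 10), c(1, 2, 3)), "degenerate")
  expect_error(fit_espvr_points(c(10, 20), c(30, 5)), "non-positive")
})

test_that("diastolic compliance falls when passive stress is scaled up", {
  hs <- get_baseline()
  fr <- c(1, 0.9, 0.8)
  c_base <- diastolic_compliance(hs$model, fr, base_run = hs$run)$compliance
  stiff <- hs$model
  for (w in c("L", "S", "R")) {
    stiff$walls[[w]]$sarcomere$k_titin <- stiff$walls[[w]]$sarcomere$k_titin * 4
    stiff$walls[[w]]$sarcomere$k_collagen <- stiff$walls[[w]]$sarcomere$k_collagen * 4
  }
  run_s <- run_to_convergence(stiff, state = hs$run$state, warm = hs$run$warm)
  c_stiff <- diastolic_compliance(stiff, fr, base_run = run_s)$compliance
  expect_gt(c_base, 0)
  expect_lt(c_stiff, c_base)
  expect_error(preload_series(hs$model, numeric(0)), "at least one")
  expect_error(preload_series(hs$model, 0.3), "fractions")
})

test_that("fold-change reports carry both the ratio and the fractional change", {
  r <- fold_change_report(list(a = 2, b = 1), list(a = 1, b = 1))
  expect_equal(r$ratio, c(2, 1))
  expect_equal(r$fractional_change, c(1, 0))
  # the published control/disease systolic pressures: ratio and fractional
  # change genuinely differ, which is why both are always emitted
  r2 <- fold_change_report(list(RVSP = 42.9), list(RVSP = 20.9))
  expect_equal(r2$ratio, 42.9 / 20.9, tolerance = 1e-12)
  expect_equal(r2$fractional_change, (42.9 - 20.9) / 20.9, tolerance = 1e-12)
  expect_error(fold_change_report(list(a = 1), list(b = 1)), "lacks")
})

test_that("arterial elastance rises with afterload at fixed contractility", {
  hs <- get_baseline()
  b0 <- beat_metrics(hs$run$trajectory)
  ea0 <- arterial_elastance(b0$Pes, b0$SV)
  m <- hs$model
  m$circ$PVR <- m$circ$PVR * 1.5
  m$circ$C_PA <- m$circ$C_PA * 0.8
  run <- run_to_convergence(m, state = hs$run$state, warm = hs$run$warm)
  b1 <- beat_metrics(run$trajectory)
  expect_gt(arterial_elastance(b1$Pes, b1$SV), ea0)
})

test_that("end-systolic elastance is afterload-insensitive but falls with Fmax", {
  hs <- get_baseline()
  fr <- c(1, 0.95, 0.9, 0.85, 0.8)
  ees0 <- fit_espvr(hs$model, fr, base_run = hs$run)$Ees
  # a moderate afterload step at fixed contractility: within +-10%
  # (load dependence grows with the size of the step; see the methods
  # vignette for the quantification)
  m_a <- hs$model
  m_a$circ$PVR <- m_a$circ$PVR * 1.3
  run_a <- run_to_convergence(m_a, state = hs$run$state, warm = hs$run$warm)
  ees_a <- fit_espvr(m_a, fr, base_run = run_a)$Ees
  expect_lt(abs(ees_a / ees0 - 1), 0.10)
  # reduced maximum force at fixed afterload: clearly lower
  m_f <- hs$model
  m_f$walls$R$sarcomere <- calibrate_contractility(m_f$walls$R$sarcomere, 0.64)
  run_f <- run_to_convergence(m_f, state = hs$run$state, warm = hs$run$warm)
  ees_f <- fit_espvr(m_f, fr, base_run = run_f)$Ees
  expect_lt(ees_f, ees0 * 0.9)
})
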