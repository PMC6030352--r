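test_that("cap metrics match the closed forms", {
  flat <- cap_metrics(0, 2)
  expect_equal(flat$Vm, 0)
  expect_equal(flat$Am, pi * 4)
  expect_equal(flat$Cm, 0)
  hemi <- cap_metrics(1, 1)
  expect_equal(hemi$Vm, 2 * pi / 3)
  expect_equal(hemi$Am, 2 * pi)
  expect_equal(hemi$Cm, 1)
  g <- cap_metrics(1, 2)
  expect_equal(g$Vm, 13 * pi / 6)
  expect_equal(g$Am, 5 * pi)
  expect_equal(g$Cm, 0.4)
  expect_error(cap_metrics(1, 0), "y must")
})

test_that("cap-height inversion round-trips random geometries to 1e-9", {
  expect_equal(solve_cap_height(2 * pi / 3, 1), 1, tolerance = 1e-12)
  expect_equal(solve_cap_height(0, 2), 0, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:50) {
    x <- runif(1, -3, 3); y <- runif(1, 0.5, 4)
    Vm <- cap_metrics(x, y)$Vm
    expect_equal(solve_cap_height(Vm, y), x, tolerance = 1e-9)
  }
})

test_that("fibre strain is zero at reference, exact at e^2, and monotone", {
  expect_equal(fiber_strain(50, 50), 0)
  expect_equal(fiber_strain(exp(2) * 30, 30), 1)
  grid <- seq(10, 100, length.out = 50)
  expect_true(all(diff(fiber_strain(grid, 40)) > 0))
})

test_that("wall tension resolves into axial and radial components on the unit circle", {
  flat <- wall_tension_components(10, 50, 0, 2)
  expect_equal(flat$Tx, 0)
  expect_equal(flat$Ty, flat$Tm)
  hemi <- wall_tension_components(10, 50, 1.5, 1.5)
  expect_equal(hemi$Tx, hemi$Tm)
  expect_equal(hemi$Ty, 0, tolerance = 1e-12)
  zero <- wall_tension_components(0, 50, 1, 2)
  expect_equal(c(zero$Tm, zero$Tx, zero$Ty), c(0, 0, 0))
  # sin^2 + cos^2 = 1 for arbitrary geometry
  t <- wall_tension_components(7, 30, 1.3, 2.2)
  expect_equal((t$Tx / t$Tm)^2 + (t$Ty / t$Tm)^2, 1, tolerance = 1e-12)
})

test_that("symmetric ventricles with an unloaded septum give a flat septum and equal pressures", {
  m <- test_model()
  walls <- m$walls
  sarc <- m$walls$L$sarcomere
  sarc$mu_visc <- 1e-300   # remove rate coupling so the septal wall is unloaded
  st <- sarcomere_state(2.1, 0.5, 0.08)
  walls$L <- wall_segment("lv_free_wall", 40, 60, sarc, st)
  walls$R <- wall_segment("rv_free_wall", 40, 60, sarc, st)
  # septum at slack length: passive zero, no attached bridges
  walls$S <- wall_segment("septum", 20, 40, sarc,
                          sarcomere_state(sarc$Ls_slack, 0, sarc$x0))
  g <- solve_heart(45, 45, walls)
  expect_equal(g$x_S, 0, tolerance = 1e-4)
  expect_equal(g$P_LV, g$P_RV, tolerance = 1e-6 * max(1, g$P_LV))
})

test_that("septal transmural pressure difference obeys the membrane relation", {
  hs <- get_baseline()
  tr <- hs$run$trajectory
  i <- which.max(tr$P_LV)   # peak systole: septum strongly loaded
  walls <- walls_with_state(hs$model,
                            Ls = c(tr$Ls_LW[i], tr$Ls_SW[i], tr$Ls_RW[i]),
                            A = rep(min(max(tr$A_LW[i], 0), 1), 3),
                            xb = c(tr$xb_LW[i], tr$xb_SW[i], tr$xb_RW[i]))
  g <- solve_heart(tr$V_LV[i], tr$V_RV[i], walls,
                   warm_start = c(tr$Vm_S[i], tr$y_junction[i]))
  dP <- 2 * g$Tm_S * g$Cm_S * 7.50062
  expect_equal(g$P_LV - g$P_RV, dP, tolerance = 0.01 * abs(dP))
})

test_that("a closed two-cap sphere satisfies the axial membrane force balance", {
  # two identical hemispherical free walls, negligible septal load: the
  # cavity pressure from the tension formula must equal the pressure
  # implied by the axial equilibrium of each cap, p * pi y^2 = 2 pi y Tx
  m <- test_model()
  sarc <- m$walls$L$sarcomere
  sarc$mu_visc <- 1e-300
  st <- sarcomere_state(2.1, 0.6, 0.08)
  walls <- list(
    L = wall_segment("lv_free_wall", 40, 60, sarc, st),
    S = wall_segment("septum", 1e-3, 40, sarc,
                     sarcomere_state(sarc$Ls_slack, 0, sarc$x0)),
    R = wall_segment("rv_free_wall", 40, 60, sarc, st)
  )
  g <- solve_heart(45, 45, walls)
  for (w in c("L", "R")) {
    Tm <- g[[paste0("Tm_", w)]]
    x <- g[[paste0("x_", w)]]
    sin_a <- 2 * x * g$y / (x^2 + g$y^2)
    p_axial <- abs(2 * Tm * sin_a / g$y) * 7.50062
    p_solver <- if (w == "L") g$P_LV else g$P_RV
    expect_equal(p_solver, p_axial, tolerance = 0.02 * p_solver)
  }
})

test_that("junction residuals at accepted solutions are below 1e-8", {
  hs <- get_baseline()
  tr <- hs$run$trajectory
  for (i in round(seq(1, nrow(tr), length.out = 7))) {
    walls <- walls_with_state(hs$model,
                              Ls = c(tr$Ls_LW[i], tr$Ls_SW[i], tr$Ls_RW[i]),
                              A = rep(min(max(tr$A_LW[i], 0), 1), 3),
                              xb = c(tr$xb_LW[i], tr$xb_SW[i], tr$xb_RW[i]))
    g <- solve_heart(max(tr$V_LV[i], 1), max(tr$V_RV[i], 1), walls,
                     warm_start = c(tr$Vm_S[i], tr$y_junction[i]))
    expect_lt(g$residual, 1e-8)
  }
})

test_that("RV pressure does not decrease with RV volume at a frozen wall state", {
  # scanned at the end-diastolic state: the property expresses passive
  # chamber stiffness in the filling direction
  hs <- get_baseline()
  tr <- hs$run$trajectory
  i <- max(which(tr$q_tv > 0))
  walls <- walls_with_state(hs$model,
                            Ls = c(tr$Ls_LW[i], tr$Ls_SW[i], tr$Ls_RW[i]),
                            A = rep(min(max(tr$A_LW[i], 0), 1), 3),
                            xb = c(tr$xb_LW[i], tr$xb_SW[i], tr$xb_RW[i]))
  warm <- c(tr$Vm_S[i], tr$y_junction[i])
  vols <- seq(max(tr$V_RV[i], 5), max(tr$V_RV[i], 5) + 15, length.out = 8)
  prv <- numeric(0)
  for (v in vols) {
    g <- solve_heart(tr$V_LV[i], v, walls, warm_start = warm)
    warm <- c(g$Vm_S, g$y)
    prv <- c(prv, g$P_RV)
  }
  expect_true(all(diff(prv) > -1e-8))
})

test_that("warm-started and cold-started geometry solves agree", {
  hs <- get_baseline()
  tr <- hs$run$trajectory
  i <- which.max(tr$P_LV)
  walls <- walls_with_state(hs$model,
                            Ls = c(tr$Ls_LW[i], tr$Ls_SW[i], tr$Ls_RW[i]),
                            A = rep(min(max(tr$A_LW[i], 0), 1), 3),
                            xb = c(tr$xb_LW[i], tr$xb_SW[i], tr$xb_RW[i]))
  g_warm <- solve_heart(tr$V_LV[i], tr$V_RV[i], walls,
                        warm_start = c(tr$Vm_S[i], tr$y_junction[i]))
  g_cold <- solve_heart(tr$V_LV[i], tr$V_RV[i], walls)
  expect_equal(g_cold$Vm_S, g_warm$Vm_S, tolerance = 1e-6 * max(1, abs(g_warm$Vm_S)))
  expect_equal(g_cold$y, g_warm$y, tolerance = 1e-6 * g_warm$y)
})

test_that("the passive equilibrium solve yields consistent sarcomere lengths", {
  m <- test_model()
  g <- solve_heart_passive(40, 40, m$walls)
  for (w in c("L", "S", "R")) {
    p <- m$walls[[w]]$sarcomere
    Ls <- g[[paste0("Ls_", w)]]
    expect_equal(Ls, p$Ls_ref * exp(g[[paste0("eps_f_", w)]]) - p$L_SE_iso,
                 tolerance = 1e-9)
  }
  expect_gt(g$P_LV, 0)
  expect_gt(g$P_RV, 0)
})
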