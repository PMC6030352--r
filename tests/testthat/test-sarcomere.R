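p <- sarcomere_params()

test_that("calcium transient starts at the diastolic level, peaks at tau, and is periodic", {
  period <- 60 / 420
  expect_equal(calcium_transient(0, p, period), p$Ca_dia)
  expect_equal(calcium_transient(p$tau_Ca, p, period), p$Ca_dia + p$Ca_amp)
  # tau is the analytic maximum of the chosen form
  grid <- seq(0, period, length.out = 2000)
  expect_lt(max(calcium_transient(grid, p, period)),
            p$Ca_dia + p$Ca_amp + 1e-12)
  expect_equal(calcium_transient(0.03, p, period),
               calcium_transient(0.03 + period, p, period))
  expect_true(all(calcium_transient(grid, p, period) >= p$Ca_dia))
  expect_error(calcium_transient(0.01, p, -1), "period")
})

test_that("cross-bridge kinetics have the analytic steady states", {
  # dA/dt = 0 at A = f perm / (f perm + g), for constant permissiveness,
  # checked on a grid of calcium levels
  for (Ca in c(0.1, 0.3, 0.6, 1.0, 5)) {
    perm <- Ca^p$hill_n / (Ca^p$hill_n + p$Ca50^p$hill_n)
    A_ss <- p$f_attach * perm / (p$f_attach * perm + p$g_detach)
    d <- crossbridge_derivatives(sarcomere_state(2.1, A_ss, p$x0), Ca, 0, p)
    expect_equal(d[["dA"]], 0, tolerance = 1e-12)
    # isometric, steady attachment: distortion fixed point at x0
    expect_equal(d[["dxbar"]], 0, tolerance = 1e-10)
  }
  # pure detachment at zero calcium
  s <- sarcomere_state(2.1, 0.4, 0.05)
  d0 <- crossbridge_derivatives(s, 0, 0, p)
  expect_equal(d0[["dA"]], -p$g_detach * 0.4)
})

test_that("attached fraction stays in [0,1] along integrated trajectories", {
  # forward-Euler trajectory under a strong oscillating drive
  s <- sarcomere_state(2.1, 0.5, p$x0)
  dt <- 1e-4
  for (i in 1:3000) {
    Ca <- calcium_transient((i * dt), p, 60 / 420)
    d <- crossbridge_derivatives(s, Ca, 5 * sin(i * dt * 40), p)
    s$A <- s$A + dt * d[["dA"]]
    s$xbar <- s$xbar + dt * d[["dxbar"]]
  }
  expect_gte(s$A, 0)
  expect_lte(s$A, 1)
})

test_that("active stress is linear in the stiffness scale and vanishes off the overlap tent", {
  s <- sarcomere_state(p$Ls_ref, 0.6, 0.07)
  expect_equal(active_stress(sarcomere_state(p$Ls_ref, 0, 0.07), p), 0)
  p2 <- p; p2$k_stiff2 <- 2 * p$k_stiff2
  expect_equal(active_stress(s, p2), 2 * active_stress(s, p))
  edge <- sarcomere_state(p$Ls_ref + p$overlap_width, 0.9, 0.1)
  expect_equal(active_stress(edge, p), 0)
  expect_equal(overlap_factor(p$Ls_ref, p), 1)
})

test_that("passive stress is zero at slack, linear in the collagen multiplier, and strictly increasing", {
  ps <- passive_stress(p$Ls_slack, p)
  expect_equal(ps$total, 0)
  # doubling the multiplier exactly doubles the collagen component
  Ls <- 2.3
  p2 <- p; p2$con_collagen_mult <- 2
  expect_equal(passive_stress(Ls, p2)$collagen,
               2 * passive_stress(Ls, p)$collagen)
  grid <- seq(p$Ls_slack, p$Ls_slack + 0.6, length.out = 200)
  tot <- passive_stress(grid, p)$total
  expect_true(all(diff(tot) > 0))
  # components are individually non-negative above slack
  expect_true(all(passive_stress(grid, p)$titin >= 0))
  expect_true(all(passive_stress(grid, p)$collagen >= 0))
})

test_that("series element is in equilibrium at the isometric stretch", {
  s <- sarcomere_state(2.1, 0.4, 0.06)
  # choose strain so that e_SE = L_SE_iso exactly
  eps <- log((s$Ls + p$L_SE_iso) / p$Ls_ref)
  fs <- fiber_stress_and_rate(s, eps, p)
  expect_equal(fs$dLs_dt, 0, tolerance = 1e-9)
  expect_equal(fs$sigma_f, fs$sigma_act + fs$sigma_pas, tolerance = 1e-9)
  # stretched series element lengthens the sarcomere
  fs2 <- fiber_stress_and_rate(s, eps + 0.01, p)
  expect_gt(fs2$dLs_dt, 0)
  # with no viscosity the stress is independent of the rate
  p0 <- p; p0$mu_visc <- 1e-300
  expect_equal(fiber_stress_and_rate(s, eps + 0.05, p0)$sigma_f,
               fiber_stress_and_rate(s, eps - 0.05, p0)$sigma_f,
               tolerance = 1e-9)
})

test_that("simulated isometric Fmax matches the closed-form steady state", {
  expect_equal(isometric_fmax(p), isometric_fmax_closed_form(p),
               tolerance = 1e-3)
  # exactly linear in k_stiff2
  p2 <- p; p2$k_stiff2 <- 2 * p$k_stiff2
  expect_equal(isometric_fmax(p2) / isometric_fmax(p), 2, tolerance = 1e-6)
  # increasing in the attachment duty ratio
  p3 <- p; p3$f_attach <- 2 * p$f_attach
  expect_gt(isometric_fmax_closed_form(p3), isometric_fmax_closed_form(p))
})

test_that("active stress decays to below 1% of Fmax within ten detachment time constants", {
  # clamp calcium at the diastolic level (far below Ca50)
  s <- sarcomere_state(p$Ls_ref, p$f_attach / (p$f_attach + p$g_detach), p$x0)
  dt <- 1e-5
  t_end <- 10 / p$g_detach
  for (i in seq_len(round(t_end / dt))) {
    d <- crossbridge_derivatives(s, p$Ca_dia, 0, p)
    s$A <- s$A + dt * d[["dA"]]
    s$xbar <- s$xbar + dt * d[["dxbar"]]
  }
  expect_lt(active_stress(s, p), 0.01 * isometric_fmax_closed_form(p))
})

test_that("contractility calibration reaches the bleomycin and treatment force ratios", {
  expect_identical(calibrate_contractility(p, 1)$k_stiff2, p$k_stiff2)
  q <- calibrate_contractility(p, 0.64)
  expect_equal(isometric_fmax(q) / isometric_fmax(p), 0.64, tolerance = 1e-3)
  q2 <- calibrate_contractility(p, 0.78)
  expect_equal(isometric_fmax(q2) / isometric_fmax(p), 0.78, tolerance = 1e-3)
  expect_error(calibrate_contractility(p, 1.5), "target_ratio")
})

test_that("fibrosis calibration reproduces the passive-stress ratio at the operating length", {
  q <- calibrate_fibrosis(p, 2.7, Ls_op = 2.2)
  expect_equal(passive_stress(2.2, q)$total / passive_stress(2.2, p)$total,
               2.7, tolerance = 1e-9)
  # unattainable below the titin floor
  expect_error(calibrate_fibrosis(p, 1e-6, Ls_op = 2.2), "unattainable")
})

test_that("parameter validation rejects invalid inputs", {
  expect_error(sarcomere_params(Ls_slack = 3), "Ls_slack")
  expect_error(sarcomere_params(hill_n = 0.5), "hill_n")
  expect_error(sarcomere_params(con_collagen_mult = -1), "con_collagen")
  expect_error(sarcomere_params(bogus = 1), "unknown")
  expect_error(sarcomere_state(2.1, 1.4, 0.05), "A must")
})
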