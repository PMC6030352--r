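#' Spherical-cap geometry of a wall segment
#'
#' A wall segment is a spherical cap spanning a junction ring of radius `y`
#' with signed cap height `x` along the left-to-right axis. Returns the signed
#' midwall cap volume, midwall area and signed curvature:
#' `Vm = (pi/6) x (x^2 + 3 y^2)`, `Am = pi (x^2 + y^2)`,
#' `Cm = 2 x / (x^2 + y^2)`.
#'
#' @param x signed cap height (mm)
#' @param y junction radius (mm), `> 0`
#' @return list `Vm` (ul = mm^3), `Am` (mm^2), `Cm` (1/mm)
#' @export
cap_metrics <- function(x, y) {
  if (any(y <= 0)) stop("y must be > 0")
  list(Vm = (pi / 6) * x * (x^2 + 3 * y^2),
       Am = pi * (x^2 + y^2),
       Cm = 2 * x / (x^2 + y^2))
}

#' Invert the cap-volume relation for the cap height
#'
#' Solves `(pi/6) x (x^2 + 3 y^2) = Vm` for the unique real root `x` (the
#' cubic is strictly increasing in `x`), by Newton iteration with an
#' analytic derivative and a bisection fallback.
#'
#' @param Vm signed midwall cap volume (ul)
#' @param y junction radius (mm), `> 0`
#' @return cap height `x` (mm) with residual `< 1e-10 * max(1, |Vm|)`
#' @export
solve_cap_height <- function(Vm, y) {
  if (y <= 0) stop("y must be > 0")
  f <- function(x) (pi / 6) * x * (x^2 + 3 * y^2) - Vm
  fp <- function(x) (pi / 6) * (3 * x^2 + 3 * y^2)
  x <- Vm / ((pi / 2) * y^2)              # linear-term initial guess
  for (i in 1:100) {
    dx <- f(x) / fp(x)
    x <- x - dx
    if (abs(dx) < 1e-15 * max(1, abs(x))) return(x)
  }
  # fallback: guaranteed bracket (f is strictly increasing, unbounded)
  lo <- -1; hi <- 1
  while (f(lo) > 0) lo <- lo * 2
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(lo, hi), tol = 1e-14)$root
}

#' Natural fibre strain from midwall area
#'
#' `epsilon_f = 0.5 * log(Am / Am_ref)`: zero at the reference area and
#' strictly increasing in `Am`.
#'
#' @param Am midwall area (mm^2), `> 0`
#' @param Am_ref reference midwall area (mm^2), `> 0`
#' @return natural strain (dimensionless)
#' @export
fiber_strain <- function(Am, Am_ref) {
  if (any(Am <= 0) || any(Am_ref <= 0)) stop("areas must be > 0")
  0.5 * log(Am / Am_ref)
}

#' Midwall tension and its junction components
#'
#' Representative midwall tension `Tm = sigma_f * Vw / (2 Am)` resolved at
#' the junction ring: `sin a = 2xy/(x^2+y^2)`, `cos a = (y^2-x^2)/(x^2+y^2)`,
#' `Tx = Tm sin a` (axial), `Ty = Tm cos a` (radial).
#'
#' @param sigma_f fibre stress (kPa)
#' @param Vw wall volume (ul)
#' @param x signed cap height (mm)
#' @param y junction radius (mm)
#' @return list `Tm`, `Tx`, `Ty` (kPa mm)
#' @export
wall_tension_components <- function(sigma_f, Vw, x, y) {
  Am <- pi * (x^2 + y^2)
  if (Am <= 0) stop("degenerate cap: Am must be > 0")
  Tm <- sigma_f * Vw / (2 * Am)
  sin_a <- 2 * x * y / (x^2 + y^2)
  cos_a <- (y^2 - x^2) / (x^2 + y^2)
  list(Tm = Tm, Tx = Tm * sin_a, Ty = Tm * cos_a)
}

#' Wall segment constructor
#'
#' @param name one of `"lv_free_wall"`, `"septum"`, `"rv_free_wall"`
#' @param Vw wall volume (ul), `> 0`
#' @param Am_ref reference midwall area (mm^2), `> 0`
#' @param sarcomere [sarcomere_params()]
#' @param state [sarcomere_state()]
#' @return object of class `wall_segment`
#' @export
wall_segment <- function(name, Vw, Am_ref, sarcomere,
                         state = sarcomere_state(sarcomere$Ls_ref, 0, sarcomere$x0)) {
  name <- match.arg(name, c("lv_free_wall", "septum", "rv_free_wall"))
  if (Vw <= 0 || Am_ref <= 0) stop("Vw and Am_ref must be > 0")
  structure(list(name = name, Vw = Vw, Am_ref = Am_ref,
                 sarcomere = sarcomere, state = state),
            class = "wall_segment")
}

# kPa -> mmHg
KPA_TO_MMHG <- 7.50062

#' Passive biventricular equilibrium
#'
#' Static variant of [solve_heart()] used for initialization: cross-bridges
#' detached and each wall's sarcomere at its series-element equilibrium, so
#' the fibre stress responds directly to strain,
#' `sigma(eps) = passive(Ls_ref * exp(eps) - L_SE_iso)`. Returns the
#' geometry plus the equilibrated sarcomere lengths.
#'
#' @inheritParams solve_heart
#' @return list: `Vm_S`, `y`, per-wall `Ls`, `eps_f`, and `P_LV`, `P_RV`
#' @export
solve_heart_passive <- function(V_LV, V_RV, walls, tol = 1e-10,
                                max_iter = 120) {
  VwL <- walls$L$Vw; VwS <- walls$S$Vw; VwR <- walls$R$Vw
  wstress <- function(w, eps) {
    p <- walls[[w]]$sarcomere
    Ls <- p$Ls_ref * exp(eps) - p$L_SE_iso
    if (Ls <= 0) return(NA_real_)
    passive_stress(Ls, p)$total
  }
  r_est_dom <- ((3 / (4 * pi)) * (V_LV + V_RV + VwL + VwS + VwR))^(1 / 3)
  resid <- function(u) {
    Vm_S <- u[1]; y <- u[2]
    if (y < 0.2 * r_est_dom || y > 3 * r_est_dom || abs(Vm_S) > 1e4)
      return(list(r = c(NA_real_, NA_real_), Ts = NA_real_))
    Vm <- c(L = -V_LV - VwL / 2 - VwS / 2 + Vm_S, S = Vm_S,
            R = V_RV + VwR / 2 + VwS / 2 + Vm_S)
    Tx <- 0; Ty <- 0; Ts <- 0
    for (w in c("L", "S", "R")) {
      x <- solve_cap_height(Vm[[w]], y)
      cm <- cap_metrics(x, y)
      eps_f <- fiber_strain(cm$Am, walls[[w]]$Am_ref)
      if (abs(eps_f) > 1.5)
        return(list(r = c(NA_real_, NA_real_), Ts = NA_real_))
      sg <- wstress(w, eps_f)
      if (!is.finite(sg))
        return(list(r = c(NA_real_, NA_real_), Ts = NA_real_))
      tc <- wall_tension_components(sg, walls[[w]]$Vw, x, y)
      Tx <- Tx + tc$Tx; Ty <- Ty + tc$Ty; Ts <- Ts + abs(tc$Tm)
    }
    list(r = c(Tx, Ty), Ts = Ts)
  }
  r_est <- ((3 / (4 * pi)) * (V_LV + V_RV + VwL + VwS + VwR))^(1 / 3)
  best <- c(Inf, 0.15 * V_LV, 0.9 * r_est)
  for (v in seq(-(V_LV + VwL), V_RV + VwR, length.out = 25)) {
    for (yy in seq(0.4 * r_est, 2 * r_est, length.out = 15)) {
      rr0 <- resid(c(v, yy))
      if (!all(is.finite(rr0$r))) next
      sc <- sqrt(sum(rr0$r^2)) / (rr0$Ts + 1e-30)
      if (sc < best[1]) best <- c(sc, v, yy)
    }
  }
  u <- best[2:3]
  rr <- resid(u)
  nr <- sqrt(sum(rr$r^2)) / (rr$Ts + 1e-30)
  r <- rr$r
  for (it in seq_len(max_iter)) {
    if (nr < tol) break
    h1 <- 1e-6 * max(1, abs(u[1])); h2 <- 1e-6 * max(1, abs(u[2]))
    J <- cbind((resid(u + c(h1, 0))$r - r) / h1,
               (resid(u + c(0, h2))$r - r) / h2)
    du <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du)))
      stop("passive equilibrium: singular Jacobian")
    un <- 1 + sqrt(sum(u^2))
    if (sqrt(sum(du^2)) > un) du <- du * un / sqrt(sum(du^2))
    lambda <- 1; ok <- FALSE
    for (bt in 1:40) {
      rt <- resid(u + lambda * du)
      if (all(is.finite(rt$r))) {
        nt <- sqrt(sum(rt$r^2)) / (rt$Ts + 1e-30)
        if (nt < nr) { u <- u + lambda * du; r <- rt$r; nr <- nt; ok <- TRUE; break }
      }
      lambda <- lambda / 2
    }
    if (!ok) {
      if (nr < 1e-8) break
      stop("passive equilibrium failed: scaled residual ", nr)
    }
  }
  out <- list(Vm_S = u[1], y = u[2], scaled_residual = nr)
  Vm <- c(L = -V_LV - VwL / 2 - VwS / 2 + u[1], S = u[1],
          R = V_RV + VwR / 2 + VwS / 2 + u[1])
  for (w in c("L", "S", "R")) {
    x <- solve_cap_height(Vm[[w]], u[2])
    cm <- cap_metrics(x, u[2])
    eps_f <- fiber_strain(cm$Am, walls[[w]]$Am_ref)
    p <- walls[[w]]$sarcomere
    out[[paste0("Ls_", w)]] <- p$Ls_ref * exp(eps_f) - p$L_SE_iso
    out[[paste0("eps_f_", w)]] <- eps_f
    tc <- wall_tension_components(wstress(w, eps_f), walls[[w]]$Vw, x, u[2])
    if (w == "L") out$P_LV <- 2 * abs(tc$Tm * cm$Cm) * KPA_TO_MMHG
    if (w == "R") out$P_RV <- 2 * abs(tc$Tm * cm$Cm) * KPA_TO_MMHG
  }
  out
}

#' Solve the three-segment biventricular geometry
#'
#' Given cavity volumes and the three wall segments (LV free wall, septum,
#' RV free wall) with their current sarcomere states, finds the septal
#' midwall cap volume `Vm_S` and junction radius `y` such that (a) the cap
#' volumes are consistent with the cavity volumes
#' (`Vm_L = -V_LV - Vw_L/2 - Vw_S/2 + Vm_S`,
#' `Vm_R =  V_RV + Vw_R/2 + Vw_S/2 + Vm_S`) and (b) the axial and radial
#' tension sums at the junction ring vanish. Fibre stress for each wall is
#' evaluated from its sarcomere state at the strain implied by the geometry
#' (via [fiber_strain()] and [fiber_stress_and_rate()]).
#'
#' Cavity pressures follow the membrane relation
#' `P = 2 |Tm * Cm| * 7.50062` (kPa mm * 1/mm -> mmHg).
#'
#' @param V_LV,V_RV cavity volumes (ul), `> 0`
#' @param walls list of three [wall_segment()]s named `L`, `S`, `R`
#' @param warm_start optional numeric `c(Vm_S, y)` from a previous solution
#' @param tol residual norm tolerance (kPa mm)
#' @param max_iter Newton iteration bound
#' @return list of class `heart_geometry`: `x_L, x_S, x_R, y, Vm_S`, per-wall
#'   `Am`, `Cm`, `Tm`, `epsilon_f`, `sigma_f`, `dLs_dt`, and `P_LV`, `P_RV`
#'   (mmHg), plus `residual` (the final 2-norm of the tension sums)
#' @export
solve_heart <- function(V_LV, V_RV, walls, warm_start = NULL,
                        tol = 1e-10, max_iter = 80,
                        fallback = c("error", "least_imbalance")) {
  fallback <- match.arg(fallback)
  if (V_LV <= 0 || V_RV <= 0) stop("cavity volumes must be > 0")
  stopifnot(all(c("L", "S", "R") %in% names(walls)))
  VwL <- walls$L$Vw; VwS <- walls$S$Vw; VwR <- walls$R$Vw

  r_est_dom <- ((3 / (4 * pi)) * (V_LV + V_RV + VwL + VwS + VwR))^(1 / 3)
  resid <- function(u) {
    Vm_S <- u[1]; y <- u[2]
    # junction ring commensurate with heart size: excludes the spurious
    # pinch-off (y -> 0) and inflation (y -> inf) attractors
    if (y < 0.2 * r_est_dom || y > 3 * r_est_dom || abs(Vm_S) > 1e4)
      return(list(r = c(NA_real_, NA_real_), Ts = NA_real_))
    Vm_L <- -V_LV - VwL / 2 - VwS / 2 + Vm_S
    Vm_R <-  V_RV + VwR / 2 + VwS / 2 + Vm_S
    Vm <- c(L = Vm_L, S = Vm_S, R = Vm_R)
    Tx <- 0; Ty <- 0; Ts <- 0
    for (w in c("L", "S", "R")) {
      x <- solve_cap_height(Vm[[w]], y)
      cm <- cap_metrics(x, y)
      eps_f <- fiber_strain(cm$Am, walls[[w]]$Am_ref)
      if (abs(eps_f) > 1.5)
        return(list(r = c(NA_real_, NA_real_), Ts = NA_real_))
      fs <- fiber_stress_and_rate(walls[[w]]$state, eps_f, walls[[w]]$sarcomere)
      tc <- wall_tension_components(fs$sigma_f, walls[[w]]$Vw, x, y)
      Tx <- Tx + tc$Tx; Ty <- Ty + tc$Ty; Ts <- Ts + abs(tc$Tm)
    }
    list(r = c(Tx, Ty), Ts = Ts)
  }

  u <- if (!is.null(warm_start) && all(is.finite(warm_start)) && warm_start[2] > 0) {
    as.numeric(warm_start)
  } else {
    # cold start: coarse scan for the basin of the physical root
    r_est <- ((3 / (4 * pi)) * (V_LV + V_RV + VwL + VwS + VwR))^(1 / 3)
    best <- c(Inf, 0.15 * V_LV, 0.9 * r_est)
    for (v in seq(-(V_LV + VwL), V_RV + VwR, length.out = 25)) {
      for (yy in seq(0.4 * r_est, 2 * r_est, length.out = 15)) {
        rr0 <- resid(c(v, yy))
        if (!all(is.finite(rr0$r))) next
        sc <- sqrt(sum(rr0$r^2)) / (rr0$Ts + 1e-30)
        if (sc < best[1]) best <- c(sc, v, yy)
      }
    }
    best[2:3]
  }

  # Newton on the tension-scaled residual (scale invariance removes the
  # false minimum at infinite junction radius where all tensions vanish)
  rr <- resid(u)
  if (!all(is.finite(rr$r))) {
    r_est <- ((3 / (4 * pi)) * (V_LV + V_RV + VwL + VwS + VwR))^(1 / 3)
    u <- c(0.15 * V_LV, 0.9 * r_est)
    rr <- resid(u)
    if (!all(is.finite(rr$r)))
      stop("geometry solver: no valid starting point at V_LV=", V_LV,
           ", V_RV=", V_RV)
  }
  r <- rr$r
  nr <- sqrt(sum(r^2)) / (rr$Ts + 1e-30)
  for (it in seq_len(max_iter)) {
    if (nr < tol) break
    h1 <- 1e-6 * max(1, abs(u[1])); h2 <- 1e-6 * max(1, abs(u[2]))
    J <- cbind((resid(u + c(h1, 0))$r - r) / h1,
               (resid(u + c(0, h2))$r - r) / h2)
    du <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(du) || !all(is.finite(du))) {
      if (fallback == "least_imbalance") break
      stop("geometry solver: singular Jacobian at V_LV=", V_LV,
           ", V_RV=", V_RV)
    }
    # trust region: cap the relative step so iterates stay local
    un <- 1 + sqrt(sum(u^2))
    if (sqrt(sum(du^2)) > un) du <- du * un / sqrt(sum(du^2))
    lambda <- 1
    ok <- FALSE
    for (bt in 1:40) {
      u_try <- u + lambda * du
      if (u_try[2] > 0) {
        rt <- resid(u_try)
        if (all(is.finite(rt$r))) {
          nt <- sqrt(sum(rt$r^2)) / (rt$Ts + 1e-30)
          if (nt < nr) {
            u <- u_try; r <- rt$r; nr <- nt; ok <- TRUE
            break
          }
        }
      }
      lambda <- lambda / 2
    }
    if (!ok) {
      if (nr < 1e-8) break  # stagnated at the FD noise floor; acceptable
      # the exact equilibrium can cease to exist transiently (fold of the
      # junction system); optionally continue on the least-imbalance
      # configuration, mirroring the compiled integrator
      if (fallback == "least_imbalance") break
      stop("geometry solver failed to converge: V_LV=", V_LV, " V_RV=", V_RV,
           " scaled residual=", nr)
    }
    if (it == max_iter && nr >= 1e-8 && fallback == "error")
      stop("geometry solver failed to converge: V_LV=", V_LV, " V_RV=", V_RV,
           " scaled residual=", nr)
  }

  Vm_S <- u[1]; y <- u[2]
  Vm <- c(L = -V_LV - VwL / 2 - VwS / 2 + Vm_S, S = Vm_S,
          R = V_RV + VwR / 2 + VwS / 2 + Vm_S)
  out <- list(y = y, Vm_S = Vm_S, residual = sqrt(sum(r^2)),
              scaled_residual = nr)
  for (w in c("L", "S", "R")) {
    x <- solve_cap_height(Vm[[w]], y)
    cm <- cap_metrics(x, y)
    eps_f <- fiber_strain(cm$Am, walls[[w]]$Am_ref)
    fs <- fiber_stress_and_rate(walls[[w]]$state, eps_f, walls[[w]]$sarcomere)
    tc <- wall_tension_components(fs$sigma_f, walls[[w]]$Vw, x, y)
    out[[paste0("x_", w)]] <- x
    out[[paste0("Am_", w)]] <- cm$Am
    out[[paste0("Cm_", w)]] <- cm$Cm
    out[[paste0("Tm_", w)]] <- tc$Tm
    out[[paste0("eps_f_", w)]] <- eps_f
    out[[paste0("sigma_f_", w)]] <- fs$sigma_f
    out[[paste0("dLs_dt_", w)]] <- fs$dLs_dt
  }
  out$P_LV <- 2 * abs(out$Tm_L * out$Cm_L) * KPA_TO_MMHG
  out$P_RV <- 2 * abs(out$Tm_R * out$Cm_R) * KPA_TO_MMHG
  class(out) <- "heart_geometry"
  out
}
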