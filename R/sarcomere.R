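#' Myofilament parameter set
#'
#' Constructs the parameter list for the reduced cross-bridge myofilament
#' model: a calcium-driven two-state attachment model with mean cross-bridge
#' distortion, a tent-shaped length-overlap factor, exponential titin and
#' collagen passive stress, a linear viscous element and a series element
#' coupling sarcomere length to the wall fibre contour length.
#'
#' Active fibre stress is `k_stiff2 * overlap(Ls) * A * xbar`, so `k_stiff2`
#' (kPa/um) is the model's maximum-force (Fmax) control: the simulated
#' isometric maximal calcium-activated stress is exactly linear in it.
#' Fibrosis acts through `con_collagen_mult`, a dimensionless multiplier on
#' the collagen component of passive stress (1 = control).
#'
#' @param ... named overrides of the default values.
#'
#' @return An object of class `sarcomere_params` (a named list). Fields:
#' \describe{
#'   \item{Ls_ref}{reference sarcomere length (um), optimal overlap}
#'   \item{Ls_slack}{titin slack length (um), `< Ls_ref`}
#'   \item{k_stiff2}{active stiffness scale (kPa/um); the Fmax control}
#'   \item{x0}{power-stroke distortion (um)}
#'   \item{f_attach, g_detach}{cross-bridge attach/detach rates (1/s)}
#'   \item{Ca_dia, Ca_amp}{diastolic and peak-increment calcium (uM)}
#'   \item{tau_Ca}{calcium transient time constant (s)}
#'   \item{Ca50, hill_n}{activation half-point (uM) and Hill steepness}
#'   \item{k_titin, alpha_titin}{titin exponential scale (kPa) and rate (1/um)}
#'   \item{k_collagen, alpha_collagen, Ls_collagen}{collagen exponential scale
#'     (kPa), rate (1/um) and engagement length (um)}
#'   \item{con_collagen_mult}{collagen multiplier (1 = control)}
#'   \item{mu_visc}{viscosity (kPa s/um)}
#'   \item{L_SE_iso}{isometric series-element stretch (um)}
#'   \item{v_max}{unloaded shortening velocity scale (um/s)}
#'   \item{overlap_width}{half-width of the overlap tent (um)}
#' }
#' @export
sarcomere_params <- function(...) {
  p <- list(
    Ls_ref          = 2.25,
    Ls_slack        = 1.80,
    k_stiff2        = 1400,    # kPa/um  (= 1.4 MPa/um)
    x0              = 0.10,
    f_attach        = 950,
    g_detach        = 300,
    Ca_dia          = 0.10,
    Ca_amp          = 0.95,
    tau_Ca          = 0.020,
    Ca50            = 0.55,
    hill_n          = 8,
    k_titin         = 0.000005,
    alpha_titin     = 28.0,
    k_collagen      = 0.010,
    alpha_collagen  = 12.0,
    Ls_collagen     = 2.05,
    con_collagen_mult = 1.0,
    mu_visc         = 0.15,
    L_SE_iso        = 0.02,
    v_max           = 10.0,
    overlap_width   = 0.50,
    k_comp          = 0.02,
    alpha_comp      = 40.0
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown sarcomere parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_sarcomere_params(p)
  structure(p, class = "sarcomere_params")
}

validate_sarcomere_params <- function(p) {
  pos <- c("Ls_ref", "Ls_slack", "k_stiff2", "x0", "f_attach", "g_detach",
           "tau_Ca", "Ca50", "k_titin", "alpha_titin", "k_collagen",
           "alpha_collagen", "Ls_collagen", "mu_visc", "L_SE_iso", "v_max",
           "overlap_width")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("sarcomere parameter '", nm, "' must be strictly positive")
  if (p$hill_n < 1) stop("hill_n must be >= 1")
  if (p$Ls_slack >= p$Ls_ref) stop("Ls_slack must be < Ls_ref")
  if (p$con_collagen_mult < 0) stop("con_collagen_mult must be >= 0")
  if (p$Ca_dia < 0 || p$Ca_amp < 0) stop("calcium levels must be >= 0")
  invisible(p)
}

#' Myofilament dynamic state
#'
#' @param Ls sarcomere length (um)
#' @param A attached cross-bridge fraction (0..1)
#' @param xbar mean cross-bridge distortion (um)
#' @return An object of class `sarcomere_state`.
#' @export
sarcomere_state <- function(Ls, A, xbar) {
  if (Ls <= 0) stop("Ls must be > 0")
  if (A < 0 || A > 1) stop("A must lie in [0, 1]")
  structure(list(Ls = Ls, A = A, xbar = xbar), class = "sarcomere_state")
}

#' Intracellular calcium transient
#'
#' Beat-periodic free-calcium drive: `Ca_dia + Ca_amp * (t/tau) * exp(1 - t/tau)`
#' with `t` the time since the activation onset of the current beat. The form
#' peaks at exactly `Ca_dia + Ca_amp` at `t = tau_Ca` and relaxes toward the
#' diastolic level.
#'
#' @param t_in_beat time since beat onset (s), in `[0, period)`; values outside
#'   are wrapped.
#' @param p [sarcomere_params()]
#' @param period beat period (s)
#' @return calcium concentration (uM)
#' @export
calcium_transient <- function(t_in_beat, p, period) {
  if (period <= 0 || p$tau_Ca <= 0) stop("period and tau_Ca must be > 0")
  t <- t_in_beat %% period
  p$Ca_dia + p$Ca_amp * (t / p$tau_Ca) * exp(1 - t / p$tau_Ca)
}

#' Cross-bridge state derivatives
#'
#' Two-state attachment with calcium permissiveness
#' `perm = Ca^n / (Ca^n + Ca50^n)`:
#' `dA/dt = f*perm*(1-A) - g*A`, and mean-distortion kinetics
#' `dxbar/dt = 0.5*dLs_dt + (f*perm*(1-A)/max(A, eps)) * (x0 - xbar)`,
#' so newly attached bridges pull the mean distortion toward the power-stroke
#' value while filament sliding advects it.
#'
#' @param s [sarcomere_state()]
#' @param Ca calcium (uM), `>= 0`
#' @param dLs_dt sarcomere shortening/lengthening velocity (um/s)
#' @param p [sarcomere_params()]
#' @param eps guard on the attached fraction in the distortion term
#' @return named numeric `c(dA, dxbar)` (1/s, um/s)
#' @export
crossbridge_derivatives <- function(s, Ca, dLs_dt, p, eps = 1e-3) {
  if (Ca < 0) stop("Ca must be >= 0")
  perm <- Ca^p$hill_n / (Ca^p$hill_n + p$Ca50^p$hill_n)
  dA <- p$f_attach * perm * (1 - s$A) - p$g_detach * s$A
  dxbar <- 0.5 * dLs_dt +
    (p$f_attach * perm * (1 - s$A) / max(s$A, eps)) * (p$x0 - s$xbar)
  c(dA = dA, dxbar = dxbar)
}

#' Length-overlap factor
#'
#' Tent function: 1 at `Ls_ref`, falling linearly to 0 at
#' `Ls_ref +/- overlap_width`, clipped at 0.
#'
#' @param Ls sarcomere length (um)
#' @param p [sarcomere_params()]
#' @return overlap in `[0, 1]`
#' @export
overlap_factor <- function(Ls, p) {
  pmax(0, 1 - abs(Ls - p$Ls_ref) / p$overlap_width)
}

#' Active fibre stress
#'
#' `sigma_act = k_stiff2 * overlap(Ls) * A * xbar` (kPa).
#'
#' @inheritParams crossbridge_derivatives
#' @return stress (kPa)
#' @export
active_stress <- function(s, p) {
  p$k_stiff2 * overlap_factor(s$Ls, p) * s$A * s$xbar
}

#' Passive fibre stress (titin + collagen + compressive support)
#'
#' Titin engages above the slack length, collagen above its (longer)
#' engagement length; both are offset exponentials so each component is zero
#' at its own engagement point and strictly increasing beyond it. The
#' collagen component is scaled by `con_collagen_mult` (fibrosis). Below the
#' slack length a compressive-support branch engages (negative stress, the
#' wall resists compression), so total passive stress is continuous and
#' non-decreasing over the whole length range and cavities cannot collapse
#' to zero.
#'
#' @param Ls sarcomere length (um), vectorised
#' @param p [sarcomere_params()]
#' @return list with numeric `titin`, `collagen`, `compression`, `total` (kPa)
#' @export
passive_stress <- function(Ls, p) {
  if (any(Ls <= 0)) stop("Ls must be > 0")
  titin <- ifelse(Ls > p$Ls_slack,
                  p$k_titin * (exp(p$alpha_titin * (Ls - p$Ls_slack)) - 1), 0)
  collagen <- ifelse(Ls > p$Ls_collagen,
                     p$con_collagen_mult * p$k_collagen *
                       (exp(p$alpha_collagen * (Ls - p$Ls_collagen)) - 1), 0)
  compression <- ifelse(Ls < p$Ls_slack,
                        -p$k_comp * (exp(p$alpha_comp * (p$Ls_slack - Ls)) - 1),
                        0)
  list(titin = titin, collagen = collagen, compression = compression,
       total = titin + collagen + compression)
}

#' Total fibre stress and sarcomere length rate
#'
#' The wall fibre contour length is `L_tot = Ls_ref * exp(epsilon_f)`; the
#' series-element stretch is `e_SE = L_tot - Ls`. The sarcomere relaxes
#' toward the isometric stretch `L_SE_iso` at rate
#' `dLs_dt = v_max * (e_SE / L_SE_iso - 1)`, and the transmitted fibre
#' stress is `sigma_act + sigma_pas + mu_visc * dLs_dt`.
#'
#' @param s [sarcomere_state()]
#' @param epsilon_f natural fibre strain of the wall (dimensionless)
#' @param p [sarcomere_params()]
#' @return list with `sigma_f` (kPa), `dLs_dt` (um/s), and components
#'   `sigma_act`, `sigma_pas` (kPa)
#' @export
fiber_stress_and_rate <- function(s, epsilon_f, p) {
  L_tot <- p$Ls_ref * exp(epsilon_f)
  e_SE <- L_tot - s$Ls
  v_raw <- p$v_max * (e_SE / p$L_SE_iso - 1)
  # smooth rate saturation: |dLs/dt| is bounded by a few times the unloaded
  # shortening velocity scale (guards extreme startup transients; deviation
  # from the linear law is < 1% for |v| < 1.5 v_max)
  v_cap <- 6 * p$v_max
  dLs_dt <- v_cap * tanh(v_raw / v_cap)
  s_act <- active_stress(s, p)
  s_pas <- passive_stress(s$Ls, p)$total
  list(sigma_f = s_act + s_pas + p$mu_visc * dLs_dt,
       dLs_dt = dLs_dt, sigma_act = s_act, sigma_pas = s_pas)
}

#' Simulated isometric maximal calcium-activated stress (Fmax)
#'
#' Clamps the sarcomere at `Ls = Ls_ref` under saturating calcium
#' (`100 * Ca50`), integrates the cross-bridge states to steady state and
#' returns the active stress. In this reduced model the steady state has the
#' closed form `k_stiff2 * overlap(Ls_ref) * x0 * f / (f + g)` (see
#' [isometric_fmax_closed_form()]), which serves as an independent check.
#'
#' @param p [sarcomere_params()]
#' @param dt integration step (s)
#' @param t_max bound on the clamp duration (s)
#' @param tol steady-state detection: relative state change per millisecond
#' @return stress (kPa)
#' @export
isometric_fmax <- function(p, dt = 1e-4, t_max = 5, tol = 1e-9) {
  Ca <- 100 * p$Ca50
  perm <- Ca^p$hill_n / (Ca^p$hill_n + p$Ca50^p$hill_n)
  A <- 0; xbar <- p$x0   # start detached; distortion at power stroke
  st <- sarcomere_state(p$Ls_ref, A, xbar)
  t <- 0
  repeat {
    d <- crossbridge_derivatives(st, Ca, 0, p)
    A2 <- st$A + dt * d[["dA"]]
    x2 <- st$xbar + dt * d[["dxbar"]]
    # relative change per ms
    rel <- max(abs(A2 - st$A) / max(abs(A2), 1e-12),
               abs(x2 - st$xbar) / max(abs(x2), 1e-12)) * (1e-3 / dt)
    st$A <- A2; st$xbar <- x2
    t <- t + dt
    if (rel < tol) break
    if (t > t_max) stop("isometric_fmax: no steady state within ", t_max, " s")
  }
  active_stress(st, p)
}

#' Closed-form isometric Fmax of the reduced model
#'
#' Steady state of the two-state attachment model at saturating calcium:
#' `A -> f/(f+g)`, `xbar -> x0`, hence
#' `Fmax = k_stiff2 * overlap(Ls_ref) * x0 * f/(f+g)`.
#'
#' @param p [sarcomere_params()]
#' @return stress (kPa)
#' @export
isometric_fmax_closed_form <- function(p) {
  p$k_stiff2 * overlap_factor(p$Ls_ref, p) * p$x0 *
    p$f_attach / (p$f_attach + p$g_detach)
}

#' Calibrate the maximum-force scale to a target Fmax ratio
#'
#' Rescales `k_stiff2` so that the simulated isometric Fmax of the returned
#' parameter set is `target_ratio` times that of the input set. Because Fmax
#' is exactly linear in `k_stiff2`, the scale equals the target ratio; the
#' result is verified by simulation to 1e-3.
#'
#' @param p control [sarcomere_params()]
#' @param target_ratio desired Fmax ratio in `(0, 1]`
#' @param verify logical; re-simulate both parameter sets to confirm
#' @return calibrated `sarcomere_params`
#' @export
calibrate_contractility <- function(p, target_ratio, verify = TRUE) {
  if (target_ratio <= 0 || target_ratio > 1)
    stop("target_ratio must lie in (0, 1]")
  q <- p
  q$k_stiff2 <- p$k_stiff2 * target_ratio
  if (verify) {
    achieved <- isometric_fmax(q) / isometric_fmax(p)
    if (abs(achieved - target_ratio) > 1e-3)
      stop(sprintf("contractility calibration failed: achieved %.5f, target %.5f",
                   achieved, target_ratio))
  }
  q
}

#' Calibrate the collagen multiplier to a total passive-stress ratio
#'
#' Solves for `con_collagen_mult` such that total passive stress at the
#' operating sarcomere length `Ls_op` is `target_ratio` times the control
#' value. Since the collagen component is linear in the multiplier the
#' solution is closed-form:
#' `m = (target * (titin + collagen) - titin) / collagen`.
#'
#' @param p control [sarcomere_params()]
#' @param target_ratio desired total passive-stress ratio (> 0)
#' @param Ls_op operating sarcomere length (um), default 2.2
#' @return calibrated `sarcomere_params`
#' @export
calibrate_fibrosis <- function(p, target_ratio, Ls_op = 2.2) {
  if (target_ratio <= 0) stop("target_ratio must be > 0")
  ps <- passive_stress(Ls_op, p)
  base_coll <- ps$collagen / p$con_collagen_mult  # un-multiplied component
  if (base_coll <= 0)
    stop("collagen not engaged at Ls_op = ", Ls_op,
         "; fibrosis calibration unattainable")
  m <- (target_ratio * ps$total - ps$titin) / base_coll
  if (m < 0)
    stop("fibrosis calibration unattainable: required multiplier < 0")
  q <- p
  q$con_collagen_mult <- m
  achieved <- passive_stress(Ls_op, q)$total / ps$total
  stopifnot(abs(achieved - target_ratio) < 1e-9 * target_ratio)
  q
}
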