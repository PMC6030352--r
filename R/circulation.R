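#' Lumped-parameter circulation constants
#'
#' Four linear vascular compartments (aorta, systemic veins, pulmonary
#' artery, pulmonary veins) with unstressed volumes, two vascular beds
#' (SVR, PVR), four diode-resistor valves and two venous-return resistances.
#' Units: volumes ul, pressures mmHg, resistances mmHg s/ul, compliances
#' ul/mmHg, heart rate beats/min. Defaults target a healthy ~25-30 g rodent:
#' systolic aortic pressure near 117 mmHg, RV systolic pressure ~21 mmHg,
#' cardiac output ~12-15 ml/min at 420 bpm.
#'
#' @param ... named overrides of the defaults.
#' @return object of class `circulation_params`
#' @export
circulation_params <- function(...) {
  p <- list(
    C_Ao  = 0.90,   # aortic/arterial compliance
    C_SV  = 50,     # systemic venous
    C_PA  = 3.0,    # pulmonary arterial
    C_PV  = 10,      # pulmonary venous
    PVR   = 0.065,
    SVR   = 0.60,
    R_av   = 0.010,
    R_pval = 0.002,
    R_mv   = 0.002,
    R_tv   = 0.002,
    R_ven_s = 0.015,
    R_ven_p = 0.002,
    V0_Ao = 60,
    V0_SV = 700,
    V0_PA = 35,
    V0_PV = 60,
    V_total = 1310,
    HR    = 420
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown circulation parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  for (nm in setdiff(names(p), c("V0_Ao", "V0_SV", "V0_PA", "V0_PV")))
    if (p[[nm]] <= 0) stop("circulation parameter '", nm, "' must be > 0")
  v0sum <- p$V0_Ao + p$V0_SV + p$V0_PA + p$V0_PV
  if (p$V_total <= v0sum)
    stop("V_total must exceed the summed unstressed volumes (", v0sum, " ul)")
  structure(p, class = "circulation_params")
}

#' Time-varying atrial compliance parameters
#'
#' @param C_max diastolic (relaxed) atrial compliance (ul/mmHg)
#' @param C_min contracted atrial compliance (ul/mmHg), `< C_max`
#' @param t_onset contraction onset as fraction of the beat period
#' @param d_a contraction duration as fraction of the period, in (0, 1)
#' @return object of class `atrial_params`
#' @export
atrial_params <- function(C_max = 3.6, C_min = 1.2,
                          t_onset = 0.75, d_a = 0.25) {
  if (!(C_min > 0 && C_min < C_max)) stop("need 0 < C_min < C_max")
  if (!(d_a > 0 && d_a < 1)) stop("need 0 < d_a < 1")
  structure(list(C_max = C_max, C_min = C_min,
                 t_onset = t_onset, d_a = d_a),
            class = "atrial_params")
}

#' Time-varying atrial compliance waveform
#'
#' Relaxed compliance `C_max` outside the contraction window; inside
#' `[t_onset*T, (t_onset+d_a)*T]` a half-cosine dip to `C_min` and back.
#' Continuous, beat-periodic, with range exactly `[C_min, C_max]`. With the
#' default timing the atrial contraction ends exactly at ventricular
#' activation onset (t = 0 of the next beat).
#'
#' @param t_in_beat time since beat onset (s); wrapped into `[0, period)`
#' @param p [atrial_params()]
#' @param period beat period (s)
#' @return compliance (ul/mmHg)
#' @export
atrial_compliance <- function(t_in_beat, p, period) {
  if (period <= 0) stop("period must be > 0")
  t <- t_in_beat %% period
  phase <- t / period
  # window may wrap past 1; evaluate in window-relative phase
  rel <- (phase - p$t_onset) %% 1
  ifelse(rel < p$d_a,
         p$C_max - (p$C_max - p$C_min) * 0.5 * (1 - cos(2 * pi * rel / p$d_a)),
         p$C_max)
}

#' Atrial pressure
#'
#' `P = V / C` with the instantaneous atrial compliance.
#'
#' @param V_atria atrial volume (ul)
#' @param C_atria atrial compliance (ul/mmHg), `> 0`
#' @return pressure (mmHg)
#' @export
atrial_pressure <- function(V_atria, C_atria) {
  if (any(C_atria <= 0)) stop("C_atria must be > 0")
  V_atria / C_atria
}

#' Diode-resistor valve flow
#'
#' `max(P_up - P_down, 0) / R`: forward flow only, continuous at zero
#' pressure difference.
#'
#' @param P_up,P_down upstream/downstream pressures (mmHg)
#' @param R valve resistance (mmHg s/ul), `> 0`
#' @return flow (ul/s)
#' @export
valve_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("R must be > 0")
  pmax(P_up - P_down, 0) / R
}

# State vector layout shared by the R and C derivative paths.
STATE_NAMES <- c("V_Ao", "V_SV", "V_PA", "V_PV", "V_LA", "V_RA", "V_LV", "V_RV",
                 "Ls_LW", "A_LW", "xb_LW",
                 "Ls_SW", "A_SW", "xb_SW",
                 "Ls_RW", "A_RW", "xb_RW")

OUT_NAMES <- c("P_Ao", "P_SV", "P_PA", "P_PV", "P_LA", "P_RA", "P_LV", "P_RV",
               "q_av", "q_pval", "q_mv", "q_tv", "q_sys", "q_pul",
               "q_ven_s", "q_ven_p", "Vm_S", "y_junction")

#' Full-system time derivatives (reference R implementation)
#'
#' Assembles the closed-loop ODE right-hand side: compartment pressures from
#' linear compliances, atrial pressures from the time-varying compliance,
#' ventricular pressures from [solve_heart()], valve and bed flows, volume
#' derivatives as inflow minus outflow (summing to zero identically), and
#' sarcomere state derivatives per wall. This path mirrors the compiled
#' right-hand side used by the integrator and is cross-checked against it in
#' the test suite.
#'
#' @param state named numeric vector in the `STATE_NAMES` layout
#' @param t absolute time (s)
#' @param cp [circulation_params()]
#' @param ap [atrial_params()]
#' @param walls list of three [wall_segment()]s named `L`, `S`, `R`
#' @param warm_start optional geometry warm start `c(Vm_S, y)`
#' @param act_scale multiplier on active stress (0 gives the passive system)
#' @return list `derivatives` (named, same layout), `outputs` (pressures,
#'   flows, geometry), `geometry` (the [solve_heart()] solution)
#' @export
system_derivatives <- function(state, t, cp, ap, walls,
                               warm_start = NULL, act_scale = 1) {
  s <- as.list(state)
  period <- 60 / cp$HR
  t_beat <- t %% period

  # wall states at current lengths; active stress scaled for passive mode
  for (w in c("L", "S", "R")) {
    suff <- c(L = "LW", S = "SW", R = "RW")[[w]]
    ps <- walls[[w]]$sarcomere
    if (act_scale != 1) ps$k_stiff2 <- ps$k_stiff2 * act_scale
    walls[[w]]$sarcomere <- ps
    walls[[w]]$state <- sarcomere_state(
      s[[paste0("Ls_", suff)]],
      min(max(s[[paste0("A_", suff)]], 0), 1),
      s[[paste0("xb_", suff)]])
  }

  # small positive clamp for the geometry solve, mirroring the compiled
  # path; outflow gating keeps the true volumes positive
  geo <- solve_heart(max(s$V_LV, 1), max(s$V_RV, 1), walls,
                     warm_start = warm_start, fallback = "least_imbalance")

  P_Ao <- (s$V_Ao - cp$V0_Ao) / cp$C_Ao
  P_SV <- (s$V_SV - cp$V0_SV) / cp$C_SV
  P_PA <- (s$V_PA - cp$V0_PA) / cp$C_PA
  P_PV <- (s$V_PV - cp$V0_PV) / cp$C_PV
  C_at <- atrial_compliance(t_beat, ap, period)
  P_LA <- atrial_pressure(s$V_LA, C_at)
  P_RA <- atrial_pressure(s$V_RA, C_at)

  # an emptying cavity has nothing left to eject: smooth volume gating of
  # the outlet valves keeps cavity volumes strictly positive
  gL <- if (s$V_LV > 0) s$V_LV^2 / (s$V_LV^2 + 9) else 0
  gR <- if (s$V_RV > 0) s$V_RV^2 / (s$V_RV^2 + 9) else 0
  q_av   <- gL * valve_flow(geo$P_LV, P_Ao, cp$R_av)
  q_pval <- gR * valve_flow(geo$P_RV, P_PA, cp$R_pval)
  q_mv   <- valve_flow(P_LA, geo$P_LV, cp$R_mv)
  q_tv   <- valve_flow(P_RA, geo$P_RV, cp$R_tv)
  q_sys  <- (P_Ao - P_SV) / cp$SVR
  q_pul  <- (P_PA - P_PV) / cp$PVR
  q_ven_s <- (P_SV - P_RA) / cp$R_ven_s
  q_ven_p <- (P_PV - P_LA) / cp$R_ven_p

  dV <- c(
    V_Ao = q_av - q_sys,
    V_SV = q_sys - q_ven_s,
    V_PA = q_pval - q_pul,
    V_PV = q_pul - q_ven_p,
    V_LA = q_ven_p - q_mv,
    V_RA = q_ven_s - q_tv,
    V_LV = q_mv - q_av,
    V_RV = q_tv - q_pval
  )

  Ca <- calcium_transient(t_beat, walls$L$sarcomere, period)
  dsar <- c()
  for (w in c("L", "S", "R")) {
    suff <- c(L = "LW", S = "SW", R = "RW")[[w]]
    dLs <- geo[[paste0("dLs_dt_", w)]]
    Ca_w <- calcium_transient(t_beat, walls[[w]]$sarcomere, period)
    cb <- crossbridge_derivatives(walls[[w]]$state, Ca_w, dLs,
                                  walls[[w]]$sarcomere)
    v <- c(dLs, cb[["dA"]], cb[["dxbar"]])
    names(v) <- paste0(c("Ls_", "A_", "xb_"), suff)
    dsar <- c(dsar, v)
  }

  outputs <- c(P_Ao = P_Ao, P_SV = P_SV, P_PA = P_PA, P_PV = P_PV,
               P_LA = P_LA, P_RA = P_RA, P_LV = geo$P_LV, P_RV = geo$P_RV,
               q_av = q_av, q_pval = q_pval, q_mv = q_mv, q_tv = q_tv,
               q_sys = q_sys, q_pul = q_pul,
               q_ven_s = q_ven_s, q_ven_p = q_ven_p,
               Vm_S = geo$Vm_S, y_junction = geo$y)

  list(derivatives = c(dV, dsar), outputs = outputs, geometry = geo)
}
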