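#' Assemble a full cardiovascular model
#'
#' Bundles circulation constants, atrial waveform parameters, the three wall
#' segments and the simulation protocol into one object consumed by the
#' simulator. Wall volumes and reference midwall areas default to a healthy
#' rodent heart (LV free wall / septum / RV free wall).
#'
#' @param circ [circulation_params()]
#' @param atria [atrial_params()]
#' @param walls optional list of three [wall_segment()]s named `L`, `S`, `R`
#' @param sarc_L,sarc_S,sarc_R per-wall [sarcomere_params()] used when
#'   `walls` is NULL (defaults shared)
#' @param Vw wall volumes (ul), named `L`, `S`, `R`
#' @param Am_ref reference midwall areas (mm^2), named `L`, `S`, `R`
#' @param protocol list of solver/protocol settings; see Details
#'
#' @details Protocol settings: `rtol` (1e-7) and `atol_frac` (1e-9, times
#'   `V_total`) for the integrator, `nsamp` samples per beat (500),
#'   `max_beats` (500), `sv_tol` relative RV/LV stroke-volume mismatch for
#'   convergence (0.01), `edv_tol` relative beat-to-beat end-diastolic volume
#'   change (0.001), `aop_range` homeostasis target for systolic aortic
#'   pressure (c(110, 125) mmHg).
#'
#' @return object of class `rv_model`
#' @export
rv_model <- function(circ = circulation_params(),
                     atria = atrial_params(),
                     walls = NULL,
                     sarc_L = sarcomere_params(),
                     sarc_S = sarcomere_params(),
                     sarc_R = sarcomere_params(k_stiff2 = 850),
                     Vw = c(L = 54, S = 30, R = 16),
                     Am_ref = c(L = 66, S = 23, R = 74),
                     protocol = list()) {
  if (is.null(walls)) {
    walls <- list(
      L = wall_segment("lv_free_wall", Vw[["L"]], Am_ref[["L"]], sarc_L),
      S = wall_segment("septum",       Vw[["S"]], Am_ref[["S"]], sarc_S),
      R = wall_segment("rv_free_wall", Vw[["R"]], Am_ref[["R"]], sarc_R)
    )
  }
  proto <- list(rtol = 1e-7, atol_frac = 1e-9, nsamp = 500, max_beats = 500,
                sv_tol = 0.01, edv_tol = 5e-4, aop_range = c(110, 125))
  proto[names(protocol)] <- protocol
  structure(list(circ = circ, atria = atria, walls = walls,
                 protocol = proto, meta = list(scenario = "baseline")),
            class = "rv_model")
}

# order of the per-wall sarcomere block in the packed parameter vector
SARC_PACK_ORDER <- c("Ls_ref", "Ls_slack", "k_stiff2", "x0", "f_attach",
                     "g_detach", "Ca_dia", "Ca_amp", "tau_Ca", "Ca50",
                     "hill_n", "k_titin", "alpha_titin", "k_collagen",
                     "alpha_collagen", "Ls_collagen", "con_collagen_mult",
                     "mu_visc", "L_SE_iso", "v_max", "overlap_width",
                     "k_comp", "alpha_comp")

#' Pack a model into the flat parameter vector used by the compiled core
#'
#' The layout is fixed and mirrored by the C++ right-hand side; a test
#' asserts the two sides agree on the length.
#'
#' @param model [rv_model()]
#' @param act_scale active-stress multiplier (0 = passive system)
#' @return numeric vector
#' @export
pack_params <- function(model, act_scale = 1) {
  cp <- model$circ; ap <- model$atria
  head <- c(cp$HR,
            cp$C_Ao, cp$C_SV, cp$C_PA, cp$C_PV,
            cp$PVR, cp$SVR,
            cp$R_av, cp$R_pval, cp$R_mv, cp$R_tv, cp$R_ven_s, cp$R_ven_p,
            cp$V0_Ao, cp$V0_SV, cp$V0_PA, cp$V0_PV,
            ap$C_max, ap$C_min, ap$t_onset, ap$d_a,
            act_scale)
  blocks <- unlist(lapply(c("L", "S", "R"), function(w) {
    wl <- model$walls[[w]]
    c(wl$Vw, wl$Am_ref, unlist(wl$sarcomere[SARC_PACK_ORDER]))
  }))
  unname(c(head, blocks))
}

#' Initial state: venous filling with primed arterial windkessels
#'
#' Distributes total blood volume with the venous compartments and heart at
#' a common filling pressure and the two arterial windkessels pre-charged to
#' typical diastolic pressures (a heart that has never beaten into an empty
#' aorta does not exist; priming avoids a violently unphysiological first
#' ejection). Sarcomeres start at the passive biventricular equilibrium
#' ([solve_heart_passive()]) with cross-bridges at their diastolic steady
#' state.
#'
#' @param model [rv_model()]
#' @param P0 venous/atrial filling pressure for the initial split (mmHg)
#' @param P_art initial aortic pressure (mmHg)
#' @param P_pa initial pulmonary artery pressure (mmHg)
#' @return named state vector in the `STATE_NAMES` layout; attribute `warm`
#'   carries the geometry warm start
#' @export
initial_state <- function(model, P0 = 5, P_art = 85, P_pa = 12) {
  cp <- model$circ
  V_LV <- 40; V_RV <- 40
  V_LA <- model$atria$C_max * P0
  V_RA <- model$atria$C_max * P0
  V_Ao <- cp$V0_Ao + cp$C_Ao * P_art
  V_PA <- cp$V0_PA + cp$C_PA * P_pa
  V_PV <- cp$V0_PV + cp$C_PV * P0
  V_SV <- cp$V_total - (V_LV + V_RV + V_LA + V_RA + V_Ao + V_PA + V_PV)
  if (V_SV <= cp$V0_SV * 0.1)
    stop("initial_state: V_total too small for the chosen configuration")

  # sarcomere lengths consistent with the passive geometry: rested
  # cross-bridges with each wall at its series-element equilibrium
  g <- solve_heart_passive(V_LV, V_RV, model$walls)
  Ls <- c(L = g$Ls_L, S = g$Ls_S, R = g$Ls_R)

  A0 <- vapply(c("L", "S", "R"), function(w) {
    p <- model$walls[[w]]$sarcomere
    perm0 <- p$Ca_dia^p$hill_n / (p$Ca_dia^p$hill_n + p$Ca50^p$hill_n)
    p$f_attach * perm0 / (p$f_attach * perm0 + p$g_detach)
  }, numeric(1))

  st <- c(V_Ao, V_SV, V_PA, V_PV, V_LA, V_RA, V_LV, V_RV,
          Ls[["L"]], A0[["L"]], model$walls$L$sarcomere$x0,
          Ls[["S"]], A0[["S"]], model$walls$S$sarcomere$x0,
          Ls[["R"]], A0[["R"]], model$walls$R$sarcomere$x0)
  names(st) <- STATE_NAMES
  attr(st, "warm") <- c(g$Vm_S, g$y)  # geometry warm start for the first beat
  st
}
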