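#' @useDynLib rvfsim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot lm coef setNames residuals runif
#' @importFrom utils write.csv
NULL

TRAJ_NAMES <- c("time_s", STATE_NAMES, OUT_NAMES)

as_trajectory <- function(mat, hr) {
  df <- as.data.frame(mat)
  names(df) <- TRAJ_NAMES
  attr(df, "HR") <- hr
  class(df) <- c("rv_trajectory", class(df))
  df
}

#' Integrate one heart beat
#'
#' Advances the full system over one period `T = 60/HR` with the compiled
#' adaptive RK45 core (relative tolerance `rtol`, absolute tolerance
#' `atol_frac * V_total`), warm-starting the heart-geometry solver between
#' steps, and samples the trajectory at `nsamp` uniform points per beat.
#'
#' @param state named state vector (`STATE_NAMES` layout)
#' @param model [rv_model()]
#' @param t0 absolute start time (s); beat phase is `t mod T`
#' @param act_scale active-stress multiplier (0 = passive system)
#' @param warm geometry warm start `c(Vm_S, y)` or NULL
#' @return list: `state` (end of beat), `trajectory` (data.frame of class
#'   `rv_trajectory`), `warm` (geometry warm start for the next beat)
#' @export
integrate_beat <- function(state, model, t0 = 0, act_scale = 1, warm = NULL) {
  pr <- model$protocol
  parms <- pack_params(model, act_scale = act_scale)
  period <- 60 / model$circ$HR
  if (is.null(warm)) warm <- c(NA_real_, -1)
  res <- c_integrate(unname(state), t0, t0 + period, pr$nsamp, parms, warm,
                     pr$rtol, pr$atol_frac * model$circ$V_total)
  st <- res$state
  names(st) <- STATE_NAMES
  list(state = st, trajectory = as_trajectory(res$traj, model$circ$HR),
       warm = res$warm)
}

#' Reference one-beat integration via deSolve over the pure-R derivatives
#'
#' Slow path used for cross-validation of the compiled core: integrates the
#' same system with [deSolve::lsoda()] calling [system_derivatives()].
#'
#' @inheritParams integrate_beat
#' @param rtol,atol solver tolerances
#' @param nsamp output samples over the beat
#' @return list with `state` at beat end and the deSolve output matrix
#' @export
integrate_beat_r <- function(state, model, t0 = 0, act_scale = 1,
                             rtol = 1e-8, atol = 1e-8, nsamp = 100,
                             warm = NULL) {
  period <- 60 / model$circ$HR
  env <- new.env()
  env$warm <- warm
  f <- function(t, y, parms) {
    names(y) <- STATE_NAMES
    d <- system_derivatives(y, t, model$circ, model$atria, model$walls,
                            warm_start = env$warm, act_scale = act_scale)
    env$warm <- c(d$geometry$Vm_S, d$geometry$y)
    list(unname(d$derivatives))
  }
  times <- seq(t0, t0 + period, length.out = nsamp + 1)
  sol <- deSolve::lsoda(unname(state), times, f, parms = NULL,
                        rtol = rtol, atol = atol)
  st <- sol[nrow(sol), -1]
  names(st) <- STATE_NAMES
  list(state = st, sol = sol)
}

beat_volumes <- function(traj) {
  list(EDV_LV = max(traj$V_LV), ESV_LV = min(traj$V_LV),
       EDV_RV = max(traj$V_RV), ESV_RV = min(traj$V_RV))
}

#' Run the system to a converged periodic state
#'
#' Starting from a passive equilibration phase (active stress off for
#' `passive_beats` beats), integrates beats until the convergence criterion
#' holds: RV versus LV stroke-volume mismatch below `sv_tol` (default 1%)
#' and beat-to-beat change in both end-diastolic volumes below `edv_tol`
#' (default 0.1%). Reports the number of active beats used.
#'
#' @param model [rv_model()]
#' @param state optional starting state; defaults to [initial_state()]
#' @param warm optional geometry warm start
#' @param passive_beats beats of passive relaxation before activation (only
#'   applied when starting from the default initial state)
#' @param max_beats bound on active beats; exceeding it is an error
#' @return list: `trajectory` (last beat), `state`, `warm`, `beats_used`,
#'   `metrics` (per-beat stroke volumes of the last beat), `converged`
#' @export
run_to_convergence <- function(model, state = NULL, warm = NULL,
                               passive_beats = 0,
                               max_beats = model$protocol$max_beats) {
  if (max_beats < 1) stop("max_beats must be >= 1")
  cold <- is.null(state)
  if (cold) {
    state <- initial_state(model)
    if (is.null(warm)) warm <- attr(state, "warm")
  }
  if (cold) {
    if (passive_beats > 0) {
      for (b in seq_len(passive_beats)) {
        r <- integrate_beat(state, model, t0 = 0, act_scale = 0, warm = warm)
        state <- r$state; warm <- r$warm
      }
    }
    # soft start: activation ramps up over a few beats while the
    # windkessels settle toward their working pressures
    for (a in c(0.5, 0.65, 0.8, 0.9, 0.95)) {
      r <- integrate_beat(state, model, t0 = 0, act_scale = a, warm = warm)
      state <- r$state; warm <- r$warm
    }
  }
  prev_edv <- NULL
  traj <- NULL
  beats <- 0
  converged <- FALSE
  sv_mismatch <- NA_real_
  repeat {
    beats <- beats + 1
    if (beats > max_beats)
      stop("run_to_convergence: no convergence within ", max_beats, " beats",
           " (last SV mismatch ", signif(sv_mismatch, 3), ")")
    r <- integrate_beat(state, model, t0 = 0, act_scale = 1, warm = warm)
    state <- r$state; warm <- r$warm; traj <- r$trajectory
    if (max(traj$P_LV, traj$P_RV) > 500 || min(traj$V_LV, traj$V_RV) < 0.05 ||
        !all(is.finite(unlist(state))))
      stop(sprintf(
        "run_to_convergence: unphysiological trajectory at beat %d (PLVmax %.0f, PRVmax %.0f, VLVmin %.2f, VRVmin %.2f)",
        beats, max(traj$P_LV), max(traj$P_RV), min(traj$V_LV), min(traj$V_RV)))
    bv <- beat_volumes(traj)
    sv_lv <- bv$EDV_LV - bv$ESV_LV
    sv_rv <- bv$EDV_RV - bv$ESV_RV
    sv_mismatch <- abs(sv_rv - sv_lv) / sv_lv
    edv <- c(bv$EDV_LV, bv$EDV_RV)
    edv_change <- if (is.null(prev_edv)) Inf else
      max(abs(edv - prev_edv) / prev_edv)
    prev_edv <- edv
    if (sv_mismatch < model$protocol$sv_tol &&
        edv_change < model$protocol$edv_tol) {
      converged <- TRUE
      break
    }
  }
  list(trajectory = traj, state = state, warm = warm, beats_used = beats,
       converged = converged, sv_mismatch = sv_mismatch)
}

systolic_aop <- function(traj) max(traj$P_Ao)

#' Adjust blood volume and SVR to the systolic-pressure target
#'
#' The homeostasis step of the simulation protocol: run the model to
#' convergence and, if the systolic aortic pressure falls outside
#' `aop_range` (default 110-125 mmHg), adjust total blood volume by
#' bisection toward the mid-range target; if the volume bracket is
#' exhausted, adjust SVR the same way. Deterministic given its inputs.
#'
#' @param model [rv_model()]
#' @param v_bracket multiplicative search bracket on `V_total`
#' @param svr_bracket multiplicative search bracket on `SVR`
#' @param max_iter bisection iteration bound per knob
#' @return list: `model` (adjusted), `run` (the converged run at the final
#'   parameters), `aop_sys`, `adjusted` (logical), `iterations`
#' @export
homeostasis_adjust <- function(model, v_bracket = c(0.55, 1.9),
                               svr_bracket = c(0.5, 2.0), max_iter = 25) {
  lo_hi <- model$protocol$aop_range
  target <- mean(lo_hi)
  run <- run_to_convergence(model)
  aop <- systolic_aop(run$trajectory)
  if (aop >= lo_hi[1] && aop <= lo_hi[2])
    return(list(model = model, run = run, aop_sys = aop,
                adjusted = FALSE, iterations = 0))

  iters <- 0
  rerun <- function(m, prev) {
    # carry volume changes through the systemic venous reservoir, then
    # reconverge warm-started from the previous periodic state
    st <- prev$state
    st[["V_SV"]] <- st[["V_SV"]] + (m$circ$V_total - sum(st[1:8]))
    if (st[["V_SV"]] <= 0) stop("homeostasis: venous reservoir exhausted")
    run_to_convergence(m, state = st, warm = prev$warm)
  }

  adjust_knob <- function(model, run, knob, bracket) {
    base <- model$circ[[knob]]
    lo <- bracket[1]; hi <- bracket[2]
    aop <- systolic_aop(run$trajectory)
    for (i in seq_len(max_iter)) {
      if (aop >= lo_hi[1] && aop <= lo_hi[2]) break
      # systolic pressure increases with V_total and with SVR
      if (aop < target) lo <- max(lo, model$circ[[knob]] / base) else
        hi <- min(hi, model$circ[[knob]] / base)
      mult <- (lo + hi) / 2
      model$circ[[knob]] <- base * mult
      run <- rerun(model, run)
      aop <- systolic_aop(run$trajectory)
      iters <<- iters + 1
      if (hi - lo < 1e-4) break
    }
    list(model = model, run = run, aop = aop)
  }

  res <- adjust_knob(model, run, "V_total", v_bracket)
  if (res$aop < lo_hi[1] || res$aop > lo_hi[2])
    res <- adjust_knob(res$model, res$run, "SVR", svr_bracket)
  if (res$aop < lo_hi[1] || res$aop > lo_hi[2])
    stop(sprintf(
      "homeostasis target unreachable: achieved systolic AoP %.1f mmHg", res$aop))
  list(model = res$model, run = res$run, aop_sys = res$aop,
       adjusted = TRUE, iterations = iters)
}

#' Write a trajectory to CSV
#'
#' One row per sample with the documented column header
#' (`time_s`, pressures, volumes, flows, sarcomere lengths).
#'
#' @param traj `rv_trajectory`
#' @param path output file
#' @return invisibly, the path
#' @export
write_trajectory <- function(traj, path) {
  ord <- c("time_s", "P_LV", "P_RV", "P_Ao", "P_PA", "P_PV", "P_SV",
           "P_LA", "P_RA", "V_LV", "V_RV", "V_Ao", "V_SV", "V_PA", "V_PV",
           "V_LA", "V_RA", "q_av", "q_pval", "q_mv", "q_tv",
           "Ls_LW", "Ls_SW", "Ls_RW")
  utils::write.csv(as.data.frame(traj)[, ord], path, row.names = FALSE)
  invisible(path)
}
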