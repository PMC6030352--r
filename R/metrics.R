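#' Per-beat hemodynamic metrics
#'
#' End-diastole is taken at tricuspid (mitral for the LV) valve closure —
#' the last sample of the beat with inflow > 0 — and end-systole at
#' pulmonary (aortic) valve closure, the last sample with outflow > 0.
#' These valve-event definitions are deterministic and unambiguous in a
#' simulated trajectory. `RVSP` is the maximum RV pressure over the beat,
#' `EF = (EDV - ESV)/EDV`, `CO = SV * HR`. The RV diastolic pressure is
#' reported both at end-diastole (`RVDP`) and as the beat minimum
#' (`RVDP_min`).
#'
#' @param traj `rv_trajectory` covering one full beat
#' @return list of class `beat_metrics`: RV fields `RVSP`, `RVDP`,
#'   `RVDP_min`, `EDV`, `ESV`, `SV`, `EF`, `CO` (ul/min), `Pes`; LV
#'   equivalents prefixed `LV_`; `AoP_sys`; `HR`
#' @export
beat_metrics <- function(traj) {
  hr <- attr(traj, "HR")
  if (is.null(hr)) stop("trajectory lacks an HR attribute")
  n <- nrow(traj)
  if (n < 10) stop("trajectory does not cover a full beat")

  last_pos <- function(q) {
    idx <- which(q > 0)
    if (!length(idx)) stop("no valve flow detected; not a complete beat")
    idx[length(idx)]
  }

  ed_rv <- last_pos(traj$q_tv)
  es_rv <- last_pos(traj$q_pval)
  ed_lv <- last_pos(traj$q_mv)
  es_lv <- last_pos(traj$q_av)

  EDV <- traj$V_RV[ed_rv]; ESV <- traj$V_RV[es_rv]
  SV <- EDV - ESV
  EDV_L <- traj$V_LV[ed_lv]; ESV_L <- traj$V_LV[es_lv]
  SV_L <- EDV_L - ESV_L

  m <- list(
    RVSP = max(traj$P_RV),
    RVDP = traj$P_RV[ed_rv],
    RVDP_min = min(traj$P_RV),
    EDV = EDV, ESV = ESV, SV = SV,
    EF = SV / EDV,
    CO = SV * hr,
    Pes = traj$P_RV[es_rv],
    EDP = traj$P_RV[ed_rv],
    LV_SP = max(traj$P_LV),
    LV_EDV = EDV_L, LV_ESV = ESV_L, LV_SV = SV_L,
    LV_EF = SV_L / EDV_L,
    LV_CO = SV_L * hr,
    LV_Pes = traj$P_LV[es_lv],
    AoP_sys = max(traj$P_Ao),
    HR = hr
  )
  class(m) <- "beat_metrics"
  m
}

#' Effective arterial elastance
#'
#' `Ea = Pes / SV` (mmHg/ul): a lumped afterload index.
#'
#' @param Pes end-systolic pressure (mmHg)
#' @param SV stroke volume (ul), `> 0`
#' @return Ea (mmHg/ul)
#' @export
arterial_elastance <- function(Pes, SV) {
  if (any(SV <= 0)) stop("SV must be > 0")
  Pes / SV
}

#' Least-squares line through end-systolic pressure-volume points
#'
#' @param V end-systolic volumes (ul)
#' @param P end-systolic pressures (mmHg)
#' @return list `Ees` (slope, mmHg/ul), `V0` (volume intercept, ul),
#'   `r_squared`
#' @export
fit_espvr_points <- function(V, P) {
  if (length(V) < 2 || length(V) != length(P))
    stop("need >= 2 matched (V, P) points")
  if (length(unique(V)) < 2) stop("degenerate ESPVR fit: collinear volumes")
  fit <- stats::lm(P ~ V)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("ESPVR fit produced a non-positive slope")
  tss <- sum((P - mean(P))^2)
  r2 <- if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1
  list(Ees = slope,
       V0 = -unname(coef(fit)[1]) / slope,
       r_squared = r2)
}

#' Converged runs over a preload series
#'
#' Re-runs the model to convergence at total blood volume scaled by each
#' preload fraction (homeostasis disabled), warm-starting each level from
#' the previous one. Volume is added/removed through the systemic venous
#' reservoir. Used by both the ESPVR and the chamber-compliance fits.
#'
#' @param model [rv_model()]
#' @param fractions preload fractions in `(0.5, 1]`, e.g. `c(1, .95, .9, .85, .8)`
#' @param base_run optional pre-computed converged run of `model` (reused
#'   for the fraction 1.0 level)
#' @return data.frame: one row per fraction with `fraction`, RV `ESV`,
#'   `Pes`, `EDV`, `EDP`, `SV`, `EF`, `CO`
#' @export
preload_series <- function(model, fractions = c(1, 0.95, 0.9, 0.85, 0.8),
                           base_run = NULL) {
  if (length(fractions) < 1) stop("need at least one preload fraction")
  if (any(fractions <= 0.5 | fractions > 1))
    stop("preload fractions must lie in (0.5, 1]")
  fractions <- sort(fractions, decreasing = TRUE)
  if (is.null(base_run)) base_run <- run_to_convergence(model)
  prev <- base_run
  V_base <- model$circ$V_total
  rows <- lapply(fractions, function(fr) {
    if (abs(fr - 1) < 1e-12) {
      run <- base_run
    } else {
      m <- model
      m$circ$V_total <- V_base * fr
      st <- prev$state
      st[["V_SV"]] <- st[["V_SV"]] + (m$circ$V_total - sum(st[1:8]))
      if (st[["V_SV"]] <= 0) stop("preload_series: venous reservoir exhausted")
      run <- run_to_convergence(m, state = st, warm = prev$warm)
    }
    prev <<- run
    bm <- beat_metrics(run$trajectory)
    data.frame(fraction = fr, ESV = bm$ESV, Pes = bm$Pes,
               EDV = bm$EDV, EDP = bm$EDP, SV = bm$SV, EF = bm$EF, CO = bm$CO)
  })
  do.call(rbind, rows)
}

#' End-systolic elastance by multi-preload ESPVR fit
#'
#' Runs converged simulations over the preload series and fits the RV
#' end-systolic pressure-volume line by least squares; `Ees` is the slope.
#'
#' @inheritParams preload_series
#' @return list `Ees`, `V0`, `r_squared`, and the `series` data.frame
#' @export
fit_espvr <- function(model, fractions = c(1, 0.95, 0.9, 0.85, 0.8),
                      base_run = NULL) {
  if (length(fractions) < 3) stop("need >= 3 preload fractions")
  ser <- preload_series(model, fractions, base_run)
  fit <- fit_espvr_points(ser$ESV, ser$Pes)
  c(fit, list(series = ser))
}

#' RV chamber (diastolic) compliance across preloads
#'
#' Least-squares slope of RV end-diastolic volume against end-diastolic
#' pressure over the preload series (ul/mmHg).
#'
#' @inheritParams fit_espvr
#' @param series optional pre-computed [preload_series()] output
#' @return list `compliance` (ul/mmHg), `r_squared`, `series`
#' @export
diastolic_compliance <- function(model, fractions = c(1, 0.95, 0.9, 0.85, 0.8),
                                 base_run = NULL, series = NULL) {
  if (is.null(series)) {
    if (length(fractions) < 2) stop("need >= 2 preload fractions")
    series <- preload_series(model, fractions, base_run)
  }
  if (nrow(series) < 2) stop("need >= 2 preload levels")
  fit <- stats::lm(EDV ~ EDP, data = series)
  tss <- sum((series$EDV - mean(series$EDV))^2)
  list(compliance = unname(coef(fit)[2]),
       r_squared = if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1,
       series = series)
}

#' Fold-change report against a reference metric set
#'
#' For each shared metric reports both conventions explicitly: the ratio
#' `sim/ref` and the fractional change `(sim - ref)/ref`. Published fold
#' changes in the embedded reference tables mix the two conventions, so
#' reports always carry both and never silently pick one.
#'
#' @param sim,ref named lists or vectors of metrics with matching keys
#' @return data.frame with `metric`, `sim`, `ref`, `ratio`,
#'   `fractional_change`
#' @export
fold_change_report <- function(sim, ref) {
  sim <- unlist(sim); ref <- unlist(ref)
  missing <- setdiff(names(sim), names(ref))
  if (length(missing))
    stop("reference lacks metric(s): ", paste(missing, collapse = ", "))
  keys <- names(sim)
  data.frame(metric = keys,
             sim = unname(sim[keys]),
             ref = unname(ref[keys]),
             ratio = unname(sim[keys] / ref[keys]),
             fractional_change = unname((sim[keys] - ref[keys]) / ref[keys]),
             row.names = NULL)
}
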