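#' Recompute the study's headline quantities from scratch
#'
#' Runs the complete in-silico protocol: homeostasis-adjusted baseline,
#' the pressure-overload, full-disease and treatment arms (each to
#' convergence, inheriting the adjusted volume and resistance), the
#' multi-preload end-systolic elastance fits, and the two cellular
#' calibrations. Deterministic; used by both the acceptance test block and
#' `scripts/acceptance.R`.
#'
#' @param model baseline [rv_model()]
#' @param preload_fractions fractions for the elastance fits
#' @return list of named numeric quantities (percentages and ratios on the
#'   scale conventionally reported) plus a `detail` list with the underlying
#'   runs and metrics
#' @export
acceptance_quantities <- function(model = rv_model(),
                                  preload_fractions = c(1, 0.95, 0.9, 0.85, 0.8)) {
  hs <- homeostasis_adjust(model)
  base <- hs$model
  brun <- hs$run
  bb <- beat_metrics(brun$trajectory)
  ees_base <- fit_espvr(base, preload_fractions, base_run = brun)

  run_arm <- function(name) {
    m <- apply_scenario(base, build_scenario(name))
    run <- run_to_convergence(m, state = brun$state, warm = brun$warm)
    list(model = m, run = run, metrics = beat_metrics(run$trajectory))
  }
  po  <- run_arm("pressure_overload")
  rvf <- run_arm("rvf_full")
  a6  <- run_arm("a6_rescue")

  ees_po  <- fit_espvr(po$model, preload_fractions, base_run = po$run)
  ees_rvf <- fit_espvr(rvf$model, preload_fractions, base_run = rvf$run)

  # cellular calibrations, evaluated by re-simulation
  ctrl <- base$walls$R$sarcomere
  cal_f <- calibrate_contractility(ctrl, 0.64, verify = FALSE)
  fmax_ratio_pct <- 100 * isometric_fmax(cal_f) / isometric_fmax(ctrl)
  cal_c <- calibrate_fibrosis(ctrl, 2.7, Ls_op = 2.2)
  passive_ratio <- passive_stress(2.2, cal_c)$total /
    passive_stress(2.2, ctrl)$total

  list(
    co_drop_po_pct   = 100 * (bb$CO - po$metrics$CO) / bb$CO,
    ees_drop_po_pct  = 100 * (1 - ees_po$Ees / ees_base$Ees),
    ees_drop_rvf_pct = 100 * (1 - ees_rvf$Ees / ees_base$Ees),
    ef_gain_a6_pct   = 100 * (a6$metrics$EF - rvf$metrics$EF) / rvf$metrics$EF,
    co_gain_a6_pct   = 100 * (a6$metrics$CO - rvf$metrics$CO) / rvf$metrics$CO,
    aop_sys          = hs$aop_sys,
    fmax_ratio_pct   = fmax_ratio_pct,
    passive_ratio    = passive_ratio,
    detail = list(baseline = list(model = base, run = brun, metrics = bb,
                                  espvr = ees_base),
                  pressure_overload = c(po, list(espvr = ees_po)),
                  rvf_full = c(rvf, list(espvr = ees_rvf)),
                  a6_rescue = a6)
  )
}
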