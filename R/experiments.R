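SCENARIO_NAMES <- c("baseline", "pressure_overload", "po_fibrosis",
                    "rvf_full", "po_fmax_only", "a6_rescue")

#' Build a named perturbation scenario
#'
#' Multiplicative perturbations relative to the healthy baseline:
#' \describe{
#'   \item{baseline}{all neutral}
#'   \item{pressure_overload}{PVR x1.96, pulmonary artery compliance x0.70,
#'     RV free-wall hypertrophy (wall volume x`rv_mass_mult`)}
#'   \item{po_fibrosis}{pressure overload plus total RV passive stress
#'     calibrated to x2.7 of control at the operating sarcomere length}
#'   \item{rvf_full}{po_fibrosis plus RV Fmax reduced to 64% of control}
#'   \item{po_fmax_only}{rvf_full without the fibrosis component}
#'   \item{a6_rescue}{rvf_full afterload, hypertrophy and fibrosis with
#'     Fmax restored to the treatment level (default 78% of control, a
#'     fractional-change reading of the published stiffness factor; this
#'     level is an interpretation, not a measured force ratio, and is
#'     configurable)}
#' }
#' Cellular changes (fibrosis, Fmax) apply to the RV free wall only; LV
#' free-wall and septal parameters stay at baseline in every scenario.
#' The published per-parameter stiffness/collagen factors are carried in
#' the scenario metadata for traceability; calibration is driven by the
#' force and passive-stress ratios.
#'
#' @param name one of `r paste(SCENARIO_NAMES, collapse = ", ")`
#' @param rv_mass_mult RV hypertrophy wall-volume multiplier (the magnitude
#'   is a package default; no published value)
#' @param a6_fmax_ratio Fmax target for the treatment arm
#' @return object of class `rv_scenario`
#' @export
build_scenario <- function(name, rv_mass_mult = 1.15, a6_fmax_ratio = 0.78) {
  if (!name %in% SCENARIO_NAMES)
    stop("unknown scenario '", name, "'; expected one of: ",
         paste(SCENARIO_NAMES, collapse = ", "))
  sc <- list(name = name, pvr_mult = 1, cpa_mult = 1, rv_mass_mult = 1,
             passive_force_target_ratio = 1, fmax_target_ratio = 1,
             applies_to = "rv_free_wall",
             metadata = list(published_kstiff2_factor = NA_real_,
                             published_con_collagen_factor = NA_real_))
  po <- function(s) {
    s$pvr_mult <- 1.96; s$cpa_mult <- 0.70; s$rv_mass_mult <- rv_mass_mult
    s
  }
  fib <- function(s) {
    s$passive_force_target_ratio <- 2.7
    s$metadata$published_con_collagen_factor <- 1.69
    s
  }
  fmax <- function(s, ratio, factor) {
    s$fmax_target_ratio <- ratio
    s$metadata$published_kstiff2_factor <- factor
    s
  }
  sc <- switch(name,
    baseline = sc,
    pressure_overload = po(sc),
    po_fibrosis = fib(po(sc)),
    rvf_full = fmax(fib(po(sc)), 0.64, 0.46),
    po_fmax_only = fmax(po(sc), 0.64, 0.46),
    a6_rescue = fmax(fib(po(sc)), a6_fmax_ratio, 0.22)
  )
  structure(sc, class = "rv_scenario")
}

#' Apply a scenario to a model
#'
#' Returns a perturbed copy of the model. Circulation changes scale PVR and
#' pulmonary artery compliance; hypertrophy scales the RV free-wall volume;
#' fibrosis calibrates the RV collagen multiplier to the passive-stress
#' target at `Ls_op`; the Fmax target calibrates the RV active-stiffness
#' scale. LV free-wall and septal parameters are never touched.
#'
#' @param model baseline [rv_model()]
#' @param scenario [build_scenario()] output
#' @param Ls_op operating sarcomere length for the fibrosis calibration (um)
#' @return perturbed `rv_model`
#' @export
apply_scenario <- function(model, scenario, Ls_op = 2.2) {
  stopifnot(inherits(scenario, "rv_scenario"))
  m <- model
  m$circ$PVR <- m$circ$PVR * scenario$pvr_mult
  m$circ$C_PA <- m$circ$C_PA * scenario$cpa_mult
  m$walls$R$Vw <- m$walls$R$Vw * scenario$rv_mass_mult
  if (scenario$passive_force_target_ratio != 1)
    m$walls$R$sarcomere <- calibrate_fibrosis(
      m$walls$R$sarcomere, scenario$passive_force_target_ratio, Ls_op = Ls_op)
  if (scenario$fmax_target_ratio != 1)
    m$walls$R$sarcomere <- calibrate_contractility(
      m$walls$R$sarcomere, scenario$fmax_target_ratio)
  m$meta$scenario <- scenario$name
  stopifnot(identical(m$walls$L, model$walls$L),
            identical(m$walls$S, model$walls$S))
  m
}

scenario_metric_set <- function(bm, ea, ees = NULL) {
  out <- list(RVSP = bm$RVSP, EDV = bm$EDV, ESV = bm$ESV, SV = bm$SV,
              EF = bm$EF, CO = bm$CO, Pes = bm$Pes, Ea = ea,
              AoP_sys = bm$AoP_sys)
  if (!is.null(ees)) {
    out$Ees <- ees$Ees
    out$coupling <- ees$Ees / ea
  }
  out
}

#' Run the full scenario suite
#'
#' Homeostasis (blood volume, then SVR, targeting systolic aortic pressure
#' 110-125 mmHg) is applied to the baseline; by default the perturbed
#' scenarios inherit the adjusted volume and resistance so that preload
#' effects of RV failure are not masked (per-scenario homeostasis is
#' available via `homeostasis = "per_scenario"`; reports state which mode
#' ran). Each scenario is run to convergence warm-started from the baseline
#' periodic state, and metrics are normalized to baseline; the treatment
#' arm is additionally normalized to the full-disease arm.
#'
#' @param names scenarios to run (baseline is always included)
#' @param model optional baseline model (defaults to [rv_model()])
#' @param with_ees if TRUE also fit end-systolic elastance per scenario
#'   (multi-preload series; slower)
#' @param homeostasis `"baseline_only"` (default) or `"per_scenario"`
#' @param preload_fractions fractions for the Ees fits
#' @return list of class `scenario_suite`: per-scenario entries with
#'   `metrics`, `fold_vs_baseline`, the treatment arm's `fold_vs_rvf`,
#'   `runs` (converged runs), `homeostasis_mode`, `baseline_model`
#' @export
run_scenario_suite <- function(names = SCENARIO_NAMES, model = rv_model(),
                               with_ees = FALSE,
                               homeostasis = c("baseline_only", "per_scenario"),
                               preload_fractions = c(1, 0.95, 0.9, 0.85, 0.8)) {
  homeostasis <- match.arg(homeostasis)
  bad <- setdiff(names, SCENARIO_NAMES)
  if (length(bad)) stop("unknown scenario(s): ", paste(bad, collapse = ", "))
  names <- union("baseline", names)

  hs <- homeostasis_adjust(model)
  base_model <- hs$model
  base_run <- hs$run

  results <- list()
  for (nm in names) {
    if (nm == "baseline") {
      m <- base_model; run <- base_run
    } else {
      m <- apply_scenario(base_model, build_scenario(nm))
      if (homeostasis == "per_scenario") {
        h <- homeostasis_adjust(m)
        m <- h$model; run <- h$run
      } else {
        run <- run_to_convergence(m, state = base_run$state,
                                  warm = base_run$warm)
      }
    }
    bm <- beat_metrics(run$trajectory)
    ea <- arterial_elastance(bm$Pes, bm$SV)
    ees <- if (with_ees) fit_espvr(m, preload_fractions, base_run = run)
    results[[nm]] <- list(model = m, run = run,
                          metrics = scenario_metric_set(bm, ea, ees),
                          espvr = ees)
  }

  base_metrics <- results$baseline$metrics
  for (nm in names(results)) {
    keys <- intersect(names(results[[nm]]$metrics), names(base_metrics))
    results[[nm]]$fold_vs_baseline <-
      fold_change_report(results[[nm]]$metrics[keys], base_metrics[keys])
  }
  if (all(c("a6_rescue", "rvf_full") %in% names(results))) {
    keys <- intersect(names(results$a6_rescue$metrics),
                      names(results$rvf_full$metrics))
    results$a6_rescue$fold_vs_rvf <-
      fold_change_report(results$a6_rescue$metrics[keys],
                         results$rvf_full$metrics[keys])
  }
  structure(list(scenarios = results, homeostasis_mode = homeostasis,
                 baseline_model = base_model),
            class = "scenario_suite")
}

#' Fmax sweep at baseline afterload
#'
#' Runs converged simulations at `n` Fmax target ratios evenly spaced
#' between the full-disease level (0.64) and control (1.0), with PVR and
#' pulmonary artery compliance at baseline, and fits CO and EF against the
#' Fmax ratio by least squares.
#'
#' @param n number of Fmax levels (>= 3), default 5
#' @param model optional baseline model
#' @param base optional pre-computed `homeostasis_adjust()` result to reuse
#' @return list: `table` (fmax_ratio, CO, EF), `fit_CO` and `fit_EF`
#'   (slope, intercept, r_squared)
#' @export
fmax_sweep <- function(n = 5, model = rv_model(), base = NULL) {
  if (n < 3) stop("n must be >= 3")
  if (is.null(base)) base <- homeostasis_adjust(model)
  ratios <- seq(0.64, 1.0, length.out = n)
  rows <- lapply(ratios, function(r) {
    m <- base$model
    if (r != 1)
      m$walls$R$sarcomere <- calibrate_contractility(m$walls$R$sarcomere, r)
    run <- run_to_convergence(m, state = base$run$state, warm = base$run$warm)
    bm <- beat_metrics(run$trajectory)
    data.frame(fmax_ratio = r, CO = bm$CO, EF = bm$EF)
  })
  tab <- do.call(rbind, rows)
  lin <- function(yname) {
    fit <- stats::lm(tab[[yname]] ~ tab$fmax_ratio)
    tss <- sum((tab[[yname]] - mean(tab[[yname]]))^2)
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = if (tss > 0) 1 - sum(residuals(fit)^2) / tss else 1)
  }
  list(table = tab, fit_CO = lin("CO"), fit_EF = lin("EF"))
}

#' Treatment-arm comparison: restored Fmax versus full disease
#'
#' Runs the full-disease and treatment scenarios and reports the change in
#' EF, CO, Ea, RVSP, Ees and ventricular-vascular coupling of the treatment
#' arm relative to the disease arm (both conventions).
#'
#' @param model optional baseline model
#' @param suite optional pre-computed [run_scenario_suite()] result holding
#'   `rvf_full` and `a6_rescue` with Ees fits
#' @return list: `report` (fold-change data.frame), `suite`
#' @export
a6_rescue <- function(model = rv_model(), suite = NULL) {
  if (is.null(suite))
    suite <- run_scenario_suite(c("rvf_full", "a6_rescue"), model,
                                with_ees = TRUE)
  rep <- suite$scenarios$a6_rescue$fold_vs_rvf
  if (is.null(rep)) stop("suite lacks the rvf_full/a6_rescue pair")
  list(report = rep, suite = suite)
}

#' Seeded random scenarios for property testing
#'
#' Uniform sampling of perturbation multipliers within physiological
#' ranges; deterministic for a given seed.
#'
#' @param seed integer RNG seed
#' @param n number of scenarios, `>= 1`
#' @param ranges named list of 2-vectors: `pvr_mult`, `cpa_mult`,
#'   `passive_ratio`, `fmax_ratio`
#' @return list of `rv_scenario` objects
#' @export
generate_random_scenarios <- function(seed, n,
                                      ranges = list(pvr_mult = c(1, 3),
                                                    cpa_mult = c(0.5, 1),
                                                    passive_ratio = c(1, 3),
                                                    fmax_ratio = c(0.4, 1))) {
  if (n < 1) stop("n must be >= 1")
  need <- c("pvr_mult", "cpa_mult", "passive_ratio", "fmax_ratio")
  if (!all(need %in% names(ranges)))
    stop("ranges must name: ", paste(need, collapse = ", "))
  for (nm in need) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] >= r[2] || r[1] <= 0)
      stop("invalid range for ", nm)
  }
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sc <- build_scenario("baseline")
    sc$name <- paste0("random_", i)
    sc$pvr_mult <- stats::runif(1, ranges$pvr_mult[1], ranges$pvr_mult[2])
    sc$cpa_mult <- stats::runif(1, ranges$cpa_mult[1], ranges$cpa_mult[2])
    sc$passive_force_target_ratio <-
      stats::runif(1, ranges$passive_ratio[1], ranges$passive_ratio[2])
    sc$fmax_target_ratio <-
      stats::runif(1, ranges$fmax_ratio[1], ranges$fmax_ratio[2])
    sc
  })
}

#' Embedded experimental reference tables
#'
#' Published hemodynamic reference values (control, disease and treated
#' columns with printed fold changes) and the published simulation
#' parameter factors, shipped as plain TSV files. Values are carried
#' verbatim for report generation; the printed fold-change column mixes
#' ratio and fractional-change conventions, which is why
#' [fold_change_report()] always emits both.
#'
#' @return list of two data.frames: `hemodynamics`, `parameters`
#' @export
reference_tables <- function() {
  dir <- system.file("extdata", package = "rvfsim")
  list(
    hemodynamics = utils::read.delim(file.path(dir, "reference_hemodynamics.tsv"),
                                     check.names = FALSE),
    parameters = utils::read.delim(file.path(dir, "reference_parameters.tsv"),
                                   check.names = FALSE)
  )
}
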