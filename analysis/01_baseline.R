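#!/usr/bin/env Rscript
# Baseline rodent run: homeostasis-adjusted converged beat, trajectory CSV
# and metrics JSON. The baseline defines the reference state every disease
# arm is normalized against.

library(rvfsim)

out_dir <- "results/baseline"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- parse_config()
model <- model_from_config(cfg)
write_resolved_config(cfg, out_dir)

hs <- homeostasis_adjust(model)
run <- hs$run
bm <- beat_metrics(run$trajectory)

cat(sprintf(
  "baseline converged in %d beats (SV mismatch %.2f%%)\n",
  run$beats_used, 100 * run$sv_mismatch))
cat(sprintf(
  "systolic AoP %.1f mmHg (homeostasis %s), RVSP %.1f mmHg, EF %.2f, CO %.1f ml/min\n",
  hs$aop_sys, if (hs$adjusted) "adjusted" else "already in range",
  bm$RVSP, bm$EF, bm$CO / 1000))

write_trajectory(run$trajectory, file.path(out_dir, "trajectory.csv"))
metrics <- c(bm[setdiff(names(bm), "HR")],
             list(HR = bm$HR, Ea = arterial_elastance(bm$Pes, bm$SV),
                  beats_used = run$beats_used,
                  V_total = hs$model$circ$V_total,
                  SVR = hs$model$circ$SVR))
jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                     auto_unbox = TRUE, digits = NA)
cat("wrote", out_dir, "\n")
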