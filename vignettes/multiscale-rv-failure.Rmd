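---
title: "A multiscale model of right ventricular pressure overload and failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale model of right ventricular pressure overload and failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rvfsim` couples a reduced cross-bridge myofilament model to a
three-wall-segment (TriSeg-style) biventricular heart inside a closed-loop
lumped-parameter circulation, tuned to a healthy rodent at 420 beats/min.
Its purpose is an in-silico pressure-overload study: impose the published
multiplicative perturbations of bleomycin-type pulmonary hypertension
(pulmonary vascular resistance x1.96, pulmonary artery compliance x0.70,
right ventricular hypertrophy, fibrosis raising total passive fibre stress
to x2.7 of control at 2.2 um, and maximum calcium-activated force reduced
to 64% of control), and quantify which cellular change drives the
organ-level failure phenotype. A treatment arm restores the force scale to
78% of control with everything else left diseased.

## The myofilament model

Each wall carries one representative sarcomere with three state variables:
sarcomere length $L_s$, attached cross-bridge fraction $A$, and mean
cross-bridge distortion $\bar{x}$. A beat-periodic calcium drive
$\mathrm{Ca}(t) = \mathrm{Ca}_{dia} + \mathrm{Ca}_{amp}\,(t/\tau)e^{1-t/\tau}$
sets the permissive fraction through a Hill function,
$\phi = \mathrm{Ca}^n / (\mathrm{Ca}^n + \mathrm{Ca}_{50}^n)$, and the
attachment kinetics are first order,
$\dot A = f\,\phi\,(1-A) - g\,A$. Newly attached bridges carry the
power-stroke distortion $x_0$ while filament sliding advects the mean:
$\dot{\bar{x}} = \tfrac12 \dot L_s + \frac{f\phi(1-A)}{\max(A,\epsilon)}(x_0 - \bar{x})$.
Active stress is $\sigma_{act} = k_{stiff,2}\,\mathrm{ov}(L_s)\,A\,\bar{x}$
with a tent-shaped overlap factor equal to 1 at the reference length and
zero at the reference plus or minus the overlap width. $k_{stiff,2}$ is the
model's maximum-force (Fmax) control: the simulated isometric
saturating-calcium force equals $k_{stiff,2}\,\mathrm{ov}(L_{s,ref})\,x_0\,f/(f+g)$
exactly, so force calibration is an exact rescaling and the published 64%
and 78% force targets are met to machine precision
(`calibrate_contractility()`).

Passive stress decomposes into a titin exponential engaging above the slack
length and a collagen exponential engaging later (2.05 um); the collagen
term carries the fibrosis multiplier. Below slack a compressive-support
branch engages (negative stress) so a wall cannot be compressed
indefinitely; total passive stress is therefore continuous and
non-decreasing over the whole length range, and zero exactly at slack.
Fibrosis is imposed by solving for the collagen multiplier that makes total
passive stress at the 2.2 um operating length reach the target ratio
(`calibrate_fibrosis()`); the published per-parameter collagen factor is
retained as scenario metadata only, because the force-level targets are
what the study states as outcomes.

A series element couples the sarcomere to the wall: the fibre contour
length is $L_{tot} = L_{s,ref}e^{\varepsilon_f}$, the series stretch
$e_{SE} = L_{tot} - L_s$, and the sarcomere relaxes toward the isometric
stretch at rate $\dot L_s = v_{max}(e_{SE}/L_{SE,iso} - 1)$, smoothly
saturated at six times $v_{max}$ (the saturation deviates from the linear
law by under 1% below 1.5 $v_{max}$ and only bounds extreme startup
transients). Transmitted fibre stress is
$\sigma_f = \sigma_{act} + \sigma_{pas} + \mu\,\dot L_s$; the viscous
coefficient doubles as the instantaneous stiffness coupling wall strain to
stress, which damps ejection transients.

Default rates ($f = 950\,s^{-1}$, $g = 300\,s^{-1}$, $x_0 = 0.1$ um) were
chosen so that (i) the distortion recovery rate — which at the cross-bridge
steady state equals $g$ — keeps $\bar{x}$ within about 10% of $x_0$ during
diastolic lengthening (the ratio $\tfrac12|\dot L_s|/(g\,x_0)$ sets both
the early-systolic force overshoot and the force-velocity depletion), and
(ii) relaxation is complete well inside the 143 ms beat. The calcium
transient uses a high Hill coefficient (n = 8) so activation is plateau-like
over about 55 ms: the end-systolic activation state is then locked to the
activation cutoff rather than to valve-closure timing, which keeps the
end-systolic elastance estimate approximately load-independent. The wall
stiffness scale differs per wall (1.4 MPa/um for the left free wall and
septum, 0.85 MPa/um for the right free wall): with a shared scale the thin
right wall is disproportionately strong relative to its trivial afterload,
ejecting to unphysiologically small volumes and producing an end-systolic
elastance an order of magnitude above measured rodent values. The
wall-specific scale puts the baseline right ventricle at an ejection
fraction near 0.6 and an elastance of ~1.6 mmHg/ul.

## The heart and circulation

The two ventricles are three spherical-cap wall segments sharing a junction
ring: cap volume, midwall area and curvature follow the standard closed
forms, fibre strain is $\tfrac12\ln(A_m/A_{m,ref})$, midwall tension is
$T_m = \sigma_f V_w / (2A_m)$, and the solver finds the septal cap volume
and junction radius that zero the axial and radial tension sums. Cavity
pressures follow the membrane relation $P = 2|T_m C_m|$ (converted to
mmHg). The septal cap height is free to change sign, so septal flattening
and leftward shift under right-sided overload emerge naturally. Thin-wall
tension is used without curvature-correction terms, keeping the junction
system two-by-two; this is a deliberate fidelity trade-off.

The circulation has four linear compartments (aorta, systemic veins,
pulmonary artery, pulmonary veins) with unstressed volumes, diode-resistor
valves without inertance or regurgitation, systemic and pulmonary beds, and
two atria with the time-varying compliance waveform: relaxed compliance
outside the contraction window and a half-cosine dip to the contracted
value inside it, timed so atrial contraction ends exactly at ventricular
activation onset. Atrial pressure is volume over instantaneous compliance.
The waveform numbers (maximum-to-minimum ratio 3, duration one quarter of
the beat) are fitted defaults, not published values.

Because the valves have no inertance, outlet valve resistances are chosen
large enough to bound peak flows near physiological values; an emptying
cavity also has its outflow smoothly gated to zero (scale 3 ul), which
guarantees positive cavity volumes without hard clamps.

## Numerical realization

The full state (eight volumes plus three sarcomere states per wall) is
integrated by an adaptive embedded Cash-Karp Runge-Kutta pair implemented
in compiled code, at relative tolerance 1e-7 and absolute tolerance 1e-9
times total blood volume, sampled 500 times per beat. The assembled system
has no time constant below a few milliseconds (no inertances; bounded
cross-bridge rates), so stiff machinery is unnecessary; a `deSolve::lsoda`
integration over the pure-R derivative path is retained as an independent
cross-check and agrees with the compiled path to ~1e-5 ul over a beat.

The junction force balance is solved at every derivative evaluation by a
damped Newton iteration on the *tension-scaled* residual — scale invariance
removes a false minimum at infinite junction radius where all tensions
vanish — warm-started from the previous solution, with the junction radius
constrained to a physical band around the heart radius (excluding pinch-off
and inflation configurations) and strains bounded at |1.5|. Cold starts use
a coarse grid scan restricted to physiological strains. Accepted solutions
carry residual norms below 1e-8 kPa mm.

Two genuinely delicate phenomena shaped the solver design. First, the
force balance can transiently lose its physical root during rapid
activation (a saddle-node of the two-equation system when wall stresses
become strongly asymmetric); when warm-started Newton fails, the geometry
tracks the least-imbalance configuration (a trust-region Levenberg
iteration from the warm start), which continues the physical branch
smoothly through the fold. Second, a global re-search after a failure can
converge to a contorted root (septum folded deeply into a ventricle) and
silently poison the trajectory; re-searches are therefore restricted to
cold starts and to strain-plausible candidates. The reference R solver
(`solve_heart()`) errors on unsolvable states by default and only uses the
least-imbalance continuation when serving as the integrand.

Initialization primes the two arterial windkessels at typical diastolic
pressures (85 and 12 mmHg), distributes the remaining volume at a common
venous filling pressure, places each sarcomere at the passive biventricular
equilibrium (`solve_heart_passive()`, where the stress-strain coupling is
closed through the series element), and ramps activation over five beats.
A heart that has never ejected into an unpressurized aorta does not exist;
priming avoids a violently unphysiological first beat and makes the
convergence count meaningful. Runs converge in 15-60 beats from cold
starts and in under 5 beats when warm-started from a converged state.

## Protocol

`run_to_convergence()` iterates beats until the right-left stroke-volume
mismatch is below 1% *and* beat-to-beat end-diastolic volumes change by
less than 0.05% (the stroke-volume criterion alone can be met transiently).
`homeostasis_adjust()` then brings systolic aortic pressure into 110-125
mmHg by bisection on total blood volume first and systemic resistance
second. Homeostasis is applied to the baseline only; perturbed arms inherit
the adjusted volume and resistance, because re-tuning volume per scenario
would mask the preload consequences of right-heart failure. The
per-scenario mode exists behind `homeostasis = "per_scenario"` and reports
state which mode ran. Left free-wall and septal parameters are structurally
untouched by every scenario (asserted in the scenario builder).

End-systole and end-diastole are valve events (last sample with outflow,
respectively inflow, through the corresponding valve) — deterministic in a
simulation, unlike pressure heuristics. End-systolic elastance is the
least-squares slope of the end-systolic pressure-volume points from
converged runs at total-volume fractions {1.0, 0.95, 0.9, 0.85, 0.8}
(homeostasis disabled, each level warm-started from the previous);
chamber compliance is the analogous end-diastolic slope. The hypertrophy
multiplier defaults to 1.15 of right free-wall volume: no magnitude is
published, and sensitivity runs showed that multipliers much above ~1.3
make pure pressure overload *raise* ejection fraction, contradicting the
reported direction; 1.15 is within the mass increase reported for this
disease model. The treatment force target (78% of control) follows the
fractional-change reading of the published stiffness factor table, whose
arrow convention is internally inconsistent; it is configuration, clearly
flagged, not a measured force ratio.

## What the synthetic inputs emulate, and what they do not

There is no external data: inputs are parameter sets. The scenario builder
reproduces the published multipliers exactly; the seeded random-scenario
generator (`generate_random_scenarios()`) draws uniform multipliers within
physiological ranges for the property suite (conservation, valve
directionality, solver invariants under perturbation). Passing these tests
shows the pipeline is internally consistent and directionally faithful; it
does not show that any individual rodent's hemodynamics are matched, since
the underlying healthy parameterization is a package default tuned only to
the protocol's pressure targets (systolic aortic pressure 110-125 mmHg,
right ventricular systolic pressure near the low-20s control value) and
textbook rodent volumes.

## Known limitations

* The end-systolic elastance estimate is load-independent only locally:
  a 30% resistance step moves it by under 10%, but the full
  pressure-overload afterload change moves the fitted slope by ~25-30%
  through the window shift along a convex end-systolic locus. The
  elastance *drop* reported for the full-disease arm (~59%) therefore
  overshoots the published "almost 50%" figure.
* Cardiac output in this closed loop is strongly supply-regulated: venous
  return compensates contractility changes, so the simulated output
  deficit of the disease arm (~14%) and the treatment recovery (~8%) are
  smaller than the published ~20% figures, and the output-force relation
  saturates near control force (linear R^2 ~0.89 against the 0.95
  property threshold).
* Right ventricular dilation under pure overload is modest (EDV ~x1.1
  against a reported near-doubling): with fixed reference geometry the
  sarcomere-length headroom between the operating point and the passive
  knee limits volume growth; the published model may operate on a more
  compliant diastolic branch.
* No pericardium, no intrathoracic pressure, no valve inertance, no
  regurgitation, no interventricular activation delay, no growth or
  remodeling; metabolic coupling of the cited full myofilament model is
  out of scope.

## Reproducing the study

The `analysis/` scripts run the arms in order (`01_baseline.R`,
`02_scenarios.R`, `03_fmax_sweep.R`, `04_treatment.R`) and write
trajectories, metrics and fold-change reports under `results/`.
`scripts/acceptance.R` recomputes the headline quantities from scratch
(see the README). Problem sizes are desk scale: one converged run is
15-60 beats of a 17-state system; the full suite including the elastance
series is a few hundred beats and completes in minutes on one CPU.
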