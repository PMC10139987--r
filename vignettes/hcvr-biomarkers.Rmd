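---
title: "Physiology-based PK/PD analysis of opioid effects on the hypercapnic ventilatory response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physiology-based PK/PD analysis of opioid effects on the hypercapnic ventilatory response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcvr)
```

## The question the package answers

Opioids depress breathing, but "breathing" is not one number. A
hypercapnic ventilatory response (HCVR) experiment yields several
candidate biomarkers of respiratory depression: resting (poikilocapnic)
ventilation V̇E, resting end-tidal PCO2, the ventilatory recruitment
threshold (VRT, the PCO2 at which ventilation starts to rise under CO2
inhalation), the slope S of the response above that threshold, and the
ventilation extrapolated to a PCO2 of 55 mmHg (V̇E55). Because resting
variables sit inside the CO2 chemoreflex feedback loop — an opioid
lowers ventilation, PCO2 then rises and partially restores ventilation —
their apparent drug sensitivity is blunted. Quantifying which biomarker
is most sensitive therefore requires a model that carries the CO2
kinetics along with the pharmacology. `hcvr` implements that joint
model, an estimator for each of its layers, and a synthetic-trial
generator so the entire chain can be validated by parameter recovery.

## Model

**Pharmacokinetics.** Plasma concentration follows a two-compartment
model with zero-order absorption: the oral dose enters the central
compartment at a constant rate over a duration `tabs` (a tablet
dissolving into the blood), distributes to a peripheral compartment via
the intercompartmental clearance CL2, and is eliminated with clearance
CL. Volumes and clearances are apparent oral quantities (bioavailability
fixed at 1, so they are V/F and CL/F) for a 70-kg individual and scale
linearly with weight/70. The analytic bi-exponential solution is used
throughout. Concentrations are carried in mg/L (dose in mg over volumes
in L); the reference potency values below live on the same scale.

**CO2 loop.** With the linear blood dissociation relation
P = λ0·C (λ0 = 0.115), the lung and tissue mass balances are

    VALV · dPa/dt = max(V̇E − V̇D, 0) · (PI − Pa) + λ1·Q̇·(Pv − Pa)
    VTS  · dPv/dt = Q̇·(Pa − Pv) + λ2·V̇CO2
    τ    · dPbr/dt = Pa − Pbr

with arterial = alveolar = end-tidal PCO2, dead-space ventilation
V̇D = 1.8 L/min, alveolar volume VALV = 3 L, tissue volume VTS = 10 L,
cardiac output Q̇ = 4 L/min, λ1 = 10, λ2 = 100·λ0, and a brain-tissue
(effect-site) PCO2 Pbr lagging the arterial pressure with time constant
τ = 2.5 min. The tissue equation is written with Q̇·(Pa − Pv) so that
venous exceeds arterial PCO2 at steady state, as physiology requires.
Ventilation feeds back through the smooth hinge (softplus) law

    V̇E = baseline V̇E + S · H(Pbr − VRT),   H(x) = δ·log(1 + exp(x/δ))

with δ = 0.1 mmHg. At steady state the system satisfies the metabolic
hyperbola (V̇E − V̇D)(Pa − PI) = λ1·λ2·V̇CO2, which is also how the
package calibrates the metabolic CO2 production from a resting pair
(`calibrate_vco2()`): with V̇E = 8.3 L/min and Pa = 41 mmHg this gives
266.5/115 ≈ 2.32 model units.

**Dynamic end-tidal forcing.** `simulate_run()` reproduces the
idealized effect of an end-tidal forcing system: a
proportional–integral controller adjusts inspired PCO2 (clipped at
zero) to steer end-tidal PCO2 onto stepped targets 4.5/9/13.5/18 mmHg
above resting, after a resting phase without added CO2. The commanded
target passes through a short first-order lag (0.15 min), as a
gas-mixing controller's output does; this keeps the inspired-gas
command continuous, which matters when a fit later reconstructs it from
sampled records. If the default protocol would exceed 20 min the last
(+18) step is dropped, so the default run is 6 min rest + 3 × 7 min
steps. Runs are integrated with lsoda (compiled right-hand side,
rtol 1e-8, atol 1e-10), sampled on a 1-s grid, and averaged into the
1-min records that constitute the observed data.

**Per-run estimation.** `fit_run()` estimates the four HCVR parameters
per run by nonlinear least squares of this kinetic forward model driven
by the recorded inspired PCO2. The objective is joint over the 1-min
ventilation and end-tidal channels (scales 0.44 L/min and 0.5 mmHg):
ventilation alone constrains resting PCO2 only weakly through the
V̇CO2 calibration, and an unanchored resting PCO2 drags the threshold
estimate with it; the end-tidal channel — which the experiment records
anyway — pins both. Starting values are data-driven (resting means,
step-plateau regression). Parameters are optimized on the log scale
inside physiologic boxes; a run whose fitted threshold lies above the
tested end-tidal range, or whose slope pins at zero, never recruited
the CO2 response and is flagged rather than trusted. V̇E55 and the
apneic threshold B = 55 − V̇E55/S are derived from the fit.

**Pharmacodynamics.** Each biomarker's per-run estimates over the 8-h
session are linked to plasma concentration through a first-order effect
compartment (ke0 = log 2/h½) and a sigmoid EMAX model with shape γ
fixed to 1. Depressed biomarkers (resting V̇E, S, V̇E55) use
e0·C50/(C50 + Ce); biomarkers that rise under opioid (resting PCO2,
VRT) use the reciprocal elevated form e0·(C50 + Ce)/C50. The elevated
form is a package choice — it makes generator and estimator
self-consistent and reproduces the observed direction — not a claim
about any particular historical implementation. `fit_pd_biomarker()`
profiles the per-subject baselines e0 in closed form at every objective
evaluation and optimizes (C50, h½) by a coarse grid followed by a
quasi-Newton polish; the three resting-class biomarkers can share one
(C50, h½) pair, and `compare_dynamics()` tests that constraint with a
Gaussian likelihood-ratio statistic, N·log(RSS ratio) against
chi-squared.

## Reference population values

`study_truth()` stores the reference parameter set used by the
generator and the recovery experiments: PK V1 = 90 L, V2 = 557 L,
CL = 197 L/h (ω² = 0.06), CL2 = 726 L/h, tabs = 1.2 h, proportional
residual variance 0.015; biomarker baselines 8.3 L/min, 41 mmHg,
44 mmHg, 2.5 L·min⁻¹·mmHg⁻¹ and V̇E55 37.1 L/min with their ω² and
within-subject σ; potencies C50 = 0.81 mg/L (h½ 1.3 h) for the resting
class, 0.23 mg/L (0.6 h) for the slope, and — as a reference value
only — 0.08 mg/L (0.9 h) for V̇E55. A note on scale: a 100/200-mg oral
dose with these PK parameters produces plasma concentrations of order
0.1–0.5 mg/L, and the potencies are coherent exactly on that mg/L
scale; the package therefore uses mg/L end to end.

The generator never imposes dynamics on V̇E55. It scales only the four
primitive biomarkers; V̇E55's high apparent potency *emerges* from the
composition (a modest rise of the threshold plus a modest fall of the
slope slashes the extrapolated ventilation at 55 mmHg). Simulating the
reference subject noise-free and fitting the EMAX model to the
composite V̇E55 trajectory yields an apparent C50 of about 0.10 mg/L
and h½ of about 0.9 h — close to the reference values, which is the
model-level content of the claim that V̇E55 is the most sensitive
biomarker.

## What the synthetic trial emulates — and what it does not

`generate_trial()` draws 12 subjects per dose arm (100/200 mg), weight
normal(74, 10) truncated to 57–103 kg, log-normal between-subject
deviations with the reference ω² (the three resting-class biomarkers
share one C50 draw per subject, matching the shared-dynamics
constraint), one pre-dose HCVR plus hourly runs for 8 h, and hourly
plasma samples 0–7 h with proportional noise. Drug effect is evaluated
at each run's start and held constant within the ~27-min run (intra-run
drift is second order at these half-lives). Within-subject variability
enters twice, following the study structure: run-level parameter jitter
with the reference σ, and 1-min ventilation noise with SD 0.44 L/min at
rest scaling linearly with ventilation. All randomness derives from one
root seed via fixed per-subject streams, so a dataset is reproducible
byte for byte.

The generator does *not* emulate breath-by-breath mechanics, sighs or
apneas, face-mask artifacts, assay censoring, O2 effects (end-tidal O2
is assumed perfectly clamped), or dropout. Passing recovery tests
therefore demonstrates that the estimation chain inverts the model
faithfully at realistic noise levels — not that the model captures
every feature of real recordings.

Because the between-subject deviations of resting PCO2 and VRT are
drawn independently, roughly a quarter of simulated subjects have a
threshold at or below their resting PCO2 — no dog-leg, chemoreflex
active at rest. These subjects are physiologically plausible and are
handled consistently: the run record shows the realized resting point,
and the fit recovers the realized curve.

## Numerical choices

* ODE integration: lsoda with compiled right-hand sides, rtol 1e-8 /
  atol 1e-10, dense output every second; 1-min values are arithmetic
  means of 60 grid points.
* Inspired-PCO2 reconstruction in `fit_run()`: the simulator's
  fine trace when available; otherwise a per-minute staircase whose
  transition minutes place the jump at the within-minute time that
  preserves the recorded minute average. This keeps the round-trip bias
  of all four parameters below one percent from minute data alone.
* PK estimation: least squares on the log-concentration scale (the
  natural transform under proportional error). The absorption duration
  acts as a breakpoint, so it is profiled on a grid before a joint
  polish; per-subject clearances start from noncompartmental
  (trapezoid-AUC) values. Stage 2 reports medians, the variance of log
  clearance, and nonparametric bootstrap standard errors over subjects.
* PD optimization: grid start over (C50, h½) then `nlminb` on the log
  scale with bounds (C50 ≤ 50 mg/L); a potency at its bound flags the
  series as carrying no usable drug signal.
* Recovery problem sizes: 24 subjects × 9 runs, five seed replicates,
  with medians across replicates reported — the design of the study
  being emulated, kept at that scale so the full recovery suite runs in
  minutes.

## Known limitations

* The two-stage population PK path reports bootstrap standard errors;
  no joint mixed-effects likelihood is fitted, and the structural
  parameters (V1, V2, CL2, tabs) are only weakly identified by an
  hourly 0–7 h schedule — clearance, the quantity the PD layer needs,
  is identified by the AUC and recovers well.
* Per-run HCVR fits are independent across runs; no information is
  shared within a subject, which inflates run-level scatter relative
  to a joint fit but matches the per-run granularity of the PD layer.
* The linear-above-threshold response is used throughout; at extreme
  PCO2 a real response saturates.
* The dynamics likelihood-ratio test relies on the Gaussian asymptotic
  chi-squared reference; its empirical size at α = 0.01 is checked by
  simulation in the test suite rather than assumed.
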