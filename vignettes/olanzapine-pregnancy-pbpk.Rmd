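---
title: "Methods: a whole-body PBPK model of olanzapine across pregnancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a whole-body PBPK model of olanzapine across pregnancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olapbpk)
```

## The question

Olanzapine is a first-line antipsychotic that women often need to keep
taking through pregnancy, when therapeutic drug monitoring (TDM) targets a
trough of 20–80 ng/mL. Gestation changes nearly everything that governs the
drug's disposition at once: plasma albumin falls (raising the unbound
fraction), CYP1A2 — the main metabolic route — loses more than half of its
activity by late pregnancy, while UGT1A4, CYP3A4 and FMO3 are induced, and
renal filtration rises. No single direction of change is obvious a priori.
This package asks the quantitative question: under a standard 10 mg daily
dose, how much does maternal steady-state exposure actually change across
the trimesters?

## Model structure

The body is a whole-body, perfusion-limited compartment model in the
standard small-molecule layout: lung, brain, heart, kidney, liver, gut
(lumen + wall), stomach, spleen, pancreas, muscle, adipose, skin, bone,
gonads, and arterial, venous and portal blood — 18 drug-containing
maternal compartments. Pregnancy adds uterus, placenta, mammary gland, a
lumped non-eliminating fetal compartment (first-order exchange with the
placenta, 2 L/h) and amniotic fluid (volume only; no drug transfer, a
deliberate non-goal). Each perfused organ obeys

$$V_i \frac{dC_i}{dt} = Q_i \left(C_{art} - \frac{C_i}{K_{p,i}}\right),$$

splanchnic organs drain through the portal vein into the liver, and the
gut lumen feeds the gut wall via first-order dissolution (half-time 10
min) and first-order transcellular absorption (permeability
3.85×10⁻⁶ cm/min over an effective absorptive area of 60 m², i.e.
k_a ≈ 0.55 h⁻¹; luminal solubility is checked at dose time and is
non-limiting at 10 mg). All processes are first-order — metabolic
saturation is not observed for olanzapine in the clinical range — so the
assembled system is linear and time-invariant between doses.

Because of that linearity the primary integrator is not a step-size
controlled ODE solver but the exact propagator: the matrix exponential of
the system matrix over the 0.1 h output step, applied recursively. This
is exact for the LTI system, conserves mass to machine precision
(~10⁻¹² of the dose), and makes population runs cheap. `deSolve::lsoda`
(rtol 1e-8, atol 1e-10) is retained as an alternative path and the two
agree in the test suite; the tolerance-halving check is run on the lsoda
path.

## Tissue partitioning

Tissue:plasma partition coefficients come from a composition-based
(Schmitt-type) scheme for a monoprotic base (pKa 7.24): each tissue's
affinity, referenced to unbound drug in plasma water, sums a water term
with pH-dependent ion trapping, a neutral-lipid term for the neutral
species (10^logP, logP 2.85), a phospholipid term in which the protonated
species binds with a relative affinity `ion_pl_affinity`, and a protein
term whose plasma-side coefficient is solved from the measured fu = 0.07
(so a tissue with plasma's composition has Kp ≡ 1, and plasma lipid
binding is implicitly folded into that measured value). The composition
table ships as a versioned CSV and is pinned in the tests.

`ion_pl_affinity` is the model's one identified distribution constant —
the charge-dependent element the partitioning method calls for but whose
platform value is unpublished. It was calibrated once, during model
development, against the single-dose test-set observations (observed
Cmax 18.6 ng/mL; the AUC is insensitive to it), giving a value of 24,
and is fixed thereafter. The resulting steady-state volume of
distribution (~900 L) and terminal half-life sit in the range reported
for olanzapine, with distribution dominated by phospholipid-rich lean
tissue rather than fat, as expected for a moderately lipophilic base.

## Clearance: a middle-out calibration

The published inputs give whole-body-normalized intrinsic clearances for
five enzymes (CYP1A2 26.67, CYP3A4 0.82, CYP2C8 2.14, FMO3 4.05, UGT1A4
20.06 L/h) plus renal terms, and — from mass balance and a fluvoxamine
DDI study via the Rowland–Matin equation — the fractions of an oral dose
each pathway eliminates (CYP1A2 0.50, UGT1A4 0.23, the minor oxidases
0.067 each, renal 0.07). These two sets are not mutually consistent
under any single flux convention (UGT1A4 carries 37 % of the summed
CLint but 23 % of the dose), because the platform that produced them
scales each enzyme by unpublished expression factors.

The package therefore adopts the same middle-out logic the analysis
itself used: renal clearance is computed mechanistically as unbound
filtration plus kidney-volume-normalized unbound tubular secretion,
CL_R = fu·(GFR + CL_TSspec·V_kidney·60); the well-stirred identity and
the oral first-pass relation are then solved so that the simulated dose
fractions equal the published decomposition, yielding one in-vivo
scaling factor per enzyme. The factors are properties of the baseline
liver: they are calibrated once in the non-pregnant reference adult and
never re-fitted. Everything downstream — CL/F ≈ 12.6 L/h, the simulated
fm values, the DDI limit (complete CYP1A2 inhibition → AUC ratio 2.0,
bracketing the observed 1.76) — emerges from the simulation.

Note one deliberate deviation: tubular secretion acts on unbound drug.
Without the fu factor the implied total clearance (CL_R / f_R) would
exceed hepatic blood flow, which is physically untenable; with it, all
published magnitudes are reproduced.

## Gestational scaling

All pregnancy scaling uses fertilization week (FW = gestational week − 2)
as the independent variable.

* **Protein binding.** Albumin follows
  P(FW) = 14.7·e^(−0.0454·FW) + 31.7 g/L; fu follows a single-site
  association model, fu = 1/(1 + K_A·P/MW_alb), with K_A solved at the
  calibration week. Calibrating at FW = 0 (albumin 46.4 g/L) reproduces
  the canonical trimester values 0.075/0.085/0.091; calibrating at the
  asymptotic 31.7 g/L — which a literal reading of the source text
  suggests — does not, so the package calibrates at FW 0 and documents
  the choice.
* **Enzymes.** CYP1A2: 0.0291·FW² − 2.77·FW percent (−60 % by FW 34).
  UGT1A4: the weighted cubic 8.669·FW − 0.339·FW² + 0.00462·FW³ percent,
  refittable from probe data with `fit_ugt1a4_cubic()` (weighted least
  squares through the origin, study sizes as weights). CYP3A4: the
  induction polynomial 1.00736 + 0.00564·FW + 0.00172·FW² − 0.00003·FW³.
  CYP2C8: unchanged (no quantitative data). FMO3: a step at the start of
  the third trimester (FW 27); the canonical mode uses the trimester
  table's implied +75.6 %, a literature mode offers the +58 % probe
  estimate — the two sources disagree and we expose both. The FMO3 step
  is the one discontinuity in the otherwise continuous equation mode.
* **Canonical vs equation mode.** At FW 6/20/34 the canonical mode
  returns the printed trimester parameter sets bit-exactly (the printed
  CYP1A2 column deviates a few percent from the quadratic evaluated at
  those weeks, so the table wins at the anchor weeks); at any other FW
  the continuous equations are used, with a warning when canonical mode
  was requested.
* **Physiology.** Body weight, cardiac output, GFR, blood volume,
  hematocrit, renal/cutaneous flows and the gestational compartments
  follow smooth literature-based polynomial trajectories stored with the
  reference constants; absolute liver blood flow is deliberately held
  constant (reports on hepatic flow in pregnancy conflict), and cardiac
  output is defined as the sum of all arterial draws so flow balance
  holds identically at every FW. Kp values are recomputed at each FW
  from the gestational fu, so the distribution volume grows as binding
  loosens — which is what keeps the terminal half-life nearly flat while
  clearance rises.

## Study design mirrored by the package

The canonical experiment is: reference adult female (body weight 60 kg,
ICRP-style organ inventory), 10 mg once daily to steady state
(convergence: successive interval AUCs within 0.5 %, capped at 40 doses;
the acceptance path tightens this to 0.1 %), compared with the
representative trimester individuals at FW 6, 20 and 34 using the
canonical parameter sets. Non-compartmental analysis uses the
linear-up/log-down trapezoid, terminal slope from the last 3+ points
extended while adjusted r² improves, CL/F = dose/AUC. Virtual
populations sample FW uniformly within a trimester window, body size
log-normally (CV 0.15; volumes scale linearly, flows allometrically with
exponent 0.75), per-enzyme CLint multipliers log-normally (CV 0.35,
median-preserving) and tubular secretion with CV 0.25 — the platform's
own variability settings are unpublished, so these are conventional
choices, pinned in the tests and configurable. Change estimates pair the
pregnant and reference populations on a common seed so that shared
variability cancels from the ratio; population sizes of 200 per group
pin the geometric-mean ratio to within a few percent, and the analysis
scripts state the sizes they use.

## The synthetic-data generators

Three generators stand in for data that cannot be shipped: (a) noisy
"observed" mean profiles — multiplicative log-normal observation noise
(concentrations are positive, errors reported relatively) applied per
subject and sampling time to a simulated truth; (b) lamotrigine-like
clearance-change points — the UGT1A4 cubic evaluated at a few
fertilization weeks per contributing study, Gaussian noise scaled by
1/√(study size); and (c) the packaged table of ten predicted/observed
validation pairs. They emulate the *structure* of the real inputs (mean ±
SD profiles, study-size weighting), not their full covariance: real
studies differ in formulation, assay and sampling design, so passing the
synthetic checks demonstrates correctness of the machinery, not clinical
transferability.

## Numerical choices and degenerate inputs

Output grid 0.1 h (0.2–0.5 h in the heavier test and population paths);
amounts in µmol, concentrations converted through MW 312.4; doses must
fall on the output grid. Negative fertilization weeks, non-calibrated
binding models, missing tissue compositions, rank-deficient cubic
designs, non-decaying NCA tails and non-converged steady states all
raise informative errors; an AUC ratio below 1 or an inhibition solve
outside [0, 1] is rejected rather than clipped silently. The steady-state
flag marks the last simulated interval; the trough is the concentration
at its end.

## What the model does and does not claim

The ratio-type endpoints — percent changes of CL/F, interval AUC and
trough across pregnancy — are the robust outputs: engine-specific
constants largely cancel, and the package reproduces the published
changes within a few percentage points. Absolute single-dose AUC and
Cmax depend on engine internals (gut geometry, composition database,
expression scaling) and are reproduced at the ±25 % level, not bit-wise.
Known limitations: no gut-wall metabolism (Fg ≡ 1 — the likely source of
the remaining few-point underestimate of the clearance rise, since
UGT1A4 and CYP3A4 induction would also erode gut availability), a
static-inhibition stand-in instead of a mechanistic inhibitor
co-simulation, no permeation-limited distribution mode, no fetal or
placental transfer kinetics, no genotype or smoking covariates, and a
blood:plasma ratio defaulted to 1 (configurable, weakly identified, and
largely cancelling from the ratio endpoints).
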