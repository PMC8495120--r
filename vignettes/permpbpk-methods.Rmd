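---
title: "A gestational PBPK model for permethrin isomers in the rat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gestational PBPK model for permethrin isomers in the rat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Permethrin, a widely used pyrethroid insecticide, crosses the placenta,
and prenatal exposure is a suspected risk factor for altered
neurodevelopment.  Risk assessment therefore needs the internal dose in
the fetal brain, which cannot be measured directly in most settings.
`permpbpk` implements a pregnancy physiologically based pharmacokinetic
(pPBPK) model for the *cis*- and *trans*-isomers of permethrin in the
Sprague–Dawley rat: a maternal whole-body model coupled through the
placenta to a lumped-litter fetal model, driven by daily oral gavage
dosing over the whole of gestation (GD0–GD20).  Around the model the
package provides non-compartmental summary metrics with
limit-of-quantification (LOQ) handling, a synthetic toxicokinetic-study
generator, Bayesian calibration by MCMC, and Sobol global sensitivity
analysis.

## Model structure

**Maternal sub-model.**  Twelve compartments: stomach lumen, intestinal
lumen, GI tissue, liver, blood, rapidly perfused tissue, placenta, and
six diffusion-limited tissues (brain, muscle, kidney, fat, mammary
gland, slowly perfused tissue), each of the latter split into a
capillary-blood and a cellular sub-compartment.  Oral absorption is a
two-step chain: gavage boluses enter the stomach, move to the
intestinal lumen at rate $k_{sI}$, and are absorbed into GI tissue at
rate $k_{aI}$; unabsorbed material is excreted in feces at rate
$k_{fec}$.  The liver receives hepatic arterial blood and the portal
outflow of the GI tissue (hepatic first pass); metabolism occurs in GI
tissue, liver and blood as linear clearances (L/h/kg, scaled by the
current maternal body weight).

For a flow-limited tissue $T$,
$$\frac{dA_T}{dt} = Q_T\left(C_{Art} - \frac{C_T}{PC_T}\right),$$
with $PC_T$ the tissue:blood partition coefficient.  For a
diffusion-limited tissue the capillary sub-compartment exchanges with
the cellular one through a permeability–surface-area product:
$$\frac{dA_{TB}}{dt} = Q_T\,(C_{Art} - C_{TB}) - PS_T\,(C_{TB} - C_T/PC_T),
\qquad \frac{dA_T}{dt} = PS_T\,(C_{TB} - C_T/PC_T),$$
with venous return at $C_{TB}$.

**Permeability convention.**  The permeability parameters are stored as
unitless permeability:flow ratios: the effective exchange coefficient
of tissue $T$ is $PS_T \times Q_T(t)$.  This is the convention of the
adult-rat permethrin model lineage this model extends, and it is the
reading under which the calibrated parameter set reproduces the
single-dose tissue exposures coherently across all six
diffusion-limited tissues (with an absolute L/h reading, fat and
mammary exposures come out several-fold too high while the well-perfused
tissues are unaffected — the kidney, whose flow is close to 1 L/h, is
insensitive to the distinction).  All printed permeability values lie
in (0, 1] and share the (1e-5, 1) calibration bounds, consistent with a
fraction.

**Placenta and fetus.**  The placenta is flow-limited; its mass balance
is
$$\frac{dA_{Pla}}{dt} = Q_{Pla}\left(C_{Art}-\frac{C_{Pla}}{PC_{Pla}}\right)
  - K_{trans1}\frac{C_{Pla}}{PC_{Pla}} + K_{trans2}\,C_{Art,F},$$
with bidirectional first-order diffusion constants
$K_{trans,i} = scK_{trans,i}\,BW^{0.75}$ (maternal body weight by
default; the allometric basis is configurable because the printed unit,
L/h/kg^0.75, does not name the weight).  The fetal sub-model lumps the
whole litter into four compartments — blood, liver, brain (the only
diffusion-limited fetal tissue) and rest of body — with fetal
metabolism set to zero.  Everything that leaves the placenta via
$K_{trans1}$ appears in fetal blood and vice versa, so the barrier
conserves mass exactly.

**Isomers.**  The two isomers share the model structure and are
simulated independently with their own parameter vectors; no
interconversion or interaction is modelled.

## Gestational physiology

Constant-size tissues are fixed fractions of the *initial* body weight
and constant flows fixed fractions of the *initial* cardiac output;
this is deliberate — only the tissues with measured gestational ranges
(fat, mammary gland, placenta, the fetus) change during pregnancy.
Maternal body weight interpolates linearly through the measured study
means (0.277 kg at GD0, 0.356 at GD15, 0.422 at GD20) and the cardiac
output index linearly from 24.56 to 21.6 L/h/kg.  The slowly perfused
volume is the balance $1 - \sum \text{organ fractions} - 0.05$
(non-perfused), and the rapidly perfused flow is the balance between
cardiac output and all other flows, which keeps the arterial draw
exactly equal to cardiac output at every instant.

The growth equations of the source study's supplementary material are
not public, so the package uses stand-in laws chosen once: linear
interpolation for fat and mammary volume and flow, and a normalised
logistic curve for the placenta and all fetal tissues — exactly zero at
conceptus onset (GD6, implantation), endpoint at GD20, midpoint GD15,
rate 0.5/day — reflecting the near-exponential growth of the conceptus
over the last week of gestation.  Before onset the conceptus
compartments are frozen at zero and take no arterial flow; a 1-nL
volume floor guards the concentration divisions around the transition.

Two printed fetal endpoints (brain 0.0034 L, liver 0.0044 L at GD20)
exceed the per-fetus body weight of 0.0068 kg and are therefore
interpreted as litter totals at the reference litter of 13.5 fetuses —
0.25 g brain and 0.33 g liver per 6.8-g fetus, which is anatomically
sensible — divided down so that litter totals still scale linearly with
litter size.

## Dosing and study design

The emulated study dosed 50 mg/kg/day permethrin (40:60 *cis*:*trans*,
i.e. 20 and 30 mg/kg of the isomers) by daily gavage, with group
sacrifice (n = 4) at 1, 2, 3, 4, 6, 10 and 24 h after the dose on GD1,
GD15 or GD20.  The GD1 group is treated as a single administration
(the study describes it as such, and gestational changes at GD1 are
negligible); the GD15/GD20 groups carry the full daily history from
GD1.  Doses are boluses into the stomach with integration restart at
each event, scaled to the body weight at the dosing instant.

## Measurement model, LOQ handling and the synthetic generator

Concentrations are reported in mg/L (≡ µg/ml ≡ µg/g at unit density).
A tissue homogenate includes its residual capillary blood, so the
measured concentration of a diffusion-limited tissue is
$(A_T + A_{TB})/(V_T + V_{TB})$.  Feces are the cumulative amount
excreted over the 24 h following a dose (metabolic-cage collection,
GD1 and GD15 only).

The synthetic generator applies a single multiplicative lognormal error
layer (log-scale SD 0.15, matching the residual-error model of the
calibration; no inter-animal kinetic variability) and censors each
record against the matrix- and isomer-specific LOQ of the LC–MS/MS
assay: detected-but-below-LOQ records are substituted with LOQ/2;
latent values below LOQ/10 (configurable) are marked not-detected and
excluded from analysis.  Passing tests on these synthetic studies shows
that the inference machinery is self-consistent under the assumed error
model; it cannot show that the error model, or the model structure,
matches real animals.

## Bayesian calibration

Priors follow the calibration table: truncated normals (mean from the
adult-rat models, CV 50% except one tighter printed spread) for
parameters with adult reference values, bounded uniforms for the rest,
and fixed values for the absorption and blood/intestinal-metabolism
constants.  The likelihood is lognormal with fixed $\sigma = 0.15$
around the ODE predictions; censored records enter at their LOQ/2 value
(as they did in the source analysis — an integrated censoring
likelihood is deliberately out of scope).  Calibration modes mirror the
study: `gd1` fits maternal parameters to single-dose data; `gd15_20`
jointly fits the repeated-dose data including placental/fetal
parameters, optionally sharing those across isomers.

The sampler is adaptive Metropolis-within-Gibbs on log-transformed
parameters (all are positive and span decades), with the prior
evaluated on the natural scale plus the log-transform Jacobian.
Proposal scales adapt in batches of 50 toward 44% acceptance.  Chains
start from overdispersed prior draws (redrawn, up to 100 times, if the
posterior is not finite there).  Convergence is judged by the classic
potential scale reduction factor
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$ with the conventional
$\hat R \le 1.2$ threshold.  The default reduced budget — 3 chains ×
2,000 sweeps, retaining one in two of the last 800 — calibrates a GD1
study in about five minutes on one core and passes parameter recovery
within 25% for the identifiable parameters; the full published budget
(3 × 10,000, thinned tail of 4,000) is a function argument away.

## Sensitivity analysis

`run_gsa()` perturbs every calibrated chemical parameter with an
independent truncated normal centred on its calibrated mean (CV 30%,
truncated at the calibration prior bounds — the source analysis states
the CV but no bounds, and re-using the prior bounds keeps every sample
physically admissible).  Outputs are the maternal arterial, fetal
arterial and fetal brain concentrations at 4, 6 and 12 h after the dose
on GD15 or GD20.  Indices use the Saltelli (2010) first-order estimator
and the Jansen total-order estimator on an A/B/AB design (any
consistent estimator would do; the source does not state its variant),
with bootstrap confidence bounds (100 resamples).  The default base
sample is 256 (≈ 5,900 model runs, a few minutes); 1,024 is recommended
for reported figures.  Small negative index estimates are Monte-Carlo
noise and are not truncated away.

## Numerical choices

* Integration: `deSolve::lsoda` on a C implementation of the
  right-hand side; a pure-R mirror of the derivatives is kept and
  tested against it to machine precision.  Default tolerances
  `rtol = 1e-8`, `atol = 1e-10` for reported simulations; `1e-6` inside
  MCMC and GSA loops (halving tolerances changes a 24-h blood AUC by
  far less than 0.1%).
* Mass balance: the rate vector sums to zero by construction between
  doses; along a full GD1–GD20 repeated-dose trajectory the relative
  defect stays below 1e-6.
* AUCs: linear trapezoid on the stored grid, no extrapolation.
  Observed-style composite curves from destructive sampling use the
  per-time mean and an optional (0, 0) anchor (the study is silent on
  the anchor; it is exposed as an argument).
* Terminal half-life: log-linear least squares on all points from Tmax
  onward, requiring at least three positive points and a positive
  elimination slope, otherwise undefined — with seven-point
  group-sacrifice curves peaking at 6 h, the published half-lives are
  only computable if the peak anchors the fit.
* Tie-breaks: Tmax takes the earliest time among equal maxima.

## Problem sizes used by the shipped checks

The test-suite and acceptance script deliberately run at desk scale:
single-dose GD1 simulations on a 0.05-h grid; one synthetic GD1 study
(200 records); calibration at 3 × 2,000 sweeps; GSA at a base sample of
256.  These sizes were chosen as the smallest at which the respective
statistical checks are stable, and the vignette states them so that
reported numbers can be reproduced exactly.

## Known limitations

* The gestational growth laws are stand-ins for unpublished equations;
  endpoints and anchor points are honoured, trajectories between them
  are assumptions.
* The forward model reproduces the published *maternal* model-estimated
  exposures well (all six tissues within ~20% at GD1), but predicts
  late-gestation fetal blood close to its quasi-steady ratio
  $K_{trans1}/K_{trans2} \approx 0.76$ of the placental free
  concentration, where the source model reports a feto-maternal blood
  AUC ratio of 0.25.  The difference must lie in unpublished structural
  detail of the placental–fetal coupling (for example a different
  allometric basis or an additional lag).  Fetal exposures from this
  package are therefore conservative (high) by roughly three-fold
  relative to the source model, and the published feto-maternal ratios
  are reproduced from the printed tables by the ratio machinery rather
  than by forward simulation.
* No metabolite kinetics, no enterohepatic recirculation, no active
  placental transport, no inter-animal variability in physiology.
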