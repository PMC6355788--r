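---
title: "Modelling cervical tumour regression under chemoradiotherapy and pulsed-dose-rate brachytherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cervical tumour regression under chemoradiotherapy and pulsed-dose-rate brachytherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervosim)
```

## The model

`cervosim` simulates the volumetric response of a cervical tumour to the
standard curative protocol — external-beam radiotherapy (EBRT) with
concomitant weekly cisplatin, followed by two fractions of pulsed-dose-rate
brachytherapy (PDR-BT) — with a predominantly discrete, multiscale
cellular-automaton model.

The gross tumour volume is discretised into cubic *geometrical cells*
(GCs, default edge 1 mm), each holding a census of biological cells at the
typical packing density of $10^9$ cells/cm$^3$ ($10^6$ cells per default
GC).  Within a GC every cell belongs to one of five classes: stem cells
(unlimited mitotic potential), LIMP cells (LImited Mitotic Potential
progenitors that terminally differentiate after `n_limp` divisions),
terminally differentiated cells, and apoptotic or necrotic cells awaiting
clearance.  Stem and LIMP cells cycle through G1/S/G2/M or rest in the
dormant, hypoxic G0 phase.

Every simulated hour applies, in fixed order:

1. **Therapy events** scheduled for that hour (EBRT fraction, cisplatin
   administration, or one BT pulse).
2. **The cytokinetic scan**: spontaneous apoptosis of stem/LIMP cells and
   spontaneous death of differentiated cells; crowding-gated dormancy
   exit; phase advancement and mitosis (symmetric or asymmetric stem
   division, LIMP generation bookkeeping, terminal differentiation after
   the last LIMP division, a crowding-scaled fraction `p_sleep` of
   daughters entering G0); necrotic death of dormant cells that outstay
   `t_g0`; clearance of the dead pools with mean residence times
   `t_necrosis` and `t_apoptosis`.
3. **The spatial scan**: under-populated GCs (occupancy below 10% of
   capacity) hand their contents to their most occupied neighbours,
   boundary GCs first, so the tumour shrinks inward; over-full GCs spill
   surplus to their least occupied neighbour, annexing an adjacent
   non-tumour voxel when every neighbour is full.  Cells are moved, never
   created or destroyed, and tie-breaks are decided by a deterministic
   seeded hash of the voxel id, making runs bit-reproducible and
   independent of storage order.

The order therapy → cytokinetics → spatial movement is load-bearing (the
operators do not commute) and is pinned by a regression test.

### Cell survival under irradiation

Cell kill by EBRT follows the linear-quadratic (LQ) model,
$SF(d) = \exp[-(\alpha d + \beta d^2)]$, applied acutely (fractions are
delivered in minutes, so no intra-fraction repair correction is needed).
Dormant G0 cells are the hypoxic population: they see a reduced effective
dose $d/\mathrm{OER}$.  For the LQ model the dose-modifying convention is
algebraically identical to dividing $\alpha$ by OER and $\beta$ by
OER$^2$, so no separate convention switch is provided.

A PDR-BT fraction delivers $N = 20$ pulses of duration $t \approx
0.2$–$0.3$ h at a 1 h start-to-start interval.  Between pulses, sublethal
damage is only partially repaired (monoexponential repair, rate $\mu =
\ln 2 / T_{1/2}$), so the quadratic LQ term must carry a protraction
factor.  The survival is applied *after each pulse* on the current census
— so that cell birth and death between pulses act on the right population —
using the increment form

$$SF_i(d) = e^{-\alpha d}\, e^{-\beta d^2\,[\,i G_i - (i-1) G_{i-1}\,]},$$

where $G_i$ is the protraction factor of the train truncated at pulse $i$
in the *per-pulse* normalisation: the whole-fraction survival is
$SF_N = \exp[-(\alpha N d + \beta N G_N d^2)]$, which makes $G_i$ equal to
$i$ times the canonical $(2/D^2)\iint$ Lea–Catcheside integral.  With this
convention the per-pulse increments are strictly positive, tend to the
single-pulse factor $G_1$ when the inter-pulse gap grows (independent
pulses), and the product of the $SF_i$ telescopes exactly to the standard
protracted-LQ survival of the whole train.  The closed forms (`g_first()`,
`g_factor()`) are verified to $10^{-6}$ relative against an independent
adaptive-quadrature evaluation of the defining double integral
(`lea_catcheside_numeric()`) across the plausible repair half-time range
(0.26–5.7 h).  Below $\mu t = 10^{-4}$ a Taylor expansion replaces the
closed form of $G_1$, which loses digits to cancellation there.

Cisplatin kills a fraction CKR of stem and LIMP cells per administration
(apoptotic death); radiation kill is necrotic.  Radio/chemo-toxicity is
additive.  Stem cells can optionally be made more sensitive than LIMP
cells (`stem_sens`, default 1 = equal sensitivity, since only the option —
not a value — is established).  Differentiated cells are radio-killable by
default (`kill_diff` flag provided; their radiosensitivity is not
separately established).

### Expected-value engine, stochastic cross-check

Cell counts are continuous expected values by default: every per-hour
transition moves the corresponding fraction of its compartment.  Phase
residence is exponential with the configured mean (fraction
$1/\text{duration}$ advances per hour), so the hourly update is linear in
the census at fixed crowding.  An optional per-cell stochastic mode
(`cytokinetic_step(..., stochastic = TRUE)`) draws every transition from
binomial distributions on integer counts; the test suite verifies that the
expected-value engine matches the stochastic mean within sampling error
over 240 h at $10^5$ cells.  The expected-value choice makes whole-course
runs deterministic, cheap, and differentiable in the parameters, at the
price of ignoring demographic noise — negligible at $10^6$ cells per voxel
but a caveat for reading the model at near-eradication censuses (fractions
of a cell per voxel are propagated rather than rounded).

### Local crowding and dormancy

The trigger for dormancy entry/exit in the underlying biology is the local
oxygen and nutrient supply, for which no quantitative rule is established.
The package uses a documented proxy: the *effective occupancy* of a GC is
the maximum of its own total census and those of its 6-neighbours
(a voxel adjacent to densely packed tissue shares its saturated supply),
and local crowding is `min(1, effective occupancy / crowd_saturation)`
with `crowd_saturation = 0.3` of capacity by default.  Crowding multiplies
`p_sleep` (dormancy influx) and gates dormancy exit (`p_g0g1` acts only
below `crowd_exit_threshold = 0.9`).  Consequences: a packed tumour bulk
is fully crowded; therapy-depleted regions progressively release dormant
cells back into cycle (accelerated repopulation); and the thin, newly
colonised boundary shell of a growing tumour does not behave as an
artificial fast-growth rim, because it borders packed tissue.  Both
constants are configuration keys of `parameter_set()`.

### Doubling time as an operator eigenvalue

For fixed crowding the cytokinetic hour is a linear map, so the asymptotic
free-growth rate of a parameter set is the Perron eigenvalue $\lambda$ of
the living-compartment block of the hourly transition matrix
(`cyto_operator()`), evaluated at full crowding — the regime of the packed
tumour bulk.  `doubling_time()` converts it to days,
$T_d = \ln 2 / (24 \ln \lambda)$.  Because the matrix is built by pushing
unit vectors through the same compiled kernel that advances the
simulation, analysis and simulation cannot drift apart.  A lattice
free-growth run converges to this rate once the internal composition
transient decays; with initial phase/generation spreads taken from the
operator's dominant eigenvector (see below) the agreement is within a few
percent after ~6 weeks of simulated growth even for deep LIMP ladders.

## Tumour profiles and initialization

A tumour profile is the feature triple {GF, HF, DF}: growth fraction
(percent of living cells proliferating), hypoxic fraction (percent of all
cells dormant in G0) and dead fraction (percent of all cells dead),
optionally joined by a cisplatin kill rate and target doubling time(s).
`init_tumour()` realises a profile exactly: every tumour voxel is filled
to capacity with `DF`% necrotic cells, `HF`% dormant cells, `GF`% of
living cells cycling, stem cells making up `stem_frac` of living cells
(default 1%, the typical literature value), and the remaining living cells
terminally differentiated.  Infeasible triples (requiring a negative
differentiated pool, i.e. HF > (100−DF)(100−GF)/100) raise an error naming
the violated balance.  The initial dead pool is placed in the necrotic
compartment: the modelled tumours had no more than minimal necrotic
components, and the dead fraction estimate derives from imaging of the
necrotic core; a different split can be arranged by editing the returned
lattice state.

*Within* each class, cells are spread over cycle phases and LIMP
generations proportionally to the dominant eigenvector of the hourly
operator (falling back to phase-duration/uniform weights when degenerate).
The class-level pools — the clinically meaningful quantities — follow the
profile exactly either way; the eigenvector spread only removes a
months-long internal transient that a uniform generation fill would
impose on deep LIMP ladders, making the labelled doubling time meaningful
on clinical timescales.

## Parameter catalogue and sampling

`param_ranges()` records the biologically plausible ranges used to
constrain sampling: cell-cycle duration 16–70 h, G0 duration 96–240 h,
necrosis clearance 34–3456 h, apoptosis clearance 0–25 h, up to 18 LIMP
divisions, $\alpha \in$ 0.01–0.7 Gy$^{-1}$, $\beta \in$ 0.001–0.06
Gy$^{-2}$ (drawn through an $\alpha/\beta$ ratio around the typical
10 Gy), OER 1.5–3, $T_{1/2}$ 0.26–5.7 h, CKR 0–0.86, and the death,
dormancy and division-programme rates.  Two package choices deserve
mention: no range is established for the necrosis rate of differentiated
cells, so it is bounded by a conservative 0–0.02 h$^{-1}$ (the same order
as their apoptosis rate); and the necrosis-clearance time is drawn
log-uniformly, since its range spans two orders of magnitude.

`sample_parameter_sets(profile, td, ckr, n)` implements the one-to-many
mapping from tumour features to parameter sets: fields are drawn within
the ranges, and each draw is calibrated to the target doubling time by
bisection — on the spontaneous apoptosis rate `r_a` first, then on the
symmetric-division fraction `p_sym` when `r_a` alone cannot reach the
target — with draws rejected when neither lever suffices.  The achieved
doubling time is within 1% of the target by construction (asserted at 10%
in the tests after free-growth re-measurement).  The exact
feature-to-parameter relationships used in the original calibration work
are not public; this constrained-sampling scheme is a documented stand-in
that honours the same contract (initial composition exact, doubling time
matched, all values in range).

## Fitting, mean-value sets, and patient pairs

`fit_patient()` scans a CKR × doubling-time grid (defaults: CKR 0–0.5 in
the study's steps; $T_d$ 20–500 days by 20, then 500-day steps to 3750),
simulates each sampled set through the patient's full course, and retains
as *solutions* the sets satisfying a volumetric-compliance criterion at
every available imaging timepoint: `VRP5`/`VRP10` (simulated volume
reduction percentage within 5/10 points of the clinical one), `MIXED`
(5 early, 10 late), or `DV40` (absolute volume within 40% of clinical).
All bounds are inclusive; `vrp()` may be negative for growing tumours.
Solutions are grouped into one family per CKR value and scored by
`mae_solution()`, the mean absolute VRP deviation over the follow-up
timepoints.

`mean_value_set()` collapses a family to a single representative set by
field-wise arithmetic averaging (`n_limp` rounded), re-simulates it, and
records its MAE and whether it is itself a solution.
`mae_patient_profile()` averages the per-CKR mean-set MAEs over the CKR
values that retrieved solutions.

`cross_predict()` uses one patient's mean-value sets to predict another
patient's course — on the *target's* own geometry, dose maps and schedule
(the alternative, transplanting the source geometry, would conflate
regression-profile similarity with anatomy).  `pair_mae()` averages the
two directional errors, assigning the single available error to the pair
when only one patient retrieved solutions (single-run rule), and
`rank_pairs()` sorts pairs ascending with a configurable 10% annotation
threshold for very good mutual predictability — an annotation, not a
filter.

## Synthetic patients

The imaging data behind the original study are restricted, so the package
generates synthetic patients that emulate the protocol and data layout:
ellipsoidal masks of requested volume; 25 × 2 Gy weekday EBRT fractions;
weekly cisplatin; two 20-pulse BT fractions (1 h start-to-start, 0.25 h
pulses — the middle of the reported 0.2–0.3 h range) with centrally peaked
dose maps (inverse-square falloff from an internal source point, scaled to
a 15 Gy tumour-mean fraction dose) and the per-pulse map defined as the
fraction map divided by 20; and the five imaging timepoints pretherapy,
midterm (day 21), BT0, BT1, BT2.  `synth_clinical()` plants a known
parameter set as ground truth; `synth_cohort()` builds cohorts with two
regression archetypes — steep regressors ($\alpha \approx$ 0.38–0.5
Gy$^{-1}$, fast clearance 40–80 h) and shouldered regressors
($\alpha \approx$ 0.04–0.08 Gy$^{-1}$, slow clearance 600–1200 h) — which
bracket the clinically observed spectrum from near-exponential early decay
to little midterm shrinkage.

What the synthetic fixtures do *not* emulate: real delineation error (the
compliance thresholds exist to absorb it, but the synthetic "clinical"
volumes are exact), anatomy deformation between fractions, heterogeneous
intra-tumour profiles, and imaging noise.  Passing the recovery and
archetype-separation tests therefore demonstrates the internal consistency
and discriminative machinery of the method, not clinical validity.

## Numerical choices

* 1 h time step throughout; timepoint volumes are read at 00:00 of the
  imaging day, before that day's events.
* Tc split over G1/S/G2/M as 0.40/0.35/0.20/0.05 (configurable); per-hour
  advance probabilities are capped at 1.
* Cells lethally hit by therapy stop cycling immediately and enter the
  dead pool with a full clearance timer.
* Dormant cells that neither re-enter cycle nor are rescued within `t_g0`
  die through necrosis.
* The spatial scan's occupancy floor is 10% of capacity and the spill
  ceiling is 100%; dissolution fills each receiving neighbour only up to
  capacity, so the scan never creates over-full voxels.
* Volume readout counts living *plus* uncleared dead cells (imaging cannot
  distinguish them); a label-based readout (tumour voxels × voxel volume)
  is also reported.
* Masks and dose maps must share dimensions and affine; mismatch is an
  error, never a resample.  Masks must be binary.
* Conservation is exact by construction (cells are moved by
  subtract-and-add of identical amounts); the suite asserts it to
  floating-point rounding (≤1 cell in 10^9).

## Problem sizes used by the shipped experiments

The round-trip recovery experiment plants a typical radiosensitivity set
($\alpha = 0.3$ Gy$^{-1}$, $\alpha/\beta = 10$ Gy, $T_{1/2} = 1.5$ h,
OER 2, CKR 0.2, $T_d = 80$ d) in an 8 cm$^3$ (≈20³ voxel) tumour, runs the
full ~1100 h course, and re-fits with 120 sampled sets at the true tumour
features (profile, CKR and doubling time) under `VRP5`.  The features are
supplied, not searched: in this workflow {GF, HF, DF, $T_d$, CKR} are
user-selected inputs, and the recovery question is whether the underlying
parameter set is identifiable *given* them.  Pooling solution families
across neighbouring doubling-time cells degrades the mean-value set
noticeably (members calibrated to different growth rates compensate
through other parameters, and their field-wise mean inherits neither
compensation), which is worth remembering when averaging families over
feature grids.
The archetype-separation experiment uses ten replicate 6-patient cohorts
of 0.25 cm$^3$ tumours, fits each patient with 8 sets per cell over
$T_d \in \{50, 200\}$ at CKR 0.2 under `VRP10`, and pools the 15 pair
errors per replicate into a one-sided rank-sum comparison.  These sizes
are the package's own choices for a self-contained demonstration; a
workstation analysis of a real cohort would raise `n` to the 100 sets per
cell used in the original workflow and widen the grids (the defaults of
`fit_patient()`).

## Known limitations

* No explicit oxygen/nutrient transport: hypoxia is a dormancy label
  driven by the crowding proxy, and reoxygenation after kill is implicit.
* No cycle-phase-specific radiosensitivity; no repopulation-onset switch —
  repopulation emerges from crowding release instead.
* Exponential (memoryless) phase residence rather than fixed-duration
  clocks: the mean durations are honoured, higher moments are not.
* The dead-cell census is part of the measured volume until cleared;
  clinical volumes may count differently depending on delineation
  practice.
* Cross-patient prediction shares nothing but parameters; it cannot
  capture anatomy-driven dose differences beyond what the target's own
  dose maps encode.
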