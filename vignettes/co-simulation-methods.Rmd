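---
title: "Co-simulation methods: from synthetic gait to screw-fixation failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-simulation methods: from synthetic gait to screw-fixation failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paosim)
```

## Scope and model chain

`paosim` implements a desk-scale co-simulation chain for evaluating screw
fixation of the acetabular fragment after periacetabular osteotomy (PAO):

1. **Synthetic gait** — parametric trials (hip angles, ground reaction
   force/moment, events) with group-level statistics for healthy,
   preoperative and postoperative cohorts.
2. **Gait processing** — normalization to the 0–100% cycle, Rancho Los
   Amigos (RLA) phase segmentation, medoid selection of typical trials and
   representative subjects.
3. **Musculoskeletal stage** — inverse dynamics on a simplified
   stance-limb linkage, polynomial muscle recruitment, hip joint reaction
   force (HRF) in body-weight (BW) multiples.
4. **Finite elements** — linear tetrahedral models of a parametric
   hemipelvis block with bonded cylindrical screws, CT-style density
   mapping, callus weakening, phase-wise load coupling.
5. **Failure analysis** — peak-stress statistics, mesh convergence, and
   incremental yield-load prediction under the maximum principal strain
   criterion, compared across fixation layouts.

Patient CT geometry and recorded gait are not inputs anywhere; every stage
is driven by the synthetic-data module, so the package's claims are
properties of the *methods*, not reproductions of any patient's numbers.

## The synthetic gait generator

Signals are sums of raised-cosine bumps and sinusoids over one 1.1 s cycle
with a 62% stance fraction (the standard convention). The vertical ground
reaction force is a mid-stance base plus two humps with compact support,
so swing-phase forces are exactly zero. Noise, when enabled, is
band-limited (white noise convolved with a Gaussian kernel, then rescaled)
because the kinematic channels are double-differentiated downstream; this
mirrors the low-pass filtering any motion-capture pipeline applies before
inverse dynamics.

The generator's defaults are the cohort conditions the package models:

* postoperative initial HRF peak 3.12 ± 1.41 BW and a flatter, wider
  second peak (2.00 ± 0.80 BW, a representative value for the "lower,
  flatter, sometimes absent" pattern);
* preoperative second peak 2.11 ± 1.03 BW;
* per-plane range-of-motion targets 35.5/14.3/13.6° (postoperative),
  37.6/11.5/8.4° (preoperative) and representative healthy values
  45/16/16°;
* healthy peaks 2.9/2.8 BW, representative of the balanced M-shape of
  normal gait under static-optimization muscle recruitment.

Because the reported peaks are properties of the *downstream* HRF rather
than of the raw force plate signal, the generator calibrates its two hump
amplitudes through the package's own musculoskeletal stage: a cached
fixed-point iteration matches the noiseless template peaks to the profile
means, then each seeded trial draws its own peak targets from the
profile's mean/SD and applies one further correction step. The calibrated
map is close to linear (recruitment scales linearly with the demand while
the active muscle set is stable), which is why a single correction step
suffices.

What the generator does **not** emulate: marker trajectories and soft
tissue artefact, inter-subject anatomy, asymmetric or pathological event
timing, and the correlation structure of real repeated trials. Passing
tests therefore demonstrate method correctness and calibration fidelity on
idealised inputs, not clinical validity.

## Gait processing choices

* RLA boundaries default to 0/2/12/31/50/62/75/87/100% of the cycle — the
  standard eight functional phases; they are configurable because the
  split is a convention, not a measurement.
* Typical-trial and subject screening both use k-medoids on the Euclidean
  distance between z-scored, concatenated signal curves. z-scoring keeps
  degree-valued angles from being swamped by Newton-valued forces. Medoid
  sets are found by exact enumeration whenever `choose(n, k)` is small
  (guaranteeing the optimum on the cohort sizes this package targets) and
  by PAM otherwise; both are deterministic, so no restart seeds are
  needed.
* HRF peak detection: the initial peak is the largest stance local maximum
  before 35% of the cycle; the second peak is a stance local maximum after
  35% exceeding the inter-peak minimum by at least 0.02 BW, otherwise the
  curve is flagged "flat" — the postoperative pattern where the second
  peak may disappear. The 35% boundary and prominence threshold are
  configurable.

## Musculoskeletal stage

**Strength scaling.** Generic model strength is scaled by
`F = F0 (k_m / k_L) (R_muscle,subject / R_muscle,generic)` with
`R_muscle = 0.5 - R_fat`: strength grows with body mass, shrinks with
height (longer levers), and is corrected by lean-mass fraction. The
denominator ratio is the generic model's own lean-mass fraction, so the
identity case returns `F0`.

**Muscle set.** Twelve elements in the four functional groups
(extensors, flexors, abductors, adductors — the superior gluteus maximus
classified with the abductors, as its gait function suggests). Attachments
are synthesized from representative physiological moment-arm vectors
(1–6 cm components) so that the set forms a well-conditioned positive
spanning set of the three hip moment axes: any demanded moment is
reachable with physiological forces, which a naive literal-attachment
reduced model does not guarantee. The iliopsoas instead carries explicit
origin/insertion geometry with a wrapping cylinder at the anterior pelvic
brim; its tangent-arc-tangent path is solved in the plane normal to the
cylinder axis with the axial travel recovered by unrolling. Moment arms
are held fixed over the cycle (quasi-static recruitment).

**Inverse dynamics.** The stance leg is a single lumped segment (16.1% of
body mass, centre of mass at 45% of the hip height, gyration radius 35%)
rotating about a fixed hip centre 0.9 m above the plate; ground reaction
force and moment act at the plate origin. Accelerations come from central
finite differences (one-sided at the ends). This is deliberately the
simplest linkage that exercises every quantity the downstream equations
need (3-axis net moments with gravity and inertia); it does not reproduce
published joint-moment curves sample-by-sample.

**Recruitment.** The force distribution minimises
`sum_i (f_i / N_i)^p` subject to `C f = r`, `f >= 0`, with `p = 3` (the
cubic criterion) by default and any `p > 1` supported. The solver works on
the dual: partial minimisation gives the closed form
`f_i = N_i (N_i s_i / p)^(1/(p-1))` with `s = max(0, C' lambda)`, the
smooth concave dual is maximised by BFGS, and a damped Newton iteration
polishes the multipliers to a constraint residual below `1e-6 (1 + |r|)`.
Infeasible demands are detected with a non-negative least-squares
diagnostic and reported with the residual. `p = 1` is rejected: the
criterion becomes a linear program whose solution is not unique, and
nothing in the pipeline needs it.

**HRF.** The joint reaction closes the force balance:
`HRF = -(sum_i f_i u_i + F_external + F_inertial)`, reported as a vector
in N and magnitude in BW (`mass * 9.81` N).

## Finite-element stage

**Geometry.** The hemipelvis is a 60 × 40 × 50 mm block cut by an oblique
osteotomy plane; the fragment is the material below the plane. Screws are
smooth cylinders (radius 3.25 mm, i.e. 6.5 mm PAO screws without thread
geometry) crossing the plane: three iliac-crest screws (IS), two oblique
plus one transverse screw (TS), or the five two-screw subsets
(2S-a … 2S-e). Screw elements share nodes with bone — bonded fixation.
Mesh generation validates that every screw has purchase on both sides of
the osteotomy. The geometry is deliberately non-anatomical: the quantities
under test (material mapping, load coupling, stress statistics, failure
protocol) are geometry-agnostic, and the parametric solid keeps every run
reproducible from code.

**Materials.** Hounsfield units map to apparent density by
`rho = (HU + 1.4246) * 0.001 / 1.058` above −1 HU and zero at or below
(the branch boundary is an acceptance-tested exact value). Density maps to
modulus by the power law `E = max(2017.3 rho^2.46, 1)` MPa — a published
pelvic/femoral mapping chosen because the density-modulus relation is a
configuration decision here; `nu = 0.3` for bone and screws; screws are
titanium alloy (110 GPa). A 1 cm band around the osteotomy surface is
degraded to 10% modulus to represent the healing callus (the weakening factor is a
modelling choice and is configurable).

**Elements and solver.** Constant-strain tet4 elements, one integration
point at the centroid; sparse Cholesky solve; global equilibrium holds to
1e-8 relative and the patch test to machine precision. Loads are coupled
to surface patches either by static equivalence (equal nodal split plus a
minimal-norm correction that realises a prescribed moment about the patch
centroid) or as consistent surface tractions. The coupled/uncoupled muscle-force
distinction maps to including or omitting the muscle-group
patch forces next to the joint contact force.

## Failure analysis

* `p100_mean`: mean of the 100 largest integration-point von Mises values
  (all values, flagged, when fewer exist).
* `wmv_s100`: the phase-peak weighted mean
  `sum_i p100_i (p_i / S_p)`; the weights use each phase's single maximum
  stress (the natural reading; configurable to use `p100` itself).
* Mesh convergence: refine from 4 mm in 0.5 mm steps until the maximum von
  Mises stress changes by less than 1% of the previous (coarser) value,
  then record one confirmation step. The variation rate uses the coarser
  mesh in the denominator; that convention reproduces the worked
  refinement example's 2.1% and 1.6% rates exactly.
* Yield: from the maximum-HRF gait phase load, scale upward in 10 N steps;
  an element fails when its maximum principal strain exceeds 0.73% tension
  or 1.04% compression (standard bone yield strains; the criterion source
  gives no values, so these are package defaults). The run stops when
  failed volume reaches 1% of bone volume (element-volume weighted, screws
  excluded). With deletion on (the default for single-model analysis),
  failed elements are knocked down to a negligible modulus and the system
  re-solved, stepping between failure events via the linearity of the
  current configuration — this is exact for the 10 N protocol and avoids
  re-solving at every increment. With deletion off the result comes from a
  single solve and analytic scaling; the two paths are cross-checked on a
  graded-stiffness bar in the tests.

## Cohort pipeline and statistics

`run_cohort_pipeline()` chains all stages per cohort profile and, when
fixation layouts are configured, runs the comparison harness on the
postoperative loads. The high-stress comparison contrasts per-phase
`p100` samples at phases 2–4: difference of means with SE and 95% CI,
and a one-way ANOVA F and p (ANOVA is the package's choice of two-group
test). The fixation-comparison harness defaults to the
no-deletion yield path and a 5 mm mesh so a seven-layout screen (7 × 8
phase solves plus yield scans, about 10^4 elements each) completes in a
couple of minutes on one CPU; single-model analyses can use finer meshes
and the deletion protocol. These problem sizes are the package's
desk-scale defaults, stated here so results are interpreted at the
resolution they were computed.

## Numerical edge cases

* Recruitment at `r = 0` returns zero force without invoking the solver.
* Fewer than 100 integration points: `p100_mean` averages all values and
  sets a `truncated` attribute.
* Degenerate phase weights (`S_p = 0`) and empty stress fields are
  errors, not silent zeros.
* Singular stiffness systems (insufficient constraints) raise a solver
  error naming the cause rather than returning garbage.
* The second HRF peak may legitimately not exist; all downstream code
  treats `NA` + `second_peak_flat` as a valid outcome.

## Known limitations

* The stance-limb linkage is quasi-static at the muscle level and lumps
  the leg into one segment; net moments are representative, not
  subject-accurate.
* Constant-strain tetrahedra are stiff in bending; peak stresses on coarse
  meshes underestimate, which is why the convergence protocol and its
  worked example are part of the test surface.
* Screw-bone interfaces are fully bonded; no contact, friction, thread
  geometry, or post-yield material behaviour.
* The parametric hemipelvis reproduces topology (fragment, plane, screws,
  coupling patches), not anatomy; absolute stress magnitudes are not
  comparable to patient-specific models, and the package asserts only
  ordering and protocol properties across layouts.
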