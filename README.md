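# paosim

Musculoskeletal–finite-element co-simulation of screw fixation after
periacetabular osteotomy (PAO).

PAO treats developmental dysplasia of the hip by cutting the acetabular
fragment free, reorienting it, and fixing it with a small number of
cortical screws — three iliac-crest screws (IS), two oblique screws plus a
transverse screw (TS), or, at the margin, only two screws (2S). Whether a
layout survives early postoperative gait is a biomechanics question:
muscle forces and the hip joint reaction force (HRF) load the healing
osteotomy through the screws. `paosim` implements the full desk-scale
analysis chain for that question, for researchers who want a tested,
reproducible reference implementation of each stage:

1. **Synthetic gait** — cohort profiles (healthy / preoperative /
   postoperative) generate hip-angle and ground-reaction time series whose
   downstream HRF reproduces the group statistics (e.g. a sharpened
   initial peak of 3.12 ± 1.41 BW after surgery, M-shaped double peaks in
   healthy gait).
2. **Gait processing** — 0–100% cycle normalization, the eight Rancho Los
   Amigos phases, k-medoid selection of typical trials and representative
   subjects.
3. **Musculoskeletal stage** — inverse dynamics on a stance-limb linkage
   and polynomial muscle recruitment: minimise `sum_i (f_i / N_i)^p`
   subject to `C f = r`, `f >= 0` (cubic criterion, `p = 3`), then
   `HRF = -(sum_i f_i u_i + F_ext + F_inertial)` in body-weight units.
4. **Finite elements** — tet4 linear elasticity on a parametric
   hemipelvis-fragment-screw mesh; Hounsfield units map to density
   (`rho = (HU + 1.4246) * 0.001 / 1.058`, zero at or below −1 HU) and to
   modulus (`E = max(2017.3 rho^2.46, 1)` MPa); a 1 cm callus band around
   the osteotomy is weakened; screws are bonded smooth cylinders.
5. **Failure analysis** — `p̄100` (mean of the top-100 integration-point
   von Mises stresses), the phase-weighted mean
   `WMV_s-100 = sum_i p̄100_i p_i / S_p`, a 1%-tolerance mesh-convergence
   protocol, and incremental yield loads (10 N steps, maximum principal
   strain criterion, stop at 1% failed bone volume).

Everything runs from code — no patient CT or motion-capture data is
required or used.

## Worked example

```r
library(paosim)

prof  <- cohort_profile("postop", noise_sd = 0)
trial <- generate_gait_trial(prof, seed = 1)
ida   <- run_ida(normalize_to_cycle(trial))
ida
#> Inverse dynamics + recruitment result: 101 samples, 12 muscles
#> HRF peak 1: 2.29 BW at 15%; peak 2: 2.11 BW at 41%

cmp <- compare_fixation_layouts(ida, layouts = c("IS", "TS", "2S-a"))
cmp[, c("fixation", "wmv", "p100_phase2", "yield_load_N", "yield_load_bw")]
#>   fixation       wmv p100_phase2 yield_load_N yield_load_bw
#> 1       IS  9.799407    10.05538     5592.719      8.770828
#> 2       TS 12.392768    12.26340     4112.719      6.449806
#> 3     2S-a 11.406000    11.73343     4902.719      7.688730
```

Read: this seed's postoperative trial produced a sharp initial HRF peak at
2.29 BW (each trial draws its own peak target from the 3.12 ± 1.41 BW
group distribution). On identical synthetic geometry, the transverse-screw
layout concentrates more stress (weighted mean 12.4 vs 9.8 MPa for IS)
and the two-screw construct yields below its three-screw parent
(4903 vs 5593 N) — the layout orderings the analysis is designed to
expose. The high-stress-phase contrast reports the standard
two-group statistics (difference of means, SE, 95% CI, F, p):

```r
compare_fixations(unlist(cmp[2, c("p100_phase2", "p100_phase3", "p100_phase4")]),
                  unlist(cmp[1, c("p100_phase2", "p100_phase3", "p100_phase4")]),
                  labels = c("TS", "IS"))
#> TS vs IS: difference of means 2.83 MPa (SE 1.6)
#> 95% CI [-1.6, 7.26]; F = 3.14, p = 0.151
```

`run_cohort_pipeline()` chains all stages from a single configuration and
writes a manifest; a thin command-line front end with the same stages
lives at `inst/cli/paosim`. Every result type has `autoplot()`, `tidy()`
and `glance()` methods. The methods vignette
(`vignettes/co-simulation-methods.Rmd`) documents the model assumptions,
parameter defaults and numerical choices.

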