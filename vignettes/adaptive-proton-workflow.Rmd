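---
title: "Assessing CBCT-based adaptive proton therapy on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing CBCT-based adaptive proton therapy on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptkit)
```

## The problem this package addresses

Intensity-modulated proton therapy (IMPT) of head-and-neck cancer is highly
sensitive to anatomical change: weight loss shrinks the external contour and
tumours grow or regress over the 6–7 week course, shifting the tissues that
set each proton spot's range. Cone-beam CT (CBCT) images acquired for daily
setup would be the natural trigger and substrate for plan adaptation, but
their HU fidelity is too poor for dose calculation. A practical workflow
deforms the planning CT (pCT) onto the CBCT to obtain a *synthetic CT* (sCT)
with trustworthy HU in the anatomy-of-the-day frame, recalculates or
re-optimizes on the sCT, and accumulates the weekly doses back on the pCT
through the inverse deformation to compare adapted against non-adapted
treatment, including the expected change in normal-tissue complication
probability (NTCP).

`aptkit` implements that entire assessment loop as reusable, tested
components, exercised end-to-end on synthetic digital phantoms so that every
step has a known ground truth and no patient data are involved. The package
answers two kinds of question:

1. *Validation*: how accurate is proton dose computed on an sCT, measured by
   3D gamma analysis against a gold-standard image in the same frame, and
   how trustworthy are DIR-propagated contours (Dice coefficient, and the
   dose-volume index error they induce)?
2. *Benefit of adaptation*: over a course with weekly anatomy sampling, what
   do coverage (V95/V100), organ-at-risk (OAR) dose and NTCP gain from full
   weekly re-optimization versus recalculating the initial plan?

## The phantom generator: what it emulates and what it does not

`phantom_spec()` / `build_planning_phantom()` construct an axial-cylindrical
neck: an elliptical soft-tissue body (40 HU) against air, spine and mandible
bone, a pharyngeal airway, and ellipsoidal/cylindrical OARs (spinal cord,
larynx, pharyngeal constrictors, parotids, oral cavity, esophagus). A
spherical tumour defines `CTV_primary`; 5 mm expansions define the secondary
and tertiary CTVs, prescribed 70/63/56 Gy in 35 fractions by default (one to
three levels, constrained to 56–70 Gy in 30–35 fractions). A high-HU box near
the teeth models dental streak artifacts, with its delineation mask, and an
anterior wedge provides the chin/teeth beam-avoidance region. The default
grid is 2 mm isotropic, 96×96×64 voxels — matching the planning dose-grid
resolution — and unit tests run mostly on a 4 mm, 48×48×32 version of the
same anatomy.

Weekly change is an *analytic* pull-back displacement field: a global
in-plane contraction about the body axis (weight loss; radius factor
`(1 - s)^week`) plus a Gaussian-enveloped radial dilation at the tumour
(growth factor `(1 + g)^week` near the centre). Analytic fields give the
test suite exact ground truth: the deformed CT and the "physician-corrected"
gold-standard contours are defined as the planning data resampled through
the field, and the numeric field inverse can be checked by direct
composition. Magnitudes are configuration, not constants, because weekly
change varies strongly between patients; the cohort defaults (2%/week body
shrink, ±3%/week tumour radius) produce displacement of a few millimetres
per week at the body surface — the scale at which adaptation decisions
become non-trivial. The CBCT model adds a radial low-frequency cupping bias
(±30 HU default), seeded Gaussian HU noise (15 HU default), and an axial
field-of-view (FOV) crop (80% default); voxels outside the FOV are flagged
invalid. It does *not* simulate projection physics, scatter streaks, or
motion, so validation numbers on the phantom bound only the
registration-and-transfer part of the sCT error chain, not detector physics.
Simplifications to note: the in-plane contraction is global, so bone shrinks
with the soft tissue (real spines do not), and tissue-class HUs are uniform,
which makes registration *harder* in homogeneous regions (no texture) and
easier at interfaces.

## Deformable registration

`deformable_register()` is a multi-resolution cubic B-spline free-form
deformation. Three stages/choices matter:

* **Translation stage.** A global translation is optimized first at the
  coarsest resolution. Image forces exist only where there is intensity
  gradient; in the phantom's homogeneous interior nothing else can carry a
  bulk setup shift, and the known-translation recovery requirement
  (sub-millimetre mean error for a 6 mm shift) is met exactly by giving the
  B-spline stage a translation-consistent initialization (constant
  coefficients represent a translation exactly, by partition of unity).
* **Similarity metric.** The default is sum-of-squared-differences with a
  radial quadratic cupping pre-correction of the fixed (CBCT) image,
  estimated on tissue voxels only. Locally normalized cross-correlation
  (LNCC) is implemented with exact box-filtered analytic gradients and
  available via `registration_config(metric = "lncc")`, but on
  piecewise-constant synthetic anatomy its normalized windows carry almost
  no signal and it underfits badly; bias-corrected SSD recovers the
  ground-truth weekly field to ~0.5 mm mean error. On real CBCTs, where
  residual shading is not a clean radial polynomial, LNCC would deserve
  another look.
* **Regularization and optimization.** B-spline coefficients are optimized
  by projected gradient descent with a backtracking line search (accepted
  steps never increase the objective, making the per-level metric trace
  monotone — a tested invariant). The coefficient gradient is the exact
  adjoint of the B-spline interpolation, mass-normalized so updates act as
  local force averages. Smoothness is a membrane (first-difference) penalty
  on coefficients: its null space is constant fields, so translations are
  free but linear extrapolation into metric-indifferent regions (air) is
  damped — a bending-energy penalty, whose null space includes linear
  fields, let such regions drift unboundedly.

`invert_dvf()` inverts fields by fixed-point iteration
`v <- -u(x + v(x))`, stopping at a composition residual below `tol_mm`
(default 0.1 mm) and failing loudly with the worst residual otherwise.

## Synthetic CT and contours

`build_sct()` applies the dental-artifact HU override (default 40 HU, the
surrounding soft tissue) on the pCT *before* warping, so the overridden
value is what gets transferred; it then resamples the overridden pCT through
the DVF onto the CBCT grid and, outside the FOV, copies the
(override-applied) pCT unwarped. The FOV seam is a hard switch with the
provenance mask attached to the result; no blending is attempted, so
downstream evaluation can flag structures crossing the seam (the inferiorly
extended tertiary CTV of the `fov_truncated` cohort phantom exists to
exercise exactly this caveat). Contours propagate by trilinear interpolation
of the 0/1 indicator re-thresholded at 0.5 — the package-wide mask
convention, chosen because it is symmetric and resolution-consistent; the
interpolation order for HU transfer is likewise trilinear.

## The analytic proton dose engine

The engine is a deliberately small pencil-beam model that preserves every
property the assessment depends on — water-equivalent range, scenario
response, linearity in spot weights — at desk scale:

* HU → relative stopping power (RSP) by a piecewise-linear calibration with
  a mandatory water anchor (`default_rsp_curve()`; editable YAML).
* Water-equivalent thickness (WET) by midpoint-rule integration of RSP
  along the beam axis; `wet_raytrace()` provides the general-direction
  primitive for validation.
* A documented analytic Bragg curve: entrance plateau (30% of peak) joined
  to a Gaussian peak with distal width `sigma_d = max(0.012 R, 0.8)` mm and
  peak depth `R - 0.668 sigma_d`, so the distal-80% depth equals the
  nominal range `R`; zero beyond `R_p + 6 sigma_d`.
* Lateral Gaussian spread growing with depth (`sigma = 3 mm + 0.03 × WET`).
* Setup-error scenarios shift the patient by `t` — equivalently the dose
  pattern by `-t` in the patient frame — with WET recomputed on the
  shifted anatomy; range scenarios scale each spot's nominal range.
* Influence matrices store dose per unit weight as sparse voxel×spot
  matrices; entries below 1e-4 of the per-spot maximum are dropped (this
  cutoff bounds the DVH error of the linear dose model).

Beams are coplanar fields along the cardinal lateral axes; the default
arrangement is two lateral opposed fields, a generic choice for mid-neck
targets (the assessment does not depend on beam angles, which real planners
pick per anatomy). Spot placement covers the field-specific target — the
CTV union expanded isotropically by the 3 mm setup margin, with energy
layers spanning the target's WET extent expanded by the 3% range margin —
plus one ring of border spots (4 mm allowance) beyond the lateral
projection: without those penumbra-covering "horns" no weighting can hold
the target rim under shifted scenarios. Rays crossing the chin/teeth
avoidance mask before the target are removed. RBE is a constant 1.1; all
doses reported are RBE-weighted.

## Robust planning

`enumerate_scenarios(3, 0.03)` builds the 12 uncertainty scenarios (six
signed cardinal 3 mm shifts × range scales 0.97/1.03); the nominal scenario
is carried separately and included in the robust set by default (the
alternative is a flag, since reasonable implementations differ).
`generate_objectives()` is the deterministic stand-in for DVH-prediction
automated planning: per CTV a robust minimum-dose objective at prescription
and a robust maximum at 103% of it (applied to the CTV's *exclusive* volume
where levels nest — inner volumes legitimately carry the higher level's
dose); per OAR one non-robust objective at 90% of its constraint-table
limit. The shipped constraint table covers body Dmax (115% of prescription),
spinal cord/brainstem/mandible maxima, parotid mean and V20Gy, larynx,
constrictor, oral-cavity, esophageal and other means; structures without a
table entry are excluded with a warning.

`optimize_weights()` minimizes the weighted one-sided quadratic penalties by
projected gradient descent (weights ≥ 0, uniform deterministic start,
backtracking line search, monotone objective trace). Robust target terms
default to the *per-voxel worst case* over the scenario set: each voxel is
scored at its minimum (coverage) or maximum (overdose) dose across
scenarios, with the gradient flowing to the voxel's active scenario. The
scenario-level worst-case and expectation aggregations are implemented and
selectable, but scenario-level minimax converges poorly under subgradient
descent (the active scenario flips each iteration) and stalls with
worst-case rim coverage around 80–90%; the voxel-wise form reaches
full robust coverage on the same iteration budget.

`normalize_factor()` fixes V100 = 95% for the primary CTV with an explicit
percentile convention: sorting the `N` CTV doses ascending,
`s = rx / d_(k)` with `k = floor(0.05 N) + 1`, so voxels `k..N` reach
prescription after scaling and ties break toward covering at least 95%.
The convention makes normalization idempotent and exact up to voxel
quantization (`100/N` percent). `robust_evaluate()` reports each CTV's V95
under every scenario and the worst case, with pass defined as
worst-case V95 > 95%. `adapt_plan()` re-runs the identical automated pass
on a weekly image — no warm start, so the adapted and initial plans are
methodologically interchangeable and the arms differ only by their input
anatomy.

## Evaluation conventions

* **Indices** (`dose_indices()`): Dmean is the voxel mean; Dmax the
  single-voxel maximum (no near-max percentile); VxGy and V95/V100 are
  percent of structure volume at or above the level, V95/V100 relative to
  each structure's own prescription.
* **Gamma** (`gamma_3d()`): 3D global gamma with the dose criterion as a
  percent of the primary prescription (the "global" normalization; a
  global-max alternative is a config choice), analyzed where the reference
  dose exceeds 10% of prescription, search radius 1.5×DTA, evaluated dose
  interpolated at DTA/3 steps (tests use DTA/10 against a brute-force
  oracle). γ ≤ 1 is a pass, inclusive, with a 1e-9 tolerance at the exact
  boundary.
* **Accumulation** (`accumulate_dose()`): the weekly samples stand for
  equal blocks of fractions (fraction 1, 6, 11, ...), so the accumulated
  dose is the fraction-weighted *average* of the weekly full-course doses
  warped through the inverse DVFs. This makes the accumulated dose directly
  commensurate with the planned full-course dose; weighting weeks by
  remaining fractions at course end would be an alternative had the
  sampling been irregular.
* **NTCP**: LKB, `NTCP = pnorm((gEUD - TD50)/(m TD50))` with
  `gEUD = (mean d^(1/n))^n`. The four default endpoints (larynx edema,
  dysphagia via constrictors, xerostomia via parotid, acute esophagitis)
  ship with *editable literature stand-in* parameters, each row carrying a
  source string — the package makes no claim that these are calibrated
  clinical models, and studies on real data must substitute audited values.
* **Statistics**: two-sided paired t-tests across the cohort
  (`paired_ttest()`, a thin wrapper over `t.test` with the zero-variance
  case reported as degenerate, p = 1).

## Study orchestration, problem sizes and determinism

`run_validation_study()` and `run_adaptation_study()` chain the modules per
phantom-week and emit tidy data frames (optionally CSV). The default cohort
spans six phenotypes: static, weight loss, tumour growth, tumour shrinkage,
combined, and weight loss with an inferiorly extended tertiary CTV
truncated by a reduced FOV. Everything is deterministic given the master
seed: per-phantom seeds derive as `master_seed + 101 i`, and CBCT noise
seeds mix the phantom seed with the week index.

The shipped studies are sized for a desk machine: unit tests run the 4 mm
48×48×32 phantom (a full robust plan in ~10 s), the acceptance checks run
one 2 mm plan (~1–2 min) and a 3-phantom × 3-week adaptation cohort at 4 mm
(~2 min). The same code runs the 2 mm 96×96×64 default throughout; only
wall-time grows. The registration-free mode (`use_registration = FALSE`)
substitutes the analytic ground-truth fields and exists to exercise the
planning/accumulation chain in isolation; the validation study always makes
sense only with registration on.

## Known limitations

* The dose engine has no nuclear halo, no Monte Carlo transport, no
  absolute MU calibration; beams are axis-aligned. Comparative conclusions
  (adapt vs non-adapt, sCT vs gold standard) are the intended use, not
  absolute dosimetry.
* The phantom's piecewise-constant tissues understate DIR difficulty in
  textured regions and overstate it in homogeneous ones; passing Dice/gamma
  thresholds here demonstrates correct mechanics, not clinical DIR
  validation.
* NTCP parameters are stand-ins; gEUD/LKB machinery is exact but the
  absolute probabilities are only as good as the parameter table.
* Setup error during re-optimization is retained (same robustness settings
  for both arms); an online-adaptive variant would justify shrinking the
  setup term.
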