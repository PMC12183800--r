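---
title: "Quantitative plan-of-the-day assessment: models and methods"
author: "potdassess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative plan-of-the-day assessment: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potdassess)
```

## The clinical problem

In library-based adaptive radiotherapy for locally advanced cervical
cancer, a small library of treatment plans is prepared before treatment,
each plan targeting the anatomy expected over a sub-range of bladder
filling. At every fraction a cone-beam CT is acquired and the plan of the
day (POTD) is chosen: the plan whose planning target volume (PTV) best
covers the day's clinical target volumes (CTVs) while irradiating the
least healthy tissue. Done by eye this is subjective and
resource-intensive; done quantitatively it needs three ingredients, which
this package provides:

1. **geometry** -- binary structure masks with physical-unit morphology
   (margin expansions, set algebra) and coverage statistics;
2. **HR-CTV propagation** -- the high-risk CTV is not visible on CBCT, so
   it is carried from the reference planning anatomy onto the daily
   anatomy by mask-to-mask deformable registration with the low-risk CTV
   as the controlling structure;
3. **a decision rule (qSOP)** -- a quantitative standard operating
   procedure that classifies every library plan as optimal, acceptable or
   unacceptable from its coverage statistics and flags fractions where no
   plan is safe to deliver.

Because clinical images cannot be redistributed, the package also ships a
synthetic female-pelvis phantom and plan-library builder so the whole
pipeline can be exercised, tested and audited end to end.

## Data model and conventions

All structures are `mask_volume` objects: boolean occupancy arrays in
`(x, y, z)` order (the native NIfTI layout) with voxel spacing and origin
in millimetres. The anatomical convention is +x = patient-left,
+y = anterior, +z = superior. I/O is deliberately literal: volumes are
read exactly as stored, spacing from `pixdim`, origin from the stored
xform translation, with no orientation reslicing. All masks of one case
must share a grid (spacing/origin equal within 1e-3 mm, absorbing header
float round-off); resampling between mismatched grids is out of scope and
left to the caller. Intensities are thresholded at > 0.5 on read so masks
written by lossy or float-valued writers still round-trip.

Margin expansion is the Minkowski sum with a *closed* Euclidean ball in
physical units: a voxel is occupied after expansion iff its centre lies
within the margin of some occupied voxel centre. Anisotropic spacing is
honoured exactly (the structuring element is enumerated in integer voxel
offsets whose physical length is within the margin). Coverage is
voxel-centre containment with no partial-volume weighting -- appropriate
for binary inputs, and consistent with using PTVs as a surrogate for the
high-dose region rather than running a dose model.

## Plan-library construction

`build_plan_library()` mirrors the clinical margin recipe: each sub-range
internal target volume (ITV) is the union of the LR-CTV over its group of
planning anatomies; sub-range ITVs grow by a uniform **5 mm** margin to
form PTV1..PTV3, and the union of all ITVs grows by **7 mm** to form the
robust PTV, last in library order. Because the robust ITV contains every
sub-range ITV and 7 mm ≥ 5 mm, the robust PTV contains every sub-range
PTV, which makes its coverage dominance a *theorem* of the construction --
the test suite asserts it on every generated library. The clinical
sub-range grouping involves judgement about physiological changes unseen
at planning (tumour regression, rectal filling); the builder simplifies
this to pure unions over sampled fillings, which is the one deliberate
departure from clinical practice and is stated here rather than hidden.

The HR-CTV used at planning is expanded by **10 mm** superiorly and
inferiorly and kept inside the LR-CTV (`expand_directional()` followed by
intersection), compensating for possible shrinkage or positional
uncertainty of the propagated contour.

## HR-CTV propagation

`propagate_hrctv()` re-implements the structure-guided propagation step:

1. the reference LR-CTV is the *moving* mask, the daily LR-CTV the
   *fixed* mask;
2. **affine initialisation** is closed-form moment matching: the
   transform maps the fixed centroid onto the moving centroid and scales
   each world axis by the ratio of per-axis standard deviations of the
   two masks. No iterative optimiser is involved, so it is exact for pure
   translations and axis-aligned scalings and cannot diverge. A full
   principal-axes rotation was considered and rejected: pelvic CTV masks
   are near-symmetric, making eigenvector sign/order unstable, whereas
   the axis-aligned form is deterministic and covers the motions the
   phantom (and bladder filling generally) produces. Degenerate masks
   fall back to centroid translation with a warning.
3. **fast symmetric-forces demons** runs on smooth scalar images made
   from the 0/1 masks by Gaussian smoothing (sigma = `smoothing_sigma_mm`,
   default 2 mm), block-mean down-sampled by `shrink_factor` (default 8,
   one stage, 20 iterations). The update at each voxel is
   `u = -2 (m - f)(grad f + grad m) / (|grad f + grad m|^2 + a^2 (m - f)^2)`
   with `a` the reciprocal mean coarse voxel size, which caps each
   per-iteration step at about one coarse voxel (the standard demons
   normalisation). The accumulated field is Gaussian-smoothed every
   iteration with sigma = max(`smoothing_sigma_mm`, half a coarse voxel):
   at shrink 8 the nominal 2 mm sigma is far below the coarse voxel size,
   so the floor keeps the field regularised independently of the shrink
   factor. The coarse field is up-sampled to the native grid by linear
   interpolation of each component.
4. the affine and demons transforms are composed **once** into a single
   displacement field, `T(x) = A(x + d(x)) + t - x`, and the reference
   HR-CTV is warped **once** through it (linear interpolation of the 0/1
   mask, threshold 0.5);
5. the warped HR-CTV is intersected with the daily LR-CTV, so containment
   in the controlling structure holds exactly, by construction.

All transforms use the pull-back (resampling) convention -- they map
fixed-space points into the moving image -- stated explicitly because
nothing breaks more silently than a reversed registration convention.
The pipeline is deterministic: there is no random initialisation, and the
result does not depend on any parallel execution of the caller.

## The qSOP decision rule

`assess()` applies a two-tier candidacy test followed by an OAR
trade-off, with every comparison recorded in a rationale:

* **optimal coverage tier**: LR-CTV ≥ 99% *and* HR-CTV ≥ 99.8% (inclusive);
* **mandatory coverage tier**, only if the first tier is empty:
  LR-CTV ≥ 95% with the same HR-CTV ≥ 99.8% requirement;
* if neither tier is populated, every plan is unacceptable and the
  fraction requires an intervention (bladder filling, bowel emptying, or
  replanning) before delivery.

Among candidates the plan with the least bowel coverage is the default
optimum. A challenger displaces it only through the **exception ladder**:
a rung grants the swap when the challenger's bowel increase is *strictly*
below the rung's allowance and its bladder sparing is *at least* the
rung's requirement, and no exception may exceed a 20% bowel increase cap.
The default ladder has two rungs, `{sparing >= 20% : increase < 10%}` and
`{sparing >= 40% : increase < 20%}`: the first rung and the cap are the
published anchors; the intermediate rung is a configurable placeholder
and institutions should review it (`qsop_config()` / YAML). Differences
are measured relative to the reference plan's covered organ volume
(`oar_diff_mode = "relative"`, matching how the assessment report
normalises its OAR columns), with a percentage-points mode available
because the distinction is genuinely ambiguous in clinical usage; when
the reference covers none of the organ a relative change is undefined and
the comparison falls back to percentage points with a warning. Ties are
broken by library order, so the robust plan -- last in the library -- is
chosen only when it is strictly better, consistent with tracking robust
plan usage as an escalation signal. Rectal coverage is computed and
displayed but never used in selection.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds the five structures as smooth parametric
shapes: a superellipsoid-like bladder whose volume interpolates
`bladder_volume_range_cc` (default 80-400 cc) linearly with a filling
fraction; a tapered bent-tube uterocervix whose tilt from vertical varies
linearly with filling (`tilt = uterus_tilt_deg + tilt_filling_coef_deg *
filling`, default 60 - 45*filling degrees: an anteverted uterus pushed
upright by a filling bladder -- the simplest monotone motion model that
orders the library by filling); the LR-CTV as the uterocervix plus a
12 mm lateral parametrial extension; the HR-CTV as the cervix segment of
the canal expanded 10 mm superior/inferior inside the LR-CTV; a posterior
rectal tube; and a bowel bag filling a superior/anterior compartment
minus the other structures (with a 2 mm serosal gap). Disjointness of the
organ roles and HR ⊆ LR therefore hold by construction. Each seed draws
small jitters of position, tilt, length and shape, so seeds are virtual
patients; generation is otherwise deterministic, and anatomy that cannot
fit the grid raises a geometry error rather than clipping silently.

The phantom gives the pipeline realistic *geometry and motion topology*
-- filling-driven target displacement, OAR crowding, margin-driven plan
ordering. It does **not** model CT/CBCT intensities, image artefacts,
tumour regression, rectal-filling variability, or inter-patient anatomy
beyond its jitters. Tests passing on the phantom therefore validate the
computational method -- metrics, morphology, registration behaviour,
decision logic -- not clinical segmentation accuracy on real CBCT.

Contour error is emulated by `perturb_mask()`: a smooth random
displacement field (low-pass-filtered Gaussian noise generated on a
coarse lattice, linearly up-sampled, unit-RMS normalised) whose amplitude
is tuned by bisection (at most 30 iterations, amplitude bracketed by half
the mask's bounding-box diagonal) until the Dice coefficient against the
unperturbed mask is within 0.03 of the target. Smooth low-frequency
fields are near-incompressible, so perturbed masks approximately keep
their volume -- matching how segmentation models err (boundary
displacement) rather than salt-and-pepper voxel noise.

## The virtual audit

`run_virtual_audit()` emulates an offline plan-selection audit at desk
scale: per case, a virtual patient is generated, a library is built from
a three-filling planning series (0.15, 0.5, 0.85), the daily anatomy is
drawn at a uniform random filling, and the ground truth is the assessment
of the clean daily masks. The daily structures are then perturbed with
*one shared* displacement field calibrated on the LR-CTV (correlated
contour error, as a single segmentation model would produce) and
re-assessed. Agreement is scored against the clean optimal/acceptable
sets, with "no acceptable plan" as a distinct outcome so that a
zero-error audit scores exactly 1.0. The audit's default problem size is
a 64^3 grid at 3 mm spacing -- the same 19 cm field of view as the
phantom default at a resolution where a many-case audit remains cheap;
the phantom's own default (96^3 at 2 mm) is used for the registration
accuracy checks, where resolution matters more.

## Numerical choices and degenerate inputs

* Grid equality tolerance 1e-3 mm; mask threshold > 0.5 at read; warp
  threshold 0.5 (so an identity warp reproduces a mask exactly).
* Margin 0 and directional margin 0 are exact identities.
* Coverage of an empty structure and DSC of two empty masks are errors,
  not zeros -- silent zeros would masquerade as "no coverage".
* Absent OARs propagate as `NA` columns, never as zeros; a zero-bowel
  reference plan yields an `Inf` difference sentinel with a warning.
* Demons guards against non-finite intermediates; out-of-volume samples
  are background; `stages` other than 1 and negative margins are argument
  errors.
* All stochastic components (phantom jitter, perturbation fields, audit
  case draws) take explicit integer seeds and restore the caller's RNG
  state.

## Known limitations

* The exception ladder between its published anchors is institutional
  policy, not a derived quantity; the default middle rung is a
  placeholder.
* The affine initialisation has no rotation component; a strongly
  rotated daily anatomy relies entirely on the demons stage.
* Single-stage demons at shrink 8 cannot recover deformations much
  sharper than its coarse grid; that matches its role of refining an
  affine initialisation between smooth CTV masks, not general DIR.
* Whole-organ masks are used for OAR coverage; a clinical system cropped
  to the imaging field of view would report different absolute bowel
  percentages (the *differences* used in selection are less affected).
* The phantom is a geometric stand-in; nothing in this package validates
  segmentation accuracy on real images.
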