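---
title: "The bposim model: geometry, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bposim model: geometry, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bposim)
```

## The procedure and the model

A bilateral pelvic opening-wedge osteotomy (BPO) cuts each ilium from the
anterior inferior iliac spine to the sciatic notch and opens an anterior
wedge of angle OA, hinging on the posterior cortex at the notch. In the
sagittal plane this is modelled as a rigid rotation: the caudal fragment
(acetabula, femora — represented by the femoral head centre) stays fixed
relative to gravity, and the cranial fragment (sacrum and, because the
spine is assumed rigid, the entire trunk: S1 endplate corners, T1 and C7
centroids) rotates by +OA about the fulcrum.

Two assumptions define the model's scope:

* **Rigid spine.** Lumbar lordosis is a carried constant. The model is
  therefore appropriate for fused, ankylosed or otherwise fixed deformities;
  it says nothing about how a flexible spine would respond. Correction is
  effected on pelvic incidence (which the osteotomy unlocks) rather than on
  lordosis.
* **One-dimensional muscles.** Muscle segments are straight lines between a
  cranial and a caudal attachment; no wrapping surfaces, via points, force
  or activation modelling. Broad muscles (gluteus medius/maximus) are split
  into anterior, middle and posterior segments because their fibres can
  lengthen and shorten simultaneously.

## Coordinate frame and sign conventions

All interfaces use a sagittal frame with x anterior-positive and
y cranial-positive, units mm; the origin is arbitrary. Angles are degrees
at every interface and radians internally. A positive opening angle is a
counterclockwise rotation of the cranial fragment in this frame, i.e. a
posterior displacement of the trunk (retroversion). These choices reproduce
the expected correlation pattern: SVA, PI and TPA decrease with OA while PT
increases.

The parameter conventions, chosen once and enforced by tests:

* **PT** is positive when the S1 midpoint lies posterior to the vertical
  through the femoral head (compensatory retroversion).
* **SS** is positive when the endplate descends anteriorly — the endplate
  faces antero-superiorly, as on any standing lateral radiograph. This is
  the orientation under which the identity **PI = PT + SS** holds exactly
  with PI measured between the endplate perpendicular at the S1 midpoint
  and the line from that midpoint to the femoral head. The identity is
  asserted (at 1e-9 degrees) inside `measure_parameters()` itself.
* **PI** is measured as a signed angle (counterclockwise from the caudal
  endplate perpendicular to the midpoint-to-femoral-head ray) so that the
  identity survives even contrived configurations where PT + SS crosses
  zero; for any plausible anatomy it is the usual positive angle.
* **TPA** is measured signed, positive when the femoral-head ray to T1 lies
  anterior of the ray to the S1 midpoint — equivalently TPA = PT + T1SPi.
  A signed TPA varies smoothly through zero as the trunk passes over the
  pelvis, which keeps it monotone in OA and lets the closed form track it
  exactly; the magnitude agrees with the unsigned radiographic reading
  whenever the reading is meaningful.
* **SVA** is the horizontal offset of the C7 centroid from the posterior
  S1 corner. Published definitions vary between the C7 and T1 plumblines;
  both landmarks are carried and the choice is a switch
  (`plumbline = "c7"` default, `"t1"` available).
* Under the osteotomy the endplate rotates rigidly with the fragment, so
  **SS(OA) = SS(0) − OA** exactly, and hence PT(OA) = PI(OA) − SS(0) + OA.

Degenerate inputs (coincident landmarks, S1 midpoint on the femoral head,
anterior corner not anterior) are rejected at construction with errors that
name the offending landmarks.

## The closed form and how its constants are fixed

The oracle (`oracle_predict()`) rotates landmarks and re-measures; the
closed form (`derive_geometry()` + `closed_form_predict()`) expresses the
same quantities as explicit functions of OA. The three arcsine kernels

$$\arcsin\!\left(\frac{\sin(\gamma_0 + OA)}{\sqrt{1 + k^2 - 2k\cos(\gamma_0 + OA)}}\right)$$

are law-of-sines angles in two triangles whose vertices are the fulcrum,
the femoral head, and either the S1 midpoint (sides `a`, `b`, ratio
`k = b/a` for the angle at the midpoint driving PI; ratio `k' = a/b` for
the angle at the femoral head driving TPA) or the T1 centroid (ratio
`k'' = a/L` for the angle at the femoral head driving T1 inclination). The
included fulcrum angle grows one-for-one with OA, which is what makes the
expressions closed-form.

Because only the baseline landmark positions are available at derivation
time, the angular offsets α1…α6 and the triangle orientation signs are
frozen per patient by requiring agreement with the oracle at OA = 0 and at
a 10-degree reference opening; thereafter the closed form is evaluated
independently of the oracle. The oracle is normative throughout: the test
suite requires agreement within 1e-6 degrees (angles) and 1e-3 mm (SVA)
over 0–40 degrees on seeded random patients, and the planner accepts either
engine.

One modelling note on the SVA expression: decomposing the plumb offset
through the fulcrum gives exactly

$$SVA(OA) = L_{pl}\,\sin(\varphi_{pl} - OA) + L'\cos(\alpha_4 - OA),$$

where $L_{pl}$ and $\varphi_{pl}$ are the baseline length and anterior
inclination of the fulcrum ray to the plumb landmark and $L'$ that of the
ray to the posterior S1 corner. The trunk term must use the fulcrum-ray
inclination (which falls one-for-one with OA), not the T1-to-femoral-head
inclination: with the trunk-length scalar defined as
$L = |fulcrum - T1|$ (the definition `k'' = a/L` requires), only the
fulcrum decomposition is exact, and it is what the package implements.

## The planner

The allowable opening angle is confined by the standard balance criteria
(−50 mm < SVA < 50 mm, TPA < 14°, PT < 20°, PI−LL < 9°), each evaluated as
a closed inequality — the distinction from the strict form is below solver
tolerance. Decreasing parameters bounded above yield lower bounds (the
smallest OA that corrects them); the increasing PT, and SVA continuing
through its lower limit, yield upper bounds. Each crossing is found by
bisection to 1e-6 degrees after a monotonicity check on a 0.5-degree grid;
bisection is used even for linear engines so that all engines share one
solver path. Feasible intervals are verified on a 0.1-degree grid (slack
1e-3 in each threshold's unit). Infeasibility is a result, not an error —
a patient whose baseline PT already exceeds 20° has no feasible wedge,
because opening only increases PT. PI−LL uses the baseline LL as a
constant, per the rigid-spine assumption.

## The muscle model

For a segment with fulcrum-centred in-plane lengths $l_1$ (cranial) and
$l_2$ (caudal), signed included angle β (counterclockwise from the caudal
to the cranial ray) and out-of-plane offset Δz, the post-osteotomy length
is

$$d(OA) = \sqrt{l_1^2 + l_2^2 - 2 l_1 l_2 \cos(\beta + OA) + \Delta z^2},
\qquad \lambda = d / L_0 .$$

β is deliberately **signed**, although the length formula itself is even in
β: every cranial attachment rotates by the same +OA, so whether a segment
lengthens or shortens at small openings is decided by the sign of β
(the chord derivative is proportional to $l_1 l_2 \sin(\beta + OA)$).
Anterior muscles (positive β: tensor fasciae latae, anterior gluteus
medius) lengthen; posterior ones (negative β) shorten. A segment within
1e-6 of λ = 1 is labelled isometric. Lengthening segments are flagged
unsafe only at the critical stretch, default `critical_sr = 0.254`
(25.4 %; some sources round to 25 % — it is a configurable parameter).
Shortening segments are considered safe: their attachments approach and
the muscle bears no stretch. This sign convention for muscle β is unrelated
to the β auxiliary angle of the closed-form TPA expression; they never
share a data structure.

### The packaged fixture

Subject-specific attachment geometry would normally come from a
musculoskeletal model; no such data ships with this package. The packaged
fixture (`default_muscle_fixture()`,
`inst/extdata/muscle_attachments_synthetic.json`) is **synthetic**:
eight segments whose (l1, l2, Δz, β) were solved (script in
`data-raw/muscle_fixture.R`) so that a 20-degree opening reproduces the
reference stretch pattern — anterior GMed +8 %, TFL +4 %, middle GMed
isometric (β = −10°, so isometry at 20° is exact by the symmetry
cos(β + 20°) = cos(β)), posterior GMed −6 %, GMax sections −5/−6/−8 %,
piriformis −5 % — with plausible segment lengths (baseline 59–191 mm) and
no segment approaching the critical stretch below a 40-degree opening.
The fixture demonstrates and tests the machinery; it does not reproduce
any real subject's moment arms, and per-subject attachment files should be
supplied for real planning.

## The synthetic patient generator

`make_patient()` inverts the measurement: femoral head at the origin; S1
midpoint at distance 0.22 × trunk height along the prescribed PT direction;
endplate corners (width 35 mm) oriented so SS = PI − PT; C7 placed so the
measured SVA is exact, at a height of trunk height + 18 mm; T1 placed just
below C7 (parameter 0.93) on a quadratic arc from the S1 midpoint whose
anterior bulge scales with LL — the trunk is rigid, so the arc is cosmetic
and only endpoint positions enter the model. The fulcrum sits 55 mm from
the femoral head at 35° posterior of vertical, a typical femoral-head to
sciatic-notch offset. Defaults (trunk height 420 mm, endplate width 35 mm)
are adult-scale values. Round-trip recovery of (PI, PT, SVA) is exact to
1e-9 by construction and asserted over 200 seeded random specs.

Cohorts are sampled uniformly from deformity-like ranges (PI 45–85°,
PT 15–35°, SVA 80–250 mm, LL 20–40°) with a fixed seed; no epidemiological
realism is claimed. What passing tests on these synthetic patients shows is
that the geometry, the closed form and the planner are mutually consistent
and behave monotonically across the plausible range — not that any
particular clinical population is represented, and not that the reference
case's specific linear coefficients (e.g. SVA slope −8.3 mm/degree) follow
from the generator: those depend on landmark geometry that is not publicly
available, so they are carried as the transcribed constants of
`example_linear_models()` and only their signs and near-linearity are
asserted for generated patients (fits over 0–40° at 1-degree steps reach
r² > 0.99).

## Decompensation of pelvic tilt

A posteriorly tilted pelvis (high PT) partially masks the deformity: SVA
looks better than the deformity warrants. `decompensate_pt()` rotates the
whole image — both fragments — about the femoral head until PT reaches a
chosen target before planning. PI is invariant under this whole-image
rotation (asserted at 1e-9 degrees), and removing compensation increases
SVA, unmasking the true correction target. Planning on the compensated
image under-corrects.

## Numerical choices

* Bisection tolerance 1e-6° on opening angles; monotonicity pre-check grid
  0.5°; interval verification grid 0.1° with slack 1e-3.
* Arcsine arguments are clamped within 1e-12 of [−1, 1]; beyond that the
  closed form errors, citing the offending opening angle.
* Opening angles are capped (default 60° for raw rotation, 40° for
  planning); negative openings are rejected.
* CSV output uses 6 fixed decimals for diff-stability; JSON landmark and
  attachment files keep full precision.
* Isometric tie-break: |λ − 1| ≤ 1e-6.
* Problem sizes in the test and acceptance runs — 20-patient cohorts on
  0–40° grids at 1° steps, 200 round-trip specs, 1000 random muscle
  segments — were chosen as the smallest sizes that exercise every branch
  and keep the whole suite comfortably fast.

## Known limitations

* PT and SVA after surgery also depend on hip position; the model assumes
  the compensatory mechanism relaxes as the deformity is corrected and does
  not model hip contracture, weakness or stiffness that could prevent PT
  normalisation.
* No modelling of fixation, grafting, weight-bearing, acetabular
  consequences, or intraoperative muscle injury.
* Landmarks are inputs; there is no image processing.
* The feasible interval is a range, not an optimum: no objective function
  ranks angles inside it.
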