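---
title: "Measuring subglottic stenosis from illumination decline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring subglottic stenosis from illumination decline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoscope)
```

## The problem

Subglottic stenosis (SGS) is a narrowing of the airway just below the
vocal cords. Its severity is graded by the stenosis index: the fraction
of the airway cross-section that is obstructed, judged against a healthy
reference section. In practice the index is estimated either from CT
(radiation exposure, unsuitable for frequent monitoring) or visually
during bronchoscopy, which is subjective and known to be inconsistent
between raters. `stenoscope` implements a fully automated two-stage
pipeline that produces the index from a bronchoscopy video alone, without
the scope ever traversing the stenosis.

Both stages exploit the same physical fact. In endoscopy the light source
is co-located with the camera, so image intensity declines with distance
$d$ to the tissue following the inverse square law and the camera's gamma
correction,

$$\mathcal{I} \approx \left(\tfrac{1}{d^2}\right)^{1/\gamma}.$$

Darkness is therefore a depth cue: the darkest image region is the lumen
(the open airway channel), and intensity itself supports a single-frame,
up-to-scale 3D reconstruction.

## Stage one: lumen tracking and keyframe selection

Each frame is converted to 8-bit luma (BT.601 weights) and thresholded at
intensity 50; the largest 8-connected dark component is the lumen
candidate. An IoU tracker associates it across frames: a detection whose
intersection-over-union with the last tracked segment is at least 0.5
continues the track, anything else is a *miss*. Misses do not update the
reference mask, and up to 25 consecutive misses are tolerated, which
makes the tracker robust to transient illumination changes. When the miss
run exceeds the patience the track is declared lost: the darkest segment
has changed shape for good, which happens exactly when the camera passes
the vocal cords and the subglottis comes into view. The *keyframe* is the
first frame of that terminal miss run — the frame where the appearance
first changed — not the frame where the patience ran out, which would be
25 frames too late.

All three constants (threshold 50, minimum IoU 50%, patience 25) are the
pipeline's standard operating point for real bronchoscopy footage and are
exposed in `tracker_config()`.

## Stage two: single-frame reconstruction and the indices

At the keyframe we invert the illumination model. The pure inversion
(`depth_from_intensity()`, estimator id `"photometric"`) is
$\hat d = I^{-\gamma/2}$ per pixel, up to one global scale factor. Pixels
at the noise floor (default below 0.02, where photometric information is
no longer sufficient) or at saturation (default 250/255, specular
highlights) are masked invalid.

The pure inversion ignores the Lambertian shading term
$n \cdot l$. On the airway wall that term is nearly constant, but at the
stenosis rim the surface turns away from the camera and $n \cdot l$
collapses towards zero, which would inflate the apparent rim radius by
$(n\cdot l)^{-1/2}$ — 40% and more. The package therefore ships a second,
shading-corrected estimator, `"tube_shading"`
(`tube_shading_depth()`), used by default for measurement. For a surface
of revolution viewed along its axis the shading term has a closed form in
terms of the ray-distance profile $t(\theta)$ over ray angle $\theta$:

$$n \cdot l = \frac{t}{\sqrt{t^2 + t'^2}},$$

which turns the photometric model into a one-dimensional ODE in
$q = \log t$:

$$q'(\theta) = -\sqrt{e^{4\,(q_0(\theta) - q(\theta))} - 1},
\qquad q_0 = -\tfrac{1}{2}\log I^{\gamma}.$$

$q_0$ is the pure inversion; the ODE is integrated inward from the image
periphery, where a straight wall supplies the initial condition
$n\cdot l = \sin\theta$. Integrating in that direction is *contracting*
(an error in the initial condition decays), so the profile stays accurate
all the way to the rim. On rendered phantoms the correlation with
ground-truth depth exceeds 0.999 and the median relative error is about
0.1%. A 2-D Lambert fixed-point iteration (alternating depth and
finite-difference normals) was evaluated first and diverges at the rim
discontinuity; the 1-D formulation is what makes the analytic route
viable. Its assumptions — roughly tubular anatomy, camera near the axis —
match the subglottis at the keyframe but *not* arbitrary endoscopic
scenes; for those, a learned single-frame estimator can be registered
through `register_depth_estimator()` and selected by id, which is the
intended path to clinical-grade reconstructions.

Valid pixels are back-projected through the intrinsics as unit rays
scaled by $\hat d$ (depth is Euclidean ray distance, consistent with a
light source at the camera centre). The dark stenotic region is
segmented with the same intensity rule as the tracker; the 3D points
under the *outer edge* of that mask delineate the stenosis contour. A
total-least-squares plane through the contour is intersected with the
cloud (a slab of half-thickness $\tau$), the slab points are projected
into the plane, and their convex hull gives the stenosis area
$A_{\text{stenosis}}$ plus a Kåsa least-squares circle for the diameter.
A series of camera-perpendicular planes is then swept between the camera
and the stenosis; the plane of maximum intersection area is the healthy
reference $A_k$ (ties resolve to the plane nearest the camera, which is
least occluded). The report is

$$\mathrm{PSA} = \left(1 - \frac{A_{\text{stenosis}}}{A_k}\right)\cdot 100,
\qquad
\mathrm{PSD} = \left(1 - \frac{d_{\text{stenosis}}}{d_k}\right)\cdot 100,$$

never clamped: negative values are flagged
(`reference_smaller_than_stenosis`) instead of hidden. Because every
quantity is a ratio within one cloud, both indices are exactly invariant
to the unknown global scale.

### Numerical choices

* **Slab tolerance.** Default $\tau$ is 2% of the median point distance —
  scale-free, so it tracks the up-to-scale ambiguity. `measure_cloud()`
  widens it to twice the median plane-fit residual of the contour when
  the reconstruction is noisy, so the stenosis slab never empties.
* **Sweep.** 50 planes from the 5th percentile of cloud depth to the mean
  depth of the stenosis slab.
* **Section boundary.** Convex hull of the slab points. With points
  sampled on a cross-section ring the hull is the ring polygon and the
  shoelace area converges to the true disc area from below; a concave
  boundary would only matter for strongly non-convex lumens, which the
  subglottis does not present at the keyframe.
* **Circle fit.** Kåsa's algebraic fit (a single linear solve): exact on
  circles, and flagged (`circle_fit_poor`) when the RMS radial residual
  exceeds 10% of the radius.
* **Degenerate inputs** error early with stage labels: fewer than three
  contour points, collinear plane/circle points, empty slabs, a keyframe
  with no pixel under the dark threshold.

## The synthetic phantom

Because no public SGS imagery with ground truth exists, every stage is
validated on a rendered phantom (`make_stenotic_airway()`,
`render_sequence()`) whose geometry and photometry are exactly known.

The airway is a straight surface of revolution: radius 10 mm, with a
smooth Gaussian narrowing (sigma 4 mm) to the stenotic radius at
z = 40 mm. The severity conditions used throughout the tests are stenotic
radii of 3, 5 and 7 mm — true PSD of 70/50/30 and PSA of 91/75/51. The
vocal cords are a thin membrane at z = 20 mm pierced by a 3 mm circular
aperture (a realistic glottal gap) whose edge passes through the tube
axis. The membrane, rather than a smooth funnel in the radius profile, is
a deliberate choice: with a funnel the darkest region — the set of rays
that reach the distal airway — evolves *continuously* as the camera
advances, so no tracker could ever observe an abrupt change at the cords.
With the half-occluding membrane the pre-transition dark segment is the
upper half of the distal view; the moment the camera crosses the plane
the full stenotic lumen appears, the IoU against the tracked segment
drops to about 0.45, and the keyframe fires exactly at the transition.
What the membrane does not attempt is realistic cord tissue: it is an
aperture, nothing more.

Rendering follows the spotlight model: linear radiance
$L = g\,\rho\,(n\cdot l)/d^2$ with ray-cast depth and analytic normals,
gamma encoding with $\gamma = 2.2$, additive Gaussian sensor noise
(sigma 0.01 on the [0,1] scale), 8-bit quantization, and a noise floor of
5/255 for lumen rays that exit the far end. The gain $g$ is chosen once
per sequence so the median wall pixel of the first pose encodes near 0.5,
keeping both dark-threshold and unsaturated regimes present. An optional
co-located Phong lobe provides specular highlights for testing the
saturation-masking path; it is off by default. The camera is 96×96 px
with a 100° field of view, travelling on-axis from z = 2 to 30 mm over
100 frames. With fixed seeds the renderer is bit-reproducible.

What the phantom does **not** emulate: breathing deformation, curved
centerlines, secretions, texture and albedo variation, off-axis camera
motion, rolling shutter. Passing the phantom suite therefore demonstrates
the correctness of the geometry, photometry inversion and index
arithmetic under the stated model — not clinical performance, which in
the real pipeline additionally depends on the quality of the plugged-in
depth estimator.

## A worked run

```{r run, eval = FALSE}
ph <- make_stenotic_airway(stenosis_radius = 5)   # true PSA 75, PSD 50
sq <- render_sequence(ph, axial_trajectory(ph), render_config(seed = 7))
out <- run_pipeline(sq$frames, default_camera())
out$keyframe$keyframe_index   # 64 == ground-truth transition index
out$report                    # PSA 73.4%, PSD 48.3%
```

Across 12 end-to-end phantom runs (three severities, four seeds each) the
mean absolute error is about 1.3 PSA points and 1.6 PSD points, with a
consistent slight underestimate; the keyframe lands inside
$[T-2,\,T+25]$ of the true transition $T$ in 20/20 seeded sequences.
These numbers are recomputed from scratch by `scripts/acceptance.R`.

## Evaluation utilities

`keyframe_correct()`, `mae()` and `consistency()` implement the study
metrics: whether the keyframe falls in an annotated optimal interval, the
mean absolute error $\mathrm{MAE} = \sum_i |GT_i - ce_i| / N$ against CT
or expert references, and the per-patient range/difference of repeated
estimations. The package ships the published per-sequence estimates for
the three patients with repeated procedures
(`repeated_procedure_estimates()`); running `consistency()` on them
reproduces the reported mean differences — 1.79 PSA points and 5.07 PSD
points between repeated automated runs, versus 7.5 points between expert
raters — which places the pipeline's repeatability at or better than
inter-expert variability.

## Known limitations

* The analytic estimators assume the co-located light model; strong
  secondary illumination, wet specular sheets or fogging violate it.
* `tube_shading` assumes near-axial viewing of a roughly tubular scene
  and azimuthal symmetry of the intensity profile; oblique keyframes
  degrade it gracefully but measurably.
* The reference section is measured *between the cords and the stenosis*,
  which is not the same location as the tracheal reference of the
  clinical Myer–Cotton grading; absolute grades are therefore not
  directly comparable and no grade assignment is attempted.
* Scale is never metric: all areas and diameters are up-to-scale, and
  only the ratio-based indices are reported.
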