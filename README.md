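# stenoscope

Automated severity estimation of subglottic stenosis (SGS) — the
narrowing of the airway between the vocal cords and the trachea — from
bronchoscopy video alone. The package is aimed at researchers in
endoscopic image analysis and at anyone who needs an objective,
repeatable stenosis index without CT and without the bronchoscope
traversing the stenosis.

## Method

Both stages of the pipeline are built on *illumination decline*: with the
light source co-located with the camera, image intensity falls with
tissue distance *d* as

    I ≈ (1 / d²)^(1/γ)

so the darkest image region is the lumen, and intensity itself yields an
up-to-scale single-frame 3D reconstruction.

1. **Tracking / keyframe selection.** Per frame, pixels with 8-bit luma
   below 50 are segmented; the largest 8-connected component is tracked
   with an IoU tracker (minimum IoU 0.5, patience 25 frames). When the
   tracked dark segment changes for good, the camera has just passed the
   vocal cords; that frame is the measurement keyframe.
2. **Reconstruction / indices.** Depth is recovered by inverting the
   illumination model (optionally with a shading correction for tubular
   scenes, or any registered learned estimator), back-projected through
   the camera intrinsics `K` into a point cloud `X₃D = π⁻¹(d̂, K)`. The
   dark-region contour defines the stenosis plane 𝒫; its slab
   intersection gives the stenosis area, a sweep of camera-perpendicular
   planes 𝒬ₖ gives the maximum-area healthy reference `A_k`, and circles
   are fitted to both sections:

       PSA = (1 − A_stenosis / A_k) · 100
       PSD = (1 − d_stenosis / d_k) · 100

Both indices are invariant to the unknown reconstruction scale.

A synthetic stenotic-airway phantom renderer (exact ray-cast depth,
inverse-square shading, sensor noise, seeded) makes every stage testable
without clinical data, and evaluation helpers implement the study
metrics: keyframe correctness, MAE against CT/expert references, and
same-patient consistency.

## Worked example

```r
library(stenoscope)

ph  <- make_stenotic_airway(stenosis_radius = 5)   # true PSA 75, PSD 50
sq  <- render_sequence(ph, axial_trajectory(ph), render_config(seed = 7))
out <- run_pipeline(sq$frames, default_camera())

out$keyframe$keyframe_index
#> [1] 64                      # == sq$ground_truth$transition_index
out$report
#> stenosis_report: PSA 73.44%, PSD 48.34%
#>   A_stenosis 1.236, A_reference 4.654 (plane 6)
#>   d_stenosis 1.257, d_reference 2.434
#>   flags: sparse_section
```

The keyframe lands exactly on the ground-truth vocal-cord transition
(frame 64), and the measured indices are within ~1.6 points of the
phantom truth (PSA 75, PSD 50) — a slight underestimate is the method's
characteristic bias. `sparse_section` flags that the stenosis slab holds
fewer than 50 points, normal at this rendering resolution.

A thin CLI wrapping the same functions ships at `inst/cli/stenoscope`
(subcommands `phantom`, `track`, `run`, `eval`).

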