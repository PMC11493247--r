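# curvecage

Curve-constrained, cage-based template deformation for segmenting organs
from spatiotemporal (4D = 3D + time) volume sequences, such as swallowing
4D-CT.

## The problem

Fast-moving organs (tongue, soft palate, larynx) have blurry, sometimes
invisible boundaries in 4D-CT, which defeats intensity-based segmentation.
An effective alternative is *template deformation*: an expert prepares a
watertight triangle-mesh template of the organ and deforms it, frame by
frame, to match boundary curves they trace on cross-sections of the volume.
`curvecage` is a scriptable library and batch CLI for exactly that workflow:
the curves are data (a JSON format), the deformation is a reproducible
optimization, and the output is meshes plus voxel label maps.

## The model

**Template = mesh + FFD cage + harmonic binding.**  The template mesh
*M* (vertices *v<sub>i</sub>*, *i* = 1…*N<sub>m</sub>*) is enclosed in a
coarse closed cage *C* (vertices *c<sub>j</sub>*, *j* = 1…*N<sub>c</sub>*).
Harmonic coordinates bind them:

&nbsp;&nbsp;&nbsp;&nbsp;*v<sub>i</sub>* = Σ<sub>j</sub> *a<sub>ji</sub>* *c<sub>j</sub>*

where the weights *a<sub>ji</sub>* solve Laplace's equation inside the cage
with generalized-barycentric boundary conditions (non-negative, partition of
unity, linearly precise).  The cage is the *only* deformation handle, so
curve-driven fitting, similarity alignment and manual cage edits all compose.

**Curve constraints.**  The user (or the synthetic-fixture generator) places
≥ 3 control points on an axis-aligned cross-section (XY / YZ / ZX plane).
They are interpolated with a κ-curve — piecewise quadratic Béziers whose
middle control points are optimized so every input point is the curvature
extremum of its segment — then resampled at equal arc-length intervals
*d* (default 1 mm) into constraint points *p<sup>c</sup><sub>k</sub>*,
*k* = 1…*N<sub>p</sub>*.  A curve can be *shared* across all frames: its
control points are linearly interpolated in time between explicitly edited
keyframes.

**Fitting (per frame).**  Alternate, for *n* = 20 iterations:

1. for each *p<sup>c</sup><sub>k</sub>*, find the closest point
   *p<sub>k</sub>* on the deformed mesh (barycentric on a triangle), and
2. update the cage by the exact minimizer of

&nbsp;&nbsp;&nbsp;&nbsp;α Σ<sub>k</sub> ‖*p<sub>k</sub>* − *p<sup>c</sup><sub>k</sub>*‖² +
β Σ<sub>j</sub> ‖*c<sub>j</sub>* − *c<sup>0</sup><sub>j</sub>*‖² +
γ Σ<sub>j</sub> ‖L(*c<sub>j</sub>*) − L(*c<sup>0</sup><sub>j</sub>*)‖²

with α = 1, β = 1, γ = 5; *c<sup>0</sup>* is the cage before the update and
L the degree-normalized graph Laplacian on the cage's polygon edge graph.
Since *p<sub>k</sub>* is a fixed linear function of the cage through the
binding, each update is one sparse SPD solve per coordinate axis.

A characterized failure mode: if the target is far from the template (e.g. a
strongly bent tube from a straight one), closest-point associations are
wrong and residuals plateau; diagnostics flag the frame as non-converged
(final mean residual > 25 % of initial).  The documented remedy is coarse
manual cage pre-alignment (`set_cage_vertices()`).

## Worked example

Fit a spherical template (radius 20 mm) to three orthogonal contours of a
24 × 20 × 16 mm ellipsoid:

```r
library(curvecage)
template <- bind_template(
  template_model(icosphere(20, 3),
                 box_lattice_cage(c(-23, -23, -23), c(23, 23, 23))),
  resolution = 48)

th <- 2 * pi * (0:11) / 12
curve <- curve_constraint("xy", cross_section_plane("XY", 0),
                          cbind(24 * cos(th), 20 * sin(th)), closed = TRUE,
                          frame = 0)
points <- collect_frame_constraints(list(curve), list(), t = 0, n_frames = 1)
fit <- fit_template_to_curves(template, frame_state(0, template$cage$vertices),
                              points)
fit$diagnostics$initial_mean   # 2.00  (mm, mean curve-to-template distance)
fit$diagnostics$final_mean     # 0.02  (mm, after 20 iterations)
fit$diagnostics$converged      # TRUE
```

With all three orthogonal contours (64 samples each) the mean residual drops
from 2.17 mm to 0.021 mm — a 99 % reduction; the deformed mesh is
`fit$mesh`, ready for `voxelize_mesh()` / `write_nifti()`.

The full synthetic pipeline (5-frame deforming sphere phantom, jittered
curves sampled from the ground-truth surface, batch fit, label export):

```r
ph  <- make_phantom_job(phantom_spec(seed = 7))
res <- run_job(ph$job)
mean_surface_distance(res$meshes[[2]], ph$ground_truth$meshes[[2]])
# 0.093 mm  (grid voxel = 1 mm)
dice_coefficient(res$labels[[2]], ph$ground_truth$labels[[2]])
# 0.993
```

## Command line

```sh
Rscript inst/cli/curvecage.R synth    --spec spec.json --seed 7 --out phantom/
Rscript inst/cli/curvecage.R bind     --mesh M.ply --cage C.obj --resolution 64 --out binding.rds
Rscript inst/cli/curvecage.R fit      --mesh M.ply --cage C.obj --binding binding.rds \
        --curves curves.json --grid grid.json --alpha 1 --beta 1 --gamma 5 \
        --iters 20 --interval-mm 1.0 --out results/
Rscript inst/cli/curvecage.R voxelize --mesh X.ply --grid grid.json --out X.nii.gz
```

Per-frame residual summaries are logged to stderr; a JSON config
(`--config cfg.json`) mirrors all flags, with explicit flags taking
precedence.

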