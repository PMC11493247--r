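---
title: "Methods: curve-constrained cage-based template deformation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curve-constrained cage-based template deformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its model, numerical choices,
and the design decisions that were genuinely open.  It states no empirical
result that the test suite does not itself compute.

## Model and assumptions

`curvecage` segments a 4D (3D + time) volume by fitting a deformable
template to user-supplied planar boundary curves, independently frame by
frame.  Three assumptions shape everything:

1. **The cage is the only deformation handle.**  The template mesh is never
   edited directly; every mesh vertex is a fixed affine combination of cage
   vertices through harmonic coordinates,
   $v_i = \sum_j a_{ji}\, c_j$ with $a_{ji} \ge 0$, $\sum_j a_{ji} = 1$.
   Consequences: similarity alignment is *baked into cage vertices* (so
   curve-driven fitting, alignment, and manual cage edits compose in any
   order), mesh topology is invariant under deformation, and the fitting
   optimization is a linear least-squares problem in the cage.
2. **Boundary evidence is curves, not intensities.**  The algorithm never
   reads voxel data; volumes contribute only the voxel-grid geometry of the
   exported label maps.  This is deliberate: the target application is
   organs whose boundaries a human can trace but thresholds cannot find.
3. **Topology is constant over time.**  Per-frame states share one cage
   topology; only vertex positions vary.  Shared curves exploit this:
   control points are interpolated linearly in time between user-edited
   keyframes, with the nearest keyframe held constant outside the keyframe
   range.

## The fitting optimization

Per frame, for a fixed iteration count $n$:

* **Association.**  Each resampled constraint point $p^c_k$ is associated
  with its globally nearest point $p_k$ on the currently deformed mesh,
  stored in barycentric form on a triangle.  The query is exact (every
  triangle is examined, with bounding-box rejection).  Equidistant
  candidates are broken toward the lowest triangle index *within a relative
  tie tolerance of $10^{-9}$*: for queries on the mesh's interior medial
  surface the nearest point is genuinely non-unique, and a strict `<`
  comparison would let machine-precision noise pick different triangles for
  rigidly transformed copies of the same problem.  The tolerance restores
  determinism *and* rigid equivariance simultaneously; both are asserted in
  the acceptance suite.
* **Cage update.**  The cage minimizes
  $\alpha \sum_k \|p_k - p^c_k\|^2 + \beta \sum_j \|c_j - c^0_j\|^2
   + \gamma \sum_j \|L(c_j) - L(c^0_j)\|^2$,
  solved exactly as one sparse SPD system per coordinate axis (the operators
  are linear and isotropic, so x/y/z decouple).  The cost is used exactly as
  written — no normalization by $N_p$ or $N_c$ — so the data term strengthens
  with denser resampling; a test pins this behaviour (halving the interval
  doubles $N_p$).

Tunable parameters, defaults, and why:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 1 | data term weight (must be > 0) |
| `beta` | 1 | per-iteration cage displacement penalty |
| `gamma` | 5 | penalty on the change of cage Laplacian coordinates (shape preservation) |
| `iterations` | 20 | outer alternations; fixed, no early stopping by default |
| `interval` | 1 mm | arc-length resampling interval; sub-voxel for 0.5–1 mm CT grids |
| binding `resolution` | 64 | harmonic-coordinate grid cells along the longest cage axis |

The defaults for $\alpha, \beta, \gamma, n$ are the published empirical
settings of the method this package implements; they are reproduced rather
than re-tuned.  An optional tolerance-based early exit
(`early_stop_tol`) exists but is off by default, to reproduce the fixed-$n$
procedure exactly.

**Graph Laplacian.**  Only "graph Laplacian" is specified upstream; this
package uses uniform degree-normalized weights
$L(c_j) = c_j - \tfrac{1}{|N(j)|}\sum_{m \in N(j)} c_m$ on the cage's
*original polygon* edge graph (not the fan triangulation).  Rationale: the
penalty's role is preserving the shape of a coarse, hand-authored control
cage, where cotangent weights are ill-defined for quads; and the authored
connectivity, not an internal triangulation artifact, should define
neighbourhoods.  Because $L$ kills constants, the shape term is exactly
translation invariant.

**Convergence diagnostic.**  A frame is flagged non-converged when the final
mean residual exceeds 25 % of the initial mean residual.  This is the
signature of the method's characterized failure mode: when the target shape
is far from the template (the bent-tube fixture: a 120° global bend from a
straight tube), closest-point associations are wrong and residuals plateau.
The flag is relative, so frames whose *initial* residual is already at the
curve-jitter floor can be flagged even though they are accurate in absolute
terms; the absolute residuals are always reported alongside.

## Harmonic binding: discretization choices

Harmonic coordinates are computed the classic way: a regular grid over the
cage bounding box (margin 2 cells so the exterior flood fill surrounds the
cage), cells within half a cell diagonal of the cage surface tagged
boundary, a 6-neighbour Laplace stencil on interior cells, one Dirichlet
problem per cage vertex, solved with (block) conjugate gradients to relative
residual $10^{-8}$.

Two choices deserve emphasis:

* **Boundary data lives on polygon faces.**  The Dirichlet value at a
  boundary cell is the generalized-barycentric (mean-value) interpolation of
  cage-vertex indicators at the closest point on the *polygon* face.
  Interpolating on the internal fan triangles instead would bias weights
  toward the fan diagonal: on a cube cage the measured center weights were
  0.19/0.10 with fan triangles versus the exact symmetric 1/8 with polygon
  mean-value coordinates.  Mean-value coordinates reproduce linear functions,
  so linear precision of the binding is preserved exactly in the continuum.
* **Row renormalization after trilinear sampling.**  Sampled weight rows are
  renormalized to sum exactly to one.  This makes `deform_mesh` exactly
  translation invariant — a property downstream tests rely on — at the cost
  of a vanishing distortion of the raw solution.

**On refinement convergence.**  The acceptance suite checks reconstruction
error (rest mesh reproduced from the rest cage) at resolutions 32/64/128 on
the cube-cage fixture.  On this fixture the boundary data is exactly
linearly precise and the flat axis-aligned faces make the boundary-cell
footpoint errors normal-direction dipoles that cancel, so the measured error
sits at the solver-noise floor (order $10^{-7}$ mm) at *every* resolution —
there is no discretization-error curve to observe.  The test therefore
asserts the decreasing *bound* chain (error below one cell diagonal, a bound
that halves per refinement) together with a noise-floor cap three orders of
magnitude below the bound, rather than comparing two noise samples for
monotonicity.  A green result establishes that reconstruction is
solver-limited, not discretization-limited, on this fixture.

## Curve model

The interpolating spline is the κ-curve: per input point one quadratic
Bézier whose middle control point is free, $G^1$ joints constrained to the
segments between consecutive middle points, computed by a local/global
fixed-point iteration (tolerance $10^{-6}$, cap 50):

1. joint ratios $\lambda_i$ from square-rooted adjacent triangle areas
   (equalizing curvature across each joint);
2. per segment, the parameter $t_i$ at which the segment must interpolate
   its input point so that the point is the segment's curvature extremum —
   the $[0,1]$ root of the cubic
   $|D|^2 t^3 + 3\langle e,D\rangle t^2 + (2|e|^2 - \langle e,D\rangle)t
   - |e|^2 = 0$ with $e = c_0 - p$, $D = c_2 - c_0$ (note $t_i$ depends only
   on the segment endpoints and $p$; computing it from the current middle
   point instead creates a feedback loop that visibly diverges);
3. a (cyclic) tridiagonal solve for the middle control points so every input
   point is interpolated exactly.

Each segment's sample set includes $t_i$ itself, so control points are
polyline *vertices* and the interpolation property holds to solver precision
rather than to polyline-sampling precision.  Collinear inputs reduce to the
straight segment; duplicate consecutive points are rejected.  A centripetal
Catmull–Rom fallback (`method = "catmullrom"`) exists solely to isolate
curve-model effects when debugging.

Open questions resolved here: shared-curve interpolation operates on
*control points* (drag-editing preserves their count, making pointwise
blending well defined), and both open and closed curves are supported, with
organ boundaries typically closed.

Resampling emits points at arc-length positions $0, d, 2d, \dots$; for
closed curves the wrap-around gap is structural (between $d/2$ and $3d/2$
unless $d$ divides the length), so the spacing-uniformity guarantee applies
to consecutive non-wrap intervals.

## The synthetic world

The fixture generator emulates the target setting — a single deforming organ
observed over a few frames — while staying geometric:

* **Shapes**: icosphere (radius 20 mm), ellipsoid (24/20/16 mm), capsule,
  and a bent tube; box-lattice cages with 15 % clearance (8–64 vertices).
* **Motion** (defaults chosen once as plausible for ~0.5 s of swallowing
  motion at organ scale): smooth sinusoidal time profile with peak
  translation 5 mm, peak uniform scale change 8 %, plus seeded low-frequency
  per-vertex cage offsets of peak 1.5 mm.  Frame 0 is the rest pose.
* **Curves**: ground-truth targets are deformed *through the cage*, so the
  optimum of a recovery test is exactly representable and any residual is
  algorithmic, not model, error.  Constraint curves are sampled from
  ground-truth cross-section loops (8 control points per curve, three
  orthogonal center planes) with 0.3 mm uniform jitter emulating imprecise
  clicks.  The bent tube is the one deliberately *out-of-model* fixture.
* Everything is deterministic under a recorded seed; `curvecage synth`
  writes a manifest of every parameter.

What a green test does **not** establish: robustness to real CT appearance
(the generator produces no intensities, no blur, no contrast agent), to
curves drawn on wrong planes or with gross outliers, to non-uniform
anisotropic motion beyond the cage's expressive range, or to multi-organ
collision.  Mesh cross-section control points also carry facet error
(chord sagitta ≈ 0.07 mm on the depth-3 icosphere), which is why analytic
near-exactness claims are tested against analytic contours, not mesh
sections.

## Numerical choices and degenerate inputs

* Harmonic solve: block CG, relative tolerance $10^{-8}$, one Dirichlet
  field per cage vertex sharing each stencil sweep.  A disconnected interior
  (resolution too low) is an error with advice to raise the resolution.
* Closest points: exact scan with AABB rejection; degenerate (zero-area)
  triangles are an error naming the triangle.
* Cage update: `Matrix` sparse Cholesky per axis; with $\alpha > 0$ and
  $\beta > 0$ the system is strictly SPD.
* Voxelization: even–odd parity along a $+x$ ray per voxel row, with a
  deterministic sub-voxel perturbation of the ray origin so edge-aligned
  hits are generic; edge-on (projected-degenerate) triangles are skipped —
  their parity contribution is carried by their neighbours.
* Watertightness = every edge in exactly two triangles; the self-intersection
  scan tests edges piercing non-adjacent triangles and does not detect
  exactly coplanar overlaps (documented in `validate_mesh()`).
* Similarity alignment is uniform-scale only; per-axis scaling is
  intentionally unsupported.

## Known limitations

* The closest-point association is purely positional; shape-aware matching
  is out of scope, so strongly displaced targets require manual cage
  pre-alignment (this is the characterized bent-tube failure mode, kept as a
  red-flag diagnostic rather than "fixed").
* Frames are fitted independently; no temporal regularization of the cage
  beyond shared-curve interpolation of the *inputs*.
* The NIfTI codec is the minimal single-file little-endian subset this
  package writes (int/float scalar volumes, axis-aligned sform); it is not a
  general-purpose reader.
* O(n²) self-intersection scanning and brute-force closest points are sized
  for template-scale meshes (10³–10⁴ triangles), not full anatomical scans.
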