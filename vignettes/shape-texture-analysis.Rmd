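---
title: "Joint shape and texture analysis on triangulated surfaces: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint shape and texture analysis on triangulated surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A *textured surface* is a triangular mesh with one scalar per vertex — in the
motivating application, a proximal femur carrying a mapped cortical property
such as cortical mass surface density. Given a cohort of such surfaces,
vertex-wise statistics (statistical parametric mapping, SPM) require every
specimen's texture to be expressed on one canonical mesh, which in turn
requires a correspondence between the canonical vertices and each individual
surface. In the featureless regions between distinguished anatomy this
correspondence is *ambiguous*: the same population variance can be booked as
shape variance, as texture variance, or traded continuously between the two.
Registration algorithms resolve the ambiguity differently, and because the
resolution depends on shape, the choice contaminates any analysis of how
texture depends on shape.

`gmia` implements the full pipeline — registration, Procrustes/PCA shape
modelling, vertex-wise GLMs with permutation cluster inference — together
with a synthetic cohort generator whose ground truth is known exactly, so
that the contamination can be measured rather than assumed.

# Data model and conventions

Meshes store vertices in millimetres (right-handed frame) and 1-based face
indices with counter-clockwise orientation; validation enforces index range,
edge-manifoldness and orientation consistency. On disk, PLY/OBJ and the
landmark/correspondence CSVs use the formats' native 0-based indexing; the
conversion happens only at the I/O boundary. PLY files are written with
double-precision properties so write/read round trips are exact; the
per-vertex texture travels as a named vertex property (default `texture`) or
a `vertex,value` sidecar CSV.

Landmarks are typed: homologous `point` landmarks never move; `curve`
semilandmarks may slide tangentially along their (ordered) curve; `surface`
semilandmarks may slide in the tangent plane. Locations are intrinsic
(face + barycentric coordinates), so landmarks survive mesh deformation.

# Registration algorithms

All nonrigid registrations start from an iterative-closest-point similarity
alignment (rotation, translation, isotropic scale; weighted Umeyama fit).
ICP here is only an initialiser: it runs on a deterministic subsample of at
most 800 source vertices and stops when the mean vertex motion falls below
0.01 mm. Closest points are true point-to-triangle feet (not nearest
vertices), computed against a uniform-grid spatial index seeded with the
nearest vertex's one-ring.

**Locally affine deformation (LAD).** Every canonical vertex `k` owns a
frozen neighbourhood `N_k` — all vertices within Euclidean distance `d` on
the *undeformed* canonical mesh — with Gaussian proximity weights
`exp(-r²/2σ²)`, `σ = d/3`, truncated at `d`. Each iteration (1) pairs every
vertex with its closest point on the target, (2) fits a weighted rigid
transform (Kabsch) over each neighbourhood's pairs, and (3) moves each vertex
to the proximity-weighted average of its images under its neighbours'
transforms. `d` is the only parameter: small `d` permits more deformation,
large `d` smoother fields; `d = 15` mm is the shape-driven default.
Convergence is a mean update below `1e-3·d`, capped at 100 iterations.
Near-collinear neighbourhoods fall back to a pure translation (counted and
reported). For the local fit and blend the neighbourhood is subsampled
(distance-stratified, deterministic) to at most 300 members: at the default
resolution a 30 mm ball contains most of the mesh, and a local rigid fit is
statistically saturated long before that; `vertex_neighbourhood()` itself is
exact.

**LAD-TEX-d.** After LAD converges, iterations continue with
texture-similarity pairing: each canonical vertex is paired with the target
*vertex* within a 3 mm search radius whose texture value is closest (ties by
distance; empty search sets fall back to closest point). Because discrete
vertex pairing hops indefinitely, the texture phase stops either on the
geometric tolerance, after 50 iterations, or when the RMS paired-texture
mismatch improves by less than 0.1% in an iteration.

**TPS and TPS-LM.** Sliding-semilandmark registration with the 3D thin-plate
spline, kernel `U(r) = r`, exact interpolation (no regularisation, duplicate
guard at 1e-9 mm, coplanar-control guard). Since `|r|` is conditionally
negative definite, the bending energy is `-Σ_d w_d' K w_d ≥ 0`, zero exactly
for affine maps. Sliding minimises the bending energy of the canonical-to-
target landmark map by a closed-form generalised-least-squares step per
iteration (curve tangents by central differences, one-sided at endpoints;
surface tangent planes from face normals), followed by re-projection onto
the target surface or curve polyline; steps that fail to lower the energy
after projection are rejected, making the energy trace non-increasing. TPS
uses only automatically placed surface semilandmarks (farthest-point sampled;
476 by default); TPS-LM adds the homologous point and curve landmarks, which
must be supplied on the target — they encode expert knowledge that geometry
alone cannot recover. Target surface semilandmarks are initialised by ICP
transfer; the final warp maps every canonical vertex and projects onto the
target so correspondences always lie on the target surface.

**Perfect registration** returns the generator's stored vertex bijection and
is the oracle the other algorithms are measured against.

# Shape model

Registered specimens (deformed canonical vertex sets) are translated to a
common origin, scaled to unit centroid size (root-sum-of-squares distance to
the centroid), rotated onto the undeformed canonical mesh by orthogonal
Procrustes (determinant +1), and then rescaled by their centroid size — size
deliberately remains in the model, so that overall femur size can surface as
a shape mode. PCA is computed by SVD of the centred `n × 3V` coordinate
matrix with `(n-1)` covariance normalisation; mode signs are fixed so each
mode's largest-magnitude entry is positive. Shape coefficients are
`S_ik = m_k'(X_i - X̄)`.

# Vertex-wise GLM and cluster inference

`fit_glm()` solves ordinary least squares independently at each vertex via a
single QR decomposition; residuals are orthogonal to the design and
fitted + residual reconstructs the data exactly. Vertices with zero residual
variance (possible in noise-free synthetic data) are assigned `t = 0`
rather than 0/0. Effect maps are reported the way the field reads them:
`100·β·Δ/mean texture` for a `Δ`-unit contrast (a ±1-coded group uses
`Δ = 2`), or per sample SD of the regressor.

Cluster significance uses permutation rather than random-field theory:
two-sided supra-threshold clusters (`|t|` above the t-quantile of the
uncorrected p = 0.001 threshold at `n - p` df) are formed on the mesh edge
graph, and each observed extent is referred to the null distribution of the
*maximum* extent over Freedman–Lane permutations of reduced-model residuals
(corrected `p = (1 + #{perm ≥ obs}) / (n_perm + 1)`; default
`n_perm = 1000`, seeded). Permutation is exact under exchangeability at
these sample sizes and avoids the resel machinery random-field theory would
need on an irregular mesh. Only single-column t-contrasts are supported.

Note the discreteness caveat: with spatially white data the null maximum
cluster extent concentrates on tiny integers and the test becomes very
conservative. The calibration check in the test suite therefore simulates
smooth null fields (10% RMS, 30 mm FWHM), matching the smoothness SPM
assumes of its inputs; observed familywise error then sits inside the
binomial band around 5%.

# The synthetic cohort

The generator is the package's ground-truth instrument; its defaults *are*
the study conditions.

**Femur proxy.** A closed genus-0 mesh built by shrink-wrapping an icosphere
onto the union of two convex primitives sharing the hinge point — a
flat-capped shaft cylinder (radius 13 mm, length 78 mm) and a neck-to-head
"round cone" (neck radius 11 mm, length 40 mm, head radius 19 mm, neck-shaft
axis 50° from the shaft) — plus a fovea dimple and a trochanter bump applied
along vertex normals. Default resolution 5120 faces / 2562 vertices (the
face-count argument rounds up to an icosphere subdivision level). The proxy
carries three homologous points (fovea centre, trochanter apex, a junction
point), three curves (head–neck boundary ring, shaft truncation rim, a
12-point calcar line along the inferior neck) and the two effect patches.

**Armature.** Two bones hinged at the neck–shaft junction, hinge axis
perpendicular to the shaft/neck plane; skinning weights are 0 on the shaft,
1 on the head, and a smoothstep blend over the 6–22 mm band of the neck
axis. Bending rotates each vertex by `weight × θ` about the hinge
(Rodrigues), so faces are unchanged and the identity vertex map is the exact
ground-truth correspondence.

**Baseline texture.** The real canonical femur and its population-mean
texture are not available, so a synthetic smooth positive field (mean level
~100 units, labelled synthetic throughout) stands in: gentle large-scale
harmonics plus a dense band at the mid-calcar and a denser inferior head
region. The localized extrema matter: they give the texture non-trivial
gradients along the calcar, which the misregistration experiment needs.

**Cohort.** 41 angles (−20°…+20°, 1° steps) × 2 groups = 82 specimens.
Texture: `baseline × (1 + g·0.10·taper_I) × (1 − 0.01·θ·taper_S) + noise`,
with `g = ±1` group coding and cosine tapers falling from 1 inside 80% of
each 9 mm patch radius to 0 at the rim, so the effects are exactly
multiplicative at the cores and exactly absent outside the patches.
Generation errors if the patches overlap. The 9 mm radius is a geometric
necessity as well as a choice: the superior and inferior patches sit on
opposite sides of a ~22 mm-thick neck, and Euclidean patch disks much larger
than ~9 mm would intersect through the bone, making the two effects
inseparable by construction. Noise is white Gaussian per vertex diffused to
10 mm FWHM, centred, and rescaled to *exactly* 10% RMS of the mean baseline;
fields are generated on the canonical geometry (bending is per-vertex rigid,
hence near-isometric) with per-specimen seeds derived from the cohort seed.

**What the generator does not emulate.** Real segmentation and
cortical-mapping noise is not a stationary smoothed Gaussian field; real
femora vary in many more ways than one hinge parameter; the proxy's geometry
is topological, not anatomical. Consequently the absolute discrepancy levels
(~10% for perfect registration here) are not comparable with real-cohort
values; only orderings and recovered effect sizes are meaningful, which is
why the experiments assert those.

**Smoothing convention.** `smooth_texture()` is heat diffusion under the
cotangent Laplacian with barycentric lumped areas for total time
`t = FWHM²/(16·log 2)`, taken in explicit Euler steps at half the stability
limit; on a plane this reproduces a Gaussian of the requested FWHM, and on a
closed mesh it conserves the area-weighted mean exactly. Gaussian curvature
is the angle deficit normalised by cotangent (Voronoi) vertex areas —
barycentric areas bias the sphere estimate by ~15% at valence-5 vertices —
with a barycentric fallback at obtuse corners.

# The experiments

`run_synthetic_study()` registers the textured canonical proxy to all 82
specimens with each requested algorithm (sharing the ICP alignment, frozen
neighbourhoods and shape-driven LAD state across algorithms — results are
identical to the standalone functions), then computes per-algorithm mean
texture discrepancy, the shape model (cumulative variance over 20 modes,
mode-1 correlation with the true angle), the GLM
`1 + Gender + S1 + S2 + S3`, gender and per-SD shape-effect maps, and
patch-core summaries (mean over the central 50% of the patch radius, away
from the taper).

Two estimator details deserve record. First, the generator's −1%/degree
effect corresponds to 11.5% per SD of the continuous uniform ±20° angle
distribution (SD = 40/√12 ≈ 11.55°). Second, the "+20° versus canonical"
texture reduction at the superior patch is read off the fitted model's
*linear response* of predicted texture to angle (slope × 20°) rather than by
evaluating the linear model at the +20° endpoint of the shape-coefficient
trajectory: the bend family is a curved one-parameter manifold, so its
higher modes are symmetric or numerically null, and endpoint evaluation
hands their noise-dominated coefficients ~3-SD leverage. The linear response
is the same model quantity (the generative effect is linear in angle, and
the estimate is exactly 20% at zero noise) with several-fold smaller
Monte-Carlo variance.

`run_misregistration_sensitivity()` quantifies what sliding misregistration
along a textured curve looks like: identical copies of the canonical
surface, the calcar curve landmarks converted to *fixed points* displaced
along the curve trajectory by each specimen's displacement (the polyline is
extrapolated along the surface beyond the digitised span so end landmarks
can move; displacement past the extended trajectory is an error), TPS-LM
registration, then a GLM of registered texture on displacement. Sliding a
texture with a local extremum produces a *bipolar* %/mm effect along the
curve — opposite signs on the two flanks — whereas a genuine physiological
effect is typically monopolar; `classify_polarity()` formalises the
distinction. With all displacements zero the population is identical, the
regressor is constant, and the report is the exact null (no estimable
effect, empty mask) rather than a 0/0 artefact.

`run_ribbon_study()` is the one-dimensional demonstration: ribbons on [0, 1]
warped by `w_s(u) = u + (s/2π)·sin(2πu)` (identity at `s = 0`, fixed ends,
monotone for `|s| < 1`), `s` uniform over ±0.9, 201 individuals, base
texture a sum of three Gaussian bumps. The warp is linear in `s`, so the
shape-only reading needs exactly one PCA mode for 99% of the variance; the
texture-only reading (identity correspondence) needs several. The exact
texture-mode count depends on the profile and warp family, which is why
tests assert "more than one", not a specific number.

# Problem sizes and runtimes

The default study conditions (2562-vertex proxy, 82 specimens, six
algorithms) complete in a few minutes on one CPU; the full test suite,
including the six-algorithm study, the sensitivity analysis and a
200-simulation familywise-error calibration (reduced to 200 permutations per
simulation on a 162-vertex sphere), runs in roughly three minutes. Unit
tests use a 642-vertex proxy where study-scale geometry is not required.

# Known limitations

- LAD makes no diffeomorphism guarantee; folding is empirically absent at
  `d ≥ 15` mm on the proxy but is not prevented.
- Cluster inference offers single-column t-contrasts only; no F-tests over
  multi-column contrasts, no mixed models.
- Euclidean (not geodesic) distances define patches and LAD neighbourhoods;
  on thin structures a Euclidean ball can bridge anatomically distant
  surface regions, which is exactly why the default patch radius is small.
- The spatial index attached by `index_mesh()` is an external pointer and
  does not survive serialisation; it is rebuilt transparently when absent.
- The sensitivity experiment's zero-noise population makes t-statistics
  scale-free; its significance masks are therefore sharp and should be read
  qualitatively (polarity, location), not as effect sizes.
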