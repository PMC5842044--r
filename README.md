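# gmia — geometric morphometric analysis of textured surfaces

`gmia` is an R package for the joint statistical analysis of **shape** and
**surface texture** across cohorts of triangulated surfaces that carry one
scalar value per vertex — the situation that arises in cortical bone mapping,
where each proximal femur is represented as a mesh textured with a cortical
property such as cortical mass surface density (CMSD, mg/cm²). It is aimed at
researchers running surface-based statistical parametric mapping (SPM) who
need to understand, and control, how the choice of surface registration
algorithm shapes their statistical maps.

The central difficulty is that vertex correspondence between specimens is
inherently ambiguous: the same population variance can be explained as shape
variation, as texture variation, or as any mixture of the two. Different
registration algorithms resolve the ambiguity differently, and
shape-dependent misregistration masquerades as statistically significant
texture effects. `gmia` packages the complete tool chain needed to study and
manage this:

- **Mesh core** — validated triangle meshes with per-vertex textures, PLY
  (ascii/binary) and OBJ I/O, fast closest-point queries, barycentric texture
  transfer, heat-kernel smoothing to a stated FWHM, Gaussian curvature, and
  the RMS texture-discrepancy metric (in % of the mean texture).
- **Registration** — six algorithms producing a `CorrespondenceMap` from a
  canonical mesh onto each target: a ground-truth oracle for synthetic data;
  locally affine deformation (LAD, neighbourhood radius `d`); its
  texture-driven variant LAD-TEX-`d` (3 mm texture search); thin-plate-spline
  sliding semilandmarks (TPS); and TPS-LM, which adds homologous point and
  curve landmarks. All start from an ICP similarity alignment.
- **Shape model** — Procrustes standardisation against the canonical mesh
  (size retained by rescaling with centroid size) and a PCA shape model
  `X_i ≈ X̄ + Σ_k S_ik m_k` with orthonormal modes `m_k`, eigenvalues, and
  per-specimen shape coefficients `S_i`.
- **SPM** — the vertex-wise general linear model
  `y_j = β_0j + Σ_i β_ij x_i + ε_j`, effect maps in % of the cohort mean
  texture (per unit or per SD of a regressor), and cluster-extent
  significance by Freedman–Lane permutation of the maximum supra-threshold
  cluster extent (cluster-defining threshold p < 0.001, two-sided).
- **Synthetic data** — a parametric femur proxy with a two-bone armature so
  the neck–shaft angle can be bent ±20°, a landmarking scheme (fovea,
  trochanter, head–neck ring, shaft rim, calcar curve), an 82-specimen cohort
  with known texture effects (±10% by group at the inferior neck patch,
  −1%/degree at the superior patch, 10% RMS smooth noise), a 1D textured
  "ribbon" population demonstrating the ambiguity, and a misregistration
  sensitivity analysis with monopolar/bipolar classification.

## Worked example

Generate the synthetic cohort and run the full comparison of registration
algorithms:

```r
library(gmia)
proxy  <- make_femur_proxy()
#> femur_proxy: 2562 vertices, 5120 faces, 63 landmarks
cohort <- make_cohort(cohort_spec(seed = 1), proxy)
#> cohort: 82 specimens (41 angles x 2 groups), 2562 vertices

perfect_register(cohort, "m_+20")
#> registration_result [perfect]: 2562 vertices, 0 iterations
#>   texture discrepancy: 9.95%

run_ribbon_study()
#> experiment_report
#>   ribbon: 1 shape mode(s) vs 5 texture mode(s) for 99% variance

report <- run_synthetic_study(cohort_spec(seed = 1), proxy = proxy,
                              cohort = cohort, seed = 1)
report
#> experiment_report
#>   perfect     discrepancy 10.17%  total shape var     9647.6  gender@I +19.73%
#>   tps         discrepancy  9.75%  total shape var     7577.6  gender@I +19.68%
#>   tps-lm      discrepancy  9.96%  total shape var     8114.1  gender@I +19.72%
#>   lad         discrepancy  9.43%  total shape var     2856.8  gender@I +19.88%
#>   lad-tex-15  discrepancy  7.27%  total shape var    43452.3  gender@I  +7.62%
#>   lad-tex-30  discrepancy  8.07%  total shape var    22859.7  gender@I +13.70%
```

Reading the table: with ground-truth ("perfect") correspondences the residual
texture discrepancy is ~10% (the injected noise plus the systematic patch
effects), and the GLM `1 + Gender + S1 + S2 + S3` recovers the 20%
male-versus-female texture difference at the inferior-patch centre
(`gender@I`, here 19.7%). Every *shape-driven* algorithm (TPS, TPS-LM, LAD)
recovers the same gender effect, because their correspondences cannot depend
on a regressor that is independent of shape. The *texture-driven* LAD-TEX
variants buy a lower texture discrepancy (7–8%) at the cost of a much larger
total shape variance — the variance has been moved from texture into shape —
and an attenuated, biased gender estimate (7.6% and 13.7%): once
correspondences chase texture, group differences leak into the shape
coefficients and out of the texture analysis.

The ribbon study is the one-dimensional caricature of the same trade-off:
one linear shape mode explains ≥99% of the variance, while the texture-only
reading needs several modes.

A thin command-line front end over the same functions is installed at
`inst/cli/gmia.R` (`simulate`, `register`, `shape-model`, `spm`, `study`,
`sensitivity` subcommands writing PLY/CSV/JSON).

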