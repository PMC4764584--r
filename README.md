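# tissuescope3d

Multi-scale 3D reconstruction and quantification of dense tissue from
confocal microscopy, exemplified by mouse liver. High-resolution liver
stacks carry four information channels — nuclei (DAPI), bile canaliculi
(CD13), sinusoidal capillaries (Flk1) and the actin cell cortex
(phalloidin) — and the package turns them into digital geometrical models:
triangle meshes of nuclei and cells, centerline graphs of the two tubular
networks, and per-cell tables (volume, DNA content, lobule position) for
morphometric and zonation analysis.

The pipeline implements, end to end:

* **BFBD de-noising** — a Bayesian foreground/background discrimination
  built on the depth-dependent Poisson noise model *I = αN + β*,
  *V(I) = α(z)(I − β)*: the z-profile background of every pixel is fitted
  by an outlier-tolerant (Cauchy-IRLS) line, residuals above a threshold in
  noise-sigma units are kept as foreground, and the two components are
  smoothed independently and summed.
* **Mosaicking** of tile grids by maximizing the summed normalized
  cross-correlations *G* of neighbouring tiles, with multi-band blending,
  plus pyramid rigid (shift + z-rotation by polar correlation) registration
  of high-resolution stacks into their low-resolution context.
* **Section-surface detection** by minimizing a Bayesian energy (Cauchy
  data terms, Gaussian thickness coupling, Laplace smoothness) with
  iterated conditional modes, quadratic B-spline unbending, local
  maximum-entropy (Kapur) segmentation of unstained large vessels, and
  signed-distance bridging of inter-section gaps.
* **Segmentation and meshing** — local maximum-entropy threshold fields,
  marching-tetrahedra isosurfaces, active-mesh tuning of every vertex to
  the intensity-gradient maximum (correcting the threshold swelling), and
  topology-preserving skeletonization into radius-attributed network
  graphs.
* **Nuclei splitting** — minimum-volume-ellipsoid model selection
  (single vs double, MSE = Σ((p−c)ᵀE(p−c) − 1)²/(n−9)), a two-Gaussian
  mixture of ln(MSE) separating multi-nuclear clusters, and
  Laplacian-of-Gaussian scale-space (LoGMP, r = √2σ) seeding with
  active-mesh expansion.
* **Cell segmentation and classification** — simultaneous active-mesh
  expansion from the nuclei to the cortex with bi-nucleate merging, a
  74-parameter nuclear profile (geometry, intensity moments, 3D Haralick
  texture, fractal dimensions, lacunarity, surface shells), a
  Fisher-score-ranked LDA cascade and a K2-learned Bayesian-network
  classifier with leave-one-out validation.
* **A synthetic benchmark** — 4-channel ground-truth scenes (solid 0.5 µm
  bile-canalicular tubes, hollow 2.5/3.0 µm sinusoids, 3.5–5.5 µm nuclei
  with touching doubles/triples, 0.5 µm cell borders) degraded by uneven
  lognormal staining, a confocal PSF and depth-dependent Poisson noise at
  SNR 10:1, 4:1 and 2:1, scored voxel-wise by precision/sensitivity/F.
* **Morphometrics** — network length/radius/volume densities and branch
  angles, the cylinder-consistency check V_c = π r_s² L_s, the
  central-to-portal lobule coordinate
  χ = 50((|D − d_pv| − |D − d_cv|)/D + 1), ploidy clustering (Ward on
  standardized volume + DAPI integral) and log-normal mixture fits.

## A worked example

Generate a benchmark scene, degrade it at 4:1 signal-to-noise, reconstruct
everything and score it against the ground truth:

```r
library(tissuescope3d)

scene  <- generateScene(size = 144, spacing = 0.3, seed = 42)
images <- benchmarkDegrade(scene, snr = 4, seed = 43)
rec    <- reconstructScene(scene, images)

round(c(sinusoidF = rec$score$sinusoid$F,
        bcF       = rec$score$bc$F,
        nucleiF   = rec$score$nuclei$F,
        cellF     = rec$score$cells$F), 3)
#> sinusoidF       bcF   nucleiF     cellF
#>     0.894     0.804     0.956     0.869
round(unlist(rec$radius), 2)
#>       bc sinusoid
#>     0.44     2.58
```

The F-scores compare the reconstruction voxel-wise with the noise-free
ground truth (sinusoids as filled tubes); the radii are the mean
distance-transform values along the reconstructed centerlines, i.e. the
tuned tube radii in µm (ground truth: 0.5 µm bile canaliculi, 3.0 µm
sinusoid outer radius). Nucleus tables, cell meshes and the splitting
bookkeeping are available from `splitNuclei()` / `segmentCells()`
(`rec$nuclei`, `rec$masks$cellMeshes`).

The cylinder-consistency check of a measured network:

```r
cylinderConsistency(Vs = 0.16, Ls = 2853.4, rs = 4.05e-3)
#> $Vc
#> [1] 0.1470356
#> $ratio
#> [1] 0.9189727
```

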