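---
title: "Quantifying cardiac fiber and sheetlet architecture with cardioTensor"
author: "cardioTensor authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiac fiber and sheetlet architecture with cardioTensor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Ventricular myocardium is a hierarchically organised tissue: myocytes (the
"fibers") wind helically around the left ventricle (LV), their inclination
against the short-axis plane — the helix angle, HA — rotating roughly
linearly from a positive value at the endocardium to a negative value at the
epicardium. Myocytes are additionally grouped into branching laminae
("sheetlets") a few cells thick, whose normal vector defines the laminar
orientation. Two ex vivo MRI contrasts give access to this architecture:

* **Diffusion-tensor imaging (DTI)**: water diffuses fastest along the
  myocyte axis, so the first eigenvector of the fitted diffusion tensor
  tracks the fiber, and the third (smallest) eigenvector is associated with
  the sheet normal.
* **Structure-tensor imaging (STI)**: in a high-resolution T1-weighted
  volume the dominant intensity variation is across the laminae, so the
  first eigenvector of the locally averaged gradient outer product (the
  structure tensor) tracks the sheet normal, while the direction of *least*
  intensity variation — the third eigenvector — tracks the fiber.

`cardioTensor` implements both branches, the cardiac coordinate frame and
the four architecture angles (HA, TA, SE, SA), the AHA 17-segment regional
model with normalized transmural depth, transmural profiles with linear
fits, and Bland–Altman / bullseye / Kruskal–Wallis agreement statistics —
validated end to end on a synthetic LV phantom with analytically known
architecture.

# The processing model

## STI branch

1. **Gradients.** A matched separable 5-tap pair (antisymmetric derivative,
   symmetric prefilter; an interpolator-matched design with the derivative
   taps rescaled for exact unit response on linear ramps) forms a
   5×5×5 derivative template; at 150 µm voxels its footprint spans
   750 µm per axis. Convolution runs per axis in the Fourier domain after
   mirror padding, and matches a direct spatial-domain oracle to 1e-8.
2. **Structure tensor.** Per voxel, T = g gᵀ (rank one, trace |g|²).
3. **Resolution pyramid.** Each tensor component is smoothed with the
   order-4 binomial kernel (1,4,6,4,1)/16 per axis and decimated by two,
   per resolution doubling; two doublings take 150 µm data to the 600 µm
   analysis resolution. Per level the axis extent is `round(n/2)`
   (half-to-even), which maps a 731×665×532 grid to 183×166×133 after two
   levels; the decimator keeps the first `round(n/2)` even (0-based)
   samples, dropping a trailing sample when the two rules disagree.
4. **Eigenanalysis and roles.** Eigenvalues are sorted descending; the STI
   anatomical convention assigns the first eigenvector to the sheet normal
   and the third to the fiber. Voxels with relative eigenvalue gap below
   1e-6 are flagged degenerate and excluded from angle statistics.

Boundary handling (mirror reflection about the edge sample), the decimation
phase, and the eigenvector sign rule (positive z component, then +x, then
+y — fibers are axial, so signs only pin down determinism) are conventions
of this package, not facts inherited from any acquisition protocol.

## DTI branch

The tensor is fitted by log-linear least squares: b0 volumes are averaged
arithmetically and `ln(S_g/S̄0) = −b gᵀDg` is solved over the weighted
volumes (at least six non-collinear directions; the design matrix is
checked for rank). Weighted or nonlinear fitting is deliberately not used:
with 6 directions and ex vivo SNR the ordinary estimator is standard and
transparent. Negative eigenvalues are never clamped — they flow into the FA
map and the degeneracy flags so masking decisions stay explicit. FA and
trace follow the usual eigenvalue formulas, with FA of the zero tensor
defined as 0. The DTI role map is the mirror image of the STI one: first
eigenvector = fiber, third = sheet normal.

## Frames and angles

The cardiac frame at a voxel is (circumferential ĉ, longitudinal l̂,
radial r̂): l̂ is the LV long axis (+z after alignment; `longAxisTransform`
recovers the axis by PCA of the mask and refuses near-spherical masks with
anisotropy ratio < 1.2), r̂ points outward from the per-slice cavity
centroid, and ĉ = l̂ × r̂ (so ĉ × l̂ = r̂, right-handed). With components
(c, l, r) of a unit vector in this frame:

* HA = atan(l/c), TA = atan(r/c) — from the fiber-role vector;
* SE = atan(l/r), SA = atan(c/r) — from the sheet-normal-role vector.

All four use the principal-value arctangent (axial quantities, period
180°), live in [−90°, 90°], and are invariant under v → −v. Sign
conventions: HA > 0 toward the base (+l̂), TA > 0 outward (+r̂), SE > 0
toward +l̂, SA > 0 toward +ĉ. The pole case (zero denominator with nonzero
numerator) is canonicalized to +90°; when both components vanish the angle
is undefined (NA). The SE definition follows the convention that the
sheet-normal's projection onto the radial–longitudinal plane is measured
against the short-axis plane; the published wording ("projection onto the
radial orientation") is geometrically under-specified, and this reading is
the one consistent with the cited sheet-angle literature.

## Regional model

* **Transmural depth**: x = d_endo/(d_endo + d_epi) from Euclidean distance
  transforms (exact separable lower-envelope algorithm) to the cavity and
  outside-background regions. Masks quantize surfaces, so two refinements
  keep the depth scale honest: the EDT runs on a 2× sub-voxel replication
  of the region masks, and a quarter of the refined sub-voxel is subtracted
  from each distance (the half-voxel offset is exact only for face-aligned
  planar interfaces; for voxelized curved surfaces the staircase puts the
  effective interface nearer the nominal boundary, and a quarter sub-voxel
  sits between the two limits). On an analytic annulus this keeps every
  wall voxel within half a voxel of the true depth and the depth *scale*
  within 0.6%, which matters because any scale error multiplies every
  transmural slope. The literal convention (distances to on-wall surface
  layers, x exactly 0/1 on them) remains available via `offset = 0`.
* **AHA 17 segments**: the masked long-axis extent is split into an apex
  cap (most apical 1/9, segment 17) and three equal thirds; basal (1–6) and
  mid (7–12) rings get six 60° sectors, the apical ring (13–16) four 90°
  sectors, measured from a supplied reference angle (the RV insertion in
  real hearts; the phantom provides it). There is no automatic landmark
  detection — axial boundaries measured on the mask extent are a
  deterministic convention, and real-data landmarking is the user's call.
* **Transmural profiles**: voxels are binned by depth (bin 0.005, 200 bins)
  with a local unwrap — scanning endo→epi, each voxel value is shifted by a
  multiple of 180° to lie within 90° of the running reference (the previous
  bin mean) before averaging — so profiles crossing ±90° stay continuous.
  The first populated bin initialises the reference from its raw mean.
  Profiles are fitted by count-weighted ordinary least squares (surface
  bins are sparse); R² is the weighted coefficient of determination,
  defined as 0 for a constant profile so it stays in [0, 1]. Pooling
  voxels before binning is the default reduction; per-segment profiles use
  the same machinery per label.

## Agreement statistics

Differences between modalities are axial: a − b is wrapped into (−90°, 90°]
before any averaging (whether to wrap before Bland–Altman statistics is a
convention; wrapping is chosen here so a 2° disagreement across the ±90
boundary is not counted as 178°). Bland–Altman reports the mean difference
(bias), SD, and bias ± 1.96 SD limits of agreement, with difference order
fixed as DTI − STI. The bullseye table gives per-segment arithmetic means
per modality and the absolute axial difference of the segment means;
arithmetic (not circular) means match the convention of published
per-segment tables, and a warning fires when a segment has substantial mass
at both +90° and −90°, where that convention becomes biased. Between-group
comparisons use the tie-corrected Kruskal–Wallis test (`stats::kruskal.test`
underneath, with the all-identical case defined as H = 0, p = 1), annotated
with the usual significance stars.

# The synthetic phantom

The generator (`phantomSpec`, `phantomGroundTruth`, `renderTextureVolume`,
`synthesizeDWI`) builds an annular-cylinder LV wall with every quantity
known in closed form, co-registered across branches by construction (the
DWI grid is the texture grid decimated by the same pyramid phase).

Reference configuration: 96³ voxels at 150 µm (14.4 mm field of view), wall
radii 2.4–6.0 mm (3.6 mm wall — a mid-sized mammalian LV scaled to fit the
field of view at the published resolutions), HA from +60° (endo) to −60°
(epi) — slope −120° per unit depth, matching the order of published
per-segment slopes — zero transverse angle, untilted laminae (β = 0),
diffusion eigenvalues (1.5, 0.6, 0.4)×10⁻³ mm²/s on the fiber /
sheet-in-plane / sheet-normal axes (distinct sheet diffusivities keep the
DTI role assignment well-posed; FA ≈ 0.61), b = 1000 s/mm² with three b0
volumes and the six dual-gradient directions, and Rician noise of
selectable σ (0 by default, so tests are deterministic; noise is the
magnitude of a complex Gaussian perturbation, as in magnitude MR).

**Texture.** The FLASH-like volume superimposes two intensity components
inside the wall:

* a **laminar cosine** along the sheet normal (wavelength 600 µm, amplitude
  40 a.u. over an offset of 130). For β = 0 the normal field is radial and
  the phase (r − r_in) is exact; for tilted or bimodal laminae no global
  phase exists (the normal field has curl), and the component is synthesized
  from sparse Gabor kernels oriented along the local normal;
* a **myofiber striation** component: sparse Gabor noise whose per-kernel
  wave vector is the local sheet-in-plane direction, with an anisotropic
  envelope — σ = 100 µm across the sheet so a kernel never straddles
  laminae with different fiber orientation, 600 µm within it — wavelength
  450 µm and RMS amplitude 0.7× the laminar amplitude.

The striation component is essential, not decorative: a pure laminar wave
leaves the structure tensor rank one, so the fiber (least-variation)
direction would be undefined and the STI branch could recover nothing.
Real FLASH contrast carries both laminar and cellular-scale variation; the
two-component texture emulates exactly the feature STI exploits. Boundary
voxels get linearly mixed intensity (partial volume), and the background
equals the wall offset so the wall edge contributes only the oscillatory
part of the contrast.

**What passing the phantom does and does not show.** The phantom has ideal
geometry, stationary texture statistics, no susceptibility or bias-field
artifacts, no vessels or cleavage-plane heterogeneity, and its two branches
are perfectly co-registered. Recovery of the imposed laws therefore
validates the *computational chain* — kernels, smoothing, eigen-roles,
frames, depth, binning, statistics — not the biological fidelity of either
contrast in real tissue. Accuracy figures below are phantom-specific: at
600 µm analysis resolution on a 2.4–6.0 mm annulus the per-voxel STI fiber
error has median ≈ 3° (95th percentile ≈ 8°), limited by an
uncertainty-principle trade-off — a striation kernel must span at least a
wavelength, but over that span the fiber field itself rotates (transmurally
33°/mm; circumferentially 1/r). Transmural-slope recovery is much tighter
than per-voxel accuracy because bin means average hundreds of voxels.

**Truth mask.** Statistics are evaluated on the wall mask eroded by two
voxels with the first/last eight fine slices along z excluded: partial
volume corrupts boundary voxels, and near the axial ends of the volume the
derivative/binomial support crosses the field-of-view edge (the analogue of
excluding apex/base slices with coil signal drop-off).

# Numerical choices and degenerate inputs

* Convolution boundaries: mirror reflection about the edge sample on every
  path (FFT paths pad before transforming, so circular wrap-around never
  reaches the interior).
* Eigen ties: a relative gap (λ1 − λ3)/λ1 < 1e-6 flags the voxel
  degenerate; degenerate voxels are excluded from angle maps by default.
* Angle poles: canonicalized to +90°; doubly-degenerate directions are NA.
* Non-positive DWI signals exclude the voxel from the fit (counted and
  reported); a rank-deficient gradient scheme aborts at setup.
* Empty masks warn rather than error in the masking utilities (an empty
  tissue mask is a user-visible data problem, not a programming one), but
  empty inputs to statistics (Bland–Altman, fits with < 3 bins) error.
* All randomness (kernel placement, phases, Rician noise, the bimodal tilt
  signs) derives from the single integer seed in the phantom spec; reruns
  are bit-identical.

# Problem sizes

The shipped validation uses the 96³ reference phantom (both branches
analysed at 24³ / 600 µm) — a few minutes on one CPU — and a 48³ / 300 µm
variant of the same geometry for fast unit tests. These sizes were chosen
so the full suite exercises every stage end to end at the published
resolutions while remaining comfortable to run locally.

# Known limitations

* The cylinder phantom has no apex; the AHA apex cap is exercised
  geometrically (bottom 1/9 of the extent) but not anatomically.
* Per-slice cavity centroids equal the straight axis on the phantom; the
  curved-axis path is implemented but only validated for consistency, not
  against a curved ground truth.
* The right ventricle is out of scope: an LV-centroid frame is known to
  produce artifactual angles there.
* DTI sheet angles (SE/SA) inherit the well-documented weakness of the
  second/third diffusion eigenvectors; the phantom reproduces the
  mechanism (they are exact only because its DWI is noiseless).
* Arithmetic segment means of axial angles are biased for wrap-straddling
  segments; the package warns and offers no automatic circular fallback,
  matching the convention of published per-segment tables.
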