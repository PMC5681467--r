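---
title: "Segmenting tubular structures in large micro-CT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting tubular structures in large micro-CT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microfocus X-ray CT of wax-embedded lung tissue produces isotropic 3D
density volumes at micron resolution (typically around 8 µm voxels, scans
on the order of 1800 × 2000 × 2000 voxels, tens of gigabytes each). The
structures of diagnostic interest — airway and blood-vessel walls — appear
as bright (X-ray dense) tubular shells whose interiors are filled with the
same paraffin wax as the background, so lumen and background share one
intensity. Manual segmentation of these networks takes weeks to months;
plain thresholding, watershed or contour growing lack the sensitivity for
such low-contrast tissue. `tubuseg` implements a semi-automated workflow:
out-of-core block processing, a trainable filter-bank random-forest voxel
classifier, two-stage threshold refinement, connected-region noise removal,
and surface export.

## Out-of-core block processing

A volume is partitioned by ceiling division into cubic blocks
(`plan_grid()`; default edge 256 voxels — the only edge consistent with the
published block counts of 245 for a 1600 × 1600 × 1200 scan and 72 for
1374 × 1497 × 500, and a good fit for a 16 GB machine). Cubes are preferred
over other cuboids for their smaller surface-to-volume ratio, which
minimises halo traffic. Edge blocks are truncated, never padded, so every
voxel belongs to exactly one core block; blocks are stored as uncompressed
TIFFs named by zero-padded grid index, with a `meta.json` sidecar holding
the global properties (dims, bit depth, global min/max, a 256-bin
histogram with explicit edges). Keeping global intensity statistics outside
the blocks is what lets per-block processing remain consistent with the
whole volume — nothing is ever normalised per block.

`map_blocks()` applies an arbitrary voxel operator per block inside a
window extended by a halo (default 16 voxels). Two boundary conventions
coexist deliberately:

* `read_block_with_halo()` returns fixed-shape windows (core + 2·halo),
  mirror-reflecting at the volume boundary. Mirroring avoids the intensity
  bias that constant padding would introduce at the scan edges.
* `map_blocks()` feeds the operator windows *clipped* at the volume
  boundary instead. The reason is exactness: for cascaded filters with an
  anti-symmetric stage (the structure tensor's gradient cross-term changes
  sign under mirroring), pre-mirrored data is not equivalent to letting
  each filter stage reflect its own input at the true volume edge. With
  clipped windows, blockwise processing equals whole-volume processing
  bit-for-bit (up to storage quantisation) for any operator whose footprint
  radius is at most the halo, in any processing order.

### TIFF intensity encoding

The TIFF writer available to R persists samples in [0, 1] only and
truncates to the target integer depth; 32-bit output is unsigned integer,
not float. Block files therefore use an explicit encoding recorded in the
sidecar: 8/16-bit volumes scale by 1/(2^b − 1), which round-trips every
code value bit-exactly; 32-bit volumes are stored as uint32 codes
`q = round(v · 2^(32−k))` on a power-of-two grid over [0, 2^k] with a
half-step offset so truncation lands on the intended code. This is
bit-exact for integer-valued data and quantises other values to a step of
`2^(k−32)` (for probability maps, k = 0, a step of about 2.3 × 10⁻¹⁰).
Volumes with negative values fall back to an affine [min, max] map at
uint32 precision.

## The feature bank

Voxel values are proportional to X-ray absorption, so **no normalisation or
equalisation is applied anywhere** — any histogram-altering step would
destroy comparability across blocks and across scans. The only
pre-processing is a Gaussian blur feeding the feature filters. Features are
computed slice-wise in 2D (annotation happens on 2D slices, and the filter
screening that selected this bank was 2D); each voxel receives, in a fixed
documented order:

| group | default scales | features |
|---|---|---|
| raw intensity | — | 1 |
| Gaussian blur | σ ∈ {1, 2, 4, 8} | 4 |
| Neighbors | shifts r ∈ {1, 2}, 8 compass directions | 16 |
| Entropy | disc radius 4, 64 bins | 1 |
| Structure tensor | (σ_d, σ_i) ∈ {(1,1), (1,3), (2,3)}, both eigenvalues | 6 |
| Hessian | σ ∈ {1, 2, 4}; eigenvalues + orientation | 9 |

37 features in total. The sources do not fix the filter scales; these
defaults span wall thicknesses of one to a few voxels at 8 µm resolution.
The Hessian's strongly negative eigenvalue across a bright ridge is the
classic tube-wall detector; the structure tensor separates edges (one large
eigenvalue) from corners and texture (two); local entropy distinguishes
textured alveolar regions from flat wax. Both structure-tensor eigenvalues
are computed and the choice is left to the classifier, since the screening
images do not say which was displayed.

Numerical conventions, chosen once and frozen because oracle tests depend
on them:

* All kernels are sampled Gaussians (and derivatives) truncated at 3σ;
  derivative kernels are normalised to unit response on a ramp
  (respectively on x²/2). Convolution boundaries reflect with edge
  duplication.
* Neighbors features sample `slice(y + r·dy, x + r·dx)` with north =
  (−1, 0) and y increasing downward, i.e. a bright pixel appears displaced
  *against* the compass direction.
* Entropy is Shannon entropy (base 2) of the disc histogram after
  quantisation to equal-width bins. The quantisation range defaults to the
  slice min–max for standalone use, but the pipeline passes the
  volume-global range from the sidecar: per-slice ranges would make
  blockwise features depend on the block window, breaking blockwise ==
  whole-volume prediction. A degenerate range yields zero entropy.
* Hessian eigenvalues are ordered by signed value; orientation is the
  angle of the eigenvector of the larger-magnitude eigenvalue in [0, π)
  from the +x axis, 0 at exact ties.

A `feature_spec` serialises into the pipeline config and carries a
canonical fingerprint; prediction refuses feature stacks whose fingerprint
differs from the one the classifier was trained with. Feature stacks are
held in memory only, never persisted.

## Classifier

A random forest (probability forest, 200 trees, √p candidate features per
split, fixed seed 17, single-threaded for bit-reproducibility) is trained
on sparse manual labels: two classes, background = 0 and vessel = 1, where
the foreground class is the **wall including the lumen**. Annotating the
whole cross-section gives the classifier sharp wall edges to learn — the
easiest feature for edge filters — and the wax-filled lumen is removed
later by intensity refinement. Features are computed only on the labelled
slices; labels are used exactly as given (no resampling), duplicates
retained. The output is a per-voxel foreground probability (the soft vote
averaged over trees), which maps over the block store like any other voxel
operator.

## Post-processing

1. **Probability threshold** `t` (default 0.5): `mask = (prob ≥ t)`.
2. **Intensity refinement** `t2`: `mask & (original ≥ t2)` removes the
   wax-dark voxels (lumen interiors, over-segmented background). Both
   thresholds are manual parameters by design; the store histogram is the
   guide, and no automatic threshold (e.g. Otsu) is applied.
3. **Noise removal.** The preferred method removes connected components
   smaller than `min_size` voxels (default 700): it deletes noise while
   leaving every surviving component's voxel set — and hence the vessel
   surface — untouched, and it is idempotent. Components of size exactly
   `min_size` are kept (strict `<` removal; the sources do not state the
   tie convention). Connectivity defaults to 26, since elongated vessels
   touch diagonally across voxels; 6 is available. Two morphological
   alternatives are provided for comparison, both 3D with the 6-connected
   cross element iterated for radius > 1 (the element shape being otherwise
   unspecified): opening-then-closing, and
   closing-opening-radius-2-opening. `compare_denoisers()` quantifies the
   trade-off: the morphology schemes alter surfaces (the cross element
   rounds corners even of a perfect mask, and the radius-2 opening removes
   one-voxel-thick walls entirely), while region-size filtering loses zero
   true voxels. The operations are implemented in 3D; whether the original
   comparison was 2D or 3D is unstated.

## Synthetic phantoms: what they emulate and what they do not

`default_phantom()` renders a 96³ scene with the statistical structure of a
real slice: uniform wax background (16-bit level 20000), two curved tubes —
a wider "airway" (lumen radius 7, wall 2) and a narrower "vessel" (lumen 4,
wall 2) with bright walls (35000) and wax-level lumens — three darker air
bubbles (8000), one textured alveolar box (amplitude 6000), and additive
Gaussian noise at 10% of the wall–wax contrast, rounded to integers as a
16-bit reconstruction would be. Centerlines are polylines with linear
interpolation — the simplest geometry that produces curved tubes. Ground
truth masks are computed before noise. Intensities sit in the 16-bit range
so the 8/16/32-bit storage paths are all exercised by casting.

The phantom reproduces the *contrast relations* that drive the method (wall
> wax > air; lumen = background) and the presence of textured regions. It
does **not** simulate CT physics: no beam hardening, ring artifacts,
partial-volume blur, or spatially correlated reconstruction noise, and no
fibrotic texture. Passing the end-to-end test therefore shows the pipeline
machinery recovers known geometry under the stated noise — it does not
certify segmentation quality on real scans, whose thresholds remain manual
expert choices.

`make_labelset_from_truth()` stands in for manual annotation: on two
foreground-rich slices it samples 200 foreground voxels from wall + lumen
truth and 200 background voxels from everywhere else — a reduced-count
analogue of annotating a couple of airways and vessels against
representative background areas.

## Pipeline and reproducibility

`run_pipeline()` chains split → train (or load) → predict per block →
threshold → refine → denoise → store, logging every stage and writing a
JSON manifest of all parameters plus the feature fingerprint — the
reproducibility surface an interactive GUI lacks. Every stage is an
exported function restartable from its intermediate store; outputs are pure
functions of (inputs, config, seeds), and a rerun is bit-identical. A halo
smaller than the feature footprint (24 voxels for the default bank)
triggers a warning naming the minimum safe value. `pick_test_block()`
selects the block whose intensity variance is closest to the volume-wide
variance — a deterministic proxy for the "representative block" used to
trial a segmentation cheaply, with ties broken in enumeration order.

## Export

Overlays render a grayscale slice to RGB with alpha-blended mask colours
(last-listed mask wins on overlap). Meshes are extracted as the 0.5
iso-surface of the binary mask in cuberille fashion: every voxel face
between foreground and background becomes two consistently outward-wound
triangles, vertices in micrometres via the voxel size. The volume is padded
with one background layer first, so boundary-touching masks still produce
closed surfaces; a solid shape's enclosed mesh volume equals its voxel
volume exactly, and a solid cube has Euler characteristic 2. No smoothing
is applied — that belongs to downstream tools. STL output is binary
little-endian (80-byte header, uint32 count, 50 bytes per triangle).

## Validation strategy and problem sizes

Every operation with a tractable reference is tested against an
independent brute-force oracle: dense-loop convolution and per-pixel
histogram entropy on 32² slices, per-pixel 2 × 2 eigen-decomposition,
flood-fill connected components on ≤ 32³ masks, set-arithmetic morphology
identities, and the divergence-theorem mesh volume. Bit-exact round trips
and halo equivalence are property-tested over randomized shapes, edges and
bit depths (50 cases). The headline check trains on 2 slices of the 96³
default phantom, predicts the full volume, refines at t2 = 27500 (midway
between wax and wall), denoises at min_size 700, and requires Dice ≥ 0.8
against the true wall mask, deterministically under fixed seeds; the
observed value is ≈ 0.99997 at these settings. The 96³/48³ problem sizes
used throughout the tests were chosen as the smallest scenes that contain
all phantom scene elements at realistic wall thicknesses.

## Known limitations

* Features are 2D slice-wise; 3D filter variants are out of scope.
* Two classes only; multi-class annotation is future work.
* Over-segmentation from excessive training data is a known qualitative
  failure mode of this kind of workflow; the package exposes label-set
  size but does not attempt to reproduce it.
* Distributed or parallel block execution is deliberately absent; the
  block store is designed so it could be added without changing formats.
* No automatic threshold selection; `t` and `t2` are expert inputs.
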