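# tubuseg

Semi-automated segmentation of airway and blood-vessel walls in large 3D
microfocus-CT volumes of wax-embedded lung tissue.

Micro-CT of unstained, wax-embedded biopsies yields micron-resolution 3D
density volumes in which the tubular networks of airways and vessels are
visible but hard to extract: the images are low-contrast, tens of
gigabytes in size, and the wax filling a vessel's lumen has exactly the
intensity of the wax background. `tubuseg` is aimed at researchers who
want those networks as masks and surfaces without months of manual
tracing. It provides:

* **Out-of-core block processing** — volumes are split into cubic blocks
  (default edge 256 voxels) stored as loss-less TIFFs with a JSON sidecar
  of global intensity properties; any voxel operator with footprint radius
  ≤ halo applied block-by-block (`map_blocks()`) gives exactly the
  whole-volume result.
* **Trainable voxel classification** — a per-voxel feature bank (Gaussian
  blur, compass-shift "Neighbors", local entropy, structure-tensor and
  Hessian eigenvalues; 37 features by default, no histogram normalisation
  anywhere) feeds a 200-tree random forest trained on sparse manual
  labels, producing a foreground-probability map
  *p*(voxel ∈ wall ∪ lumen).
* **Two-stage refinement** — threshold the probability map at *t*, then
  intersect with the original intensities at *t₂* to strip the wax-dark
  lumen: `mask = (p ≥ t) ∧ (I ≥ t₂)`.
* **Noise removal** — connected components smaller than `min_size` voxels
  (default 700) are deleted, leaving surviving vessel surfaces untouched;
  3D morphological opening/closing schemes are included for comparison and
  lose measurably more true wall.
* **Synthetic phantoms** — seeded 3D scenes (wax background, air bubbles,
  alveolar texture, curved bright-walled tubes with wax-level lumens) with
  ground-truth masks, so the whole pipeline is testable without scan data.
* **Export** — colorized PNG overlays and binary STL surface meshes.

## Worked example

Segment the default 96³ phantom end-to-end and compare against its ground
truth:

```r
library(tubuseg)

ph  <- render_phantom(default_phantom(seed = 1))
lbl <- make_labelset_from_truth(ph$wall_truth, ph$lumen_truth,
                                n_slices = 2, seed = 2)

cfg <- pipeline_config(input = ph$volume, workdir = "run",
                       labels = lbl, refine_threshold = 27500)
res <- run_pipeline(cfg)
dice(res$mask, ph$wall_truth)
```

This prints the per-stage log and the final overlap:

```
[split] 1 blocks (edge 256, halo 16)
[train] 800 samples on 2 slices (background=400, vessel=400), 200 trees
[predict] probability store at run/store_prob (halo 24)
[threshold] t=0.5 kept 57680 voxels
[refine] t2=27500 kept 18392 voxels
[denoise] regions kept 18392 voxels
Warning message:
In run_pipeline(cfg) :
  halo 16 is smaller than the feature footprint; minimum safe halo is 24
[1] 0.9999728
```

Reading the log: the classifier marks wall **and** lumen as foreground
(57,680 voxels — the lumen is annotated too because its edges are what the
filters detect best); intensity refinement at *t₂* = 27500, midway between
the wax (20000) and wall (35000) levels, strips the lumen down to 18,392
wall voxels; region filtering finds nothing smaller than 700 voxels to
remove; the final mask overlaps the 18,393-voxel true wall with Dice
0.99997. The warning notes that the configured halo is narrower than the
widest filter — the prediction stage widens its own halo to the safe value
(the log's `halo 24`), but other block operations run at the configured
width. `run/manifest.json` records every parameter of the run.

A command-line front end with the same stages is installed at
`inst/exec/tubuseg` (`tubuseg split|train|predict|threshold|refine|denoise|
assemble|phantom|overlay|mesh|run ...`).

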