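# cycloplex

Automated analysis of **cyclic multiplex immunofluorescence** experiments
on tissue sections.

In a cyclic (strip-and-restain) experiment, one FFPE section is stained
with a small antibody panel plus a nuclear counterstain (DAPI), imaged,
chemically stripped, and restained — for five, eight or more rounds.
The result is a stack of grayscale channel images acquired on different
days, slightly misaligned, each carrying background and a shared
autofluorescence component. Turning that stack into per-cell biology
(which cells are Kupffer cells? how many macrophages crowd the ductular
reaction? what lives inside the tumor capsule?) requires a chain of
image-processing and quantification steps. `cycloplex` implements that
chain as a reproducible, scriptable pipeline, and ships a
synthetic-tissue renderer with complete ground truth so that every stage
can be validated by recovery rather than by eye.

## What the pipeline computes

1. **Preprocessing** — per-channel background subtraction by grayscale
   morphological opening (`clip(I − I ∘ B_r, 0)` with a disc of radius
   *r*); autofluorescence removal `clip(I − ŝ·AF, 0)` where `ŝ` is the
   least-absolute-deviation slope of `I` against the AF reference over
   high-AF pixels; collagen extraction from a Masson's-trichrome RGB by
   HSV color thresholding.
2. **Registration** — each cycle is aligned to the first cycle on its
   DAPI channel: a global translation from the cross-correlation peak,
   then coarse-to-fine Nelder–Mead refinement of the full 2×3 affine
   maximizing normalized correlation; all channels of the cycle are then
   warped (bilinear) and the stack is cropped to the largest rectangle
   of the common valid region.
3. **Segmentation** — a trainable pixel classifier (random forest over a
   Gaussian / gradient-magnitude / Laplacian-of-Gaussian feature bank)
   produces binary marker masks; nuclei are identified by Otsu
   thresholding with distance-transform watershed splitting of touching
   objects.
4. **Phenotyping** — nuclei are expanded into cell footprints (nearest-
   nucleus territories), marker positivity is called by mask-coverage
   fraction, and ordered boolean gates assign phenotypes, e.g. Kupffer
   cells `IBA1+CLEC4F+` versus monocyte-derived macrophages
   `IBA1+CLEC4F−`, with per-population proliferation (PCNA+) fractions.
5. **Spatial analysis** — mass-conserving Gaussian density maps of cell
   centroids; neighbor counts by morphological dilation of reference
   objects (a cell counts if its centroid lies within a Euclidean disc
   dilation of the object); tumor-region delineation as
   collagen-encapsulated areas (holes of the closed collagen mask)
   containing PCNA-positive nuclei, with per-region phenotype
   composition.

## Worked example

Everything below is computed, not illustrative: simulate a 3-cycle
experiment (384², 120 cells, misaligned cycles, autofluorescence,
shot-like noise), then run the full pipeline on the rendered TIFFs.

```r
library(cycloplex)

cfg   <- simulation_config(image_shape = c(384L, 384L), n_cells = 120L,
                           n_cycles = 3L, rng_seed = 42L)
paths <- simulate_bundle(cfg, "bundle")
rc    <- run_config(paths$cycles, paths$panel, "out", seed = 42L,
                    af_path = paths$af)
res   <- run_pipeline(rc)
res$summary[, c("phenotype", "n_cells", "fraction_of_all", "pcna_positive_fraction")]
```

```
  phenotype n_cells fraction_of_all pcna_positive_fraction
1  ductular      17           0.142                 0.0588
2      MoMF      34           0.283                 0.2353
3     other      37           0.308                 0.0811
4        KC      32           0.267                 0.3750
```

The simulated truth for this seed is 32 KC / 34 MoMF / 17 ductular / 37
other — the pipeline recovers every population count exactly here, and
the PCNA+ fractions track the generator's proliferation probabilities
(0.3 in the IBA1+ compartment, 0.05 elsewhere) within small-sample
noise. The estimated cycle-2 transform,

```
affine_transform (moving -> reference, 1-based row/col)
           [,1]      [,2]     [,3]
[1,]  0.9805080 0.0150208 -5.07605
[2,] -0.0150445 0.9805210 24.32730
similarity score: 0.9982
```

recovers the true misalignment (≈0.98 scale, ≈0.87° rotation, ≈(−5, 24)
px shift) to sub-pixel accuracy.

A thin command-line wrapper is installed under `inst/scripts/cycloplex`:

```sh
Rscript inst/scripts/cycloplex simulate --out bundle --seed 1 --cells 300 --cycles 5
Rscript inst/scripts/cycloplex run --config run.yaml --seed 1
```

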