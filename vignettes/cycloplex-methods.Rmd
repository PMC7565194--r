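---
title: "Methods: models, parameters and design choices in cycloplex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in cycloplex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cycloplex` analyses cyclic (strip-and-restain) multiplex
immunofluorescence experiments: one tissue section, several staining
rounds, each imaged with a nuclear counterstain (DAPI) plus one to three
marker channels. This vignette documents the models behind each stage,
the parameters that matter, the numerical choices, and what the
synthetic validation does and does not demonstrate.

## Image model and conventions

A channel is a nonnegative real-valued matrix in arbitrary fluorescence
units. Intensities are never rescaled on load — integer TIFFs are
widened losslessly — because quantitative comparisons across cycles are
the point of the experiment. Internally all coordinates are 1-based
(row, col) in the R convention; files written by the package (cell
tables, transform tables) use 0-based pixel-center coordinates, and
conversion happens only at the I/O boundary. Masks are pixel sets; no
sub-pixel geometry is attempted.

## Preprocessing

**Background subtraction** uses grayscale morphological opening with a
disc (default radius 50 px, `bg_radius_px`): the opening passes any
structure wider than the disc and removes narrower peaks, so the
clipped difference keeps spot-like stains and flattens slowly varying
background. The operator is idempotent up to numerical tolerance and
can only decrease pixel values. One implementation note: the underlying
grayscale morphology clamps to [0, 1], and opening commutes with
positive scaling, so the image is normalized by its maximum for the
operation and rescaled afterwards.

**Autofluorescence (AF) subtraction.** Tissue (notably lipid-rich
tissue) carries a shared AF component that leaks into marker channels.
Given a designated AF reference image, the mixing scale is estimated as
the least-absolute-deviation slope through the origin of marker versus
AF over pixels above the AF image's `bg_quantile` quantile (default
0.75) — computed as the AF-weighted median of pixelwise ratios. The LAD
fit is robust to genuine marker signal sitting on the same pixels;
at least 100 qualifying pixels are required. The subtraction
`clip(img − s·AF, 0)` never increases a pixel. The package accepts any
designated AF channel (an empty channel or a pre-stain acquisition);
it does not attempt multi-component spectral unmixing.

**Collagen extraction** from a trichrome RGB image is a fixed HSV color
threshold (hue window 0.50–0.72, saturation ≥ 0.25, value ≤ 0.98 by
default): blue-stained collagen is saturated and mid-valued, the white
background fails the saturation floor, and the value ceiling guards
against bright artifacts. Fixed thresholds mirror the manual
color-threshold step of interactive workflows while staying
deterministic; they are configuration, not learned.

## Registration

Every cycle is registered to the **first cycle** on its nuclear channel
— the nuclear counterstain is present in every round, which is exactly
why it anchors alignment. The estimate is two-stage:

1. a global integer translation from the circular cross-correlation
   peak of the smoothed, mean-subtracted images at the coarsest pyramid
   level (captures offsets of 20 px and more);
2. derivative-free (Nelder–Mead) refinement of all six affine
   parameters, parameterized about the image center, maximizing the
   Pearson correlation between the reference and the warped moving
   image over the valid region, coarse-to-fine over downsampling
   factors 8, 4, 2, 1 with Gaussian pre-smoothing (sigma 2 px).

At fine levels the correlation is evaluated on a strided subgrid
(~150k pixels), which leaves sub-pixel accuracy intact while bounding
cost. Bilinear interpolation is used for intensities, nearest-neighbor
for masks and labels. A similarity score below 0.2 flags the cycle as
low-confidence — flagged, not dropped, so the user can inspect the
merged-DAPI overlay and decide, mirroring manual QC practice. The
per-cycle transforms, scores and the crop rectangle are persisted.

Cropping finds the exact largest axis-aligned rectangle inside the
intersection of all validity masks (largest-rectangle-under-histogram
scan), so downstream stages see a frame where every cycle contributed
data. Brightfield images (trichrome) are aligned by least-squares
affine over three or more user-supplied landmark pairs; collinear
configurations are rejected.

On synthetic scenes with known misalignments (translations up to 20 px,
rotations up to 3 degrees, scale 0.98–1.02 — the range plausible for
re-mounted sections), recovered transforms map true cell centers with
mean error well below 1 px (typically < 0.1 px at 1024²).

## Segmentation

**Pixel classification.** Marker masks come from a probability random
forest over a standard trainable-segmentation feature bank: raw
intensity plus, per scale (defaults 1, 2, 4 px), Gaussian-smoothed
intensity, gradient magnitude and Laplacian-of-Gaussian — 3·|scales|+1
features. Brush labels can be supplied as a sparse label image; for
unattended runs an auto-labeling fallback seeds the two classes from
the image's own intensity quantiles (bottom half = background, top
0.5% = foreground, capped at 2000 px/class). The forest (50 trees) is
seeded, single-threaded, hence bit-reproducible. Probability maps are
thresholded at `p_min` (default 0.5) and components below
`min_object_px` (default 20 px) are discarded. 4-connectivity is used
throughout.

**Nuclei.** DAPI foreground by global Otsu (256-bin histogram), holes
filled, then distance-transform watershed to split touching nuclei;
the watershed tolerance (default 1) merges shallow peak pairs, which
is what keeps slightly elongated single nuclei from being cut in two.
Objects outside `nucleus_size_range` are removed and labels renumbered
1..K. Watershed splitting is on by default only for nuclei — cytoplasmic
marker masks form sheets and must not be shattered.

**Cell assembly.** Each nucleus claims a territory of up to
`cell_expand_px` (default 3 px) around it, never crossing another
cell's territory (nearest-nucleus tie-break via seeded propagation on
the distance transform). The expansion distance of interactive
pipelines is rarely documented; 3 px at typical 0.3–0.7 µm/px sampling
approximates a thin cytoplasmic rim, and the value is an exposed
parameter. Positivity is called by mask coverage — the fraction of the
footprint covered by the marker mask must reach `coverage_min`
(default 0.3) — rather than an intensity cutoff, because gating on
binary masks is how the upstream classifier output is meant to be
consumed; mean intensities are still recorded for dot plots.
Proliferation (PCNA) is nuclear, so its positivity is evaluated on the
nucleus footprint only, not the expanded cell.

## Phenotyping

Gates are ordered conjunctions of signed marker terms; the first
matching rule (lowest priority number) wins and unmatched cells are
`"other"`, making the assignment a partition. The canonical liver
panel: Kupffer cells `IBA1+CLEC4F+`, monocyte-derived macrophages
`IBA1+CLEC4F−`, ductular cells `CK19+`. Because the first two rules
differ in the sign of one marker, their order is immaterial — a
property asserted in the tests. Only conjunctions are supported: the
phenotypes this workflow targets are all conjunctions, and keeping OR
out of the rule language keeps the truth table exhaustively testable.
Ratios over empty populations are returned as flagged NaN rather than
errors, so batch runs over many images never abort on an empty gate.

## Spatial analysis

**Density maps** place a truncated Gaussian kernel (bandwidth in
full-resolution px, default 20) per centroid on a downsampled grid
(default factor 4), renormalizing each kernel to unit mass over the
grid — including at borders — so the map sums exactly to the cell
count. Renormalized kernels were chosen over raw binning precisely to
make mass conservation an exact, testable invariant.

**Neighbor counts** operationalize "expand reference objects, count
cells within the distance": a target counts for an object if its
centroid pixel lies in the object's dilation by an exact Euclidean disc
(offsets with dr² + dc² ≤ r², integer arithmetic). Membership by
centroid — not object overlap — keeps the definition identical to a
brute-force pairwise-distance oracle, and the tests assert exact
integer equality between the two routes. The radius has **no default**:
both 6 px and 10 px are in common use for this kind of proximity
analysis and they measure different biology, so the package requires
the radius explicitly rather than silently choosing one.

**Tumor regions.** "Collagen-encapsulated structures containing
proliferating nuclei" is operationalized as: close the collagen mask
with a disc (`closing_px`, default 10 — the gap tolerance of the
capsule), take holes of the closed mask (background components not
touching the image border), and promote holes with at least
`min_pcna_nuclei` (default 10) PCNA+ nucleus centroids and at least
`min_region_px` area to tumor regions; everything else is one
extratumoral region. The construction is monotone in
`min_pcna_nuclei`. Per-region composition reports phenotype fractions
both of all cells in the region and of the macrophage compartment
(KC + MoMF), since both normalizations are in common use.

## The synthetic-tissue generator

The generator is first-class, tested code — it defines the conditions
under which the pipeline is validated. It emulates: cells placed by
dart throwing with a minimum center distance (default 12 px, ≥ 2×
nucleus radius); phenotypes drawn i.i.d. from configurable frequencies
(defaults KC 0.3, MoMF 0.3, ductular 0.1, other 0.3); per-marker
amplitudes from a per-phenotype expression model (Bernoulli expression
× truncated normal amplitude; PCNA probability 0.3 in the IBA1+
compartment, 0.05 elsewhere); Gaussian spot rendering (sigma = radius/2,
truncated at 4 sigma, < 0.04% mass loss); a linear background plane; a
smooth shared autofluorescence field mixed into marker channels
(default coefficient 0.3); per-cycle affine misalignment (drawn within
±20 px, ±3°, scale 0.98–1.02 unless given); and shot-like noise
(additive Gaussian, sd = noise_sd·√intensity, clipped at 0). Transforms
are applied before noise, because sensor noise belongs to each
acquisition, not to the scene. A tumor scenario adds collagen rings
(default 3) enclosing disks where PCNA positivity is raised to 0.6 and
from which Kupffer cells are excluded. Every component draws from its
own sub-seed, so one seed gives bit-identical scenes and any single
stream (e.g. the phenotype multinomial) can be re-drawn independently
for testing.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: realistic optics (PSF, chromatic shifts),
nonrigid tissue deformation between cycles, staining-efficiency drift
across rounds, segmentation-hostile morphology (overlapping nuclei in
thick sections, anisotropic cells), structured autofluorescence with
channel-specific spectra, and imaging artifacts (tiling seams,
saturation). Recovery on synthetic scenes validates the computational
chain, not antibody performance or tissue handling.

## Validation scale and numerical notes

The shipped checks run at desk scale, chosen to exercise the stated
misalignment and density regimes while staying fast on one CPU:
registration recovery on five 1024² cycles with 300 cells; end-to-end
phenotype and proliferation recovery on a 512² field with 500 cells;
region delineation on a 1024² three-ring tumor scene with 1500 cells
(at that density each ring robustly encloses well over the 10-nucleus
threshold); neighbor-count equivalence on twenty random 200² fixtures.
The tumor-scene density was sized from the generator's own PCNA model
(expected PCNA+ nuclei per ring ≈ n_cells × ring-area fraction ×
non-KC share × 0.6 ≈ 20) before the checks were first run.

Other numerical choices: 16-bit integer TIFFs are the default on-disk
representation for images (values rounded, clipped at 65535 — synthetic
amplitudes live far below); float TIFFs are used for probability maps
and density maps, stored scaled to [0, 1] with the scale recorded in a
JSON sidecar, because the TIFF writer only persists that range. The
Otsu threshold uses a 256-bin histogram of the observed range.
Registration conventions: the estimated transform maps moving to
reference coordinates; warping resamples through its inverse; the
identity is returned for the reference cycle itself. Degenerate inputs
fail loudly (constant images for registration, singular transforms,
collinear landmarks, empty tissue masks), with two deliberate
exceptions: an empty nucleus foreground returns an empty labeling with
a warning, and empty populations yield flagged NaN fractions — both so
that batch runs degrade gracefully.

## Limitations

Rigid/affine registration only — no deformable model, so sections that
fold or stretch between cycles will not converge below the 1 px
criterion. The pixel classifier is per-channel; co-expression-aware
segmentation (classifying on stacked channels) is possible via the
multi-stack training interface but not the pipeline default. Region
delineation assumes capsules close within the closing radius; an
arbitrarily broken capsule is, correctly, not "encapsulated". The CLI
exposes `simulate` and `run`; the intermediate stages are available as
documented package functions for scripted use.
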