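---
title: "Hierarchical correlation histogram analysis: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical correlation histogram analysis: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcha)
```

## The problem and the model

Automatic contrast enhancement for brain MR slices usually means global
histogram manipulation (HE, CLAHE) or morphological filtering, none of
which targets a *specific object*. HCHA instead adapts the enhancement to
the intensity co-occurrence structure of a fixed region of interest: the
central window of the slice, where the deep-gray structures relevant to
Parkinson's-disease assessment (caudate nucleus, putamen, thalamus) sit in
a standard axial acquisition.

The statistic at the core is the **correlation histogram**: a square count
matrix `CorreHis` over the ROI's intensity range in which cell `(a, b)`
counts the ordered centroid/neighbour intensity pairs `(a, b)` produced by
sliding an overlapping 3×3 window over the ROI. Every ordered pair has its
mirror, so the matrix is exactly symmetric; homogeneous regions pile
counts on the diagonal, edges off it. The matrix side is
`L = max − min + 1` of the ROI, *not* a fixed 256 — this is what makes the
subsequent quadrant splits adaptive to the actual dynamic range.

The plane is then partitioned hierarchically. Layer 1 splits both axes at
`m = floor(L/2)`: the diagonal quadrants `B2` (low×low) and `B4`
(high×high) describe object interiors, the off-diagonal `B1`/`B3` describe
edges. Layer 2 splits `B2` and `B4` the same way into `B21..B24` and
`B41..B44`. Each sub-block is back-projected to a binary pixel mask: pixel
`p` is marked for block `B` when at least one of its in-ROI 8-neighbours
`q` gives an intensity pair `(I(p), I(q))` inside `B`'s index rectangle.

Enhancement shifts masked pixels by signed multiples of
`γ = σ/4` (population standard deviation of the ROI):

| block | B22 | B21 | B24 | B23 | B42 | B44 | B41 | B43 |
|-------|-----|-----|-----|-----|-----|-----|-----|-----|
| shift | −γ | −2γ | +γ | 0 | +γ | +γ | +2γ | 0 |

Dark non-object pixels (`B22`, `B21`) are pushed down, object pixels and
bright-side edges (`B24`, `B42`, `B44`, `B41`) up. The quarter-σ step is
the regime where the shift is visible but does not blow highlights; the
multiple is the tunable, not the formula.

## Tunable parameters

* `half_extent` (default **50** px): ROI half-size, giving the 100×100
  centre window on a 256×256 slice. The assumption is purely positional —
  the structures of interest are near the image centre.
* offset table (fixed defaults above): the per-sub-block multiples of γ.
  `B23`/`B43` receive 0 because no rule assigns them a shift; leaving them
  unchanged is stated rather than guessed.
* `clahe_config(tile_grid = c(8, 8), clip_limit = 0.01)`: the common
  reference CLAHE parameterization; `clip_limit` is the per-bin cap as a
  fraction of the tile's pixel count.
* `disk_se(radius = 3)`: flat disk for the morphological baselines.

The baseline parameters are deliberately configuration, not science: no
published values pin them down, so the harness makes them explicit.

## Design decisions in the genuinely open spots

* **ROI side 100, not 101.** "50 pixels to each side of the centre" is
  ambiguous about the centre row/column itself; the half-open window
  `[c−50, c+50)` is chosen so the ROI side is even and quadrant arithmetic
  is clean. Origins are reported 1-based in R (`(79, 79)` on 256×256).
* **Border policy.** All ROI pixels act as centroids; neighbours outside
  the ROI are skipped, no padding. This preserves exact histogram symmetry
  and the closed form `8MN − 6(M+N) + 4` for the total count, which the
  tests verify for all `2 ≤ M, N ≤ 20`.
* **Mask rule for off-diagonal sub-blocks.** A literal "pixel value equals
  both coordinates" rule can only ever mark diagonal cells and would leave
  `B21`, `B41` (which carry ±2γ!) with empty masks. The pair-membership
  rule used here reproduces the value-equality behaviour on diagonal
  blocks and gives the off-diagonal blocks their natural, non-empty
  boundary masks. Masks may overlap; offsets of overlapping masks are
  **summed**, which is order-independent, then rounded once (half away
  from zero — base R's half-to-even would make results parity-dependent)
  and clipped to `[0, 255]`. Clipping, not rescaling, prevents wraparound.
* **Quadrant orientation.** Row = centroid axis, column = neighbour axis.
  Symmetry makes the diagonal blocks invariant to this choice; it only
  fixes which off-diagonal block is called `B1` vs `B3`, and the offsets
  of those blocks are 0 anyway.
* **Odd splits.** Ranges of odd length split at `floor(len/2)`; the low
  half is the shorter one. `L = 1` degenerates to "`B2` is the whole
  plane", so a constant ROI is handled without special cases downstream
  (σ = 0 ⇒ γ = 0 ⇒ identity).

## What the phantom emulates — and what it does not

`generate_phantom()` renders a dark background, an elliptical brain with a
white-matter rim (170) and gray-matter interior (110), and three bilateral
pairs of elliptical structures at 60, 80 and 140, all inside the central
100×100 window, plus Gaussian noise (sd 5) clipped with the image to
`[0, 255]`. Intensities sit far from the range ends so the truncation bias
of the clipped noise is negligible; levels were fixed once, before any
acceptance measurement, to span both the dark (`B2`) and bright (`B4`)
halves of a realistic ROI histogram.

It does **not** emulate bias fields, partial-volume averaging, Rician
noise, or anatomy beyond "ellipses at plausible places". A green phantom
test therefore establishes that the machinery — masks, offsets, locality,
contrast direction — behaves as specified, not that clinical MR contrast
will improve by any particular amount. The label mask (0 background, 1 WM,
2 GM, 3–8 structures) is exact by construction, which is what lets the
contrast criterion be computed without a segmentation step.

## Numerical and degenerate-input conventions

* DICOM input is min–max rescaled to `[0, 255]` and rounded (windowing
  attributes ignored; a constant frame maps to 0); `MONOCHROME1` is
  inverted after rescaling. Colour inputs are converted with BT.601
  luminance weights. PNG/TIFF round-trips are bit-exact.
* `psnr()` returns `Inf` for identical images instead of erroring: method
  rankings need a total order.
* 1×K ROIs are rejected by the histogram builder (no 8-neighbour pairs);
  images smaller than `2 × half_extent` are rejected by `extract_roi()`.
* HE maps `v → round(MAX · cdf(v))` with the pixel's own bin included in
  the cdf; CLAHE with one tile and `clip_limit = Inf` reduces to exactly
  this mapping (verified bit-for-bit), which anchors the CLAHE
  implementation to the HE oracle.

## Scale of the shipped tests

Property counts were sized to keep the default suite near 30 s on one
CPU: round-trip I/O uses 60 random images (not 1000), oracle equivalence
uses 500 small instances split between histogram/mask and metric
families, and the locality property uses 100 images at 64×64 rather than
256×256 — the contracts involved are size-independent. The 20-seed
phantom-contrast criterion runs at the full 256×256.

## Known limitations

* Published per-patient benchmark values (shipped in `inst/extdata/`)
  can be checked only for internal consistency — the underlying 211
  images are not publicly available, so end-to-end reproduction of those
  tables is out of reach by construction.
* The enhancement is single-shot and 2-D; no multi-slice consistency, no
  iteration, no automatic ROI detection beyond the fixed centre window.
* The pure-R codecs cover the subsets stated in their documentation
  (8-bit PNG, uncompressed baseline TIFF, single-frame little-endian
  DICOM); they are not general-purpose format libraries.
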