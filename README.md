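# hcha

Object-adaptive contrast enhancement of grayscale brain MR slices by
**hierarchical correlation histogram analysis** (HCHA), with the standard
comparison baselines, image-quality metrics, and a seedable synthetic brain
phantom so the whole pipeline runs with no external data.

The package is aimed at people building preprocessing steps for
computer-aided analysis of brain MRI — in particular enhancing the contrast
of the deep-gray structures (caudate nucleus, putamen, thalamus) whose
atrophy is examined in Parkinson's disease workups — and at anyone who
wants a self-contained, fully tested R implementation of the algorithm and
its evaluation harness.

## The method

Given an `M x N` 8-bit image, the algorithm:

1. **ROI** — extracts the central `100 x 100` window (50 pixels each side
   of the centre point), assumed to contain the structures of interest.
2. **Correlation histogram** — scans the ROI with an overlapping `3 x 3`
   window; every pixel (as centroid `cen`) and each of its 8 in-ROI
   neighbours `n_k` add one count at cell `(I(cen), I(n_k))` of a square
   matrix `CorreHis` spanning the ROI's intensity range
   `L = max − min + 1`. The matrix is a symmetric gray-level co-occurrence
   matrix over the king-graph neighbourhood; identical neighbours
   accumulate on the diagonal.
3. **Hierarchical block analysis** — layer 1 splits the histogram plane at
   `floor(L/2)` into quadrants `B1..B4`: the diagonal quadrants `B2` (dark)
   and `B4` (bright) carry object information, the off-diagonal ones edge
   information. Layer 2 splits `B2` and `B4` again into `B21..B24`,
   `B41..B44`. Each sub-block is back-projected to a binary pixel mask:
   a pixel is marked when one of its neighbour pairs lands in the block.
4. **Enhancement** — with `μ` and population standard deviation `σ` of the
   ROI and amplitude `γ = σ/4`, pixel values in the masks are shifted by
   `B22: −γ`, `B21: −2γ`, `B24: +γ`, `B42: +γ`, `B44: +γ`, `B41: +2γ`
   (`B23`, `B43` unchanged), rounded once and clipped to `[0, 255]`. The
   result is written back into the ROI; everything outside is untouched.

Quality is scored with `MSE`, `PSNR = 10·log10(MAX²/MSE)` (original vs
enhanced — no clean reference exists) and the average gradient
`G = mean sqrt(((ΔrS)² + (ΔcS)²)/2)`. Baselines: global histogram
equalization, CLAHE, and morphological top-hat enhancement (flat disk).

## Worked example

```r
library(hcha)

ph  <- generate_phantom(phantom_spec(seed = 42))  # image + label masks
out <- enhance(ph$image)                          # HCHA enhancement
pipe <- enhance_pipeline(ph$image)                # same, with intermediates

pipe$params
#> <enhancement_params mu=109.338 sigma=21.360 gamma=5.340>
psnr(ph$image, out)
#> [1] 39.96768
average_gradient(ph$image); average_gradient(out)
#> [1] 7.713063
#> [1] 7.876215

roi <- extract_roi(ph$image)
rbind(before = structure_contrast(ph$image, ph$labels, roi),
      after  = structure_contrast(out,      ph$labels, roi))
#>            3     4     5     6     7     8
#> before 49.85 49.85 30.51 29.89 30.38 30.31
#> after  62.37 62.11 37.12 34.39 36.34 35.61
```

The ROI of the seed-42 phantom has mean 109.3 and standard deviation 21.4,
so the offset unit is `γ ≈ 5.3` intensity levels. The contrast table shows
the absolute difference between each structure's mean intensity and the
surrounding gray-matter band (labels 3–8 are the six structure ellipses):
every structure gains contrast, the caudate analogues (labels 3–4, darkest
at level 60) by ~12.5 levels. PSNR of ~40 dB says the method is
conservative — it moves only masked ROI pixels by a few levels — and the
average gradient rises because structure boundaries steepen.

Benchmark harness over a directory of images (5 methods × PSNR/average
gradient, CSV shaped like a per-patient results table):

```r
cmd_compare("path/to/images", run_config(out = "comparison.csv"))
```

or from the shell via the installed `exec/hcha` script:

```sh
hcha phantom --seed 42 --out phantom.png
hcha enhance phantom.png --method hcha --out enhanced.png
hcha compare imagedir --out comparison.csv
hcha metrics phantom.png enhanced.png
```

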