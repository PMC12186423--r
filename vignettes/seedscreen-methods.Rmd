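---
title: "Counting seeds and calling T-DNA locus number: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting seeds and calling T-DNA locus number: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedscreen)
```

## The screening problem

Agrobacterium-mediated transformation frequently integrates more than one
T-DNA copy into the plant genome. Lines carrying a single insertion locus are
strongly preferred — they segregate predictably and are less prone to
transgene silencing — so transformants are routinely screened by segregation
analysis: selfing a hemizygous T1 plant and scoring its T2 seed for a
dominant seed-coat marker. A single locus gives a 3:1 marker-positive :
marker-negative ratio; two independently segregating loci give 15:1; silencing
depresses the apparent positive fraction below 3:1.

Seed-coat markers make the scoring non-destructive: fluorescent FAST markers
(FastRed, FastGreen) are read from a fluorescence image, and the colorimetric
RUBY marker (red betalain pigment) from an ordinary RGB photograph. What
remains tedious is counting hundreds of seeds per line. `seedscreen`
automates that count from stereomicroscope images and runs the chi-squared
segregation test, so a line can be screened by pouring T2 seed into a weigh
boat and taking one or two pictures.

## The fluorescence-mode pipeline

Fluorescence mode takes a *pair* of images of the same field: a brightfield
frame, in which every seed is visible, and a fluorescence frame, in which
only marker-positive seeds glow. The two frames are counted independently;
the brightfield count is the total `N` and the fluorescent count the
marker-positive `n_t`.

Each frame passes through the same detection stack
(`segment_seeds()`), operating on grayscale images on the 0–255 scale with
seeds bright on a dark background (brightfield frames are inverted first):

1. **Grayscale conversion** (`to_grayscale()`): ITU-R BT.601 luminance
   `0.299 R + 0.587 G + 0.114 B`, rounded.
2. **Inversion** (`invert_image()`, brightfield only): `v -> 255 - v`.
3. **Scale-bar removal** (`remove_scale_bar()`): any bright connected
   component that touches the image border with bounding-box aspect ratio
   above 8 and fill solidity above 0.95 is painted over with the image's
   modal intensity. Bars are long, thin, solid and border-adjacent; seeds are
   none of these. An explicit exclusion rectangle is also accepted.
4. **Binarization** (`binarize()`): foreground iff value *strictly* exceeds
   the intensity threshold. The strict comparison makes the foreground
   monotone non-increasing in the threshold and threshold 255 empty, which
   keeps tuning behaviour predictable. The threshold is a free parameter
   (0–255) or `"auto"`, which uses Otsu's criterion: the threshold
   maximizing between-class variance of the intensity histogram, computed
   over all 256 candidates, ties broken toward the lowest maximizer.
5. **Morphological opening** (`morphological_clean()`): one opening with a
   3×3 element removes isolated pixels and pixel-scale spurs before they can
   seed spurious regions. Opening is idempotent, so a single pass suffices.
6. **Connected components** (`label_components()`): 8-connectivity, so
   antialiased boundaries never fragment a seed; per-region area, centroid
   and mean intensity are extracted.
7. **Adaptive radial threshold** (`derive_radial_threshold()`): the pixel
   scale of the image is estimated from the seeds themselves as
   `r_med = sqrt(median(area)/pi)`, the equivalent radius of the median-area
   region, and the radial threshold is `t = ratio × r_med`. The median is
   robust to merged clumps and debris, and the ratio (default **0.4**)
   transfers across species and magnifications; with Arabidopsis-scale seeds
   of `r_med = 20 px`, ratio 0.45 gives `t = 9 px` and ratio 0.5 gives
   `t = 10 px`. The threshold can also be fixed directly in pixels.
   It is recomputed for every image, so a batch mixing magnifications needs
   no per-image configuration.
8. **Noise filtering** (`filter_noise()`): regions with equivalent radius
   below `t` are removed — dirt and dust are far smaller than seeds.
9. **Distance transform** (`chamfer_distance()`): two-pass chamfer
   propagation with weights 3 (edge) and 4 (diagonal), normalised by 3,
   approximating each foreground pixel's Euclidean distance to the nearest
   background pixel.
10. **Marker cores and watershed** (`make_markers()`, `watershed_split()`):
    marker cores are the connected components of `{distance >= t}`;
    thresholding the distance map erodes every region inward by `t` pixels,
    so the thin neck between two touching seeds drops out and each seed
    contributes its own core. The watershed then floods the negated distance
    map from the cores — basins grow outward, highest distance first, until
    every foreground pixel is claimed. The result is by construction a
    partition of the mask with exactly one region per core; the final seed
    count is the number of cores.
11. **Contours** (`extract_contours()`): one closed polygon per seed, traced
    along pixel edges, drawn onto overlay images for visual verification.

### Choosing the two thresholds

The intensity threshold trades off dim seeds (threshold too high: missed)
against background and halo pickup (too low: spurious or fused regions); the
brightfield and fluorescent channels typically need different values, and
`"auto"` is a good starting point for well-separated histograms. The radial
ratio trades off splitting (too low: touching seeds merge, count drops)
against over-suppression (too high: the smallest seeds lose their distance
core entirely and are dropped). When seeds visibly clump, raising the radial
threshold is the first adjustment to try; the error message raised when *no*
core survives points the same way.

Geometry bounds what splitting can achieve. An elongated seed's interior
distances reach only its semi-minor axis (about `0.75 r` at aspect ratio
1.8), so a ratio above ~0.5 starts sacrificing the smallest seeds, while a
pair of deeply interpenetrating blobs has a neck as thick as `0.8 r` when the
centres are `1.2 r` apart — no admissible threshold separates such a pair.
Physically touching seeds, whose necks are a few antialiased pixels, split
easily. This is why counts remain accurate on fields of discrete touching
seeds but degrade gracefully (undercounting by the number of fused pairs)
when seeds pile deeply enough to overlap in projection.

### Numerical details

* The chamfer 3–4 metric is exact on the axes, reads diagonal distances ~6%
  low and oblique ones up to ~4.5% high; worst-case disagreement with the
  Euclidean distance stays below 8%. Consequently a level-set threshold acts
  up to ~5% "higher" on oblique necks than ideal-Euclidean reasoning
  suggests.
* Watershed flooding uses 8-connected growth with FIFO tie-breaking at equal
  distance, making results deterministic.
* A region that survives the noise filter but whose interior never reaches
  the radial threshold (possible for small elongated seeds when the
  threshold is set high) has no core; it is treated as below the noise floor
  the radial threshold defines and dropped with a warning, preserving the
  partition and count invariants.
* Seeds touching the image border are counted, since a poured field is
  scored in full.
* Empty masks yield a 0-seed result with a warning; a configuration in which
  *regions exist but none survives* raises an error with tuning guidance
  instead of silently reporting zero.

## Colorimetric (RUBY) mode

`classify_colorimetric()` handles a single RGB image on a white background.
The image is converted to CIELAB (standard sRGB/D65 conversion, validated to
0.01 against reference values). Seeds are darker than the white background,
so the seed mask is `L* < L_threshold` (Otsu on the L* plane when `"auto"`);
the radial threshold, noise filter and watershed then run exactly as above.
Each final region is classified RUBY iff its **mean** b* falls below the b*
threshold — red betalain pigment sits low on the blue–yellow axis, yellow
wild-type seed coats high — and the region mean makes the call robust to
specular highlights.

With `b_threshold = "auto"`, Otsu runs on the b* histogram of seed pixels,
restricted to region interiors (the ~1 px antialiased rim blends toward the
background and would smear the histogram). Because the optimal Otsu split of
even a unimodal Gaussian "explains" about 64% of its variance, a variance
criterion alone cannot detect the absence of a second class; the auto
threshold is therefore accepted only if the split explains at least half the
b* variance *and* the two class means are at least 10 b* units apart (half
the minimal yellow-vs-red contrast of ~20+ units). A single-class population
fails the guard and the run demands an explicit `b_threshold`, rather than
fabricating a split.

No white-balance correction is applied; classification is stable under
uniform brightness scaling within ±10%.

## The segregation test

With `N` total and `n_t` marker-positive seeds, `chi_squared_segregation()`
computes Pearson's goodness-of-fit statistic over the two categories against
expected counts `(f N, (1-f) N)` — no continuity correction — and the
p-value from the upper tail of the chi-squared distribution with one degree
of freedom. The default null is the single-locus fraction `f = 0.75`;
`expected_transgenic_fraction(k)` gives `1 - (1/4)^k` for `k` independent
hemizygous dominant loci (0.75, 0.9375, …). The decision rule is strict:
`p < alpha` (default 0.05) rejects the single-locus hypothesis; the result
also annotates the direction of departure, since an excess of marker seeds
points toward multiple loci while a deficit suggests silencing. The package
reports the two-locus expectation as an annotation only — it never
auto-assigns a locus number. No multiple-testing correction is applied
across a batch; the per-sample log notes how many lines were tested.

At `N = 100` the test is well calibrated (simulated type-I error ≈ 0.047 at
`alpha = 0.05`) and essentially always rejects a true two-locus line
(simulated power > 0.999 against `f = 15/16`). Linked or tandem insertions
at one locus segregate like a single locus and are invisible to this
analysis by design.

## The synthetic scene generator

Because microscope images come with no ground truth, validation uses
`generate_scene()` + `render_fluorescence_pair()` / `render_colorimetric()`:
fully reproducible scenes of elliptical "seeds" with known positions, sizes
and classes. Defaults emulate a single layer of Arabidopsis-scale seed
poured into a weigh boat: equivalent radius lognormal with mean 20 px and CV
0.15, aspect ratio uniform in 1.2–1.8, random orientation, marker class
drawn per seed (default fraction 0.75), brightness lognormal (presets for
dim and near-saturating markers), Gaussian pixel noise (default sd 3),
antialiased edges, optional solid scale bar, and an optional fraction of
seeds placed in deliberately touching/overlapping pairs at centre distance
1.2–1.8 × the mean radius. Rendering is byte-identical given the scene seed.

What the generator does **not** emulate: seed-coat texture, optical
point-spread and vignetting, uneven illumination, debris with seed-like
size, and the 3-D stacking of real piles (rendered overlaps interpenetrate
in 2-D, which is *harsher* on the splitting step than physically touching
seeds). Passing the synthetic suite therefore demonstrates the geometry and
statistics of the pipeline, not robustness to every optical artifact of a
real microscope.

Validation problem sizes used by the test suite and the acceptance script:
50 scenes of 50–200 seeds with the overlapping-pair fraction cycling through
0–10% recover counts with a mean absolute percent error below 2% at default
parameters (overlap-free scenes are recovered exactly); 10 colorimetric
scenes of 40–80 seeds are counted and classified without error; and
rendered 96-seed/90-marker and 100-seed/75-marker fields reproduce the
textbook rejected / consistent calls end to end.

## Batch processing and the CLI

`run_batch()` processes a manifest or a directory using the
`<id>_BF.*`/`<id>_FL.*` (or `<id>_RGB.*`) naming convention, isolates
per-sample failures, and writes a CSV with one row per sample
(`write_records_csv()` serialises doubles at full precision, so reading the
file back reproduces every value exactly). `adjust_counts()` applies a
reviewer's manual correction and recomputes the test, flagging the record.
A thin command-line front end wrapping these functions ships at
`system.file("cli/seedscreen.R", package = "seedscreen")`.

## Known limitations

* Locus-number inference shares the intrinsic limits of segregation
  analysis: tandem/linked multi-copy insertions look single-locus, and
  strong silencing can masquerade as a locus-count anomaly.
* The two channels are counted independently, not matched seed-by-seed; a
  gross segmentation failure in one channel is caught only when the marker
  count exceeds the total.
* Deeply overlapping seed piles undercount by roughly one per fused pair;
  the remedy is spreading the seeds, or raising the radial threshold at the
  cost of the smallest seeds.
* 16-bit inputs are linearly rescaled to 8 bits on load.
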