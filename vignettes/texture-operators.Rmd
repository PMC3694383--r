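---
title: "Generalized texture operators and interval-based segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized texture operators and interval-based segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mritex)
```

## The analysis model

`mritex` treats a grayscale image as the realization of a stochastic
process and describes it through window statistics. A recognition window
(RW) of fixed size $n_a \times n_b$ (default $6 \times 6$) scans the image
top-to-down, left-to-right; by default the scan is non-overlapping, and
partial windows at the right/bottom margins are discarded rather than
padded, so every window holds exactly $n_a n_b$ pixels — which the
histogram and co-occurrence normalizations assume. Each window is reduced
to one number per operator, producing a subsampled feature map; maps over
several operators, images and pyramid levels form a feature space.

Two first-order operators act on the window histogram $p(i)$: the
generalized moment $M(n_1)=\sum_i i^{n_1} p(i)$ and central moment
$C(n_2)=\sum_i (i - M(1))^{n_2}\, p(i)$. They measure informative content
rather than texture proper: background windows show very low $M$ and low
$C$, regions of interest high $M$ and very high $C$, and transition zones
low $M$ with high $C$.

Six second-order operators act on an *all-directions* co-occurrence
matrix. Every window pixel is the center of a discrete circumference of
radius $d$; each ordered (center, ring partner) pair increments the cell
indexed by their gray levels. We realize the discrete circumference as the
Chebyshev square ring — all displacements with
$\max(|\Delta r|, |\Delta c|) = d$, i.e. $8d$ offsets. This choice is
pinned down by the construction's own arithmetic: a circumference at
$d = 2$ must contribute 16 pairs per center (so an interior $3\times3$
window contributes $9 \times 16 = 144$ increments), and the square ring
yields $8d$ points at *every* radius by construction, while rasterized
circles match only at some radii. Ring partners are looked up in the full
image, not the window, so each window's statistics include context from a
band of width $d$ around it.

The operators — homogeneity, contrast, inverse difference, entropy,
correlation and difference entropy — are generalized by integer exponents
(`n3`–`n13`) and log bases (`k1`, `k2`); see the help pages for the exact
forms. HG and CT capture macrotexture (uniformity and amplitude
variation), ID and ET microtexture (fine structure and randomness), CR and
DE spatial relationships between patterns. Their responses are not
independent: `dependence_table()` records an empirical 1 (low) to 4 (high)
dependence level for every operator pair (e.g. $M$–$C = 4$: the mean and
variance of a zone must be evaluated jointly), which the classifier uses
as voting weights.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `window` ($n_a \times n_b$) | RW size, pixels | 6 × 6 | smallest square window that still captures micro- and macrotexture in 8-bit 512² imagery; one unit larger/smaller can help noisy zones |
| `stride` | scan step, pixels | = window | non-overlapping scan; overlap (stride < size) is useful for weakly textured structures such as bone |
| `d` | ring radius, pixels | 2 | most broadly useful radius; 2–3 in practice, larger values probe boundary dynamics |
| `n1`–`n13` | operator exponents | lead value of the region preset | the preset grids (brain/heart/liver/bone YAML files) span the useful range; exponents shape the dynamic of the response |
| `k1`, `k2` | log bases | 2 | entropy in bits |
| `q` | exponent inside $p_{x-y}$ | 1 | with $q=1$, $p_{x-y}$ is a probability distribution |
| `pyramid levels` | resolution tiers | 2 (L0, L1) | L1 (2× mean-downsampled) summarizes low-information zones; most useful for dynamic textures |
| `quantile` | interval trim fraction | 0.01 | robustifies intervals against noise; 0 gives exact min/max |

## Numerical and design choices

* **Quantization.** `quantize()` uses equal-width binning over the
  observed range, $\lfloor (v - \min) \cdot L_{out} / (\max - \min + 1)
  \rfloor$; a constant image maps to 0 (degenerate range; any constant is
  equally valid, 0 is deterministic). For full-range input this reduces to
  $\lfloor v L_{out}/L_{in} \rfloor$. On read, samples that already fit
  $[0, L-1]$ are kept untouched so 8-bit round trips are bit-exact;
  wider samples (16-bit) are requantized, mapping the observed maximum to
  $L-1$.
* **Joint normalization.** The co-occurrence constraint is read as the
  joint normalization $\sum_i \sum_j p_d(i,j) = 1$ (a per-column
  normalization cannot hold for all columns simultaneously).
* **Borders.** Ring partners outside the image are skipped and the matrix
  renormalized over realized pairs — no padding, no wrap-around. Border
  windows therefore have totals below $n_a n_b \cdot 8d$ but still sum
  to 1.
* **Marginal scale.** The correlation denominator uses standard
  deviations $\sigma_x \sigma_y$ (square roots of the marginal second
  central moments). With variances instead, CR would not normalize to
  $\pm 1$ on perfectly (anti)correlated two-level matrices, which is the
  behavior the operator's discriminating examples rely on.
* **Correlation variants.** The numerator is computed as printed in the
  operator definition, $(i-\mu_x)(i-\mu_y)$, by default
  (`variant = "as_printed"`); the standard Haralick cross-moment
  $(i-\mu_x)(j-\mu_y)$ is available as `variant = "haralick"`. They
  genuinely differ — mass at $p(0,1)=p(1,0)=\tfrac12$ gives $+1$ vs $-1$ —
  so both are first-class and covered by tests.
* **Degenerate variance.** On constant windows $\sigma_x\sigma_y = 0$; CR
  returns the sentinel 0 with a `degenerate` attribute instead of failing,
  keeping feature maps total over background windows.
* **Odd `n7`.** The inverse-difference denominator $1 + (i-j)^{n_7}$
  vanishes at $i - j = -1$ for odd $n_7$; the implementation substitutes
  $|i-j|^{n_7}$ there (the even case is computed exactly as written). The
  liver preset's $n_7 = 3$ runs on this absolute-difference form.
* **Entropy signs.** ET and DE keep the printed leading minus with the
  exponentiated logarithm and no absolute value, so even `n9`/`n13`
  produce non-positive values. The interval model compares feedbacks, so
  the sign convention only needs to be consistent.
* **Central-moment centering.** $C(n_2)$ centers on the first-order mean
  $M(1)$ by default; centering on a higher-order raw moment is
  dimensionally incoherent, but a `center_order` argument provides the
  literal behavior for fidelity experiments.
* **Pyramid.** L1 is a 2×2 rounded-mean downsampling of the source,
  re-analyzed with the same RW. Operators are not chained on feature maps:
  the second-order formulas assume gray levels of the source domain.
  Rounding is half-up throughout for platform-independent determinism.
* **Level combination.** Intervals are fitted per level; at classification
  time each level contributes independent feature columns, and an L0
  window takes its L1 value from the L1 window containing its halved
  center pixel (clamped at margins). This is an interpretation — the
  procedure leaves multi-level combination open — and is documented as
  such.
* **Voting.** A matching operator's weight is $1 +$ the mean dependence to
  the *other* operators matching the same class (same-name operators
  across levels count as dependence 4). The score is a sum over matched
  operators, hence invariant to operator order; ties break to the earliest
  class in the model's class order. This is one reasonable reading of the
  instruction that dependent operators be evaluated jointly, not a
  prescribed algorithm.
* **Parameter refinement.** The interactive expert-in-the-loop tuning
  step is replaced by a deterministic grid search (`tune_operator_set()`)
  over the region preset grids, choosing per operator the combination
  minimizing summed normalized inter-class interval overlap — the minimal
  automation of the stated aim (strong per-class feedback, low variation
  among weakly dependent operators).
* **Margins.** Pixels never covered by a window keep the reserved `NA`
  label and are excluded from error scoring; the error metric also reports
  per-class over-/under-segmentation fractions.

## The synthetic phantom generator

`make_phantom()` renders a background patch plus ordered regions (disk,
annulus, rectangle), each with its own texture process (constant, uniform
or gaussian noise, checkerboard, stripes, smoothed-noise blobs) and class
label; later regions overwrite earlier ones, and boundary pixels take the
topmost region's label. All randomness flows from one seed through a
private RNG stream. The `brainlike` preset emulates the gross structure
the operators assume in head imagery: a dark noisy background, a large
textured tissue disk (≥ 20% of the frame, mirroring the slice-selection
rule used for evaluation), and a bright rim akin to a skull — exactly the
background/tissue/boundary triplet the first-order operators are meant to
tell apart.

What the phantom does *not* emulate: acquisition physics (no $T_1/T_2$/PD
contrast mechanisms, bias fields, partial-volume mixing or Rician noise),
anatomical shape variability, or pathology. Passing the synthetic
segmentation bound therefore demonstrates that the pipeline recovers
known, well-separated texture classes at realistic geometry and noise — it
does not certify clinical performance on patient images, which are not
distributed with the package.

## Problem sizes and performance

Unit tests run on 9–96 pixel squares with reduced alphabets (L = 8–16) so
brute-force oracles (quadruple-loop co-occurrence construction, dense
double-loop operators) stay exact and fast. The segmentation bound is
exercised at the native 512 × 512, L = 256 scale: five train/test phantom
seed pairs, each fit on one phantom (both pyramid levels) and scored on a
held-out phantom, with every run required to stay below 8% pixel error;
a full pair takes roughly half a minute on one core. The per-image cost is
dominated by the per-window ring gather, which is precomputed once per
image and radius as a pair-key matrix.

## Known limitations

* Gray-level alphabets above 256 are supported in memory but not by the
  8-bit PNG/TIFF writer.
* Non-square and circular windows are out of scope; overlap is expressed
  through strides only.
* The interval classifier is axis-aligned by construction: classes
  separable only by joint (correlated) feature structure need additional
  operators or parameters rather than rotated decision boundaries.
* Direction-resolved (per-angle) co-occurrence matrices are deliberately
  absent — the all-directions ring is the point of the construction; use
  classic GLCM tooling if anisotropy matters.
* DICOM/NIfTI readers, bias-field correction and intensity windowing are
  out of scope; inputs are generic 8/16-bit grayscale rasters.
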