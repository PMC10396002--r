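---
title: "Fusing multimodal images by information clustering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing multimodal images by information clustering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icif)
```

## The problem

Infrared and visible cameras (or CT and MRI scanners, or two focal planes)
see the same scene through different physics. A hot pedestrian glows in the
thermal band but may be invisible at night in the visible band; pavement
texture is rich in the visible band but flat in the thermal one. Image
fusion combines one co-registered pair into a single frame that keeps both
the salient thermal targets and the visible texture.

Classical two-scale fusion splits each source into a smooth *base* layer
and a *detail* residual, fuses the layers separately, and recombines. The
weakness of that recipe is that each source is decomposed *on its own*:
the two detail layers then describe uncorrelated structure, and any fixed
fusion rule loses information where the layers disagree. The method
implemented here addresses that by letting each modality steer the other's
decomposition — "information clustering" — and by choosing the detail
weight adaptively from the images' global contrast.

## Information clustering: a cross-guided weighted median filter

The base layer of image $I$ is a weighted median filter of $I$ whose
weights come from the *other* modality. For the center pixel $p$ of a
$(2r+1)\times(2r+1)$ window $R(p)$, each neighbour $q$ receives the
affinity

$$ W_{pq} = g\!\left(f(p), f(q)\right) = e^{-|f(p)-f(q)|/h}, $$

where $f$ is the guidance map and $h$ a bandwidth. The output at $p$ is
the weighted median: sort the window values ascending and take the
smallest value whose cumulative weight reaches half the total. Median
selection (rather than averaging) means every output value is an actual
pixel value of the window, so no halo or overshoot artifacts can be
created.

The guidance map for clustering image $I_1$ is the other image scaled to
$[0, \tfrac12]$: $f = 0.5\, I_2^\ast$ with $I_2^\ast = I_2/255$, and
symmetrically for $I_2$. A bright/dark boundary in the partner modality
therefore reduces the affinity of pixels across it, and smoothing respects
the partner's structure. Where the partner is flat, the filter degenerates
to a plain median — maximal smoothing.

Two notational points deserve mention. The affinity above is written with
an absolute difference and an explicit bandwidth: an influence function
must be symmetric in its arguments and maximal when they coincide, and a
scale is needed because guidance lives on $[0,1]$. The default
$h = 0.1$ makes a tenth of the guidance range the natural contrast unit;
smaller $h$ sharpens edge preservation, larger $h$ approaches the plain
median. Second, the prose description of the guidance map sometimes
suggests a high-pass combination; the formula $0.5\,I^\ast$ is what is
implemented (`guidance_map()`), and the high-pass reading is left as a
possible future variant.

### Acceleration: joint histogram, balance box, necklace table

Recomputing weights and re-sorting for every window is
$O(n \log n)$ per pixel. The accelerated backend maintains, per sliding
window, a *joint histogram* $H(i, f)$ over (intensity bin, guidance bin):
because the weight of a pixel depends only on its guidance bin and on the
center's guidance bin, the weighted count of intensity bin $i$ is
$W_i = \sum_f H(i,f)\, g(f_f, f(p))$ — the window's pixels never need to
be revisited. The median search keeps a running *cut point* $c$ with its
*balance* $b$ (weighted count at-or-below $c$ minus above $c$), stored as
a per-guidance-bin *balance counting box* so that moving one pixel right
only adds/removes two histogram columns and nudges $c$ a few bins. A
*necklace table* — a circular doubly-linked ring over the occupied
guidance bins — lets every balance evaluation skip empty bins entirely.

The two backends are required to agree **pixel-exactly**, which a naive
floating-point implementation would not guarantee: regrouped sums round
differently, and a tie in the balance can then resolve to different bins.
The package removes the problem at the root: the affinity table is
quantized to multiples of $2^{-30}$ (error $< 10^{-9}$). Window sums then
involve at most $(2r+1)^2 \cdot 2^{30} < 2^{53}$ units, so *every*
accumulation the filter performs is exact in double precision, in any
order, and the backends are equal by construction, not by tolerance.

Other numerical conventions, chosen once and pinned by tests:

* **Quantization.** 256 intensity bins on $[0,255]$ (lossless for 8-bit
  data) and 32 guidance bins on $[0,1]$; weights are evaluated on
  guidance *bin centers* (the histogram factorization requires it).
* **Ties.** The median is the smallest bin whose balance is
  $\ge 0$; within the median bin the lower median of the original window
  values is returned. Fully deterministic.
* **Borders.** Windows are truncated at the image edge — only real pixels
  enter the histogram, which preserves the selection property.
* **Cut propagation.** The cut point is propagated along each row and
  reset at row starts; a full-image serpentine propagation would save a
  little work but complicates the exactness argument for no measurable
  gain at these sizes.

## Two-scale decomposition

With the base layer $IC(I)$ in hand, the residual is split by sign:

$$ I_{BD} = \max(I - IC(I),\, 0), \qquad I_{DD} = \max(IC(I) - I,\, 0), $$

the *bright* and *dark* detail layers. Both are nonnegative with disjoint
support and $I = IC(I) + I_{BD} - I_{DD}$ exactly. Written without the
clipping the two residuals are negatives of each other; the clipped form
is used because the two layers are conceptually distinct (structure
brighter vs. darker than its surroundings). Since the recombination rule
applies the same weight $k$ to both, the final fused image is identical
under the clipped and unclipped conventions — this algebraic identity is
regression-tested rather than assumed.

## Fusion rule

**Base layers.** The two bases are combined through their pixelwise
extrema $I_{B\max}$, $I_{B\min}$ and a standard-deviation weighting

$$ I_{BF} = \frac{\min(\sigma_{B\max},\sigma_{B\min})}{\sigma_{B\max}+\sigma_{B\min}} I_{B\max}
          + \frac{\max(\sigma_{B\max},\sigma_{B\min})}{\sigma_{B\max}+\sigma_{B\min}} I_{B\min}. $$

The weights sum to one and deliberately favour the *flatter* extremum:
taking the max image alone washes out texture under intense light, the min
image alone is dim; the inverted weighting lands between. Two flat inputs
(zero deviations) fall back to equal weights.

**Detail weight.** Let $\sigma_1, \sigma_2$ be the standard deviations of
the two source images and $\sigma_3, \sigma_4$ those of $I_{B\max}$ and
$I_{B\min}$ (all population-convention, 0–255 scale). The information
ratio

$$ \rho = \frac{\sqrt{\sigma_1+\sigma_2} - \sqrt{\sigma_3+\sigma_4}}{\sqrt{\sigma_3+\sigma_4}} $$

measures how much source contrast the base fusion failed to carry. The
detail weight is $k = 1 + \rho$ (enhancement) when both sources are
high-contrast ($\min(\sigma_1,\sigma_2) > 30$), and $k = 1 - \rho$
(attenuation) otherwise; in one expression,

$$ k = 1 + \operatorname{sgn}\!\bigl(\min(\sigma_1,\sigma_2) - 30\bigr)\,\rho, $$

with $\operatorname{sgn}(0) := 0$ so that $k = 1$ exactly at the
boundary (the raw expression is 0/0 there, and a neutral weight is the
only continuous choice). The rationale for the switch: when either
modality is globally flat (night-time visible, plain-tissue CT),
amplifying details amplifies mostly noise and over-brightens the flat
modality's residual, so attenuation gives the cleaner fusion; when both
modalities are information-rich, enhancement extends the texture spacing.
The threshold 30 is on the 8-bit intensity scale.

Two points were genuinely open and are exposed as configuration rather
than hard-coded:

* **Radical grouping.** "Square root of the summed information" is read
  as $\sqrt{\sigma_1+\sigma_2}$ vs. $\sqrt{\sigma_3+\sigma_4}$ (the
  default, giving the clean closed form
  $k = \sqrt{(\sigma_1+\sigma_2)/(\sigma_3+\sigma_4)}$ in the enhancement
  branch). The per-term reading $\sqrt{\sigma_1}+\sqrt{\sigma_2}$ is
  selectable (`radical_grouping = "per-term"`); the two are never mixed.
* **Which sigmas enter $\rho$'s denominator.** The extrema images' (the
  default, `sigma_source = "extrema"`) or each source's own base layer's
  (`"base"`). The former follows the rule's explicit definition; the
  latter matches how per-image figures are usually tabulated.

**Recombination.** $I_F = I_{BF} + k\,(I_{BD1}+I_{BD2}) - k\,(I_{DD1}+I_{DD2})$,
clamped to $[0,255]$ (the clamp count is reported). Every stage is
symmetric in the input order, so the full pipeline is pixel-exactly
swap-invariant.

## Quality metrics

Five single-image metrics (of the fused image) and three
gradient-preservation scores (against both sources) are provided, the
standard formulations pinned by closed-form fixture tests — constant,
ramp, step, and checkerboard images with hand-derivable values:

* `average_gradient`: mean of $\sqrt{(\Delta_x^2+\Delta_y^2)/2}$ over
  forward differences; a ramp of unit step gives $\sqrt{1/2}$.
* `img_entropy`: Shannon entropy of the 256-bin histogram, bits; at most 8.
* `std_dev`: population standard deviation (contrast).
* `spatial_frequency`: RMS of horizontal and vertical neighbour
  differences, combined in quadrature; a unit ramp gives exactly 1.
* `edge_intensity`: mean Sobel magnitude, reflect-padded; an ideal 0→255
  vertical step yields $4 \cdot 255$ on the two columns flanking the edge.
* `petrovic_scores`: per-pixel Sobel strength and orientation for A, B, F;
  relative strength preservation (weaker/stronger ratio) and orientation
  agreement are mapped through the published sigmoid constants
  ($\Gamma_g = 0.9994$, $\kappa_g = -15$, $\sigma_g = 0.5$;
  $\Gamma_\alpha = 0.9879$, $\kappa_\alpha = -22$, $\sigma_\alpha = 0.8$;
  overridable) and combined into the edge-strength-weighted total
  $Q^{AB/F}$. Loss $L^{AB/F}$ accumulates the unpreserved fraction where
  the fused gradient is weaker than a source's; artifacts $N^{AB/F}$
  where it exceeds both. No $Q+L+N=1$ constraint is imposed — the three
  are defined independently and published tabulations do not sum to one.
  Orientation differences are taken modulo $\pi$ (edge orientation, not
  gradient direction).

## The synthetic test bed

Real benchmark pairs (field thermal/visible captures, registered medical
scans) cannot ship with a package, so the test conditions are generated:
`make_pair()` renders one shared piecewise-smooth scene — smoothed
Gaussian noise, rank-flattened and posterized into five equal-mass levels,
so structure contrast is stable across seeds — twice. Modality A gets the
full structure contrast plus fine-grained texture (visible-like); modality
B gets flattened contrast, milder texture, and `n_blobs` small flat-top
hot spots placed at seeded positions (thermal-like), with a binary target
mask returned. All randomness flows from one integer seed through an
isolated RNG scope; identical parameters give bit-identical pairs.

Generator conditions are fixed, not tuned per test: the `high` texture
preset maps structure onto spans (A: 15–150, B: 40–170 plus targets)
whose equal-mass five-level layout puts both source deviations near 48 —
clearly above the branch threshold of 30; the `low` preset (A: 105–165,
B: 112–152) keeps the visible-like deviation near 21, below it. Hot spots
default to radius ≈ `min(size)/32` (≈ 3 px at the default 96×96) —
deliberately *smaller* than the default 11×11 filter window, the regime
of distant pedestrians and vehicles in thermal imagery, so targets ride
in the bright-detail layer and the fusion's detail re-injection is what
must preserve them. Default additive sensor noise is 2 intensity levels.

What the generator does *not* emulate: registration error, sensor blur
differences, non-Gaussian noise, gradual thermal gradients, or natural
texture statistics. Passing the synthetic suite therefore demonstrates
the algebraic and structural properties of the implementation and the
qualitative branch behaviour — not field performance on real captures.

## Problem sizes and runtime

The shipped tests run the filter oracle comparison on fifty 16×16 pairs
across radii 1–3 and two guidance quantizations, decomposition and fusion
properties on 32×32 pairs, and ten end-to-end 96×96 fusions; the whole
suite completes in well under a minute on one core. The acceptance script
fuses two 96×96 pairs (one per texture preset) with the default 11×11
window and recomputes every reported quantity from scratch. These sizes
were chosen to keep the full pipeline — including the deliberately slow
naive reference backend — fast enough to run habitually; the accelerated
backend itself handles megapixel frames in seconds.

## Known limitations

* Single-channel fusion only; RGB input is collapsed to luminance on
  ingest with a warning.
* Exactly two sources; no multi-exposure stacks.
* The filter's intensity representative within the median bin is the
  bin's lower-median window value; for `ni = 256` on 8-bit data this is
  exact, for coarser `ni` on continuous data it is one of several
  defensible conventions.
* No registration: misaligned pairs produce ghosting, as with any
  pixelwise fusion rule.
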