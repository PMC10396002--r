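# icif — multimodal image fusion via information clustering

`icif` fuses a co-registered pair of single-channel images — thermal +
visible, CT + MRI, two focal planes — into one frame that keeps the
salient targets of one modality and the texture of the other. It is aimed
at researchers working with multi-sensor imagery who need a deterministic,
fully inspectable spatial-domain fusion pipeline plus the standard metric
suite to evaluate it.

## The method

Each source image is decomposed by **information clustering**: a weighted
median filter whose weights come from the *other* modality. For center
pixel *p* and window neighbour *q*,

    W_pq = exp(−|f(p) − f(q)| / h),    f = 0.5 · (partner image / 255)

and the base layer IC(I) is the weighted median of each window (an
actual window value, never an average). The residual is split by sign
into nonnegative bright/dark detail layers:

    I_BD = max(I − IC(I), 0),   I_DD = max(IC(I) − I, 0).

The two base layers are fused through their pixelwise extrema with
inverted standard-deviation weights:

    I_BF = [min(σ_Bmax, σ_Bmin) / (σ_Bmax + σ_Bmin)] · I_Bmax
         + [max(σ_Bmax, σ_Bmin) / (σ_Bmax + σ_Bmin)] · I_Bmin

and the detail layers are re-injected with an adaptive weight

    k = 1 + sgn(min(σ1, σ2) − 30) · (√(σ1+σ2) − √(σ3+σ4)) / √(σ3+σ4),

which enhances detail when both sources are high-contrast
(min σ > 30 on the 8-bit scale) and attenuates it otherwise. The fused
image is

    I_F = I_BF + k (I_BD1 + I_BD2) − k (I_DD1 + I_DD2),  clamped to [0, 255].

The filter ships two backends that agree **pixel-exactly**: a naive
per-window reference, and an accelerated sliding joint-histogram backend
with balance-counting-box cut propagation and a necklace table that skips
empty guidance bins. The metric suite covers AG, entropy, SD, SF, edge
intensity, and the gradient-preservation triple Q^AB/F, L^AB/F, N^AB/F.
See the vignette (`vignettes/information-clustering-fusion.Rmd`) for the
full account, including every convention the formulas leave open.

## Worked example

```r
library(icif)

pair <- make_pair(synth_params(seed = 7))   # synthetic thermal+visible pair
fit  <- fuse_images(pair$modA, pair$modB)
print(fit)
#> Fused image: 96 x 96
#>   sigma1 = 48.169  sigma2 = 50.033  sigma3 = 45.881  sigma4 = 46.610
#>   detail weight k = 1.0304 (positive branch)
#>   base weights: 0.4961 (max) + 0.5039 (min)
#>   clamped pixels: 21

metric_report(pair$modA, pair$modB, fit$fused, name = "seed7")
#>    name    ag    h    sd    sf    ei  q_abf  l_abf  n_abf
#> 1 seed7 11.84 7.12 50.88 24.97 88.32 0.7666 0.1093 0.1241
```

Both synthetic sources have standard deviation above 30, so the adaptive
rule takes the enhancement branch (k = 1.03 > 1): the fused image's
details are slightly amplified relative to the base fusion. The report
says the fused frame carries 77% of the sources' edge information
(`q_abf`), loses 11% (`l_abf`) and introduces 12% spurious gradient
content (`n_abf`); `ag`/`sf`/`ei` quantify its sharpness and `h`/`sd` its
information content and contrast.

From a shell, the same pipeline is available as a CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "icif.R", package = "icif"))') \
  fuse A.png B.png -o fused.png --metrics --save-layers
```

with subcommands `fuse`, `decompose`, `metrics`, `synth`; exit codes 2
(missing input), 3 (shape mismatch), 4 (unwritable output).

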