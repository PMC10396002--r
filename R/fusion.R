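#' Fusion configuration
#'
#' Collects every tunable of the pipeline. Filter parameters (`radius`,
#' `ni`, `nf`, `bandwidth`) are passed to [guided_wmf()]; the remaining
#' fields control the detail-weight rule.
#'
#' @param radius filter window radius (pixels).
#' @param ni intensity bins (256 = lossless on 8-bit data).
#' @param nf guidance bins.
#' @param bandwidth affinity bandwidth on the \[0, 1\] guidance scale.
#' @param weight_mode `"auto"` (sigma-threshold switch), `"positive"`
#'   (always enhance details), `"negative"` (always attenuate), or
#'   `"fixed"` (use `fixed_k`).
#' @param sigma_threshold source-image standard deviation (0-255 scale) at
#'   which the auto rule switches branch; default 30.
#' @param radical_grouping `"grouped"` takes the square roots of the sigma
#'   *sums*, sqrt(s1+s2) and sqrt(s3+s4); `"per-term"` sums the roots,
#'   sqrt(s1)+sqrt(s2) and sqrt(s3)+sqrt(s4).
#' @param sigma_source `"extrema"`: s3, s4 are the standard deviations of
#'   the pixelwise max/min base images; `"base"`: of each source's own base
#'   layer.
#' @param fixed_k detail weight when `weight_mode = "fixed"`.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(radius = 5L, ni = 256L, nf = 32L, bandwidth = 0.1,
                          weight_mode = c("auto", "positive", "negative",
                                          "fixed"),
                          sigma_threshold = 30,
                          radical_grouping = c("grouped", "per-term"),
                          sigma_source = c("extrema", "base"),
                          fixed_k = 1) {
  weight_mode <- match.arg(weight_mode)
  radical_grouping <- match.arg(radical_grouping)
  sigma_source <- match.arg(sigma_source)
  if (sigma_threshold <= 0)
    stop("sigma_threshold must be > 0", call. = FALSE)
  if (weight_mode == "fixed" && (!is.finite(fixed_k) || fixed_k <= 0))
    stop("fixed_k must be a positive number", call. = FALSE)
  structure(list(radius = as.integer(radius), ni = as.integer(ni),
                 nf = as.integer(nf), bandwidth = bandwidth,
                 weight_mode = weight_mode,
                 sigma_threshold = sigma_threshold,
                 radical_grouping = radical_grouping,
                 sigma_source = sigma_source, fixed_k = fixed_k),
            class = "fusion_config")
}

#' Pixelwise extrema of two base layers
#'
#' @param b1,b2 base-layer matrices, same shape.
#' @return list with `bmax` and `bmin` matrices; `bmax >= bmin` everywhere
#'   and the result is invariant under swapping the inputs.
#' @export
base_extrema <- function(b1, b2) {
  check_same_shape(b1, b2, "base layers")
  list(bmax = pmax(b1, b2), bmin = pmin(b1, b2))
}

#' Fuse the two base-layer extrema by standard-deviation weighting
#'
#' The fused base is a convex combination of the pixelwise-max and
#' pixelwise-min base images: the *smaller* of the two standard deviations,
#' normalized by their sum, weights the max image and the larger weights
#' the min image. This deliberately tempers the bright extreme (Experiment
#' 1/2/3 style trade-off between washed-out brightness and dimness). When
#' both images are flat (zero deviations) the weights fall back to 1/2
#' each.
#'
#' @param bmax,bmin the [base_extrema()] images.
#' @return list with `fused` matrix and the weights `w_max`, `w_min`
#'   (always summing to 1) plus `sigma_max`, `sigma_min`.
#' @export
fuse_base <- function(bmax, bmin) {
  check_same_shape(bmax, bmin, "base extrema")
  s_max <- pop_sd(bmax)
  s_min <- pop_sd(bmin)
  tot <- s_max + s_min
  if (tot == 0) {
    w_max <- 0.5; w_min <- 0.5
  } else {
    w_max <- min(s_max, s_min) / tot
    w_min <- max(s_max, s_min) / tot
  }
  list(fused = w_max * bmax + w_min * bmin, w_max = w_max, w_min = w_min,
       sigma_max = s_max, sigma_min = s_min)
}

#' Adaptive detail-layer weight k
#'
#' The detail weight compares the information content (standard deviation)
#' of the source images against that of the fused base extrema through the
#' ratio `rho = (sqrt(s1+s2) - sqrt(s3+s4)) / sqrt(s3+s4)` (default
#' grouping; see [fusion_config()] for the per-term variant). Modes:
#' `positive` gives `k = 1 + rho` (detail enhancement), `negative`
#' `k = 1 - rho` (attenuation), and `auto` switches on the source
#' deviations: enhancement when both exceed the threshold, attenuation when
#' either falls below it, `k = 1` exactly at the boundary. When
#' `s3 + s4 = 0` (flat bases) the weight is neutral, `k = 1`.
#'
#' @param s1,s2 standard deviations of the two source images (0-255 scale).
#' @param s3,s4 standard deviations of the base max/min images.
#' @param config a [fusion_config()].
#' @return list with `k`, `rho`, and the `branch` chosen
#'   (`"positive"`, `"negative"`, `"neutral"` or `"fixed"`).
#' @export
detail_weight_k <- function(s1, s2, s3, s4, config = fusion_config()) {
  ss <- c(s1, s2, s3, s4)
  if (!all(is.finite(ss)) || any(ss < 0))
    stop("detail_weight_k: standard deviations must be finite and >= 0",
         call. = FALSE)
  if (config$weight_mode == "fixed")
    return(list(k = config$fixed_k, rho = NA_real_, branch = "fixed"))

  if (config$radical_grouping == "grouped") {
    num <- sqrt(s1 + s2); den <- sqrt(s3 + s4)
  } else {
    num <- sqrt(s1) + sqrt(s2); den <- sqrt(s3) + sqrt(s4)
  }
  rho <- if (den == 0) 0 else (num - den) / den

  sgn <- switch(config$weight_mode,
    positive = 1,
    negative = -1,
    auto = sign(min(s1, s2) - config$sigma_threshold)) # sign(0) = 0
  list(k = 1 + sgn * rho, rho = rho,
       branch = c("negative", "neutral", "positive")[sgn + 2])
}

#' Fuse two co-registered images
#'
#' The full pipeline: cross-guided clustering of both sources
#' ([cluster_base()]), bright/dark detail extraction ([detail_layers()]),
#' base fusion ([base_extrema()] + [fuse_base()]), the adaptive detail
#' weight ([detail_weight_k()]), and the recombination
#' `fused = base_fused + k (bright1 + bright2) - k (dark1 + dark2)`,
#' clamped to \[0, 255\]. Every stage is symmetric in the two inputs, so
#' `fuse_images(a, b)` and `fuse_images(b, a)` are pixel-identical.
#'
#' @param image1,image2 co-registered source images (numeric matrices,
#'   0-255 scale; see [read_image()] for file ingest).
#' @param config a [fusion_config()].
#' @return object of class `icif_fusion`: list with `fused`, the two
#'   `layer_set`s, `base` (the [fuse_base()] report), `weights` (sigma1-4,
#'   k, rho, branch), `clamp_count`, and the `config`.
#' @export
fuse_images <- function(image1, image2, config = fusion_config()) {
  image1 <- as_intensity(image1, "image1")
  image2 <- as_intensity(image2, "image2")
  check_same_shape(image1, image2)

  dec <- decompose_pair(image1, image2, config)
  l1 <- dec$layers1; l2 <- dec$layers2
  ext <- base_extrema(l1$base, l2$base)
  bf <- fuse_base(ext$bmax, ext$bmin)

  s1 <- pop_sd(image1); s2 <- pop_sd(image2)
  if (config$sigma_source == "extrema") {
    s3 <- pop_sd(ext$bmax); s4 <- pop_sd(ext$bmin)
  } else {
    s3 <- pop_sd(l1$base); s4 <- pop_sd(l2$base)
  }
  kw <- detail_weight_k(s1, s2, s3, s4, config)

  raw <- bf$fused + kw$k * (l1$bright + l2$bright) -
    kw$k * (l1$dark + l2$dark)
  fused <- clamp255(raw)
  structure(list(
    fused = fused,
    layers1 = l1, layers2 = l2,
    base = bf,
    weights = list(sigma1 = s1, sigma2 = s2, sigma3 = s3, sigma4 = s4,
                   k = kw$k, rho = kw$rho, branch = kw$branch),
    clamp_count = sum(raw < 0 | raw > 255),
    config = config), class = "icif_fusion")
}

#' @export
print.icif_fusion <- function(x, ...) {
  w <- x$weights
  cat("Fused image:", nrow(x$fused), "x", ncol(x$fused), "\n")
  cat(sprintf("  sigma1 = %.3f  sigma2 = %.3f  sigma3 = %.3f  sigma4 = %.3f\n",
              w$sigma1, w$sigma2, w$sigma3, w$sigma4))
  cat(sprintf("  detail weight k = %.4f (%s branch)\n", w$k, w$branch))
  cat(sprintf("  base weights: %.4f (max) + %.4f (min)\n",
              x$base$w_max, x$base$w_min))
  if (x$clamp_count > 0)
    cat("  clamped pixels:", x$clamp_count, "\n")
  invisible(x)
}
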