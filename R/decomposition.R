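#' Cross-modal guidance map
#'
#' The guidance used to cluster one modality is built from the *other*
#' modality: the partner image is normalized from the 0-255 scale to
#' \[0, 1\] and halved, giving a feature map in \[0, 0.5\]. Filtering image
#' A with guidance derived from image B (and vice versa) is what couples
#' the two decompositions and makes the extracted layers mutually
#' consistent.
#'
#' @param other the partner modality image (0-255 numeric matrix).
#' @return guidance matrix in \[0, 0.5\].
#' @export
guidance_map <- function(other) {
  other <- as_intensity(other, "guidance source")
  0.5 * (other / 255)
}

#' Clustered base layer of one source image
#'
#' The base layer IC(I) is the guided weighted median filter of `I` with
#' guidance built from the partner modality via [guidance_map()]. It keeps
#' large-scale structure shared with the partner and smooths away
#' modality-specific fine texture.
#'
#' @param image source image to cluster (0-255 numeric matrix).
#' @param other partner modality image, same shape.
#' @param config a [fusion_config()].
#' @param mode filter backend, see [guided_wmf()].
#' @return base-layer matrix, same shape as `image`.
#' @export
cluster_base <- function(image, other, config = fusion_config(),
                         mode = "accelerated") {
  image <- as_intensity(image)
  other <- as_intensity(other, "partner image")
  check_same_shape(image, other)
  guided_wmf(image, guidance_map(other),
             radius = config$radius, ni = config$ni, nf = config$nf,
             bandwidth = config$bandwidth, mode = mode)
}

#' Split a source image into bright and dark detail layers
#'
#' The bright detail layer is the positive part of `image - base`, the dark
#' detail layer the positive part of `base - image`. Both are nonnegative
#' with disjoint support, and `base + bright - dark` reconstructs the
#' source exactly.
#'
#' @param image source image.
#' @param base its base layer (e.g. from [cluster_base()]), same shape.
#' @return object of class `layer_set`: list with `base`, `bright`, `dark`.
#' @export
detail_layers <- function(image, base) {
  image <- as_intensity(image)
  check_same_shape(image, base, "image and base")
  d <- image - base
  structure(list(base = base, bright = pmax(d, 0), dark = pmax(-d, 0)),
            class = "layer_set")
}

#' Decompose a co-registered pair into cross-guided layer sets
#'
#' Runs [cluster_base()] both ways (each image guided by the other) and
#' splits each source with [detail_layers()].
#'
#' @param image1,image2 the two co-registered source images.
#' @param config a [fusion_config()].
#' @return list with `layers1`, `layers2` (each a `layer_set`).
#' @export
decompose_pair <- function(image1, image2, config = fusion_config()) {
  image1 <- as_intensity(image1, "image1")
  image2 <- as_intensity(image2, "image2")
  check_same_shape(image1, image2)
  b1 <- cluster_base(image1, image2, config)
  b2 <- cluster_base(image2, image1, config)
  list(layers1 = detail_layers(image1, b1),
       layers2 = detail_layers(image2, b2))
}
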