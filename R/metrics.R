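# Single-image quality metrics and source-pair-vs-fused gradient
# preservation scores. All operate on 0-255 numeric matrices.

#' Average gradient
#'
#' Mean over interior pixels of `sqrt((dx^2 + dy^2) / 2)`, with forward
#' differences `dx` (horizontal) and `dy` (vertical). Larger values mean
#' more small-detail contrast.
#'
#' @param image numeric matrix (0-255 scale).
#' @return nonnegative scalar.
#' @export
average_gradient <- function(image) {
  image <- as_intensity(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 2 || w < 2) {
    warning("average_gradient: degenerate image, returning 0")
    return(0)
  }
  dx <- image[seq_len(h - 1), seq_len(w - 1) + 1] -
        image[seq_len(h - 1), seq_len(w - 1)]
  dy <- image[seq_len(h - 1) + 1, seq_len(w - 1)] -
        image[seq_len(h - 1), seq_len(w - 1)]
  mean(sqrt((dx^2 + dy^2) / 2))
}

#' Shannon entropy of the intensity histogram (bits)
#'
#' Entropy of the 256-bin intensity histogram, log base 2, with
#' `0 log 0 := 0`. At most 8 bits for 8-bit data, attained only by a
#' perfectly uniform histogram.
#'
#' @inheritParams average_gradient
#' @return scalar in \[0, 8\].
#' @export
img_entropy <- function(image) {
  image <- as_intensity(image)
  b <- intensity_bin(image, 256L)
  p <- tabulate(b + 1L, nbins = 256L) / length(b)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Standard deviation of an image
#'
#' Population convention (divisor n), on the 0-255 scale -- the same
#' convention the fusion weight rule uses.
#'
#' @inheritParams average_gradient
#' @return nonnegative scalar.
#' @export
std_dev <- function(image) {
  pop_sd(as_intensity(image))
}

#' Spatial frequency
#'
#' `SF = sqrt(RF^2 + CF^2)` where RF is the root-mean-square of horizontal
#' neighbor differences and CF of vertical ones.
#'
#' @inheritParams average_gradient
#' @return nonnegative scalar.
#' @export
spatial_frequency <- function(image) {
  image <- as_intensity(image)
  h <- nrow(image); w <- ncol(image)
  if (h < 2 || w < 2) return(0)
  rf2 <- mean((image[, 2:w] - image[, 2:w - 1])^2)
  cf2 <- mean((image[2:h, ] - image[2:h - 1, ])^2)
  sqrt(rf2 + cf2)
}

# 3x3 correlation with reflect padding (matrix kernel, centered)
conv3_reflect <- function(image, kern) {
  h <- nrow(image); w <- ncol(image)
  ri <- c(1L, seq_len(h), h) # reflect-pad index maps
  ci <- c(1L, seq_len(w), w)
  pad <- image[ri, ci]
  out <- matrix(0, h, w)
  for (a in 1:3) for (b in 1:3) {
    k <- kern[a, b]
    if (k != 0)
      out <- out + k * pad[(a - 1) + seq_len(h), (b - 1) + seq_len(w)]
  }
  out
}

sobel_xy <- function(image) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) # d/dx (columns)
  ky <- t(kx)                                          # d/dy (rows)
  list(sx = conv3_reflect(image, kx), sy = conv3_reflect(image, ky))
}

#' Edge intensity
#'
#' Mean Sobel gradient magnitude `sqrt(sx^2 + sy^2)` over all pixels, with
#' reflect padding at the border. Larger values indicate sharper edges.
#'
#' @inheritParams average_gradient
#' @return nonnegative scalar.
#' @export
edge_intensity <- function(image) {
  image <- as_intensity(image)
  if (nrow(image) < 3 || ncol(image) < 3)
    stop("edge_intensity: image must be at least 3x3", call. = FALSE)
  s <- sobel_xy(image)
  mean(sqrt(s$sx^2 + s$sy^2))
}

#' Gradient-preservation fusion scores Q, L, N
#'
#' Pixelwise Sobel gradient strength and orientation are extracted from the
#' two sources A, B and the fused image F. For each source the relative
#' strength preservation `G` (ratio of the weaker to the stronger gradient)
#' and the orientation preservation `A = 1 - |alpha_src - alpha_F|/(pi/2)`
#' are mapped through sigmoids `Gamma / (1 + exp(kappa (x - sigma)))` and
#' multiplied into a per-pixel preservation score. `q_abf` is the
#' edge-strength-weighted mean preservation over both sources; `l_abf`
#' accumulates the unpreserved fraction at pixels where the fused gradient
#' is weaker than a source's; `n_abf` accumulates it where the fused
#' gradient exceeds both sources (fusion artifacts). Q and L lie in
#' \[0, 1\]; N is only bounded below by 0.
#'
#' @param a,b source images (numeric matrices, 0-255).
#' @param f fused image, same shape.
#' @param constants sigmoid model constants; override individual entries to
#'   recalibrate.
#' @return list with `q_abf`, `l_abf`, `n_abf`.
#' @export
petrovic_scores <- function(a, b, f,
                            constants = list(gamma_g = 0.9994, kappa_g = -15,
                                             sigma_g = 0.5,
                                             gamma_a = 0.9879, kappa_a = -22,
                                             sigma_a = 0.8)) {
  a <- as_intensity(a, "a"); b <- as_intensity(b, "b")
  f <- as_intensity(f, "f")
  check_same_shape(a, f, "source and fused images")
  check_same_shape(b, f, "source and fused images")

  grad <- function(im) {
    s <- sobel_xy(im)
    g <- sqrt(s$sx^2 + s$sy^2)
    alpha <- atan2(s$sy, s$sx)
    # fold orientation into (-pi/2, pi/2]: edge orientation, not direction
    alpha <- ifelse(alpha > pi / 2, alpha - pi, alpha)
    alpha <- ifelse(alpha <= -pi / 2, alpha + pi, alpha)
    list(g = g, alpha = alpha)
  }
  ga <- grad(a); gb <- grad(b); gf <- grad(f)

  preserve <- function(src, fus) {
    # strength preservation: weaker over stronger gradient; 0 if both flat
    gr <- ifelse(src$g > fus$g,
                 ifelse(src$g > 0, fus$g / src$g, 0),
                 ifelse(fus$g > 0, src$g / fus$g, 0))
    da <- abs(src$alpha - fus$alpha)
    da <- pmin(da, pi - da) # angular distance between orientations
    ar <- 1 - da / (pi / 2)
    qg <- constants$gamma_g / (1 + exp(constants$kappa_g *
                                         (gr - constants$sigma_g)))
    qa <- constants$gamma_a / (1 + exp(constants$kappa_a *
                                         (ar - constants$sigma_a)))
    qg * qa
  }
  qaf <- preserve(ga, gf)
  qbf <- preserve(gb, gf)

  wa <- ga$g
  wb <- gb$g
  tot <- sum(wa + wb)
  if (tot == 0) return(list(q_abf = 0, l_abf = 0, n_abf = 0))

  loss_a <- gf$g < ga$g | gf$g < gb$g # fused gradient weaker than a source
  artif  <- gf$g > ga$g & gf$g > gb$g # fused gradient exceeds both sources

  q <- sum(qaf * wa + qbf * wb) / tot
  l <- sum(((1 - qaf) * wa + (1 - qbf) * wb) * loss_a) / tot
  n <- sum(((1 - qaf) * wa + (1 - qbf) * wb) * artif) / tot
  list(q_abf = q, l_abf = l, n_abf = n)
}

#' Metric report for a fusion result
#'
#' Computes the single-image metrics of the fused image plus the
#' gradient-preservation triple against the two sources, as a one-row
#' data.frame ready for TSV/JSON export.
#'
#' @inheritParams petrovic_scores
#' @param name row label.
#' @return one-row data.frame with columns `ag`, `h`, `sd`, `sf`, `ei`,
#'   `q_abf`, `l_abf`, `n_abf`.
#' @export
metric_report <- function(a, b, f, name = "pair") {
  p <- petrovic_scores(a, b, f)
  data.frame(name = name,
             ag = average_gradient(f), h = img_entropy(f),
             sd = std_dev(f), sf = spatial_frequency(f),
             ei = edge_intensity(f),
             q_abf = p$q_abf, l_abf = p$l_abf, n_abf = p$n_abf,
             stringsAsFactors = FALSE)
}

#' Write a metric report as JSON and/or TSV
#'
#' @param report a [metric_report()] data.frame (one row per pair).
#' @param json,tsv output paths (NULL to skip either).
#' @return the report, invisibly.
#' @export
write_metric_report <- function(report, json = NULL, tsv = NULL) {
  if (!is.null(json))
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(tsv))
    write.table(report, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}
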