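#' Guidance affinity weight
#'
#' Influence of a window pixel on the center pixel, computed from their
#' guidance-map values: `exp(-|fp - fq| / bandwidth)`. Symmetric, equal to 1
#' exactly when the two guidance values coincide, and strictly decreasing in
#' their absolute difference. The `bandwidth` sets the guidance-contrast
#' scale over which influence decays (guidance lives in \[0, 1\], so the
#' default 0.1 used by [guided_wmf()] means "a tenth of full scale").
#'
#' @param fp,fq guidance values in \[0, 1\].
#' @param bandwidth positive decay scale.
#' @return weight in (0, 1].
#' @export
#' @examples
#' affinity_weight(0.5, 0.5, 0.1) # 1
#' affinity_weight(0, 1, 1)       # exp(-1)
affinity_weight <- function(fp, fq, bandwidth) {
  if (!all(is.finite(fp)) || !all(is.finite(fq)) || !is.finite(bandwidth))
    stop("affinity_weight: non-finite input", call. = FALSE)
  if (bandwidth <= 0)
    stop("affinity_weight: bandwidth must be > 0", call. = FALSE)
  exp(-abs(fp - fq) / bandwidth)
}

#' Weighted median of a set of intensities
#'
#' Sorts the (value, weight) pairs by ascending value and returns the
#' smallest value whose cumulative weight reaches half the total weight
#' (the "minimum k" rule). The result is always one of the input values.
#'
#' @param values numeric vector of intensities.
#' @param weights positive weights, same length.
#' @return one element of `values`.
#' @export
#' @examples
#' weighted_median(c(1, 2, 3), c(1, 1, 1)) # 2
#' weighted_median(c(1, 2, 9), c(3, 1, 1)) # 1
weighted_median <- function(values, weights) {
  if (length(values) == 0L)
    stop("weighted_median: empty input", call. = FALSE)
  if (length(values) != length(weights))
    stop("weighted_median: values and weights must have equal length",
         call. = FALSE)
  if (!all(is.finite(values)) || !all(is.finite(weights)) ||
      any(weights <= 0))
    stop("weighted_median: weights must be finite and positive",
         call. = FALSE)
  ord <- order(values)
  cw <- cumsum(weights[ord])
  k <- which(cw >= cw[length(cw)] / 2)[1L]
  values[ord][k]
}

#' Joint histogram of one filter window
#'
#' Counts window pixels over (intensity bin, guidance bin) cells: intensity
#' is quantized into `ni` equal bins on \[0, 255\], guidance into `nf` equal
#' bins on \[0, 1\]. Out-of-range values are clamped into the edge bins.
#' The histogram is what lets the filter evaluate all per-intensity weight
#' sums without touching individual pixels again.
#'
#' @param intensities numeric vector of window pixel intensities (0-255).
#' @param guidance numeric vector of window guidance values (\[0, 1\]).
#' @param ni,nf number of intensity / guidance bins (>= 1).
#' @return object of class `joint_histogram`: list with `counts` (ni x nf
#'   integer matrix), `ni`, `nf`, and total pixel count `n`.
#' @export
build_joint_histogram <- function(intensities, guidance, ni = 256L,
                                  nf = 32L) {
  if (length(intensities) != length(guidance))
    stop("build_joint_histogram: pixel lists must have equal length",
         call. = FALSE)
  if (ni < 1 || nf < 1)
    stop("build_joint_histogram: bin counts must be >= 1", call. = FALSE)
  ib <- intensity_bin(intensities, ni)
  fb <- guidance_bin(guidance, nf)
  counts <- matrix(0L, ni, nf)
  for (q in seq_along(ib))
    counts[ib[q] + 1L, fb[q] + 1L] <- counts[ib[q] + 1L, fb[q] + 1L] + 1L
  structure(list(counts = counts, ni = as.integer(ni), nf = as.integer(nf),
                 n = length(ib)),
            class = "joint_histogram")
}

#' Weighted count of one intensity bin of a joint histogram
#'
#' Collapses histogram row `i` against the affinity between each guidance
#' bin center and the window center's guidance value: `W_i = sum_f H(i, f)
#' g(f_f, f(p))`. With all affinities equal to 1 this is the plain count of
#' pixels in intensity bin `i`.
#'
#' @param hist a [build_joint_histogram()] result.
#' @param i 0-based intensity bin index.
#' @param center_guidance guidance value of the window center (\[0, 1\]).
#' @param bandwidth affinity bandwidth.
#' @return nonnegative scalar weight sum.
#' @export
column_weight_sum <- function(hist, i, center_guidance, bandwidth) {
  stopifnot(inherits(hist, "joint_histogram"))
  if (i < 0 || i >= hist$ni)
    stop("column_weight_sum: intensity bin out of range", call. = FALSE)
  g <- column_weights(hist$nf, center_guidance, bandwidth)
  sum(hist$counts[i + 1L, ] * g)
}

# affinity of every guidance bin center against the center pixel's bin
# center, through the same dyadic-quantized table the filter uses
column_weights <- function(nf, center_guidance, bandwidth) {
  fp <- guidance_bin(center_guidance, nf)
  gtab <- wmf_weight_table(nf, bandwidth)
  gtab[abs(seq_len(nf) - 1L - fp) + 1L]
}

#' Balance of a joint histogram at a cut point
#'
#' The balance `b` at cut `c` is the weighted count of window pixels with
#' intensity bin <= c minus the weighted count with intensity bin > c. The
#' weighted median bin is the smallest cut with `b >= 0`; the accelerated
#' filter maintains this quantity incrementally (the "balance counting
#' box") instead of recomputing it per pixel.
#'
#' @inheritParams column_weight_sum
#' @param cut 0-based intensity bin index.
#' @return object of class `balance_state`: list with `cut` and `balance`.
#' @export
balance_at_cut <- function(hist, cut, center_guidance, bandwidth) {
  stopifnot(inherits(hist, "joint_histogram"))
  if (cut < 0 || cut >= hist$ni)
    stop("balance_at_cut: cut out of range", call. = FALSE)
  g <- column_weights(hist$nf, center_guidance, bandwidth)
  bcb <- colSums(hist$counts[seq_len(cut + 1L), , drop = FALSE]) -
    colSums(hist$counts[-seq_len(cut + 1L), , drop = FALSE])
  structure(list(cut = as.integer(cut), balance = sum(bcb * g)),
            class = "balance_state")
}

#' Guided weighted median filter ("information clustering")
#'
#' Replaces every pixel by the weighted median of its (2r+1) x (2r+1)
#' window, with each window pixel weighted by its guidance-map affinity to
#' the window center ([affinity_weight()] evaluated on guidance bin
#' centers). Smoothing is therefore edge-aware with respect to the
#' *guidance* image: structure present in the guidance survives, structure
#' absent from it is flattened. Windows are truncated at the image border,
#' so no synthetic pixel values are introduced and every output value is
#' one of the window's input values.
#'
#' Two backends compute the identical result: `naive` evaluates the
#' weighted median per window from scratch (reference), `accelerated`
#' maintains a sliding joint histogram with balance-counting-box cut
#' propagation and a necklace table over occupied guidance bins.
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param guidance numeric matrix in \[0, 1\], same shape.
#' @param radius window radius in pixels (>= 1; window is (2r+1)^2).
#' @param ni number of intensity bins (256 is lossless for 8-bit data).
#' @param nf number of guidance bins.
#' @param bandwidth affinity bandwidth on the \[0, 1\] guidance scale.
#' @param mode `"accelerated"` (default) or `"naive"`.
#' @return filtered matrix, same shape, values drawn from `image`.
#' @export
guided_wmf <- function(image, guidance, radius = 5L, ni = 256L, nf = 32L,
                       bandwidth = 0.1,
                       mode = c("accelerated", "naive")) {
  mode <- match.arg(mode)
  image <- as_intensity(image)
  if (!is.matrix(guidance) || !all(is.finite(guidance)))
    stop("guidance must be a finite numeric matrix", call. = FALSE)
  check_same_shape(image, guidance, "image and guidance")
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  ni <- as.integer(ni); nf <- as.integer(nf)

  ibin <- matrix(as.integer(intensity_bin(image, ni)), nrow(image))
  fbin <- matrix(as.integer(guidance_bin(guidance, nf)), nrow(image))
  gtab <- wmf_weight_table(nf, bandwidth)

  if (mode == "accelerated")
    .guided_wmf_accel_cpp(image, ibin, fbin, as.integer(radius), ni, nf,
                          gtab)
  else
    guided_wmf_naive(image, ibin, fbin, as.integer(radius), ni, gtab)
}

# brute-force reference: per-window ascending sort + cumulative weights
guided_wmf_naive <- function(image, ibin, fbin, radius, ni, gtab) {
  h <- nrow(image); w <- ncol(image)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    rr <- max(1L, i - radius):min(h, i + radius)
    for (j in seq_len(w)) {
      cc <- max(1L, j - radius):min(w, j + radius)
      vals <- image[rr, cc]
      ib <- ibin[rr, cc]
      wq <- gtab[abs(fbin[rr, cc] - fbin[i, j]) + 1L]
      ord <- order(vals)
      cw <- cumsum(wq[ord])
      k <- which(cw >= cw[length(cw)] / 2)[1L]
      cut <- ib[ord][k]
      sel <- sort(vals[ib == cut])
      out[i, j] <- sel[ceiling(length(sel) / 2)]
    }
  }
  out
}
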