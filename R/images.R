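#' @useDynLib icif, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd
#' @importFrom utils write.table
NULL

# All images in this package are plain numeric matrices on a fixed 0-255
# scale (the sigma = 30 fusion threshold and the paper-style metric values
# only make sense on 8-bit scale); guidance maps are matrices in [0, 1].

#' Coerce and validate an intensity image
#'
#' Accepts a numeric matrix, checks finiteness, and clamps to the canonical
#' 0-255 intensity scale. All pipeline functions call this on ingest.
#'
#' @param x numeric matrix.
#' @param name label used in error messages.
#' @return numeric matrix with values in \[0, 255\].
#' @export
as_intensity <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop(name, " contains non-finite values", call. = FALSE)
  pmin(pmax(x, 0), 255)
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop(what, " must have identical dimensions (",
         paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"), ")", call. = FALSE)
  invisible(TRUE)
}

# 0-based intensity bin over [0, 255] split into ni equal bins
intensity_bin <- function(v, ni) {
  b <- floor(v * ni / 256)
  pmin(pmax(b, 0), ni - 1)
}

# 0-based guidance bin over [0, 1] split into nf equal bins
guidance_bin <- function(g, nf) {
  b <- floor(g * nf)
  pmin(pmax(b, 0), nf - 1)
}

# center of guidance bin f (weights are evaluated on bin centers; required
# by the joint-histogram factorization of the weight sum)
guidance_bin_center <- function(f, nf) (f + 0.5) / nf

# Affinity weight lookup table by guidance-bin distance d = 0..nf-1.
# Values are quantized to multiples of 2^-30 so that every window sum the
# filter forms (at most (2r+1)^2 * 2^30 < 2^53 units) is exact in double
# arithmetic in any accumulation order -- this is what makes the naive and
# accelerated backends agree pixel-exactly, ties included.  Quantization
# error is < 1e-9; zero-rounded weights are floored at 2^-30 to stay
# positive.
wmf_weight_table <- function(nf, bandwidth) {
  w <- exp(-((0:(nf - 1)) / nf) / bandwidth)
  pmax(round(w * 2^30), 1) / 2^30
}

# population standard deviation (divisor n, not n-1): the convention behind
# the sigma = 30 threshold and the base-fusion weights
pop_sd <- function(x) {
  mu <- mean(x)
  sqrt(mean((x - mu)^2))
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)
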