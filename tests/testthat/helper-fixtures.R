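# Analytic fixtures and independent oracles used across the suite.

# random 8-bit image and guidance pair
rand_pair <- function(h, w) {
  list(img = matrix(as.numeric(sample(0:255, h * w, TRUE)), h),
       guid = matrix(runif(h * w), h))
}

ramp_image <- function(h = 8, w = 8) {
  matrix(rep(seq_len(w) - 1, each = h), h) # I(i, j) = j - 1
}

step_image <- function(h = 8, w = 8, at = w %/% 2) {
  matrix(rep(c(rep(0, at), rep(255, w - at)), each = h), h, w, byrow = FALSE)
}

checkerboard_image <- function(h = 8, w = 8) {
  255 * outer(seq_len(h), seq_len(w), function(i, j) (i + j) %% 2)
}

# independent oracle: plain (unweighted) median filter with truncated
# windows and the lower-median tie rule
plain_median_filter <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    win <- img[max(1, i - radius):min(h, i + radius),
               max(1, j - radius):min(w, j + radius)]
    out[i, j] <- sort(win)[ceiling(length(win) / 2)]
  }
  out
}
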