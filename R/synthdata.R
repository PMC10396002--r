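# Deterministic generator of co-registered two-modality test scenes:
# a shared piecewise-smooth structure (posterized smoothed noise) rendered
# once with rich texture ("visible"-like) and once flattened with bright
# blob targets ("thermal"-like).

#' Parameters for the synthetic pair generator
#'
#' @param seed integer seed; the same parameters always produce the
#'   identical pair (one seeded stream, no global RNG state leaked).
#' @param size `c(height, width)` in pixels.
#' @param n_blobs number of bright "thermal" targets (>= 0).
#' @param texture_preset `"high"` renders both modalities with standard
#'   deviation above 30 on the 0-255 scale, `"low"` keeps both below 30 --
#'   the two regimes of the adaptive detail-weight rule.
#' @param target_contrast intensity added at target blobs in modality B
#'   (0-255 scale).
#' @param noise_sd additive Gaussian sensor noise, 0-255 scale.
#' @return object of class `synth_params`.
#' @export
synth_params <- function(seed = 1L, size = c(96L, 96L), n_blobs = 3L,
                         texture_preset = c("high", "low"),
                         target_contrast = 120, noise_sd = 2) {
  texture_preset <- match.arg(texture_preset)
  if (any(size < 1)) stop("zero-sized image", call. = FALSE)
  if (n_blobs < 0) stop("n_blobs must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_blobs = as.integer(n_blobs),
                 texture_preset = texture_preset,
                 target_contrast = target_contrast, noise_sd = noise_sd),
            class = "synth_params")
}

# separable Gaussian blur, replicate padding, used only by the generator
gauss_blur <- function(x, sigma) {
  t <- -ceiling(3 * sigma):ceiling(3 * sigma)
  k <- exp(-t^2 / (2 * sigma^2))
  k <- k / sum(k)
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, h, w)
  for (s in seq_along(t)) # rows
    out <- out + k[s] * x[pmin(pmax(seq_len(h) + t[s], 1L), h), ]
  x2 <- matrix(0, h, w)
  for (s in seq_along(t)) # columns
    x2 <- x2 + k[s] * out[, pmin(pmax(seq_len(w) + t[s], 1L), w)]
  x2
}

norm01 <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) return(x * 0)
  (x - r[1]) / (r[2] - r[1])
}

#' Generate a co-registered two-modality synthetic pair
#'
#' The shared scene is a posterized smoothed-noise field (piecewise-smooth
#' regions with common boundaries in both modalities). Modality A adds
#' fine-grained texture on top of the structure (visible-like); modality B
#' renders the structure with flattened contrast and adds bright Gaussian
#' blobs at `n_blobs` seeded locations (thermal-like targets), thresholded
#' into a binary target mask. Both receive additive Gaussian noise.
#'
#' @param params a [synth_params()] object.
#' @return object of class `synth_pair`: list with matrices `modA`, `modB`
#'   (0-255), binary `target_mask`, and `params`.
#' @export
make_pair <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  h <- params$size[1]; w <- params$size[2]

  # intensity spreads per preset: structure contrast chosen so that the
  # source standard deviation lands clearly on the intended side of the
  # sigma = 30 branch threshold in both modalities
  pr <- if (params$texture_preset == "high")
    list(aLo = 15, aHi = 150, bLo = 40, bHi = 170, texA = 14, texB = 5)
  else
    list(aLo = 105, aHi = 165, bLo = 112, bHi = 152, texA = 5, texB = 2)

  withr::with_seed(params$seed, {
    # shared piecewise-smooth structure: smoothed noise, rank-flattened to
    # equal-mass levels (so every posterized level is equally occupied and
    # the structure contrast is stable across seeds), then posterized
    field <- gauss_blur(matrix(rnorm(h * w), h, w),
                        sigma = max(2, min(h, w) / 16))
    u <- matrix((rank(field) - 0.5) / length(field), h, w)
    levels <- 5
    structure01 <- pmin(floor(u * levels), levels - 1) / (levels - 1)

    # fine texture layers (modality-specific)
    texA <- gauss_blur(matrix(rnorm(h * w), h, w), sigma = 0.8)
    texB <- gauss_blur(matrix(rnorm(h * w), h, w), sigma = 1.5)

    modA <- pr$aLo + (pr$aHi - pr$aLo) * structure01 + pr$texA * texA
    modB <- pr$bLo + (pr$bHi - pr$bLo) * structure01 + pr$texB * texB

    # bright thermal targets: small Gaussian hot spots (radius well below
    # the default filter window, as for distant people/vehicles in thermal
    # imagery) whose peak sits `target_contrast` above the brightest
    # structure level; mask by thresholding the bump field at half
    # prominence
    mask <- matrix(FALSE, h, w)
    if (params$n_blobs > 0) {
      bump <- matrix(0, h, w)
      rad <- max(2, round(min(h, w) / 32))
      ci <- runif(params$n_blobs, 0.15, 0.85) * h
      cj <- runif(params$n_blobs, 0.15, 0.85) * w
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      for (t in seq_len(params$n_blobs)) {
        d2 <- (rows - ci[t])^2 + (cols - cj[t])^2
        bump <- pmax(bump, exp(-d2 / (2 * rad^2)))
      }
      # flat-top hot spots: fully hot inside the mask, soft halo outside
      mask <- bump > 0.6
      modB <- pmax(modB,
                   (pr$bHi + params$target_contrast) * pmin(1, 2 * bump))
    }

    if (params$noise_sd > 0) {
      modA <- modA + rnorm(h * w, sd = params$noise_sd)
      modB <- modB + rnorm(h * w, sd = params$noise_sd)
    }

    structure(list(modA = clamp255(modA), modB = clamp255(modB),
                   target_mask = mask, params = params),
              class = "synth_pair")
  })
}
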