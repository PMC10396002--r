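test_that("base extrema are pixelwise and symmetric", {
  b1 <- matrix(c(1, 5), 1); b2 <- matrix(c(3, 2), 1)
  e <- base_extrema(b1, b2)
  expect_equal(e$bmax, matrix(c(3, 5), 1))
  expect_equal(e$bmin, matrix(c(1, 2), 1))
  expect_equal(base_extrema(b2, b1), e)
  expect_equal(base_extrema(b1, b1), list(bmax = b1, bmin = b1))
  expect_true(all(e$bmax >= e$bmin))
})

test_that("base fusion weights the extrema by inverted sigma shares", {
  x <- matrix(runif(16, 0, 255), 4)
  same <- fuse_base(x, x)
  expect_equal(same$fused, x)
  expect_equal(same$w_max + same$w_min, 1)
  # sigma(max image) = 5, sigma(min image) = 0: all weight on the min image
  r <- fuse_base(matrix(c(0, 10), 1), matrix(c(4, 4), 1))
  expect_equal(r$w_max, 0)
  expect_equal(r$w_min, 1)
  expect_equal(r$fused, matrix(c(4, 4), 1))
  # two constants: sigma fallback gives the midpoint
  r2 <- fuse_base(matrix(8, 2, 2), matrix(2, 2, 2))
  expect_equal(r2$fused, matrix(5, 2, 2))
  set.seed(8)
  for (rep in 1:10) {
    e <- base_extrema(matrix(runif(36, 0, 255), 6),
                      matrix(runif(36, 0, 255), 6))
    r <- fuse_base(e$bmax, e$bmin)
    expect_equal(r$w_max + r$w_min, 1)
    expect_lte(r$w_max, r$w_min) # the flatter image always dominates
  }
})

test_that("adaptive detail weight reproduces the closed-form branch values", {
  # balanced information: neutral weight in every mode
  for (m in c("auto", "positive", "negative"))
    expect_equal(detail_weight_k(20, 20, 20, 20,
                                 fusion_config(weight_mode = m))$k, 1)
  # both sources above threshold: enhancement branch
  k1 <- detail_weight_k(55.83, 54.64, 53.83, 52.83)
  expect_equal(k1$k, sqrt((55.83 + 54.64) / (53.83 + 52.83)),
               tolerance = 1e-12)
  expect_lt(abs(k1$k - 1.0177), 1e-3)
  expect_equal(k1$branch, "positive")
  # one source below threshold: attenuation branch
  k2 <- detail_weight_k(20.45, 30.32, 14.59, 0.32)
  expect_equal(k2$k, 2 - sqrt((20.45 + 30.32) / (14.59 + 0.32)),
               tolerance = 1e-12)
  expect_lt(abs(k2$k - 0.155), 1e-3)
  expect_equal(k2$branch, "negative")
  # flat bases: neutral
  expect_equal(detail_weight_k(10, 10, 0, 0)$k, 1)
  # boundary sigma = threshold: sign term defined as 0
  expect_equal(detail_weight_k(30, 45, 20, 10)$k, 1)
  expect_error(detail_weight_k(-1, 2, 3, 4), "finite")
})

test_that("(k - 1) flips sign exactly at the sigma threshold", {
  s3 <- 25; s4 <- 20 # fixed base information, rho > 0 throughout
  for (s in c(10, 20, 29.9)) {
    k <- detail_weight_k(s, 60, s3, s4)$k
    expect_lt(k, 1)
  }
  for (s in c(30.1, 40, 80)) {
    k <- detail_weight_k(s, 60, s3, s4)$k
    expect_gt(k, 1)
  }
})

test_that("per-term radical grouping is a distinct, selectable variant", {
  cfg <- fusion_config(radical_grouping = "per-term",
                       weight_mode = "positive")
  k <- detail_weight_k(16, 9, 4, 1, cfg)$k
  expect_equal(k, 1 + ((4 + 3) - (2 + 1)) / (2 + 1))
  kg <- detail_weight_k(16, 9, 4, 1,
                        fusion_config(weight_mode = "positive"))$k
  expect_equal(kg, sqrt(25 / 5))
  expect_false(isTRUE(all.equal(k, kg)))
})

test_that("fusing two constants returns their midpoint", {
  f <- fuse_images(matrix(40, 8, 8), matrix(100, 8, 8),
                   fusion_config(radius = 2))
  expect_equal(f$fused, matrix(70, 8, 8))
  expect_equal(f$weights$k, 1)
})

test_that("full fusion is pixel-exactly symmetric under input swap", {
  p <- make_pair(synth_params(seed = 17, size = c(32, 32)))
  cfg <- fusion_config(radius = 2)
  f1 <- fuse_images(p$modA, p$modB, cfg)
  f2 <- fuse_images(p$modB, p$modA, cfg)
  expect_identical(f1$fused, f2$fused)
  expect_equal(f1$weights$k, f2$weights$k)
})

test_that("clipped detail layers give the same result as raw residuals", {
  # since one k multiplies both detail sums, base + k(bright - dark) equals
  # base + k(I - IC(I)) without any clipping
  p <- make_pair(synth_params(seed = 23, size = c(32, 32)))
  cfg <- fusion_config(radius = 2)
  f <- fuse_images(p$modA, p$modB, cfg)
  b1 <- f$layers1$base; b2 <- f$layers2$base
  k <- f$weights$k
  unclipped <- f$base$fused + k * ((p$modA - b1) + (p$modB - b2))
  expect_equal(icif:::clamp255(unclipped), f$fused)
})

test_that("fused output stays on the 0-255 scale and reports clamping", {
  p <- make_pair(synth_params(seed = 29, size = c(32, 32),
                              target_contrast = 200))
  f <- fuse_images(p$modA, p$modB, fusion_config(radius = 2))
  expect_true(all(f$fused >= 0 & f$fused <= 255))
  expect_true(f$clamp_count >= 0)
  expect_error(fuse_images(p$modA, p$modB[1:16, 1:16]), "dimensions")
})

test_that("identical inputs fuse to base + 2k (bright - dark) of one source", {
  p <- make_pair(synth_params(seed = 31, size = c(24, 24)))
  cfg <- fusion_config(radius = 2)
  f <- fuse_images(p$modA, p$modA, cfg)
  l <- detail_layers(p$modA, cluster_base(p$modA, p$modA, cfg))
  k <- f$weights$k
  expect_equal(f$fused,
               icif:::clamp255(l$base + 2 * k * (l$bright - l$dark)))
})
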