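test_that("affinity weight is the symmetric exponential of the guidance gap", {
  expect_equal(affinity_weight(0.5, 0.5, 0.3), 1)
  expect_equal(affinity_weight(0, 1, 1), exp(-1), tolerance = 1e-12)
  expect_equal(affinity_weight(0.2, 0.7, 0.1), affinity_weight(0.7, 0.2, 0.1))
  # strictly decreasing in the gap
  expect_gt(affinity_weight(0.3, 0.5, 0.1), affinity_weight(0.3, 0.9, 0.1))
  expect_error(affinity_weight(0.1, 0.2, 0), "bandwidth")
  expect_error(affinity_weight(NA_real_, 0.2, 1), "non-finite")
})

test_that("weighted median follows the minimum-k cumulative rule", {
  expect_equal(weighted_median(c(1, 2, 3), c(1, 1, 1)), 2)
  expect_equal(weighted_median(c(1, 2, 9), c(3, 1, 1)), 1) # 3 >= 5/2
  expect_equal(weighted_median(5, 2.5), 5)
  # order of presentation is irrelevant
  expect_equal(weighted_median(c(9, 1, 2), c(1, 3, 1)), 1)
  expect_error(weighted_median(numeric(0), numeric(0)), "empty")
  expect_error(weighted_median(c(1, 2), c(1, -1)), "positive")
  # membership: result is always one of the inputs
  set.seed(11)
  for (rep in 1:25) {
    v <- runif(7, 0, 255); w <- runif(7, 0.1, 2)
    expect_true(weighted_median(v, w) %in% v)
  }
})

test_that("joint histogram counts and conserves window pixels", {
  h1 <- build_joint_histogram(100, 0.4, ni = 256, nf = 8)
  expect_equal(sum(h1$counts), 1)
  expect_equal(h1$counts[101, 4], 1) # bin 100, guidance bin floor(.4*8)=3
  h4 <- build_joint_histogram(rep(10, 4), rep(0.9, 4), ni = 16, nf = 4)
  expect_equal(max(h4$counts), 4)
  expect_equal(sum(h4$counts), 4)
  set.seed(3)
  v <- sample(0:255, 49, TRUE); g <- runif(49)
  hh <- build_joint_histogram(v, g, ni = 64, nf = 16)
  expect_equal(sum(hh$counts), 49)
  expect_true(all(hh$counts >= 0))
  # out-of-range values clamp to edge bins rather than erroring
  hc <- build_joint_histogram(c(-5, 300), c(-0.2, 1.4), ni = 16, nf = 4)
  expect_equal(hc$counts[1, 1], 1)
  expect_equal(hc$counts[16, 4], 1)
})

test_that("column weight sum collapses a histogram row against affinities", {
  # two pixels at guidance-bin 0, one at bin 1, all intensity bin 1;
  # bandwidth chosen so neighboring-bin affinity is exactly 1/2
  nf <- 2
  bw <- (1 / nf) / log(2)
  hist <- build_joint_histogram(c(1, 1, 1), c(0.1, 0.1, 0.6),
                                ni = 256, nf = nf)
  w1 <- column_weight_sum(hist, 1, center_guidance = 0.1, bandwidth = bw)
  expect_equal(w1, 2 * 1 + 1 * 0.5)
  expect_equal(column_weight_sum(hist, 2, 0.1, bw), 0) # empty row
  # constant guidance: weight sum is the plain per-bin count
  hcg <- build_joint_histogram(c(5, 5, 9), rep(0.5, 3), ni = 256, nf = 8)
  expect_equal(column_weight_sum(hcg, 5, 0.5, 0.1), 2)
})

test_that("balance at a cut is the weighted left-minus-right count", {
  hist <- build_joint_histogram(c(1, 2, 3), rep(0.5, 3), ni = 256, nf = 1)
  b <- balance_at_cut(hist, 2, 0.5, 0.1)
  expect_equal(b$balance, 2 - 1) # {1,2} left of cut 2, {3} right
  expect_equal(balance_at_cut(hist, 255, 0.5, 0.1)$balance, 3) # all left
  expect_equal(balance_at_cut(hist, 1, 0.5, 0.1)$balance, 1 - 2)
  # weighted median bin = smallest cut with balance >= 0, cross-checked
  # against the direct weighted_median (ni = 256: bin == integer value)
  set.seed(5)
  for (rep in 1:15) {
    v <- sample(0:255, 9, TRUE); g <- runif(9)
    hist <- build_joint_histogram(v, g, ni = 256, nf = 8)
    bals <- vapply(0:255, function(cc)
      balance_at_cut(hist, cc, g[5], 0.2)$balance, numeric(1))
    cut <- which(bals >= 0)[1] - 1
    gtab <- icif:::wmf_weight_table(8, 0.2)
    wq <- gtab[abs(icif:::guidance_bin(g, 8) -
                     icif:::guidance_bin(g[5], 8)) + 1]
    expect_equal(cut, weighted_median(v, wq))
  }
})

test_that("naive and accelerated backends agree pixel-exactly", {
  set.seed(101)
  for (rep in 1:12) {
    p <- rand_pair(16, 16)
    for (r in c(1, 2, 3)) for (nf in c(8, 32)) {
      expect_equal(
        guided_wmf(p$img, p$guid, radius = r, nf = nf, mode = "accelerated"),
        guided_wmf(p$img, p$guid, radius = r, nf = nf, mode = "naive"))
    }
  }
  # non-square and radius wider than the image (full truncation)
  p <- rand_pair(5, 9)
  expect_equal(guided_wmf(p$img, p$guid, radius = 7, mode = "accelerated"),
               guided_wmf(p$img, p$guid, radius = 7, mode = "naive"))
})

test_that("filter output values are drawn from each pixel's window", {
  set.seed(21)
  p <- rand_pair(12, 12)
  out <- guided_wmf(p$img, p$guid, radius = 2)
  for (i in seq_len(12)) for (j in seq_len(12)) {
    win <- p$img[max(1, i - 2):min(12, i + 2), max(1, j - 2):min(12, j + 2)]
    expect_true(out[i, j] %in% win)
  }
})

test_that("constant guidance reduces the filter to a plain median filter", {
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(as.numeric(sample(0:255, 144, TRUE)), 12)
    for (r in c(1, 2)) {
      expect_equal(guided_wmf(img, matrix(0.37, 12, 12), radius = r),
                   plain_median_filter(img, r))
    }
  }
})

test_that("a single guidance bin behaves like constant guidance", {
  set.seed(41)
  p <- rand_pair(10, 10)
  expect_equal(guided_wmf(p$img, p$guid, radius = 2, nf = 1),
               guided_wmf(p$img, matrix(0.5, 10, 10), radius = 2, nf = 32))
})

test_that("constant images pass through the filter unchanged", {
  img <- matrix(77, 9, 9)
  set.seed(51)
  g <- matrix(runif(81), 9)
  expect_equal(guided_wmf(img, g, radius = 3), img)
})

test_that("shape and parameter errors are caught", {
  expect_error(guided_wmf(matrix(0, 4, 4), matrix(0, 5, 5)), "dimensions")
  expect_error(guided_wmf(matrix(0, 4, 4), matrix(0, 4, 4), radius = 0),
               "radius")
  expect_error(guided_wmf(matrix(0, 4, 4), matrix(0, 4, 4), bandwidth = -1),
               "bandwidth")
})
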