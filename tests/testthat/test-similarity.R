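test_that("metric configuration validates weights and bins", {
  cfg <- metric_config(c("zncc", "gd"))
  expect_equal(cfg$weights, c(0.5, 0.5))
  expect_equal(cfg$bins, 64L)
  expect_error(metric_config("zncc", weights = c(0.4, 0.6)), "weights")
  expect_error(metric_config(c("nmi", "gd"), weights = c(0.9, 0.2)), "weights")
  expect_error(metric_config("nmi", bins = 1), "bins")
})

test_that("NMI: identical images, bijective remaps, independent noise", {
  set.seed(10)
  a <- matrix(runif(64), 8, 8)
  expect_equal(nmi(a, a, bins = 8), 2.0, tolerance = 1e-12)

  # two gray levels, inverted: still a bijective relation, NMI = 2
  b2 <- matrix(rep(c(0, 1), 32), 8, 8)
  expect_equal(nmi(b2, 1 - b2, bins = 2), 2.0, tolerance = 1e-12)

  # matches the explicit joint-histogram oracle
  b <- matrix(runif(64), 8, 8)
  expect_equal(nmi(a, b, bins = 6), oracle_nmi(a, b, 6), tolerance = 1e-10)

  # independent noise at N = 1e6 px: 1 + O(bins^2 / N) sampling bias
  big_a <- matrix(runif(1e6), 1000, 1000)
  big_b <- matrix(runif(1e6), 1000, 1000)
  s <- nmi(big_a, big_b, bins = 64)
  expect_gte(s, 1)
  expect_lte(s, 1.05)

  expect_error(nmi(matrix(1, 4, 4), a[1:4, 1:4]), "degenerate")
})

test_that("gradient difference: maximum, offset invariance, scale oracle", {
  set.seed(11)
  a <- matrix(runif(64), 8, 8)
  # identical images: every term is Av/Av = 1, summed over 2 * npix
  expect_equal(as.numeric(gradient_difference(a, a)), 2 * 64,
               tolerance = 1e-9)
  # derivatives kill constant offsets
  expect_equal(as.numeric(gradient_difference(a, a + 5)), 2 * 64,
               tolerance = 1e-9)
  # general pair equals the dense grid-search oracle over s
  b <- matrix(runif(64), 8, 8) + 0.5 * a
  expect_equal(as.numeric(gradient_difference(a, b)), oracle_gd(a, b),
               tolerance = 1e-9)
  expect_error(gradient_difference(matrix(1, 8, 8), a), "degenerate")
})

test_that("ZNCC: correlation identities and affine invariance", {
  set.seed(12)
  a <- matrix(runif(100), 10, 10)
  expect_equal(zncc(a, a), 1.0, tolerance = 1e-12)
  expect_equal(zncc(a, -a), -1.0, tolerance = 1e-12)
  expect_equal(zncc(a, 2 * a + 5), 1.0, tolerance = 1e-12)
  expect_error(zncc(a, matrix(2, 10, 10)), "degenerate")
})

test_that("metric symmetry and intensity-rescaling invariance", {
  set.seed(13)
  a <- matrix(runif(144), 12, 12)
  b <- matrix(runif(144), 12, 12)
  expect_equal(nmi(a, b, bins = 8), nmi(b, a, bins = 8), tolerance = 1e-12)
  expect_equal(zncc(a, b), zncc(b, a), tolerance = 1e-12)
  # GD is deliberately asymmetric: a supplies the normalizing variances
  expect_false(isTRUE(all.equal(as.numeric(gradient_difference(a, b)),
                                as.numeric(gradient_difference(b, a)))))
  # positive affine rescaling changes neither NMI nor ZNCC
  expect_equal(nmi(3 * a + 1, b, bins = 8), nmi(a, b, bins = 8),
               tolerance = 1e-9)
  expect_equal(zncc(a, 0.2 * b + 7), zncc(a, b), tolerance = 1e-9)
})

test_that("ROI restriction: scores come from the ROI only", {
  set.seed(14)
  core <- matrix(runif(64), 8, 8)
  core_b <- matrix(runif(64), 8, 8)
  # embed in a larger constant-padded image; same ROI content
  pad <- function(m) {
    out <- matrix(0.5, 16, 16)
    out[5:12, 5:12] <- m
    out
  }
  roi <- calc_roi("vertical", 4, 4, 12, 12)
  expect_equal(zncc(pad(core), pad(core_b), roi = roi), zncc(core, core_b),
               tolerance = 1e-12)
  expect_equal(as.numeric(gradient_difference(pad(core), pad(core_b), roi = roi)),
               as.numeric(gradient_difference(core, core_b)),
               tolerance = 1e-12)
})

test_that("combined cost: zero at identity, normalized dissimilarities", {
  set.seed(15)
  a1 <- matrix(runif(64), 8, 8); a2 <- matrix(runif(64), 8, 8)
  views_same <- list(list(a = a1, b = a1, roi = NULL),
                     list(a = a2, b = a2, roi = NULL))
  for (cfg in list(metric_config("zncc"), metric_config(c("zncc", "gd")),
                   metric_config(c("nmi", "gd", "zncc"), bins = 8)))
    expect_lt(combined_cost(views_same, cfg), 1e-9)

  # anti-correlated pair under ZNCC maps to the maximum cost 1
  views_anti <- list(list(a = a1, b = -a1, roi = NULL),
                     list(a = a2, b = -a2, roi = NULL))
  expect_equal(combined_cost(views_anti, metric_config("zncc")), 1,
               tolerance = 1e-12)

  # equal-weight ZNCC+GD equals the mean of the normalized dissimilarities
  b1 <- a1 + 0.3 * matrix(runif(64), 8, 8)
  b2 <- a2 + 0.3 * matrix(runif(64), 8, 8)
  views <- list(list(a = a1, b = b1, roi = NULL),
                list(a = a2, b = b2, roi = NULL))
  dz <- mean(c((1 - zncc(a1, b1)) / 2, (1 - zncc(a2, b2)) / 2))
  dg <- mean(c(1 - as.numeric(gradient_difference(a1, b1)) / 128,
               1 - as.numeric(gradient_difference(a2, b2)) / 128))
  expect_equal(combined_cost(views, metric_config(c("zncc", "gd"))),
               (dz + dg) / 2, tolerance = 1e-9)
})

test_that("combined cost decreases as the images agree better", {
  set.seed(16)
  a <- matrix(runif(256), 16, 16)
  noise <- matrix(runif(256), 16, 16)
  cfg <- metric_config(c("zncc", "gd"))
  costs <- vapply(c(2, 1, 0.5, 0.1, 0), function(lam)
    combined_cost(list(list(a = a, b = a + lam * noise, roi = NULL)), cfg),
    numeric(1))
  expect_true(all(diff(costs) < 1e-12))
})
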