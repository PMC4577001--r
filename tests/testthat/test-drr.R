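test_that("HU to attenuation: water, air, linear scale, bone weighting", {
  v <- ct_volume(array(c(0, -1000, 1000, 500), c(4, 1, 1)))
  av <- hu_to_attenuation(v, mu_water = 0.02, body = FALSE)
  expect_equal(av$values[1, 1, 1], 0.02)   # water definition
  expect_equal(av$values[2, 1, 1], 0)      # air attenuates nothing
  expect_equal(av$values[3, 1, 1], 0.04)   # linear in HU
  # bone emphasis is monotone and only acts above the threshold
  avb <- hu_to_attenuation(v, mu_water = 0.02, bone_hu = 300, bone_gain = 2,
                           body = FALSE)
  expect_equal(avb$values[1, 1, 1], av$values[1, 1, 1])
  expect_gt(avb$values[3, 1, 1], av$values[3, 1, 1])
  hu <- seq(-1000, 2000, by = 50)
  mu <- hu_to_attenuation(ct_volume(array(hu, c(length(hu), 1, 1))),
                          bone_hu = 300, bone_gain = 2, body = FALSE)$values
  expect_true(all(diff(as.numeric(mu)) >= 0))
  expect_error(hu_to_attenuation(ct_volume(array(NaN, c(2, 2, 2))),
                                 body = FALSE), "non-finite")
})

test_that("body segmentation keeps the largest component and fills cavities", {
  n <- 32
  cw <- (seq_len(n) - 0.5) - n / 2
  X <- array(cw, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3)); Z <- aperm(X, c(3, 2, 1))
  r2 <- X^2 + Y^2 + Z^2

  # water sphere in air: mask equals the sphere voxels
  hu <- array(-1000, c(n, n, n)); hu[r2 <= 10^2] <- 0
  m <- segment_body(ct_volume(hu), -300)
  expect_identical(as.logical(m), as.logical(r2 <= 10^2))

  # shell with an internal air cavity: cavity filled (lungs stay inside)
  hu <- array(-1000, c(n, n, n))
  hu[r2 <= 12^2] <- 40
  hu[r2 <= 6^2] <- -1000                   # internal air
  hu[1:2, 1:2, 1:2] <- 200                 # small separate blob: dropped
  m <- segment_body(ct_volume(hu), -300)
  # oracle: largest thresholded component, then background components not
  # reaching the border are cavities
  fg <- hu >= -300
  lab <- oracle_fill(fg)
  big <- which.max(tabulate(lab[lab > 0]))
  body <- lab == big
  bg_lab <- oracle_fill(!body)
  border_ids <- unique(c(bg_lab[1, , ], bg_lab[n, , ], bg_lab[, 1, ],
                         bg_lab[, n, ], bg_lab[, , 1], bg_lab[, , n]))
  oracle <- body | (bg_lab > 0 & !(bg_lab %in% border_ids))
  expect_identical(as.logical(m), as.logical(oracle))
  expect_true(all(m[r2 <= 6^2]))           # the cavity is inside the body
  expect_false(any(m[1:2, 1:2, 1:2]))      # the blob is not

  expect_error(segment_body(ct_volume(array(-1000, c(8, 8, 8)))),
               "empty body")
})

test_that("DRR casting: zero volume, homogeneous cube, linearity", {
  g <- phantom_geometry("vertical", size = c(64, 64), pitch = 6.4)
  zero <- hu_to_attenuation(ct_volume(array(-1000, c(16, 16, 16)),
                                      spacing = c(8, 8, 8)), body = FALSE)
  expect_true(all(cast_drr(zero, g) == 0))

  # 100 mm water cube: central path integral = mu * side
  cube <- hu_to_attenuation(ct_volume(array(0, c(50, 50, 50)),
                                      spacing = c(2, 2, 2)),
                            mu_water = 0.02, body = FALSE)
  d <- cast_drr(cube, g)
  expect_equal(d[32, 32], 2.0, tolerance = 0.005)

  # linearity in the attenuation values
  cube2 <- cube; cube2$values <- 3.5 * cube$values
  expect_equal(cast_drr(cube2, g), 3.5 * d, tolerance = 1e-9)
})

test_that("DRR matches the brute-force line-integral oracle within 1%", {
  set.seed(42)
  n <- 32
  v <- ct_volume(array(runif(n^3, 0.005, 0.03), c(n, n, n)),
                 spacing = c(2, 2, 2))
  g <- projection_geometry("vertical", pitch = 8, size = c(16, 16))
  d <- cast_drr(v, g)
  o <- oracle_drr(v, g)
  rel <- abs(d - o) / pmax(o, 1e-12)
  expect_lt(max(rel[o > 0]), 0.01)
})

test_that("ROI restriction equals masking the full DRR, exactly", {
  av <- head64_av()
  g <- phantom_geometry("vertical", size = c(64, 64), pitch = 6.4)
  roi <- calc_roi("vertical", 10, 14, 40, 50)
  full <- cast_drr(av, g)
  sub <- cast_drr(av, g, roi = roi)
  masked <- matrix(0, 64, 64)
  masked[11:40, 15:50] <- full[11:40, 15:50]
  expect_identical(unclass(sub)[, ], masked)
  expect_error(cast_drr(av, g, roi = calc_roi("vertical", -20, -20, -5, -5)),
               "empty roi")
})

test_that("body-mask bounding does not change any pixel", {
  # air outside the body is exactly zero attenuation, so restricting the
  # integration to the body bounding box must be lossless
  v <- head64()
  g <- phantom_geometry("vertical", size = c(64, 64), pitch = 6.4)
  a1 <- cast_drr(hu_to_attenuation(v, body = TRUE), g)
  a2 <- cast_drr(hu_to_attenuation(v, body = FALSE), g)
  expect_lt(max(abs(a1 - a2)) / max(a2), 1e-9)
})

test_that("automatic ROI from a target region", {
  g <- projection_geometry("vertical")
  # point target at the isocenter, 20 mm margin: 125 px on each side of
  # the center pixel at 0.16 mm pitch
  roi <- auto_roi(list(center = c(0, 0, 0), radius = 0), g, margin_mm = 20)
  # oracle: the projected center pixel expanded by margin/pitch each side
  ctr <- project_point(g, c(0, 0, 0))
  expect_equal(roi$rect,
               as.integer(c(floor(ctr - 125), floor(ctr + 125) + 1)[c(1, 2, 3, 4)]))
  expect_equal(roi$rect[3] - roi$rect[1], 251L)
  expect_equal(roi$rect[4] - roi$rect[2], 251L)
  expect_equal((roi$rect[1] + roi$rect[3]) / 2, g$size[1] / 2, tolerance = 1)

  # zero margin on a point target: the single containing pixel
  roi0 <- auto_roi(list(center = c(0, 0, 0), radius = 0), g, margin_mm = 0)
  expect_equal(roi0$rect[3] - roi0$rect[1], 1L)
  expect_equal(roi0$rect[4] - roi0$rect[2], 1L)

  # sphere target: the box covers the magnified silhouette plus margin
  roi2 <- auto_roi(list(center = c(0, 0, 0), radius = 30), g, margin_mm = 20)
  w_mm <- (roi2$rect[3] - roi2$rect[1]) * g$pitch
  expect_gt(w_mm, 2 * 30 * g$sid / g$sad + 2 * 20 - 2)
  expect_lt(w_mm, 2 * 30 * g$sid / g$sad + 2 * 20 + 4)

  # target projecting outside the detector is clipped
  small <- projection_geometry("vertical", pitch = 1.6, size = c(64, 64))
  roi3 <- auto_roi(list(center = c(40, 0, 0), radius = 10), small,
                   margin_mm = 10)
  expect_lte(roi3$rect[3], 64)
  expect_error(auto_roi(list(center = c(500, 0, 0), radius = 1), small,
                        margin_mm = 0), "empty roi")
})

test_that("in-plane shortcut update approximates a re-cast DRR", {
  av <- head64_av()
  g <- phantom_geometry("vertical", size = c(128, 128), pitch = 3.2)
  base <- cast_drr(av, g)

  # identity update returns the image unchanged
  expect_identical(in_plane_update(base, 0, 0, 0), base)

  # integer-pixel translation of a constant-interior image keeps the interior
  const <- matrix(1, 64, 64)
  sh <- in_plane_update(const, du = 2 * 3.2, dv = 0, dtheta = 0, pitch = 3.2,
                        limits = c(10, 1))
  expect_equal(sh[10:60, 10:60], const[10:60, 10:60])

  # 2 mm detector shift vs a fully re-cast DRR at the equivalent pose
  mag <- g$sid / g$sad
  recast <- cast_drr(av, g, rigid_pose(tx = 2 / mag))
  ctr <- project_point(g, c(0, 0, 0)) - 0.5
  appr <- in_plane_update(base, du = 2, dv = 0, dtheta = 0, pitch = 3.2,
                          center_px = ctr)
  expect_lt(sqrt(mean((appr - recast)^2)) / diff(range(recast)), 0.02)

  # shifts beyond the configured limits are refused
  expect_error(in_plane_update(base, du = 8, dv = 0, dtheta = 0,
                               limits = c(5, 1)),
               class = "drrreg_shortcut_refused")
  expect_error(in_plane_update(base, du = 0, dv = 0, dtheta = 2,
                               limits = c(5, 1)),
               class = "drrreg_shortcut_refused")
})
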