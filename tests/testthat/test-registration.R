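test_that("pyramid configuration and volume downsampling", {
  cfg <- pyramid_config()
  expect_equal(length(cfg$factors), 3)
  expect_error(pyramid_config(list(c(2, 2, 2), c(3, 3, 3), c(1, 1, 1)),
                              grid = c(2, 3, 1), tol = rep(1e-4, 3),
                              line_tol = rep(0.01, 3)),
               "non-increasing")
  expect_error(pyramid_config(list(c(2, 2, 2)), grid = 2, tol = 1e-4,
                              line_tol = 0.01), "original")

  av <- hu_to_attenuation(ct_volume(array(0, c(6, 6, 6))), body = FALSE)
  pyr <- build_pyramid(av, pyramid_config(list(c(3, 3, 3), c(1, 1, 1)),
                                          grid = c(3, 1), tol = c(1e-3, 1e-4),
                                          line_tol = c(0.1, 0.01)))
  expect_equal(dim(pyr[[1]]$values), c(2, 2, 2))
  expect_true(all(pyr[[1]]$values == 0.02))       # constant stays constant
  expect_equal(pyr[[1]]$spacing, c(3, 3, 3))
  expect_identical(pyr[[2]], av)                  # last stage untouched

  # ramp along x: block means equal the hand computation
  ramp <- array(rep(1:6, 36), c(6, 6, 6))
  avr <- hu_to_attenuation(ct_volume(ramp * 100), body = FALSE)
  pyr <- build_pyramid(avr, pyramid_config(list(c(2, 2, 2), c(1, 1, 1)),
                                           grid = c(2, 1), tol = c(1e-3, 1e-4),
                                           line_tol = c(0.1, 0.01)))
  manual <- 0.02 * (1 + 100 * c(1.5, 3.5, 5.5) / 1000)
  expect_equal(pyr[[1]]$values[, 1, 1], manual, tolerance = 1e-12)

  tiny <- hu_to_attenuation(ct_volume(array(0, c(2, 2, 2))), body = FALSE)
  expect_error(build_pyramid(tiny, pyramid_config(list(c(3, 3, 3), c(1, 1, 1)),
                                                  grid = c(3, 1),
                                                  tol = c(1e-3, 1e-4),
                                                  line_tol = c(0.1, 0.01))),
               "degenerate pyramid")
})

test_that("view-parameter fusion averages the shared couch axis and phi", {
  vert <- rigid_pose(tx = 1, ty = 2, tz = 99, psi = 99, phi = 1, theta = 4)
  horiz <- rigid_pose(tx = 99, ty = 4, tz = 3, psi = 5, phi = 0, theta = 99)
  fused <- fuse_view_params(vert, horiz)
  expect_equal(unclass(fused),
               unclass(rigid_pose(1, 3, 3, 5, 0.5, 4)))
  expect_identical(unclass(fuse_view_params(vert, vert)), unclass(vert))
  expect_error(fuse_view_params(vert, NULL), "fusion error")
})

test_that("single-view estimation recovers an in-plane offset", {
  av <- head64_av()
  g <- phantom_geometry("vertical", size = c(128, 128), pitch = 3.2)
  roi <- auto_roi(attr(head64(), "ptv"), g)
  truth <- rigid_pose(tx = 5)
  fpd <- cast_drr(av, g, truth)

  est <- estimate_view_params(fpd, av, g, pose0 = rigid_pose(),
                              cfg = metric_config("zncc"), roi = roi)
  expect_lt(abs(est$pose[["tx"]] - 5), 0.5)
  expect_lt(max(abs(unclass(est$pose)[c("ty", "theta", "phi")])), 0.5)

  # self-match: starting at the truth stays put
  est0 <- estimate_view_params(fpd, av, g, pose0 = truth,
                               cfg = metric_config("zncc"), roi = roi)
  expect_lt(max(abs(unclass(est0$pose) - unclass(truth))), 0.05)

  # constant background inside the ROI cannot be scored
  flat <- matrix(0, 128, 128)
  expect_error(estimate_view_params(flat, av, g, pose0 = rigid_pose(),
                                    cfg = metric_config("zncc"), roi = roi),
               "view estimation")
})

test_that("registration fixed point: self-consistent inputs return the pose", {
  av <- head64_av()
  geom <- phantom_geom_pair(size = c(128, 128), pitch = 3.2)
  fpds <- self_consistent_fpds(av, geom)
  fit <- drr_register(head64(), fpds$vertical, fpds$horizontal,
                      geometry = geom, pose0 = rigid_pose(),
                      metrics = metric_config("zncc"),
                      ptv = attr(head64(), "ptv"))
  expect_lt(max(abs(coef(fit)[1:3])), 1e-3)
  expect_true(fit$converged)
  expect_equal(pose_error(fit$pose)$tre, 0, tolerance = 1e-3)
})

test_that("registration is deterministic: identical inputs, identical traces", {
  av <- head64_av()
  geom <- phantom_geom_pair(size = c(128, 128), pitch = 3.2)
  fpds <- self_consistent_fpds(av, geom)
  run <- function() drr_register(head64(), fpds$vertical, fpds$horizontal,
                                 geometry = geom,
                                 pose0 = rigid_pose(4, 4, 4, 0.5, 0.5, 0.5),
                                 metrics = metric_config("zncc"),
                                 ptv = attr(head64(), "ptv"))
  f1 <- run(); f2 <- run()
  expect_identical(f1$trace, f2$trace)
  expect_identical(unclass(f1$pose), unclass(f2$pose))
})

test_that("partitioned and joint modes agree on a noiseless phantom", {
  av <- head64_av()
  geom <- phantom_geom_pair(size = c(128, 128), pitch = 3.2)
  fpds <- self_consistent_fpds(av, geom)
  args <- list(head64(), fpds$vertical, fpds$horizontal, geometry = geom,
               pose0 = rigid_pose(8, 8, 8, 1, 1, 1),
               metrics = metric_config("zncc"), ptv = attr(head64(), "ptv"))
  fp <- do.call(drr_register, c(args, mode = "partitioned"))
  fj <- do.call(drr_register, c(args, mode = "joint"))
  expect_lt(max(abs(coef(fp)[1:3] - coef(fj)[1:3])), 0.5)
  expect_lt(max(abs(coef(fp)[4:6] - coef(fj)[4:6])), 0.3)
})

test_that("registering +delta and -delta offsets is symmetric in magnitude", {
  av <- head64_av()
  geom <- phantom_geom_pair(size = c(128, 128), pitch = 3.2)
  fpds <- self_consistent_fpds(av, geom)
  run <- function(sgn) {
    fit <- drr_register(head64(), fpds$vertical, fpds$horizontal,
                        geometry = geom,
                        pose0 = rigid_pose(sgn * 6, sgn * 6, sgn * 6),
                        metrics = metric_config("zncc"),
                        ptv = attr(head64(), "ptv"))
    pose_error(fit$pose)
  }
  ep <- run(1); em <- run(-1)
  expect_lt(abs(ep$tre - em$tre), 0.2)
})

test_that("the registration object behaves like a fitted model", {
  av <- head64_av()
  geom <- phantom_geom_pair(size = c(128, 128), pitch = 3.2)
  fpds <- self_consistent_fpds(av, geom)
  fit <- drr_register(head64(), fpds$vertical, fpds$horizontal,
                      geometry = geom, metrics = metric_config("zncc"),
                      ptv = attr(head64(), "ptv"))
  expect_named(coef(fit), c("tx", "ty", "tz", "psi", "phi", "theta"))
  expect_output(print(fit), "registration")
  s <- summary(fit)
  expect_s3_class(s, "summary.drr_registration")
  expect_output(print(s), "ZNCC")
  drr <- predict(fit, "vertical")
  expect_equal(dim(drr), c(128, 128))
  res <- residuals(fit)
  expect_lt(max(abs(res$vertical)), 0.05)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
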