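test_that("pose matrices: identity, translation and axis rotations", {
  expect_equal(pose_to_matrix(rigid_pose()), diag(4))

  m <- pose_to_matrix(rigid_pose(20, 20, 20))
  expect_equal(m[, 4], c(20, 20, 20, 1))
  expect_equal(m[1:3, 1:3], diag(3))

  # 90 deg about Z carries x onto y
  expect_equal(pose_apply(rigid_pose(theta = 90), c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  # right-handed rotations about each axis
  expect_equal(pose_apply(rigid_pose(psi = 90), c(0, 1, 0)), c(0, 0, 1),
               tolerance = 1e-12)
  expect_equal(pose_apply(rigid_pose(phi = 90), c(0, 0, 1)), c(1, 0, 0),
               tolerance = 1e-12)
})

test_that("non-finite pose components are rejected", {
  expect_error(rigid_pose(tx = NaN), "invalid pose")
  expect_error(rigid_pose(theta = Inf), "invalid pose")
})

test_that("matrix/pose round trip and rotation orthonormality", {
  set.seed(5)
  for (i in 1:25) {
    p <- rigid_pose(runif(1, -40, 40), runif(1, -40, 40), runif(1, -40, 40),
                    runif(1, -85, 85), runif(1, -85, 85), runif(1, -85, 85))
    m <- pose_to_matrix(p)
    R <- m[1:3, 1:3]
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    expect_lt(max(abs(unclass(matrix_to_pose(m)) - unclass(p))), 1e-9)
  }
})

test_that("pose composition: inverse and associativity", {
  set.seed(6)
  rp <- function() rigid_pose(runif(1, -30, 30), runif(1, -30, 30),
                              runif(1, -30, 30), runif(1, -45, 45),
                              runif(1, -45, 45), runif(1, -45, 45))
  for (i in 1:10) {
    p <- rp(); q <- rp(); r <- rp()
    expect_lt(max(abs(unclass(pose_compose(p, pose_inverse(p))))), 1e-9)
    ab_c <- pose_to_matrix(pose_compose(pose_compose(p, q), r))
    a_bc <- pose_to_matrix(pose_compose(p, pose_compose(q, r)))
    expect_lt(max(abs(ab_c - a_bc)), 1e-9)
  }
})

test_that("default geometries match the clinical arrangement", {
  gv <- projection_geometry("vertical")
  gh <- projection_geometry("horizontal")
  expect_equal(gv$sad, 1550)
  expect_equal(gv$sid, 2130)
  expect_equal(gv$pitch, 0.16)
  expect_equal(gv$size, as.integer(round(c(350, 430) / 0.16)))
  # vertical source under the floor, ray +Z; horizontal ray +X
  expect_equal(gv$source, c(0, 0, -1550))
  expect_equal(gh$source, c(-1550, 0, 0))
  # both views share the couch (Y) axis on the detector
  expect_equal(gv$v_axis, c(0, 1, 0))
  expect_equal(gh$v_axis, c(0, 1, 0))
  expect_error(projection_geometry("vertical", sad = 2200),
               "sid > sad")
})

test_that("point projection: central ray, magnification, degeneracy", {
  g <- projection_geometry("vertical")
  expect_equal(unname(project_point(g, c(0, 0, 0))), g$size / 2,
               tolerance = 1e-12)
  # similar triangles: offsets in the isocenter plane magnify by sid/sad
  uv0 <- project_point(g, c(0, 0, 0))
  uv1 <- project_point(g, c(10, 0, 0))
  expect_equal(unname(uv1[1] - uv0[1]), 10 * (2130 / 1550) / 0.16,
               tolerance = 1e-9)
  set.seed(7)
  for (i in 1:10) {
    off <- c(runif(2, -80, 80), 0)   # in-plane offset for the vertical view
    uv <- project_point(g, off)
    expect_equal(sqrt(sum((uv - uv0)^2)) * g$pitch,
                 sqrt(sum(off^2)) * g$sid / g$sad, tolerance = 1e-9)
  }
  expect_error(project_point(g, g$source), "degenerate")
})

test_that("volume container enforces its invariants", {
  expect_error(ct_volume(array(0, c(0, 2, 2))), "non-empty")
  expect_error(ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 0, 1)),
               "positive")
  v <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 2.5))
  # centered on the isocenter by default, voxel-center convention
  expect_equal(v$origin, -c(4, 4, 10) / 2)
})
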