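#' Rigid 6DOF pose
#'
#' A rigid-body pose of the CT volume in the fixed room frame: three
#' translations in mm along the room axes X (lateral), Y (longitudinal, the
#' couch axis shared by both imaging planes) and Z (vertical), and three
#' rotations in degrees about those axes (`psi` about X, `phi` about Y,
#' `theta` about Z).  The rotation center is the room isocenter, which is the
#' origin of the room frame.
#'
#' @param tx,ty,tz translations in mm.
#' @param psi,phi,theta rotations in degrees about X, Y, Z.
#' @return an object of class `rigid_pose` (a named numeric vector of
#'   length 6).
#' @examples
#' p <- rigid_pose(tx = 20, ty = 20, tz = 20, psi = 2, phi = 2, theta = 2)
#' pose_to_matrix(p)
#' @export
rigid_pose <- function(tx = 0, ty = 0, tz = 0, psi = 0, phi = 0, theta = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, psi = psi, phi = phi, theta = theta)
  if (!all(is.finite(p)))
    stop("invalid pose: all six components must be finite")
  structure(p, class = "rigid_pose")
}

pose_names <- c("tx", "ty", "tz", "psi", "phi", "theta")

as_rigid_pose <- function(x) {
  if (inherits(x, "rigid_pose")) return(x)
  x <- as.numeric(x)
  if (length(x) != 6) stop("a pose needs exactly 6 components")
  do.call(rigid_pose, as.list(stats::setNames(x, pose_names)))
}

#' @export
print.rigid_pose <- function(x, digits = 4, ...) {
  cat(sprintf("rigid pose: t = (%s) mm, r = (%s) deg\n",
              paste(signif(x[1:3], digits), collapse = ", "),
              paste(signif(x[4:6], digits), collapse = ", ")))
  invisible(x)
}

rot_x <- function(a) {
  a <- a * pi / 180; c_ <- cos(a); s_ <- sin(a)
  matrix(c(1, 0, 0,  0, c_, s_,  0, -s_, c_), 3, 3)
}
rot_y <- function(a) {
  a <- a * pi / 180; c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, 0, -s_,  0, 1, 0,  s_, 0, c_), 3, 3)
}
rot_z <- function(a) {
  a <- a * pi / 180; c_ <- cos(a); s_ <- sin(a)
  matrix(c(c_, s_, 0,  -s_, c_, 0,  0, 0, 1), 3, 3)
}

#' Pose to homogeneous transform
#'
#' Builds the 4x4 homogeneous matrix `T = Trans(tx,ty,tz) Rz(theta) Ry(phi)
#' Rx(psi)` that places a volume-frame point in the room frame, rotating
#' about the isocenter.
#'
#' @param p a [rigid_pose()].
#' @return a 4x4 numeric matrix.
#' @export
pose_to_matrix <- function(p) {
  p <- as_rigid_pose(p)
  R <- rot_z(p["theta"]) %*% rot_y(p["phi"]) %*% rot_x(p["psi"])
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- p[1:3]
  m
}

#' Homogeneous transform to pose
#'
#' Inverse of [pose_to_matrix()] for rotation angles in (-90, 90) degrees.
#'
#' @param m a 4x4 rigid homogeneous matrix with rotation order Rz Ry Rx.
#' @return a [rigid_pose()].
#' @export
matrix_to_pose <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  phi <- asin(max(-1, min(1, -m[3, 1])))
  theta <- atan2(m[2, 1], m[1, 1])
  psi <- atan2(m[3, 2], m[3, 3])
  rigid_pose(m[1, 4], m[2, 4], m[3, 4],
             psi * 180 / pi, phi * 180 / pi, theta * 180 / pi)
}

#' Compose and invert poses
#'
#' `pose_compose(p, q)` is the pose whose transform is `T(p) %*% T(q)`;
#' `pose_inverse(p)` satisfies `pose_compose(p, pose_inverse(p)) == identity`.
#'
#' @param p,q [rigid_pose()] objects.
#' @return a [rigid_pose()].
#' @export
pose_compose <- function(p, q) {
  matrix_to_pose(pose_to_matrix(p) %*% pose_to_matrix(q))
}

#' @rdname pose_compose
#' @export
pose_inverse <- function(p) {
  m <- pose_to_matrix(p)
  R <- t(m[1:3, 1:3])
  mi <- diag(4)
  mi[1:3, 1:3] <- R
  mi[1:3, 4] <- -R %*% m[1:3, 4]
  matrix_to_pose(mi)
}

#' Apply a pose to points
#'
#' @param p a [rigid_pose()].
#' @param pts an n x 3 matrix (or length-3 vector) of points in mm.
#' @return transformed points, same shape.
#' @export
pose_apply <- function(p, pts) {
  m <- pose_to_matrix(p)
  one <- FALSE
  if (is.null(dim(pts))) { pts <- matrix(pts, 1); one <- TRUE }
  out <- t(m[1:3, 1:3] %*% t(pts)) + rep(m[1:3, 4], each = nrow(pts))
  if (one) out[1, ] else out
}

#' Divergent-beam projection geometry
#'
#' One X-ray view: a point source and a flat detector plane.  The shorthand
#' views reproduce the fixed-room arrangement of an orthogonal FPD pair: the
#' vertical view fires upwards (+Z, tube under the floor) and the horizontal
#' view sideways (+X), both with source-to-isocenter distance `sad` and
#' source-to-detector distance `sid`.  Defaults are the clinical geometry:
#' SAD 1550 mm, SID 2130 mm, 0.16 mm pixel pitch, 350 x 430 mm panel.
#'
#' Detector pixels are indexed 0-based; the center of pixel `(u, v)` lies at
#' `detector_origin + (u + 0.5) * pitch * u_axis + (v + 0.5) * pitch * v_axis`.
#' Both views share the room Y axis as the detector `v` axis.
#'
#' @param view `"vertical"`, `"horizontal"` or `"custom"`.
#' @param sad source-to-isocenter distance, mm.
#' @param sid source-to-detector distance, mm; must exceed `sad`.
#' @param pitch pixel pitch, mm.
#' @param size detector size in pixels `(nu, nv)`; default covers
#'   350 x 430 mm at `pitch`.
#' @param source,detector_origin,u_axis,v_axis explicit geometry for
#'   `view = "custom"` (room-frame mm; axes must be orthonormal).
#' @return an object of class `projection_geometry`.
#' @export
projection_geometry <- function(view = c("vertical", "horizontal", "custom"),
                                sad = 1550, sid = 2130, pitch = 0.16,
                                size = NULL,
                                source = NULL, detector_origin = NULL,
                                u_axis = NULL, v_axis = NULL) {
  view <- match.arg(view)
  if (view != "custom") {
    if (!(sid > sad && sad > 0)) stop("need sid > sad > 0")
    if (is.null(size)) size <- round(c(350, 430) / pitch)
    if (view == "vertical") {
      dir <- c(0, 0, 1)            # ray direction: source under the floor
      u_axis <- c(1, 0, 0)         # detector u along room X
    } else {
      dir <- c(1, 0, 0)
      u_axis <- c(0, 0, 1)         # detector u along room Z
    }
    v_axis <- c(0, 1, 0)           # shared couch (Y) axis
    source <- -sad * dir
    center <- (sid - sad) * dir
    detector_origin <- center - size[1] * pitch / 2 * u_axis -
      size[2] * pitch / 2 * v_axis
  } else {
    if (is.null(source) || is.null(detector_origin) ||
        is.null(u_axis) || is.null(v_axis))
      stop("custom geometry needs source, detector_origin, u_axis, v_axis")
    if (is.null(size)) stop("custom geometry needs a detector size")
    nu <- sqrt(sum(u_axis^2)); nv <- sqrt(sum(v_axis^2))
    if (abs(nu - 1) > 1e-9 || abs(nv - 1) > 1e-9 ||
        abs(sum(u_axis * v_axis)) > 1e-9)
      stop("detector axes must be unit length and orthogonal")
  }
  g <- list(view = view, source = as.numeric(source),
            detector_origin = as.numeric(detector_origin),
            u_axis = as.numeric(u_axis), v_axis = as.numeric(v_axis),
            pitch = pitch, size = as.integer(size), sad = sad, sid = sid)
  structure(g, class = "projection_geometry")
}

#' @export
print.projection_geometry <- function(x, ...) {
  cat(sprintf("projection geometry [%s]: SAD %g mm, SID %g mm, %d x %d px @ %g mm\n",
              x$view, x$sad, x$sid, x$size[1], x$size[2], x$pitch))
  invisible(x)
}

detector_normal <- function(g) {
  u <- g$u_axis; v <- g$v_axis
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Project a room-frame point onto the detector
#'
#' Intersects the ray from the source through `pt` with the detector plane
#' and returns the continuous pixel coordinate `(u, v)` (0-based, so the
#' detector center is at `size / 2`).
#'
#' @param g a [projection_geometry()].
#' @param pt a length-3 point or n x 3 matrix, room-frame mm.
#' @return a length-2 vector or n x 2 matrix of pixel coordinates.
#' @export
project_point <- function(g, pt) {
  one <- is.null(dim(pt))
  if (one) pt <- matrix(pt, 1)
  n <- detector_normal(g)
  d <- sweep(pt, 2, g$source)                  # ray directions
  denom <- drop(d %*% n)
  if (any(abs(denom) < 1e-12))
    stop("projection degenerate: ray parallel to the detector plane (or point at source)")
  tnum <- sum((g$detector_origin - g$source) * n)
  x <- sweep(d, 1, tnum / denom, "*")
  x <- sweep(x, 2, g$source, "+")
  rel <- sweep(x, 2, g$detector_origin)
  uv <- cbind(drop(rel %*% g$u_axis), drop(rel %*% g$v_axis)) / g$pitch
  colnames(uv) <- c("u", "v")
  if (one) uv[1, ] else uv
}

#' CT volume container
#'
#' A 3D grid of CT numbers (HU) or attenuation values with anisotropic
#' spacing, anchored in the room frame.  `origin` is the world position of
#' the grid corner: the center of voxel `(i, j, k)` (0-based) is at
#' `origin + (i + 0.5, j + 0.5, k + 0.5) * spacing`.  By default the volume
#' is centered on the isocenter (origin = -extent / 2).
#'
#' @param values a 3D numeric array.
#' @param spacing voxel size `(sx, sy, sz)` in mm.
#' @param origin grid-corner world position in mm, or `NULL` to center the
#'   grid on the isocenter.
#' @return an object of class `ct_volume`.
#' @export
ct_volume <- function(values, spacing = c(1, 1, 1), origin = NULL) {
  if (length(dim(values)) != 3 || any(dim(values) == 0))
    stop("values must be a non-empty 3D array")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  if (is.null(origin)) origin <- -dim(values) * spacing / 2
  structure(list(values = values, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("CT volume %d x %d x %d, spacing (%s) mm, HU range [%g, %g]\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

# world position of the centers of voxels indexed 0-based along one axis
voxel_centers <- function(v, axis) {
  n <- dim(v$values)[axis]
  v$origin[axis] + (seq_len(n) - 0.5) * v$spacing[axis]
}
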