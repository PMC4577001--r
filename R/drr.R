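#' Calculation region of interest
#'
#' A half-open rectangle of detector pixels `[u_min, u_max) x [v_min, v_max)`
#' (0-based) to which DRR casting and similarity scoring are restricted.
#'
#' @param view view label the ROI belongs to.
#' @param u_min,v_min,u_max,v_max pixel bounds, half-open.
#' @return an object of class `calc_roi`.
#' @export
calc_roi <- function(view, u_min, v_min, u_max, v_max) {
  if (!(u_min < u_max && v_min < v_max))
    stop("empty roi: need u_min < u_max and v_min < v_max")
  structure(list(view = view,
                 rect = as.integer(c(u_min, v_min, u_max, v_max))),
            class = "calc_roi")
}

full_roi <- function(g) calc_roi(g$view, 0, 0, g$size[1], g$size[2])

clip_roi <- function(roi, g) {
  r <- pmin(pmax(roi$rect, c(0, 0, 0, 0)),
            c(g$size[1], g$size[2], g$size[1], g$size[2]))
  if (!(r[1] < r[3] && r[2] < r[4]))
    stop("empty roi: rectangle falls outside the detector")
  calc_roi(roi$view, r[1], r[2], r[3], r[4])
}

roi_npix <- function(roi) (roi$rect[3] - roi$rect[1]) * (roi$rect[4] - roi$rect[2])

#' Convert CT numbers to linear attenuation
#'
#' Applies the linear HU map `mu = mu_water * (1 + HU / 1000)`, clamped at
#' zero (air, -1000 HU, attenuates nothing), with an optional piecewise-linear
#' bone-emphasis weighting above `bone_hu`:
#' `mu = mu + bone_gain * mu_water * (HU - bone_hu) / 1000`.  The map is
#' monotone non-decreasing in HU for `bone_gain >= 0`.  The body surface is
#' segmented (see [segment_body()]) and its bounding box stored so the
#' projector only walks rays through the region that can attenuate.
#'
#' @param v a [ct_volume()] in HU.
#' @param mu_water attenuation of water, mm^-1 (default 0.02, typical of the
#'   mean imaging-beam energy).
#' @param bone_hu HU threshold above which the bone weighting starts, or
#'   `NULL` for the plain linear map.
#' @param bone_gain extra slope (per 1000 HU, in units of `mu_water`) above
#'   `bone_hu`; 0 is the identity weighting.
#' @param body segment the body and restrict the projector to its bounding
#'   box?  If `FALSE` the whole grid is used.
#' @param body_threshold HU threshold passed to [segment_body()].
#' @return an object of class `attenuation_volume`.
#' @export
hu_to_attenuation <- function(v, mu_water = 0.02, bone_hu = NULL,
                              bone_gain = 0, body = TRUE,
                              body_threshold = -300) {
  stopifnot(inherits(v, "ct_volume"))
  if (!all(is.finite(v$values))) stop("invalid volume: non-finite HU values")
  if (!(mu_water > 0)) stop("mu_water must be positive")
  mu <- pmax(0, mu_water * (1 + v$values / 1000))
  if (!is.null(bone_hu) && bone_gain != 0) {
    if (bone_gain < 0) stop("bone_gain must be non-negative")
    mu <- mu + bone_gain * mu_water * pmax(0, v$values - bone_hu) / 1000
  }
  dim(mu) <- dim(v$values)
  if (body) {
    mask <- segment_body(v, body_threshold)
  } else {
    mask <- array(TRUE, dim(v$values))
    attr(mask, "bbox") <- rbind(lo = c(0, 0, 0), hi = dim(v$values) - 1L)
  }
  structure(list(values = mu, spacing = v$spacing, origin = v$origin,
                 body_mask = mask, bbox = attr(mask, "bbox")),
            class = c("attenuation_volume", "ct_volume"))
}

#' Segment the patient body
#'
#' Thresholds the CT at `threshold_hu`, keeps the largest 6-connected
#' component and fills internal cavities (so air-filled lungs and sinuses
#' stay inside the body region).
#'
#' @param v a [ct_volume()] in HU.
#' @param threshold_hu body threshold (default -300 HU, between air and soft
#'   tissue).
#' @return a logical array with an attached `bbox` attribute: a 2 x 3 matrix
#'   of 0-based inclusive voxel index bounds of the mask.
#' @export
segment_body <- function(v, threshold_hu = -300) {
  stopifnot(inherits(v, "ct_volume"))
  m <- body_mask_cpp(as.numeric(v$values), dim(v$values), threshold_hu)
  dim(m) <- dim(v$values)
  idx <- which(m, arr.ind = TRUE)
  bbox <- rbind(lo = apply(idx, 2, min) - 1L, hi = apply(idx, 2, max) - 1L)
  colnames(bbox) <- NULL
  attr(m, "bbox") <- bbox
  m
}

# world-mm bounds (volume frame) of the body bounding box, expanded by one
# voxel so the support of trilinear interpolation from in-mask voxels is
# fully contained
bbox_world <- function(av) {
  lo <- av$origin + (av$bbox["lo", ] - 1) * av$spacing
  hi <- av$origin + (av$bbox["hi", ] + 2) * av$spacing
  list(lo = lo, hi = hi)
}

#' Cast a digitally reconstructed radiograph
#'
#' Integrates linear attenuation along the divergent rays from the source to
#' each detector pixel center inside the ROI, with the volume placed in the
#' room at `pose`.  Rays are walked with a uniform parametric step of
#' `step` mm (default half the smallest voxel spacing) using midpoint
#' quadrature and trilinear interpolation of the attenuation grid, visiting
#' only the body-mask bounding region.  Pixels outside the ROI are 0.
#'
#' @param av an [hu_to_attenuation()] result (or a `ct_volume` already in
#'   mm^-1, in which case the full grid is integrated).
#' @param g a [projection_geometry()].
#' @param pose the [rigid_pose()] of the volume in the room.
#' @param roi a [calc_roi()] or `NULL` for the full detector.
#' @param step quadrature step in mm.
#' @return a `size[1] x size[2]` matrix of line integrals (unitless,
#'   mm^-1 * mm), indexed `[u, v]`, with the pixel pitch attached as
#'   attribute `pitch`.
#' @export
cast_drr <- function(av, g, pose = rigid_pose(), roi = NULL, step = NULL) {
  if (!inherits(av, "attenuation_volume")) {
    stopifnot(inherits(av, "ct_volume"))
    av <- structure(list(values = av$values, spacing = av$spacing,
                         origin = av$origin,
                         bbox = rbind(lo = c(0, 0, 0),
                                      hi = dim(av$values) - 1L)),
                    class = c("attenuation_volume", "ct_volume"))
  }
  pose <- as_rigid_pose(pose)
  if (is.null(step)) step <- 0.5 * min(av$spacing)
  roi <- if (is.null(roi)) full_roi(g) else clip_roi(roi, g)
  tinv <- solve(pose_to_matrix(pose))
  bw <- bbox_world(av)
  img <- cast_drr_cpp(as.numeric(av$values), dim(av$values),
                      av$spacing, av$origin, bw$lo, bw$hi, tinv,
                      g$source, g$detector_origin, g$u_axis, g$v_axis,
                      g$pitch, g$size[1], g$size[2], roi$rect, step)
  attr(img, "pitch") <- g$pitch
  img
}

#' Automatic calculation ROI from a target region
#'
#' Projects the corner points of the 3D target region onto the detector,
#' takes the pixel bounding box and expands it by `margin_mm / pitch` pixels
#' on every side, clipped to the detector.
#'
#' @param target either an n x 3 matrix of room-frame points (mm), or a list
#'   `list(center =, radius =)` describing a spherical planning target
#'   volume whose axis-aligned bounding-box corners are used.
#' @param g a [projection_geometry()].
#' @param margin_mm expansion margin on the detector, mm (default 20).
#' @return a [calc_roi()].
#' @export
auto_roi <- function(target, g, margin_mm = 20) {
  if (is.list(target) && !is.null(target$center)) {
    ctr <- target$center; r <- target$radius
    sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
    target <- sweep(sgn * r, 2, ctr, "+")
  }
  target <- rbind(target)
  uv <- rbind(project_point(g, target))
  m <- margin_mm / g$pitch
  rect <- c(floor(min(uv[, 1]) - m), floor(min(uv[, 2]) - m),
            floor(max(uv[, 1]) + m) + 1, floor(max(uv[, 2]) + m) + 1)
  clip_roi(calc_roi(g$view, rect[1], rect[2], rect[3], rect[4]), g)
}

# Vectorized bilinear lookup on a matrix at continuous 0-based pixel-center
# coordinates; outside the support the image is 0.
bilinear_lookup <- function(img, x, y) {
  nx <- nrow(img); ny <- ncol(img)
  out <- numeric(length(x))
  ok <- x > -0.5 & y > -0.5 & x < nx - 0.5 & y < ny - 0.5
  if (any(ok)) {
    xs <- x[ok]; ys <- y[ok]
    i0 <- pmax(0, pmin(nx - 2, floor(xs)))
    j0 <- pmax(0, pmin(ny - 2, floor(ys)))
    fx <- pmin(1, pmax(0, xs - i0)); fy <- pmin(1, pmax(0, ys - j0))
    q <- i0 + 1 + nx * j0
    out[ok] <- (img[q]          * (1 - fx) + img[q + 1]      * fx) * (1 - fy) +
               (img[q + nx]     * (1 - fx) + img[q + nx + 1] * fx) * fy
  }
  out
}

#' In-plane shortcut update of a DRR
#'
#' Approximates the DRR at a nearby pose that differs only by an in-plane
#' motion: instead of re-casting rays, the existing image is rigidly
#' resampled (bilinear) -- translated by `(du, dv)` mm on the detector and
#' rotated by `dtheta` degrees about `center_px`.  The shortcut is refused
#' (a condition of class `drrreg_shortcut_refused` is signalled) when the
#' requested motion exceeds `limits`, in which case the caller must re-cast.
#'
#' @param img a DRR matrix indexed `[u, v]` with a `pitch` attribute (or
#'   pass `pitch`).
#' @param du,dv detector translation in mm.
#' @param dtheta in-plane rotation in degrees.
#' @param pitch pixel pitch in mm; defaults to `attr(img, "pitch")`.
#' @param center_px rotation center in continuous 0-based pixel coordinates;
#'   defaults to the image center.
#' @param limits `c(translation mm, rotation deg)` shortcut limits
#'   (default 5 mm, 1 deg).
#' @return the resampled image; out-of-support pixels are 0.
#' @export
in_plane_update <- function(img, du, dv, dtheta, pitch = attr(img, "pitch"),
                            center_px = NULL, limits = c(5, 1)) {
  if (is.null(pitch)) stop("pixel pitch unknown")
  if (max(abs(c(du, dv))) > limits[1] || abs(dtheta) > limits[2]) {
    cond <- structure(class = c("drrreg_shortcut_refused", "error", "condition"),
                      list(message = "in-plane shortcut refused: motion beyond limits",
                           call = sys.call()))
    stop(cond)
  }
  nx <- nrow(img); ny <- ncol(img)
  if (is.null(center_px)) center_px <- c((nx - 1) / 2, (ny - 1) / 2)
  if (du == 0 && dv == 0 && dtheta == 0) return(img)
  a <- dtheta * pi / 180; ca <- cos(a); sa <- sin(a)
  tu <- du / pitch; tv <- dv / pitch
  # output pixel (x,y) samples the input at R(-a) * (x - c - t) + c
  xo <- rep(seq_len(nx) - 1, ny) - center_px[1] - tu
  yo <- rep(seq_len(ny) - 1, each = nx) - center_px[2] - tv
  xi <- ca * xo + sa * yo + center_px[1]
  yi <- -sa * xo + ca * yo + center_px[2]
  out <- matrix(bilinear_lookup(img, xi, yi), nx, ny)
  attr(out, "pitch") <- pitch
  out
}
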