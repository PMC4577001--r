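#' Multi-resolution pyramid configuration
#'
#' Coarse-to-fine schedule: per stage, an integer CT downsampling factor
#' triplet, a DRR calculation-grid multiplier (the detector pitch is scaled
#' by it), a cost-decrease tolerance for the optimizer, and a line-search
#' tolerance in scaled (mm / degree) units.  The defaults are the clinical
#' three-level schedule: CT factors (3,3,3), (2,2,2), (1,1,1).
#'
#' @param factors list of integer triplets, non-increasing across stages,
#'   last stage `(1,1,1)`.
#' @param grid per-stage DRR grid multipliers (detector pitch scale).
#' @param tol per-stage relative cost tolerances.
#' @param line_tol per-stage Brent line-search tolerances (mm / deg).
#' @return an object of class `pyramid_config`.
#' @export
pyramid_config <- function(factors = list(c(3, 3, 3), c(2, 2, 2), c(1, 1, 1)),
                           grid = c(3, 2, 1),
                           tol = c(1e-3, 1e-4, 1e-5),
                           line_tol = c(0.1, 0.02, 0.002)) {
  ns <- length(factors)
  stopifnot(length(grid) == ns, length(tol) == ns, length(line_tol) == ns)
  fm <- do.call(rbind, lapply(factors, rep_len, 3))
  if (any(fm != round(fm)) || any(fm < 1))
    stop("downsampling factors must be positive integers")
  if (ns > 1 && any(apply(fm, 2, diff) > 0))
    stop("factors must be non-increasing across stages")
  if (any(fm[ns, ] != 1)) stop("last stage must be the original volume (1,1,1)")
  structure(list(factors = lapply(factors, function(f) as.integer(rep_len(f, 3))),
                 grid = grid, tol = tol, line_tol = line_tol),
            class = "pyramid_config")
}

# box-mean collapse of one array axis by integer group index
collapse_axis <- function(arr, ax, f) {
  d <- dim(arr)
  g <- (seq_len(d[ax]) - 1L) %/% f
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(arr, perm), d[ax])
  s <- rowsum(m, g)
  s <- s / as.vector(table(g))
  out <- array(s, c(nrow(s), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

downsample_mean <- function(arr, f) {
  for (ax in 1:3) if (f[ax] > 1) arr <- collapse_axis(arr, ax, f[ax])
  arr
}

#' Build the attenuation-volume pyramid
#'
#' Stage `k` is a box-mean downsampling of the original attenuation volume
#' by its factor triplet, with the spacing scaled accordingly (origin
#' unchanged, so world geometry is preserved).  The body mask is collapsed
#' by "any in-body voxel in the block" and the bounding box recomputed.
#' The last stage is the original volume.
#'
#' @param av an [hu_to_attenuation()] result.
#' @param cfg a [pyramid_config()].
#' @return a list of `attenuation_volume`s, coarse to fine.
#' @export
build_pyramid <- function(av, cfg = pyramid_config()) {
  stopifnot(inherits(av, "attenuation_volume"), inherits(cfg, "pyramid_config"))
  lapply(cfg$factors, function(f) {
    if (all(f == 1)) return(av)
    if (any(dim(av$values) < f))
      stop("degenerate pyramid: volume smaller than the downsampling factor")
    vals <- downsample_mean(av$values, f)
    mask <- downsample_mean(av$body_mask + 0, f) > 0
    idx <- which(mask, arr.ind = TRUE)
    bbox <- rbind(lo = apply(idx, 2, min) - 1L, hi = apply(idx, 2, max) - 1L)
    colnames(bbox) <- NULL
    structure(list(values = vals, spacing = av$spacing * f,
                   origin = av$origin, body_mask = mask, bbox = bbox),
              class = c("attenuation_volume", "ct_volume"))
  })
}

# detector geometry for one pyramid stage: pitch scaled by m, size divided,
# grid anchored at the detector corner so each coarse pixel covers exactly
# an m x m block of fine pixels (block centers coincide)
stage_geometry <- function(g, m) {
  if (m == 1) return(g)
  g$size <- as.integer(pmax(2L, g$size %/% as.integer(m)))
  g$pitch <- g$pitch * m
  g
}

# map a full-resolution ROI onto a corner-anchored stage grid
stage_roi <- function(roi, g_full, g_stage) {
  if (is.null(roi)) return(NULL)
  m <- g_stage$pitch / g_full$pitch
  lo <- floor(roi$rect[1:2] / m)
  hi <- ceiling(roi$rect[3:4] / m)
  clip_roi(calc_roi(roi$view, lo[1], lo[2], hi[1], hi[2]), g_stage)
}

# box-mean downsampling of a radiograph matrix by an integer factor
downsample_image <- function(img, m) {
  if (m == 1) return(img)
  n1 <- nrow(img) %/% m; n2 <- ncol(img) %/% m
  img <- img[seq_len(n1 * m), seq_len(n2 * m), drop = FALSE]
  g1 <- (seq_len(n1 * m) - 1L) %/% m
  out <- rowsum(img, g1) / m
  out <- t(rowsum(t(out), (seq_len(n2 * m) - 1L) %/% m) / m)
  dimnames(out) <- NULL
  out
}

# which pose parameters are in-plane for a view, and how they map to
# detector motion.  u/v are the detector axes; rot is the rotation whose
# axis is the view's ray direction.  rot_sign accounts for the handedness
# of (u, v, ray): the horizontal basis (Z, Y, X) is left-handed, so +psi
# appears as a clockwise (negative) image rotation.
view_inplane <- function(view) {
  switch(view,
         vertical   = list(tu = "tx", tv = "ty", rot = "theta", rot_sign = 1),
         horizontal = list(tu = "tz", tv = "ty", rot = "psi", rot_sign = -1),
         NULL)
}

# line-search caps in scaled units: translations may travel the full
# capture range (mm), rotations are kept within a plausible misalignment
# band (deg)
param_caps <- function(names) ifelse(names %in% c("tx", "ty", "tz"), 32, 8)

# free pose parameters a single view can estimate
view_free_params <- function(view) {
  switch(view,
         vertical   = c("tx", "ty", "theta", "phi"),
         horizontal = c("ty", "tz", "psi", "phi"),
         stop("per-view estimation requires an orthogonal vertical/horizontal pair"))
}

# Single-view cost closure with DRR caching and the in-plane shortcut.
# Casts the DRR on an ROI expanded far enough that in-plane resampling
# always has support, scores on the nominal ROI crop.
make_view_cost <- function(fpd_px, av, g, cfg, roi, shortcut = c(5, 1),
                           edge = NULL, step = NULL) {
  ip <- view_inplane(g$view)
  mag <- g$sid / g$sad
  roi <- if (is.null(roi)) full_roi(g) else roi
  # expansion covering the largest shortcut translation + rotation sweep
  center_px <- project_point(g, c(0, 0, 0)) - 0.5
  corners <- rbind(roi$rect[c(1, 2)], roi$rect[c(1, 4)],
                   roi$rect[c(3, 2)], roi$rect[c(3, 4)]) - 0.5
  reach <- max(sqrt(rowSums(sweep(corners, 2, center_px)^2)))
  pad <- ceiling(shortcut[1] * mag / g$pitch +
                 sin(shortcut[2] * pi / 180) * reach) + 2L
  if (!is.null(edge) && edge$strength > 0)
    pad <- pad + ceiling(3 * edge$sigma)
  roi_exp <- clip_roi(calc_roi(roi$view, roi$rect[1] - pad, roi$rect[2] - pad,
                               roi$rect[3] + pad, roi$rect[4] + pad), g)
  fpd_crop <- crop_roi(fpd_px, roi)

  env <- new.env(parent = emptyenv())
  env$base_pose <- NULL
  env$base_drr <- NULL
  env$recast <- 0L
  env$shortcut <- 0L

  score_img <- function(drr_full) {
    if (!is.null(edge) && edge$strength > 0)
      drr_full <- edge_enhance(drr_full, edge$strength, edge$sigma)
    combined_cost(list(list(a = fpd_crop, b = crop_roi(drr_full, roi),
                            roi = NULL)), cfg)
  }

  list(
    cost = function(pose) {
      pose <- as_rigid_pose(pose)
      use_shortcut <- FALSE
      if (!is.null(env$base_pose) && !is.null(ip)) {
        delta <- unclass(pose) - unclass(env$base_pose)
        oop <- setdiff(pose_names, c(ip$tu, ip$tv, ip$rot))
        use_shortcut <- all(abs(delta[oop]) < 1e-12) &&
          max(abs(delta[c(ip$tu, ip$tv)])) * mag <= shortcut[1] &&
          abs(delta[ip$rot]) <= shortcut[2]
      }
      if (use_shortcut) {
        env$shortcut <- env$shortcut + 1L
        img <- in_plane_update(env$base_drr,
                               du = delta[[ip$tu]] * mag,
                               dv = delta[[ip$tv]] * mag,
                               dtheta = ip$rot_sign * delta[[ip$rot]],
                               pitch = g$pitch, center_px = center_px,
                               limits = shortcut)
      } else {
        env$recast <- env$recast + 1L
        img <- cast_drr(av, g, pose, roi = roi_exp, step = step)
        env$base_pose <- pose
        env$base_drr <- img
      }
      score_img(img)
    },
    counts = function() c(recast = env$recast, shortcut = env$shortcut))
}

#' Estimate the pose parameters visible in one view
#'
#' Optimizes only the view's free parameters (vertical: `tx, ty, theta,
#' phi`; horizontal: `ty, tz, psi, phi` -- in-plane motion plus the shared
#' out-of-plane rotation) against that view's combined similarity cost,
#' holding the other components fixed.  Small in-plane trial moves reuse the
#' cached DRR through [in_plane_update()]; anything else re-casts.
#'
#' @param fpd processed stage radiograph (matrix or [radiograph()]).
#' @param av stage attenuation volume.
#' @param g stage [projection_geometry()].
#' @param pose0 current full pose.
#' @param free character vector of free parameter names; defaults to the
#'   view's natural set.
#' @param cfg a [metric_config()].
#' @param roi stage [calc_roi()] or `NULL`.
#' @param shortcut in-plane shortcut limits `c(mm, deg)`.
#' @param edge optional `list(strength, sigma)` applied to DRRs (matching
#'   the FPD preprocessing) when gradient-difference scoring is active.
#' @param tol,line_tol,max_iter optimizer settings ([powell_brent()]).
#' @param step DRR quadrature step, mm.
#' @return list with `pose` (updated full pose), `cost`, `counts`,
#'   `converged`.
#' @export
estimate_view_params <- function(fpd, av, g, pose0, free = NULL,
                                 cfg = metric_config(), roi = NULL,
                                 shortcut = c(5, 1), edge = NULL,
                                 tol = 1e-5, line_tol = 0.01,
                                 max_iter = 20, step = NULL) {
  if (inherits(fpd, "radiograph")) fpd <- fpd$pixels
  if (is.null(free)) free <- view_free_params(g$view)
  stopifnot(all(free %in% pose_names))
  pose0 <- as_rigid_pose(pose0)
  vc <- make_view_cost(fpd, av, g, cfg, roi, shortcut, edge, step)
  fn <- function(x) {
    p <- unclass(pose0)
    p[free] <- x
    vc$cost(as_rigid_pose(p))
  }
  res <- tryCatch(
    powell_brent(fn, unclass(pose0)[free], scales = rep(1, length(free)),
                 tol = tol, line_tol = line_tol, max_iter = max_iter,
                 max_step = param_caps(free)),
    error = function(e) stop("view estimation failed (", g$view, "): ",
                             conditionMessage(e)))
  p <- unclass(pose0)
  p[free] <- res$par
  list(pose = as_rigid_pose(p), cost = res$value, counts = vc$counts(),
       evals = res$counts, converged = res$converged)
}

#' Fuse the two per-view parameter estimates
#'
#' `tx` and `theta` come from the vertical view, `tz` and `psi` from the
#' horizontal view; the shared `ty` (couch axis) and `phi` estimates are
#' averaged between the views.
#'
#' @param vert,horiz full poses estimated from the vertical and horizontal
#'   views.
#' @return the fused [rigid_pose()].
#' @export
fuse_view_params <- function(vert, horiz) {
  if (missing(vert) || missing(horiz) || is.null(vert) || is.null(horiz))
    stop("fusion error: both view estimates are required ",
         "(single-view mode must be requested explicitly)")
  vert <- as_rigid_pose(vert); horiz <- as_rigid_pose(horiz)
  rigid_pose(tx = vert[["tx"]],
             ty = (vert[["ty"]] + horiz[["ty"]]) / 2,
             tz = horiz[["tz"]],
             psi = horiz[["psi"]],
             phi = (vert[["phi"]] + horiz[["phi"]]) / 2,
             theta = vert[["theta"]])
}

#' Register a CT volume to an orthogonal radiograph pair
#'
#' The main fitting function: estimates the rigid 6DOF pose of a CT volume
#' that best reproduces two orthogonal radiographs, by multi-resolution
#' Powell-Brent minimization of a DRR-based similarity cost.
#'
#' Per pyramid stage, `mode = "partitioned"` alternates per-view estimation
#' ([estimate_view_params()]) on the vertical and horizontal images and
#' fuses the overlapping parameters ([fuse_view_params()]) until the fused
#' update norm falls below `fusion_tol`; `mode = "joint"` optimizes all six
#' parameters on the summed two-view cost (required for non-orthogonal
#' custom view pairs).  Each stage's result seeds the next, finer stage.
#'
#' @param volume a [ct_volume()] in HU, or an [hu_to_attenuation()] result.
#' @param fpd_vertical,fpd_horizontal the two [radiograph()]s.  Raw-count
#'   images are preprocessed automatically ([preprocess_fpd()]); processed
#'   images are used as-is.
#' @param geometry list with `vertical` and `horizontal`
#'   [projection_geometry()]s; `NULL` derives defaults from the radiograph
#'   grids.
#' @param pose0 starting pose.
#' @param metrics a [metric_config()].
#' @param pyramid a [pyramid_config()].
#' @param mode `"partitioned"` (per-view parameter partition with Y/phi
#'   averaging) or `"joint"`.
#' @param roi list of per-view [calc_roi()]s (full-resolution pixels), or
#'   `NULL`.
#' @param ptv optional `list(center =, radius =)` spherical target; used to
#'   derive calculation ROIs via [auto_roi()] when `roi` is `NULL`.
#' @param roi_margin [auto_roi()] margin, mm.
#' @param mu_water,i0 intensity calibration for CT conversion and FPD
#'   preprocessing.
#' @param edge `list(strength =, sigma =)` unsharp-mask settings applied to
#'   the FPDs and DRRs; `NULL` enables the default (strength 1, sigma 2 px)
#'   when gradient-difference scoring is configured, otherwise none.
#' @param shortcut_limits in-plane shortcut limits `c(mm, deg)`.
#' @param max_alternations,fusion_tol partitioned-mode loop controls:
#'   maximum view alternations per stage and the `c(mm, deg)` fused-update
#'   threshold.
#' @param step DRR quadrature step in mm (`NULL`: half the stage voxel
#'   spacing).
#' @param verbose print per-stage progress?
#' @return an object of class `drr_registration`; see [coef.drr_registration()]
#'   and friends.
#' @seealso [run_accuracy_experiment()], [make_phantom()]
#' @export
drr_register <- function(volume, fpd_vertical, fpd_horizontal,
                         geometry = NULL, pose0 = rigid_pose(),
                         metrics = metric_config(),
                         pyramid = pyramid_config(),
                         mode = c("partitioned", "joint"),
                         roi = NULL, ptv = NULL, roi_margin = 20,
                         mu_water = 0.02, i0 = NULL, edge = NULL,
                         shortcut_limits = c(5, 1),
                         max_alternations = 10, fusion_tol = c(0.1, 0.1),
                         step = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  t_start <- proc.time()[["elapsed"]]
  cl <- match.call()
  pose0 <- as_rigid_pose(pose0)

  av <- if (inherits(volume, "attenuation_volume")) volume
        else hu_to_attenuation(volume, mu_water = mu_water)
  fpds <- list(vertical = fpd_vertical, horizontal = fpd_horizontal)
  if (is.null(geometry)) {
    geometry <- lapply(stats::setNames(nm = names(fpds)), function(vw)
      projection_geometry(vw, pitch = fpds[[vw]]$pitch,
                          size = dim(fpds[[vw]]$pixels)))
  }
  if (is.null(edge))
    edge <- list(strength = if ("gd" %in% metrics$metrics) 1 else 0,
                 sigma = 2)

  # preprocessing: resample onto the DRR grid + line-integral conversion
  # (edge enhancement is applied per resolution stage, below)
  fpds <- lapply(names(fpds), function(vw) {
    r <- fpds[[vw]]
    stopifnot(inherits(r, "radiograph"))
    if (!r$processed)
      r <- preprocess_fpd(r, target_pitch = geometry[[vw]]$pitch,
                          target_size = geometry[[vw]]$size, i0 = i0)
    r
  })
  names(fpds) <- c("vertical", "horizontal")

  rois <- roi
  if (is.null(rois) && !is.null(ptv))
    rois <- lapply(geometry, auto_roi, target = ptv, margin_mm = roi_margin)
  if (is.null(rois)) rois <- list(vertical = NULL, horizontal = NULL)

  vols <- build_pyramid(av, pyramid)
  pose <- pose0
  trace <- list()
  counts <- c(recast = 0L, shortcut = 0L)
  converged <- TRUE

  for (s in seq_along(vols)) {
    g_s <- lapply(geometry, stage_geometry, m = pyramid$grid[s])
    fpd_s <- lapply(names(fpds), function(vw) {
      px <- downsample_image(fpds[[vw]]$pixels, pyramid$grid[s])
      if (edge$strength > 0) px <- edge_enhance(px, edge$strength, edge$sigma)
      px
    })
    names(fpd_s) <- names(fpds)
    roi_s <- lapply(names(fpds), function(vw)
      stage_roi(rois[[vw]], geometry[[vw]], g_s[[vw]]))
    names(roi_s) <- names(fpds)

    # coarse stages see a slightly different (smoothed) cost surface and can
    # drift off an already-good pose; restart this stage from the original
    # start if that scores better under the stage's own cost
    if (s > 1 && !identical(unclass(pose), unclass(pose0))) {
      probe <- lapply(names(fpds), function(vw)
        make_view_cost(fpd_s[[vw]], vols[[s]], g_s[[vw]], metrics,
                       roi_s[[vw]], shortcut_limits, edge, step))
      stage_cost <- function(p)
        (probe[[1]]$cost(p) + probe[[2]]$cost(p)) / 2
      if (stage_cost(pose0) < stage_cost(pose)) pose <- pose0
    }

    if (mode == "partitioned") {
      for (alt in seq_len(max_alternations)) {
        est <- lapply(c("vertical", "horizontal"), function(vw)
          estimate_view_params(fpd_s[[vw]], vols[[s]], g_s[[vw]], pose,
                               cfg = metrics, roi = roi_s[[vw]],
                               shortcut = shortcut_limits, edge = edge,
                               tol = pyramid$tol[s],
                               line_tol = pyramid$line_tol[s], step = step))
        counts <- counts + est[[1]]$counts + est[[2]]$counts
        fused <- fuse_view_params(est[[1]]$pose, est[[2]]$pose)
        delta <- unclass(fused) - unclass(pose)
        pose <- fused
        cost <- (est[[1]]$cost + est[[2]]$cost) / 2
        trace[[length(trace) + 1]] <- data.frame(
          stage = s, iteration = alt, cost = cost,
          as.list(unclass(pose)), check.names = FALSE)
        if (verbose)
          message(sprintf("stage %d alt %d cost %.6g", s, alt, cost))
        if (max(abs(delta[1:3])) < fusion_tol[1] &&
            max(abs(delta[4:6])) < fusion_tol[2]) break
      }
      # coarse stages only initialize the next level; convergence is
      # judged on the finest stage's fused update
      if (s == length(vols) &&
          !(max(abs(delta[1:3])) < fusion_tol[1] &&
            max(abs(delta[4:6])) < fusion_tol[2]))
        converged <- FALSE
    } else {
      vcs <- lapply(c("vertical", "horizontal"), function(vw)
        make_view_cost(fpd_s[[vw]], vols[[s]], g_s[[vw]], metrics,
                       roi_s[[vw]], shortcut_limits, edge, step))
      fn <- function(x) {
        p <- as_rigid_pose(x)
        (vcs[[1]]$cost(p) + vcs[[2]]$cost(p)) / 2
      }
      res <- powell_brent(fn, unclass(pose), scales = rep(1, 6),
                          tol = pyramid$tol[s],
                          line_tol = pyramid$line_tol[s], max_iter = 30,
                          max_step = param_caps(pose_names))
      counts <- counts + vcs[[1]]$counts() + vcs[[2]]$counts()
      pose <- as_rigid_pose(res$par)
      converged <- converged && res$converged
      for (k in seq_along(res$trace))
        trace[[length(trace) + 1]] <- data.frame(
          stage = s, iteration = k - 1L, cost = res$trace[k],
          as.list(unclass(pose)), check.names = FALSE)
      if (verbose)
        message(sprintf("stage %d: %d sweeps, cost %.6g", s,
                        res$iterations, res$value))
    }
  }

  # final per-metric similarity scores at the fitted pose, finest stage
  final_scores <- lapply(stats::setNames(nm = metrics$metrics), function(m) {
    vapply(c("vertical", "horizontal"), function(vw) {
      drr <- cast_drr(vols[[length(vols)]], geometry[[vw]], pose,
                      roi = rois[[vw]], step = step)
      a <- fpds[[vw]]$pixels
      if (edge$strength > 0) {
        a <- edge_enhance(a, edge$strength, edge$sigma)
        drr <- edge_enhance(drr, edge$strength, edge$sigma)
      }
      switch(m,
             nmi = nmi(a, drr, bins = metrics$bins, roi = rois[[vw]]),
             gd = as.numeric(gradient_difference(a, drr, roi = rois[[vw]])),
             zncc = zncc(a, drr, roi = rois[[vw]]))
    }, numeric(1))
  })

  trace <- do.call(rbind, trace)
  structure(list(pose = pose, pose0 = pose0, converged = converged,
                 trace = trace, counts = counts, scores = final_scores,
                 mode = mode, metrics = metrics, pyramid = pyramid,
                 geometry = geometry, rois = rois, volume = av,
                 fpds = fpds, edge = edge,
                 runtime = proc.time()[["elapsed"]] - t_start, call = cl),
            class = "drr_registration")
}
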