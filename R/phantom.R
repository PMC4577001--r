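# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Parametric CT phantoms for head, pelvis and lung anatomy
#'
#' Deterministic (seeded) digital phantoms with air / soft-tissue / bone
#' intensity strata emulating the three anatomical sites:
#'
#' * `head`: an ellipsoidal bone shell (+700 HU skull) around soft tissue
#'   (+40 HU) with internal air cavities (-1000 HU sinuses/pharynx) and an
#'   off-axis jaw-like bone block;
#' * `pelvis`: a soft-tissue trunk with paired ring-like iliac bone
#'   structures, a posterior sacral block and femoral-head bone spheres;
#' * `lung`: a soft-tissue torso with two -800 HU lungs, rib-like bone
#'   arcs, a mediastinal soft column and a +50 HU tumor sphere at the
#'   planning-target site.
#'
#' Structure centers receive a small seeded jitter (up to 2 mm) so different
#' seeds give distinct but equally difficult instances.  All HU values lie
#' in [-1000, 2000].  The attached planning target (`ptv` attribute) seeds
#' automatic calculation ROIs.
#'
#' @param site `"head"`, `"pelvis"` or `"lung"`.
#' @param n grid size per axis (>= 32; default 128).
#' @param spacing isotropic voxel size, mm (default 2).
#' @param seed integer seed fixing all randomness.
#' @return a [ct_volume()] with attributes `ptv` (`list(center, radius)` in
#'   mm) and `site`.
#' @export
make_phantom <- function(site = c("head", "pelvis", "lung"), n = 128,
                         spacing = 2, seed = 1) {
  site <- match.arg(site)
  if (n < 32) stop("invalid spec: phantom grid must be at least 32^3")
  if (spacing <= 0) stop("invalid spec: spacing must be positive")
  ext <- n * spacing
  # voxel-center world coordinates, grid centered on the isocenter
  cw <- (seq_len(n) - 0.5) * spacing - ext / 2
  X <- array(cw, c(n, n, n))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  hu <- array(-1000, c(n, n, n))
  sphere <- function(c0, r) ((X - c0[1]) / r[1])^2 + ((Y - c0[2]) / r[2])^2 +
    ((Z - c0[3]) / r[3])^2 <= 1
  # ring (torus) of major radius R and tube radius r, axis along `axis`
  torus <- function(c0, R, r, axis = 3) {
    d <- list(X - c0[1], Y - c0[2], Z - c0[3])
    ax <- d[[axis]]; inpl <- d[-axis]
    (sqrt(inpl[[1]]^2 + inpl[[2]]^2) - R)^2 + ax^2 <= r^2
  }
  s <- ext / 256  # scale anatomy to the grid extent (nominal 256 mm)

  with_seed(seed, {
    j <- function() stats::runif(3, -2, 2)  # mm jitter on structure centers
    if (site == "head") {
      c0 <- j()
      outer_r <- s * c(72, 92, 82)
      hu[sphere(c0, outer_r)] <- 700                       # skull shell
      hu[sphere(c0, outer_r - 8)] <- 40                    # brain/soft tissue
      hu[sphere(c0 + s * c(0, 55, -20) + j(), s * c(14, 18, 12))] <- -1000
      hu[sphere(c0 + s * c(0, 40, -55) + j(), s * c(10, 16, 18))] <- -1000
      jaw <- sphere(c0 + s * c(0, 48, -62) + j(), s * c(34, 26, 12))
      hu[jaw & hu > -500] <- 700                           # jaw-like block
      ptv <- list(center = c0 + s * c(22, 20, -30), radius = s * 30)
    } else if (site == "pelvis") {
      c0 <- j()
      # supine trunk: long axis along the couch (Y), anterior is +Z
      hu[sphere(c0, s * c(115, 100, 75))] <- 30
      # pelvic ring: a stout torus about the couch axis, iliac wings
      # fanning out superiorly, femoral heads inferior-lateral
      hu[torus(c0 + s * c(0, -5, -8) + j(), s * 52, s * 11, axis = 2)] <- 700
      for (side in c(-1, 1)) {
        cc <- c0 + s * c(side * 46, 28, 5) + j()
        wing <- sphere(cc, s * c(38, 34, 32)) & !sphere(cc, s * c(28, 26, 24)) &
          (side * (X - c0[1]) > s * 18) & (Y - c0[2] > s * 5)
        hu[wing] <- 700                                    # iliac wings
        hu[sphere(c0 + s * c(side * 60, -52, -18) + j(),
                  s * c(15, 15, 15))] <- 700               # femoral heads
      }
      hu[sphere(c0 + s * c(0, 5, -42) + j(), s * c(18, 30, 18))] <- 700  # sacrum
      # lumbar vertebral column entering from the superior end
      hu[sphere(c0 + s * c(0, 80, -30) + j(), s * c(14, 55, 14))] <- 700
      ptv <- list(center = c0 + s * c(0, -8, -12), radius = s * 25)
    } else {
      c0 <- j()
      # supine thorax: long axis along the couch (Y)
      hu[sphere(c0, s * c(105, 110, 80))] <- 20            # torso
      lungL <- sphere(c0 + s * c(-46, 5, 8) + j(), s * c(38, 75, 52))
      lungR <- sphere(c0 + s * c(46, 5, 8) + j(), s * c(38, 75, 52))
      hu[lungL | lungR] <- -800                            # lungs
      # pulmonary vessel trees: soft-tissue strands radiating from each
      # hilum through the lung, the texture registration locks onto
      in_lung <- lungL | lungR
      for (side in c(-1, 1)) {
        hil <- c0 + s * c(side * 24, 5, 8)
        for (k in 1:9) {
          dir <- c(side * abs(stats::rnorm(1, 1, 0.3)), stats::rnorm(1, 0, 0.8),
                   stats::rnorm(1, 0, 0.8))
          dir <- dir / sqrt(sum(dir^2))
          len <- s * stats::runif(1, 40, 75)
          rad <- s * stats::runif(1, 1.8, 3.2)
          tt <- pmin(pmax((X - hil[1]) * dir[1] + (Y - hil[2]) * dir[2] +
                            (Z - hil[3]) * dir[3], 0), len)
          d2 <- (X - hil[1] - tt * dir[1])^2 + (Y - hil[2] - tt * dir[2])^2 +
            (Z - hil[3] - tt * dir[3])^2
          hu[d2 <= rad^2 & in_lung] <- -100
        }
      }
      # liver / diaphragm dome closing the inferior right hemithorax
      hu[sphere(c0 + s * c(35, -78, -8) + j(), s * c(58, 48, 55))] <- 60
      # axial rib rings, barrel-tapered toward both chest ends
      for (yk in c(-70, -40, -10, 20, 50, 80)) {
        Rk <- s * (82 - (yk - 5)^2 / 400)
        ring <- torus(c0 + c(0, s * yk, s * 5), Rk, s * 5, axis = 2) &
          abs(X - c0[1]) > s * 12
        hu[ring] <- 700
      }
      hu[sphere(c0 + s * c(0, 0, -55) + j(), s * c(13, 108, 13))] <- 700  # spine
      hu[sphere(c0 + s * c(0, 25, 72) + j(), s * c(10, 55, 8))] <- 700    # sternum
      hu[sphere(c0 + s * c(0, 0, 8), s * c(22, 100, 30))] <- 45  # mediastinum
      # lower-lobe tumor: the calculation ROI derived from it then spans
      # the diaphragm edge, the anchor thoracic registration relies on
      ptv <- list(center = c0 + s * c(50, -32, 8), radius = s * 15)
      hu[sphere(ptv$center, rep(ptv$radius, 3))] <- 50     # tumor
    }
  })
  hu <- pmin(pmax(hu, -1000), 2000)
  dim(hu) <- c(n, n, n)
  v <- ct_volume(hu, spacing = rep(spacing, 3))
  attr(v, "ptv") <- ptv
  attr(v, "site") <- site
  v
}

#' Default phantom-scale detector geometry
#'
#' The clinical source/detector arrangement with a desk-scale panel:
#' 256 x 256 pixels at 1.6 mm pitch (10x coarser than the clinical FPD),
#' keeping registrations fast while preserving the divergent-beam
#' magnification.
#'
#' @param view `"vertical"` or `"horizontal"`.
#' @param pitch,size detector overrides.
#' @return a [projection_geometry()].
#' @export
phantom_geometry <- function(view = c("vertical", "horizontal"),
                             pitch = 1.6, size = c(256, 256)) {
  projection_geometry(match.arg(view), pitch = pitch, size = size)
}

#' Synthesize a flat-panel radiograph from a CT volume
#'
#' Emulates an acquired FPD image: the DRR of the volume at `pose` is
#' converted to transmitted counts `i0 * exp(-DRR)`, perturbed by a
#' gain/offset/gamma intensity distortion, and degraded with seeded Poisson
#' and/or Gaussian noise.  With unit gain, zero offset, unit gamma and no
#' noise, [to_line_integral()] recovers the DRR exactly.
#'
#' @param v a [ct_volume()] (HU; converted internally) or attenuation
#'   volume.
#' @param g a [projection_geometry()].
#' @param pose the true [rigid_pose()] of the volume.
#' @param i0 unattenuated fluence, counts (> 0).
#' @param gain,offset,gamma intensity perturbation applied to the
#'   transmitted counts: `offset + gain * i0 * (counts / i0)^gamma`.
#' @param noise_sigma Gaussian noise standard deviation, counts.
#' @param poisson add Poisson counting noise?
#' @param seed integer seed for the noise.
#' @param mu_water attenuation calibration for HU input.
#' @return a raw-count [radiograph()] (floor-clipped at `1e-9 * i0` so the
#'   log conversion stays defined).
#' @export
synthesize_fpd <- function(v, g, pose = rigid_pose(), i0 = 1e4,
                           gain = 1, offset = 0, gamma = 1,
                           noise_sigma = 0, poisson = FALSE, seed = 1,
                           mu_water = 0.02) {
  if (!(i0 > 0)) stop("invalid spec: i0 must be positive")
  if (!inherits(v, "attenuation_volume"))
    v <- hu_to_attenuation(v, mu_water = mu_water)
  drr <- cast_drr(v, g, pose)
  counts <- i0 * exp(-drr)
  counts <- offset + gain * i0 * (counts / i0)^gamma
  if (poisson || noise_sigma > 0) {
    counts <- with_seed(seed, {
      if (poisson) counts[] <- stats::rpois(length(counts), pmax(counts, 0))
      if (noise_sigma > 0)
        counts <- counts + stats::rnorm(length(counts), sd = noise_sigma)
      counts
    })
  }
  counts <- pmax(counts, 1e-9 * i0)
  dim(counts) <- dim(drr)
  radiograph(counts, pitch = g$pitch, view = g$view)
}

#' Synthesize the orthogonal radiograph pair of a phantom
#'
#' Convenience wrapper: [synthesize_fpd()] for the vertical and horizontal
#' views with per-view sub-seeds derived from `seed`.
#'
#' @inheritParams synthesize_fpd
#' @param geometry list with `vertical` and `horizontal` geometries
#'   (default [phantom_geometry()] pair).
#' @param ... passed on to [synthesize_fpd()].
#' @return `list(vertical =, horizontal =)` of [radiograph()]s.
#' @export
synthesize_fpd_pair <- function(v, geometry = NULL, pose = rigid_pose(),
                                seed = 1, ...) {
  if (is.null(geometry))
    geometry <- list(vertical = phantom_geometry("vertical"),
                     horizontal = phantom_geometry("horizontal"))
  if (!inherits(v, "attenuation_volume")) v <- hu_to_attenuation(v)
  s <- (as.numeric(seed) * 2) %% (.Machine$integer.max - 2)
  list(vertical = synthesize_fpd(v, geometry$vertical, pose,
                                 seed = s + 1, ...),
       horizontal = synthesize_fpd(v, geometry$horizontal, pose,
                                   seed = s + 2, ...))
}
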