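# Independent reference implementations and shared fixtures.
# Heavy objects are built lazily and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- fn()
  .fixture_cache[[key]]
}

# trilinear sample with zero padding, written independently of the C++ path
oracle_trilinear <- function(vol, x, y, z) {
  nn <- dim(vol)
  if (x <= -1 || y <= -1 || z <= -1 ||
      x >= nn[1] || y >= nn[2] || z >= nn[3]) return(0)
  i <- floor(x); j <- floor(y); k <- floor(z)
  fx <- x - i; fy <- y - j; fz <- z - k
  val <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- i + di; jj <- j + dj; kk <- k + dk
    if (ii < 0 || jj < 0 || kk < 0 ||
        ii > nn[1] - 1 || jj > nn[2] - 1 || kk > nn[3] - 1) next
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
      (if (dk) fz else 1 - fz)
    val <- val + w * vol[ii + 1, jj + 1, kk + 1]
  }
  val
}

# vectorized trilinear (zero padding) at many points; columns of `idx` are
# the three voxel-center coordinates
oracle_trilinear_vec <- function(vol, idx) {
  nn <- dim(vol)
  i0 <- floor(idx)
  f <- idx - i0
  val <- numeric(nrow(idx))
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    ii <- i0[, 1] + di; jj <- i0[, 2] + dj; kk <- i0[, 3] + dk
    ok <- ii >= 0 & jj >= 0 & kk >= 0 &
      ii <= nn[1] - 1 & jj <= nn[2] - 1 & kk <= nn[3] - 1
    if (!any(ok)) next
    w <- (if (di) f[, 1] else 1 - f[, 1]) *
      (if (dj) f[, 2] else 1 - f[, 2]) *
      (if (dk) f[, 3] else 1 - f[, 3])
    val[ok] <- val[ok] +
      w[ok] * vol[cbind(ii[ok], jj[ok], kk[ok]) + 1]
  }
  val
}

# brute-force line integral: fixed 0.05-voxel midpoint quadrature from the
# source to each pixel center
oracle_drr <- function(v, g, step_voxel = 0.05) {
  step <- step_voxel * min(v$spacing)
  out <- matrix(0, g$size[1], g$size[2])
  for (u in seq_len(g$size[1]) - 1) {
    for (vv in seq_len(g$size[2]) - 1) {
      p <- g$detector_origin + (u + 0.5) * g$pitch * g$u_axis +
        (vv + 0.5) * g$pitch * g$v_axis
      d <- p - g$source
      L <- sqrt(sum(d^2)); dir <- d / L
      nst <- ceiling(L / step); h <- L / nst
      t <- (seq_len(nst) - 0.5) * h
      q <- cbind(g$source[1] + t * dir[1], g$source[2] + t * dir[2],
                 g$source[3] + t * dir[3])
      idx <- sweep(sweep(q, 2, v$origin), 2, v$spacing, "/") - 0.5
      out[u + 1, vv + 1] <- sum(oracle_trilinear_vec(v$values, idx)) * h
    }
  }
  out
}

# joint-histogram NMI computed the long way (explicit double loop)
oracle_nmi <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  joint <- matrix(0, bins, bins)
  for (q in seq_along(a)) {
    ia <- min(bins, 1 + floor((a[q] - ra[1]) / (ra[2] - ra[1]) * bins))
    ib <- min(bins, 1 + floor((b[q] - rb[1]) / (rb[2] - rb[1]) * bins))
    joint[ia, ib] <- joint[ia, ib] + 1
  }
  joint <- joint / length(a)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (ent(rowSums(joint)) + ent(colSums(joint))) / ent(joint)
}

# gradient-difference score by dense grid search over the scale s
oracle_gd <- function(a, b, s_grid = seq(0.1, 10, by = 1e-3)) {
  n <- nrow(a); m <- ncol(a)
  iu <- pmin(seq_len(n) + 1, n); id <- pmax(seq_len(n) - 1, 1)
  ju <- pmin(seq_len(m) + 1, m); jd <- pmax(seq_len(m) - 1, 1)
  gau <- (a[iu, ] - a[id, ]) / 2; gav <- (a[, ju] - a[, jd]) / 2
  gbu <- (b[iu, ] - b[id, ]) / 2; gbv <- (b[, ju] - b[, jd]) / 2
  Au <- stats::var(as.numeric(gau)); Av <- stats::var(as.numeric(gav))
  sc <- function(s) sum(Au / (Au + (gau - s * gbu)^2)) +
    sum(Av / (Av + (gav - s * gbv)^2))
  best <- s_grid[which.max(vapply(s_grid, sc, numeric(1)))]
  fine <- seq(best - 2e-3, best + 2e-3, by = 1e-6)
  max(vapply(fine, sc, numeric(1)))
}

# 6-connected flood fill used as the segmentation oracle
oracle_fill <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nbs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  cur <- 0L
  for (seed in which(mask)) {
    if (lab[seed] != 0L) next
    cur <- cur + 1L
    queue <- seed
    lab[seed] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]; queue <- queue[-length(queue)]
      k <- (q - 1) %/% (d[1] * d[2])
      j <- ((q - 1) %% (d[1] * d[2])) %/% d[1]
      i <- (q - 1) %% d[1]
      for (t in seq_len(6)) {
        ii <- i + nbs[t, 1]; jj <- j + nbs[t, 2]; kk <- k + nbs[t, 3]
        if (ii < 0 || jj < 0 || kk < 0 ||
            ii >= d[1] || jj >= d[2] || kk >= d[3]) next
        qq <- ii + d[1] * jj + d[1] * d[2] * kk + 1
        if (mask[qq] && lab[qq] == 0L) { lab[qq] <- cur; queue <- c(queue, qq) }
      }
    }
  }
  lab
}

# shared small fixtures ------------------------------------------------------

head64 <- function() cached("head64", function()
  make_phantom("head", n = 64, spacing = 4, seed = 11))

head64_fpds <- function() cached("head64_fpds", function()
  synthesize_fpd_pair(head64(), seed = 11))

head64_av <- function() cached("head64_av", function()
  hu_to_attenuation(head64()))

# processed radiographs that are exactly the DRRs of the phantom at a pose
self_consistent_fpds <- function(av, geometry, pose = rigid_pose()) {
  lapply(geometry, function(g) {
    drr <- cast_drr(av, g, pose)
    radiograph(unclass(drr)[, , drop = FALSE], g$pitch, g$view,
               processed = TRUE)
  })
}

phantom_geom_pair <- function(size = c(256, 256), pitch = 1.6) {
  list(vertical = phantom_geometry("vertical", pitch = pitch, size = size),
       horizontal = phantom_geometry("horizontal", pitch = pitch, size = size))
}

# full-protocol fixtures: 128^3 phantoms at the 256 x 256 / 1.6 mm phantom
# detector, perturbed start (20, 20, 20) mm / (2, 2, 2) deg
acc_phantom <- function(site) cached(paste0("acc_ph_", site), function()
  make_phantom(site, n = 128, spacing = 2, seed = 7))

acc_fit <- function(site, metrics, noise = 0, margin = 20) {
  key <- paste("acc_fit", site, paste(metrics, collapse = ""), noise, margin,
               sep = "_")
  cached(key, function() {
    ph <- acc_phantom(site)
    fp <- cached(paste0("acc_fp_", site, "_", noise), function()
      synthesize_fpd_pair(ph, seed = 7, noise_sigma = noise * 1e4))
    drr_register(ph, fp$vertical, fp$horizontal,
                 pose0 = rigid_pose(20, 20, 20, 2, 2, 2),
                 metrics = metric_config(metrics), ptv = attr(ph, "ptv"),
                 roi_margin = margin)
  })
}
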