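#' 2D radiograph container
#'
#' One acquired (or synthesized) flat-panel detector image.  Pixels are
#' stored `[u, v]` with the same detector axis conventions as the DRR
#' projector.  `processed = TRUE` marks an image that has been brought onto
#' the DRR grid and line-integral intensity scale.
#'
#' @param pixels a numeric matrix, raw counts or line-integral units.
#' @param pitch pixel pitch in mm.
#' @param view view label (`"vertical"`, `"horizontal"`, ...).
#' @param processed has the preprocessing pipeline been applied?
#' @return an object of class `radiograph`.
#' @export
radiograph <- function(pixels, pitch, view = "custom", processed = FALSE) {
  if (!is.matrix(pixels) || !all(is.finite(pixels)))
    stop("invalid input: pixels must be a finite numeric matrix")
  if (!(pitch > 0)) stop("pitch must be positive")
  structure(list(pixels = pixels, pitch = pitch, view = view,
                 processed = isTRUE(processed)),
            class = "radiograph")
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf("radiograph [%s] %d x %d px @ %g mm%s\n", x$view,
              nrow(x$pixels), ncol(x$pixels), x$pitch,
              if (x$processed) " (processed)" else ""))
  invisible(x)
}

#' Resample a radiograph onto the DRR pixel grid
#'
#' Bilinear resampling onto a lattice of `target_size` pixels at
#' `target_pitch`, with the detector centers of the two grids aligned.
#' Sampling positions outside the source image clamp to the border pixel.
#'
#' @param r a [radiograph()].
#' @param target_pitch output pitch, mm.
#' @param target_size output size in pixels `(nu, nv)`.
#' @return a resampled [radiograph()].
#' @export
resample_to_drr_grid <- function(r, target_pitch, target_size) {
  stopifnot(inherits(r, "radiograph"))
  if (!(target_pitch > 0)) stop("target_pitch must be positive")
  src <- r$pixels
  if (length(src) == 0) stop("invalid input: empty image")
  nu <- target_size[1]; nv <- target_size[2]
  if (nu == nrow(src) && nv == ncol(src) && target_pitch == r$pitch)
    return(radiograph(src, target_pitch, r$view, r$processed))
  # center-aligned mapping in mm, then clamp to the source support
  u_mm <- (seq_len(nu) - 1 - (nu - 1) / 2) * target_pitch
  v_mm <- (seq_len(nv) - 1 - (nv - 1) / 2) * target_pitch
  xi <- u_mm / r$pitch + (nrow(src) - 1) / 2
  yi <- v_mm / r$pitch + (ncol(src) - 1) / 2
  xi <- pmin(pmax(xi, 0), nrow(src) - 1)
  yi <- pmin(pmax(yi, 0), ncol(src) - 1)
  x <- rep(xi, length(yi)); y <- rep(yi, each = length(xi))
  out <- matrix(bilinear_lookup(src, x, y), nu, nv)
  radiograph(out, target_pitch, r$view, r$processed)
}

#' Convert transmitted counts to attenuation line integrals
#'
#' Beer-Lambert inversion `out = log(i0 / pixels)`, clipped at 0, so a
#' radiograph lands on the same scale as a DRR (a sum of attenuation along
#' each ray).  Air regions, where the detector sees the unattenuated
#' fluence, map to ~0.
#'
#' @param r a [radiograph()] in raw counts.
#' @param i0 unattenuated fluence in counts; `NULL` auto-estimates it as the
#'   median of the brightest 5 percent of pixels (the air region).
#' @return a [radiograph()] in line-integral units.
#' @export
to_line_integral <- function(r, i0 = NULL) {
  stopifnot(inherits(r, "radiograph"))
  px <- r$pixels
  if (any(px <= 0))
    stop("invalid intensity: non-positive pixels cannot be log-converted")
  if (is.null(i0))
    i0 <- stats::median(px[px >= stats::quantile(px, 0.95)])
  out <- pmax(0, log(i0 / px))
  dim(out) <- dim(px)
  radiograph(out, r$pitch, r$view, r$processed)
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicate padding, exact direct convolution.
gaussian_blur <- function(img, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  blur1 <- function(m) {      # along rows (first index)
    n <- nrow(m)
    idx <- function(s) pmin(pmax(seq_len(n) + s, 1L), n)
    out <- 0
    for (s in -r:r) out <- out + k[s + r + 1] * m[idx(s), , drop = FALSE]
    out
  }
  t(blur1(t(blur1(img))))
}

#' Edge enhancement by unsharp masking
#'
#' `out = in + strength * (in - gaussian_blur(in, sigma))`.  Emphasizes bone
#' edges before gradient-based similarity scoring; `strength = 0` is the
#' identity.
#'
#' @param r a [radiograph()] or plain matrix.
#' @param strength unsharp gain, >= 0.
#' @param sigma Gaussian kernel width in pixels.
#' @return same type as the input.
#' @export
edge_enhance <- function(r, strength = 1, sigma = 2) {
  if (strength < 0) stop("strength must be non-negative")
  if (inherits(r, "radiograph")) {
    r$pixels <- edge_enhance(r$pixels, strength, sigma)
    return(r)
  }
  if (strength == 0) return(r)
  out <- r + strength * (r - gaussian_blur(r, sigma))
  attributes(out) <- attributes(r)
  out
}

#' Full FPD preprocessing pipeline
#'
#' Applies, in this fixed order: resampling onto the DRR grid,
#' line-integral conversion, and (optionally) edge enhancement.  The same
#' pipeline is applied to both views; when edge enhancement is used for
#' gradient-difference scoring, the registration driver applies the same
#' operator to the DRRs so both images see it.
#'
#' @param r a raw-count [radiograph()].
#' @param target_pitch,target_size DRR grid to resample onto; `NULL` keeps
#'   the acquired grid.
#' @param i0 see [to_line_integral()].
#' @param edge_strength,edge_sigma see [edge_enhance()]; `edge_strength = 0`
#'   skips enhancement.
#' @return a processed [radiograph()] (`processed = TRUE`).
#' @export
preprocess_fpd <- function(r, target_pitch = NULL, target_size = NULL,
                           i0 = NULL, edge_strength = 0, edge_sigma = 2) {
  stopifnot(inherits(r, "radiograph"))
  if (!is.null(target_pitch))
    r <- resample_to_drr_grid(r, target_pitch,
                              if (is.null(target_size)) dim(r$pixels)
                              else target_size)
  r <- to_line_integral(r, i0)
  if (edge_strength > 0) r <- edge_enhance(r, edge_strength, edge_sigma)
  r$processed <- TRUE
  r
}
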