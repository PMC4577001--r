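#' Similarity metric configuration
#'
#' Which similarity measures score a DRR/FPD pair, how they are weighted in
#' the combined cost, and the joint-histogram size for NMI.  Weights default
#' to equal shares and must be non-negative and sum to 1.
#'
#' @param metrics subset of `c("nmi", "gd", "zncc")`.
#' @param weights one weight per metric; `NULL` for equal weights.
#' @param bins NMI histogram bins per image (default 64, used at every
#'   resolution stage).
#' @return an object of class `metric_config`.
#' @export
metric_config <- function(metrics = c("zncc", "gd"), weights = NULL,
                          bins = 64) {
  metrics <- match.arg(tolower(metrics), c("nmi", "gd", "zncc"),
                       several.ok = TRUE)
  if (anyDuplicated(metrics)) stop("duplicate metrics")
  if (is.null(weights)) weights <- rep(1 / length(metrics), length(metrics))
  if (length(weights) != length(metrics) || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-12)
    stop("weights must be non-negative and sum to 1")
  if (bins < 2) stop("need at least 2 histogram bins")
  structure(list(metrics = metrics, weights = as.numeric(weights),
                 bins = as.integer(bins)),
            class = "metric_config")
}

#' @export
print.metric_config <- function(x, ...) {
  cat(sprintf("metrics: %s (weights %s), %d bins\n",
              paste(toupper(x$metrics), collapse = " + "),
              paste(signif(x$weights, 3), collapse = "/"), x$bins))
  invisible(x)
}

# crop an image (or radiograph) to a calc_roi / rectangle; NULL roi = whole
crop_roi <- function(img, roi) {
  if (inherits(img, "radiograph")) img <- img$pixels
  if (is.null(roi)) return(img)
  r <- if (inherits(roi, "calc_roi")) roi$rect else as.integer(roi)
  img[(r[1] + 1):r[3], (r[2] + 1):r[4], drop = FALSE]
}

#' Normalized mutual information
#'
#' Entropy-based similarity `(H(A) + H(B)) / H(A, B)` from a joint histogram
#' of `bins^2` equal-width bins spanning each image's ROI min-max range;
#' `0 * log 0` counts as 0.  Identical (non-constant) images score exactly 2;
#' independent images approach 1.
#'
#' @param a,b images of the same shape (matrices or [radiograph()]s).
#' @param bins histogram bins per image.
#' @param roi optional [calc_roi()] restricting the computation.
#' @return a score in `[1, 2]`.
#' @export
nmi <- function(a, b, bins = 64, roi = NULL) {
  a <- crop_roi(a, roi); b <- crop_roi(b, roi)
  stopifnot(all(dim(a) == dim(b)))
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2])
    stop("degenerate histogram: constant image inside the ROI")
  ia <- pmin(bins, 1L + floor((a - ra[1]) / (ra[2] - ra[1]) * bins))
  ib <- pmin(bins, 1L + floor((b - rb[1]) / (rb[2] - rb[1]) * bins))
  joint <- tabulate(ia + bins * (ib - 1L), nbins = bins * bins) / length(a)
  pj <- joint[joint > 0]
  pa <- tabulate(ia, nbins = bins) / length(a); pa <- pa[pa > 0]
  pb <- tabulate(ib, nbins = bins) / length(b); pb <- pb[pb > 0]
  (-sum(pa * log(pa)) - sum(pb * log(pb))) / -sum(pj * log(pj))
}

# central-difference derivative images along the two pixel axes,
# replicate edges (same size as the input)
gradient_images <- function(img) {
  n <- nrow(img); m <- ncol(img)
  iu <- pmin(seq_len(n) + 1, n); id <- pmax(seq_len(n) - 1, 1)
  ju <- pmin(seq_len(m) + 1, m); jd <- pmax(seq_len(m) - 1, 1)
  list(du = (img[iu, , drop = FALSE] - img[id, , drop = FALSE]) / 2,
       dv = (img[, ju, drop = FALSE] - img[, jd, drop = FALSE]) / 2)
}

gd_score_at_s <- function(ga, gb, Au, Av, s) {
  sum(Au / (Au + (ga$du - s * gb$du)^2)) +
    sum(Av / (Av + (ga$dv - s * gb$dv)^2))
}

#' Gradient difference similarity
#'
#' Derivative-image similarity: with derivative images of `a` and `b` along
#' the two pixel axes and an intensity scale `s` applied to `b`'s gradients,
#' the score is `sum Au / (Au + (dAu - s dBu)^2) + sum Av / (Av + (dAv - s
#' dBv)^2)` where `Au`, `Av` are the variances of the respective gradient
#' images of `a` inside the ROI.  `s` is optimized over `s_range` by Brent /
#' golden-section search.  The score is maximal (`2 * number of ROI pixels`)
#' for identical images and, because only derivatives enter, invariant to
#' constant intensity offsets.  Asymmetric in `(a, b)`: `a` supplies the
#' normalizing variances.
#'
#' @param a,b images of the same shape.
#' @param roi optional [calc_roi()].
#' @param s_range search interval for the gradient scale `s`.
#' @return the score at the optimized scale (higher = more similar), with
#'   the scale attached as attribute `s`.
#' @export
gradient_difference <- function(a, b, roi = NULL, s_range = c(0.1, 10)) {
  a <- crop_roi(a, roi); b <- crop_roi(b, roi)
  stopifnot(all(dim(a) == dim(b)))
  ga <- gradient_images(a); gb <- gradient_images(b)
  Au <- stats::var(as.numeric(ga$du)); Av <- stats::var(as.numeric(ga$dv))
  if (!is.finite(Au) || !is.finite(Av) || Au == 0 || Av == 0)
    stop("degenerate gradient: flat image inside the ROI")
  opt <- stats::optimize(function(s) gd_score_at_s(ga, gb, Au, Av, s),
                         s_range, maximum = TRUE, tol = 1e-8)
  structure(opt$objective, s = opt$maximum)
}

#' Zero-mean normalized cross-correlation
#'
#' Pearson correlation of the ROI pixels of the two images: invariant to
#' affine intensity rescaling with positive gain; -1 for anti-correlated
#' images.
#'
#' @param a,b images of the same shape.
#' @param roi optional [calc_roi()].
#' @return a score in `[-1, 1]`.
#' @export
zncc <- function(a, b, roi = NULL) {
  a <- crop_roi(a, roi); b <- crop_roi(b, roi)
  stopifnot(all(dim(a) == dim(b)))
  sa <- stats::sd(a); sb <- stats::sd(b)
  if (!is.finite(sa) || !is.finite(sb) || sa == 0 || sb == 0)
    stop("degenerate: constant image inside the ROI")
  stats::cor(as.numeric(a), as.numeric(b))
}

# normalized dissimilarity in [0, 1] for one metric on one image pair
metric_dissim <- function(metric, a, b, roi, bins) {
  switch(metric,
         nmi  = 2 - nmi(a, b, bins = bins, roi = roi),
         zncc = (1 - zncc(a, b, roi = roi)) / 2,
         gd   = {
           np <- if (is.null(roi)) length(crop_roi(a, NULL)) else roi_npix(roi)
           1 - as.numeric(gradient_difference(a, b, roi = roi)) / (2 * np)
         },
         stop("unknown metric: ", metric))
}

#' Combined two-view registration cost
#'
#' Maps every configured metric to a normalized dissimilarity in `[0, 1]`
#' (NMI: `2 - NMI`; ZNCC: `(1 - ZNCC) / 2`; GD: `1 - GD / (2 * ROI
#' pixels)`), averages each over the views, and returns the weighted sum.
#' Lower is better; identical image pairs cost 0 under any weights.
#'
#' @param views a list of views, each `list(a =, b =, roi =)` where `a` is
#'   the reference (FPD) image, `b` the DRR and `roi` an optional
#'   [calc_roi()].
#' @param cfg a [metric_config()].
#' @return a unitless cost (lower = better).
#' @export
combined_cost <- function(views, cfg = metric_config()) {
  stopifnot(inherits(cfg, "metric_config"), length(views) >= 1)
  per_metric <- vapply(cfg$metrics, function(m) {
    mean(vapply(views, function(v)
      metric_dissim(m, v$a, v$b, v$roi, cfg$bins), numeric(1)))
  }, numeric(1))
  sum(cfg$weights * per_metric)
}
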