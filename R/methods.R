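#' @export
print.drr_registration <- function(x, digits = 4, ...) {
  cat("2D/3D rigid registration (", x$mode, " mode, ",
      paste(toupper(x$metrics$metrics), collapse = " + "), ")\n", sep = "")
  cat("fitted ")
  print(x$pose, digits = digits)
  cat(sprintf("converged: %s | DRR casts: %d, in-plane shortcuts: %d | %.1f s\n",
              x$converged, x$counts[["recast"]], x$counts[["shortcut"]],
              x$runtime))
  invisible(x)
}

#' Extract the fitted pose parameters
#'
#' @param object a [drr_register()] result.
#' @param ... unused.
#' @return named numeric vector `(tx, ty, tz, psi, phi, theta)` in mm / deg.
#' @export
coef.drr_registration <- function(object, ...) {
  stats::setNames(as.numeric(object$pose), pose_names)
}

#' @export
summary.drr_registration <- function(object, ...) {
  st <- lapply(split(object$trace, object$trace$stage), function(d)
    data.frame(stage = d$stage[1], iterations = nrow(d),
               final_cost = d$cost[nrow(d)]))
  out <- list(pose = coef(object), stages = do.call(rbind, st),
              scores = object$scores, converged = object$converged,
              mode = object$mode, runtime = object$runtime)
  class(out) <- "summary.drr_registration"
  out
}

#' @export
print.summary.drr_registration <- function(x, digits = 4, ...) {
  cat("2D/3D rigid registration summary (", x$mode, " mode)\n", sep = "")
  cat("\nFitted pose (mm / deg):\n")
  print(signif(x$pose, digits))
  cat("\nPer-stage optimization:\n")
  print(x$stages, row.names = FALSE)
  cat("\nFinal similarity scores (vertical, horizontal):\n")
  for (m in names(x$scores))
    cat(sprintf("  %-5s %s\n", toupper(m),
                paste(signif(x$scores[[m]], digits), collapse = ", ")))
  cat(sprintf("\nconverged: %s | %.1f s\n", x$converged, x$runtime))
  invisible(x)
}

#' DRR at the fitted pose
#'
#' `predict()` re-casts the DRR of the registered volume for one view at
#' the fitted (or any supplied) pose.
#'
#' @param object a [drr_register()] result.
#' @param view `"vertical"` or `"horizontal"`.
#' @param pose pose to project at; defaults to the fitted pose.
#' @param ... unused.
#' @return a DRR matrix (line-integral units).
#' @export
predict.drr_registration <- function(object,
                                     view = c("vertical", "horizontal"),
                                     pose = object$pose, ...) {
  view <- match.arg(view)
  cast_drr(object$volume, object$geometry[[view]], pose,
           roi = object$rois[[view]])
}

#' Residual images of a registration
#'
#' Per-view difference between the processed radiograph and the DRR at the
#' fitted pose, inside the calculation ROI.
#'
#' @param object a [drr_register()] result.
#' @param ... unused.
#' @return list of two matrices (`vertical`, `horizontal`).
#' @export
residuals.drr_registration <- function(object, ...) {
  lapply(stats::setNames(nm = c("vertical", "horizontal")), function(vw) {
    drr <- predict(object, vw)
    crop_roi(object$fpds[[vw]]$pixels, object$rois[[vw]]) -
      crop_roi(drr, object$rois[[vw]])
  })
}

#' Plot the optimization trace
#'
#' Cost against cumulative iteration, one panel line per pyramid stage.
#'
#' @param x a [drr_register()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.drr_registration <- function(x, ...) {
  tr <- x$trace
  graphics::plot(seq_len(nrow(tr)), tr$cost, type = "b",
                 col = tr$stage, pch = 16,
                 xlab = "accepted iteration", ylab = "combined cost", ...)
  graphics::legend("topright", legend = paste("stage", unique(tr$stage)),
                   col = unique(tr$stage), pch = 16, bty = "n")
  invisible(x)
}
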