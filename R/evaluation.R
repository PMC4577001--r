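#' Pose error, TRE and AE
#'
#' Componentwise registration error after subtracting the registration
#' offset: `delta = (estimated - offset) - truth`, with the target
#' registration error `TRE = sqrt(dx^2 + dy^2 + dz^2)` (mm) and angular
#' error `AE = sqrt(dpsi^2 + dphi^2 + dtheta^2)` (degrees).  Rotations are
#' differenced per-axis in the degree parameterization, which is valid for
#' the small (about 2 degrees) misalignments this protocol evaluates.
#'
#' @param estimated,truth [rigid_pose()]s.
#' @param offset the registration offset pose subtracted from the estimate
#'   (the residual found when registering the unperturbed setup).
#' @return an object of class `pose_error` with fields `delta` (named
#'   6-vector), `tre` (mm) and `ae` (deg).
#' @export
pose_error <- function(estimated, truth = rigid_pose(),
                       offset = rigid_pose()) {
  d <- (unclass(as_rigid_pose(estimated)) - unclass(as_rigid_pose(offset))) -
    unclass(as_rigid_pose(truth))
  structure(list(delta = d,
                 tre = sqrt(sum(d[1:3]^2)),
                 ae = sqrt(sum(d[4:6]^2))),
            class = "pose_error")
}

#' @export
print.pose_error <- function(x, digits = 4, ...) {
  cat(sprintf("TRE = %.3f mm, AE = %.3f deg\n", x$tre, x$ae))
  cat(sprintf("  delta t = (%s) mm, delta r = (%s) deg\n",
              paste(signif(x$delta[1:3], digits), collapse = ", "),
              paste(signif(x$delta[4:6], digits), collapse = ", ")))
  invisible(x)
}

#' Registration accuracy experiment
#'
#' The evaluation protocol: (1) register the unperturbed setup to obtain
#' the registration offset; (2) displace the starting pose by
#' `perturbation` (default the protocol's (20, 20, 20) mm, (2, 2, 2) deg);
#' (3) register again; (4) subtract the offset and report per-run and
#' mean +/- SD TRE / AE for every metric configuration.  Repeats redraw the
#' radiograph noise with seeds derived from `seed` when `fpds` is a
#' generating function.
#'
#' @param volume a [ct_volume()] (HU) or attenuation volume.
#' @param fpds either `list(vertical =, horizontal =)` of [radiograph()]s,
#'   or a `function(seed)` returning such a list (for seeded noise
#'   redraws).
#' @param metric_sets named list of [metric_config()]s to compare.
#' @param perturbation a [rigid_pose()]: the starting-pose displacement.
#' @param n_repeats runs per metric set.
#' @param seed integer; fixes all noise redraws.
#' @param truth the true pose of the volume (defaults to identity).
#' @param ... further arguments passed to [drr_register()] (geometry, ptv,
#'   pyramid, mode, ...).
#' @return an object of class `drr_experiment`: a list with `runs` (one row
#'   per registration) and `summary` (mean +/- SD per metric set; rows that
#'   failed to converge are excluded and counted).
#' @export
run_accuracy_experiment <- function(volume, fpds,
                                    metric_sets = list(zncc = metric_config("zncc")),
                                    perturbation = rigid_pose(20, 20, 20, 2, 2, 2),
                                    n_repeats = 1, seed = 1,
                                    truth = rigid_pose(), ...) {
  stopifnot(n_repeats >= 1)
  get_fpds <- if (is.function(fpds)) fpds else function(s) fpds
  rows <- list()
  for (ms in names(metric_sets)) {
    cfg <- metric_sets[[ms]]
    for (rep_i in seq_len(n_repeats)) {
      run_seed <- (seed * 1000L + rep_i) %% .Machine$integer.max
      fp <- get_fpds(run_seed)
      off_fit <- drr_register(volume, fp$vertical, fp$horizontal,
                              pose0 = truth, metrics = cfg, ...)
      offset <- off_fit$pose
      start <- as_rigid_pose(unclass(offset) + unclass(as_rigid_pose(perturbation)))
      fit <- drr_register(volume, fp$vertical, fp$horizontal,
                          pose0 = start, metrics = cfg, ...)
      err <- pose_error(fit$pose, truth = truth, offset = unclass(offset) -
                          unclass(as_rigid_pose(truth)))
      rows[[length(rows) + 1]] <- data.frame(
        run = rep_i, metric_set = ms,
        dx = err$delta[["tx"]], dy = err$delta[["ty"]], dz = err$delta[["tz"]],
        dpsi = err$delta[["psi"]], dphi = err$delta[["phi"]],
        dtheta = err$delta[["theta"]],
        tre_mm = err$tre, ae_deg = err$ae,
        converged = fit$converged && off_fit$converged)
    }
  }
  runs <- do.call(rbind, rows)
  ok <- runs[runs$converged, , drop = FALSE]
  summ <- do.call(rbind, lapply(split(ok, ok$metric_set), function(d)
    data.frame(metric_set = d$metric_set[1], n = nrow(d),
               tre_mean = mean(d$tre_mm), tre_sd = stats::sd(d$tre_mm),
               ae_mean = mean(d$ae_deg), ae_sd = stats::sd(d$ae_deg))))
  structure(list(runs = runs, summary = summ,
                 n_excluded = sum(!runs$converged),
                 perturbation = as_rigid_pose(perturbation), seed = seed),
            class = "drr_experiment")
}

#' @export
print.drr_experiment <- function(x, ...) {
  cat("registration accuracy experiment\n")
  cat(sprintf("perturbation: (%s) mm, (%s) deg; %d run(s), %d excluded\n",
              paste(x$perturbation[1:3], collapse = ", "),
              paste(x$perturbation[4:6], collapse = ", "),
              nrow(x$runs), x$n_excluded))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s TRE = %.2f +/- %.2f mm, AE = %.2f +/- %.2f deg (n = %d)\n",
                s$metric_set[i], s$tre_mean[i],
                ifelse(is.na(s$tre_sd[i]), 0, s$tre_sd[i]),
                s$ae_mean[i], ifelse(is.na(s$ae_sd[i]), 0, s$ae_sd[i]),
                s$n[i]))
  invisible(x)
}
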