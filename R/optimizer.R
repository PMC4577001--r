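#' Powell direction-set minimization with Brent line searches
#'
#' Derivative-free minimization: cycles through a set of search directions
#' (initially the scaled coordinate axes), minimizing along each with
#' Brent's method on a bracket found by golden-section expansion, and
#' replaces the direction of largest decrease with the net sweep direction
#' when Powell's criterion holds.  Terminates when the relative cost
#' decrease over a full sweep drops below `tol` or after `max_iter` sweeps.
#' Fully deterministic.
#'
#' @param fn cost function, numeric vector -> scalar.
#' @param x0 start vector; `fn(x0)` must be finite.
#' @param scales per-parameter scale (the natural step size, e.g. 1 mm or
#'   1 degree); the search works in `x / scales` units.
#' @param tol relative cost-decrease tolerance.
#' @param max_iter maximum Powell sweeps.
#' @param line_tol Brent tolerance (in scaled units) for each line search.
#' @param max_step largest scaled move the bracketing may take along any
#'   single parameter; a scalar or one value per parameter (so rotations
#'   can be capped tighter than translations).
#' @return a list with `par`, `value`, `counts` (function evaluations),
#'   `iterations`, `converged`, and `trace` (accepted cost after each
#'   sweep, starting with the initial cost).
#' @export
powell_brent <- function(fn, x0, scales = rep(1, length(x0)), tol = 1e-6,
                         max_iter = 50, line_tol = 1e-4, max_step = 32) {
  n <- length(x0)
  scales <- rep_len(scales, n)
  evals <- 0L
  f <- function(z) {
    evals <<- evals + 1L
    val <- fn(z * scales)
    if (!is.finite(val)) {
      cond <- structure(class = c("drrreg_nonfinite_cost", "error", "condition"),
                        list(message = "optimizer abort: non-finite cost",
                             call = sys.call()))
      stop(cond)
    }
    val
  }
  z <- x0 / scales
  fz <- f(z)   # non-finite at the start is a hard error

  max_step <- rep_len(max_step, n)
  # Brent line minimization of f along direction d from z; returns
  # list(z, f) never worse than the start.
  linmin <- function(z, fz, d) {
    f1 <- function(a) f(z + a * d)
    # largest |alpha| keeping every parameter within its max_step
    nz <- abs(d) > 1e-12
    cap <- if (any(nz)) min(max_step[nz] / abs(d[nz])) else 0
    if (cap <= 0) return(list(z = z, f = fz))
    ax <- 0; fa <- fz
    bx <- min(1, cap); fb <- f1(bx)
    if (fb > fa) { bx <- -bx; fb <- f1(bx) }
    if (fb > fa) {
      # minimum bracketed inside [-bx, bx]
      opt <- stats::optimize(f1, c(-abs(bx), abs(bx)), tol = line_tol)
    } else {
      # golden expansion until the function turns upward or the cap is hit
      gold <- 1.618034
      cx <- bx + gold * (bx - ax); fc <- f1(min(abs(cx), cap) * sign(cx))
      cx <- min(abs(cx), cap) * sign(cx)
      while (fc < fb && abs(cx) < cap) {
        ax <- bx; bx <- cx; fb <- fc
        cx <- bx + gold * (bx - ax)
        cx <- min(abs(cx), cap) * sign(cx)
        fc <- f1(cx)
      }
      opt <- stats::optimize(f1, sort(c(ax, cx)), tol = line_tol)
    }
    if (opt$objective < fz)
      list(z = z + opt$minimum * d, f = opt$objective)
    else
      list(z = z, f = fz)    # guard: move only on strict improvement
  }

  dirs <- diag(n)
  trace <- fz
  converged <- FALSE
  aborted <- FALSE
  iter <- 0L
  tryCatch(
  while (iter < max_iter) {
    iter <- iter + 1L
    z0 <- z; f0 <- fz
    ibig <- 1L; del <- 0
    for (i in seq_len(n)) {
      fprev <- fz
      res <- linmin(z, fz, dirs[, i])
      z <- res$z; fz <- res$f
      if (fprev - fz > del) { del <- fprev - fz; ibig <- i }
    }
    trace <- c(trace, fz)
    if (2 * (f0 - fz) <= tol * (abs(f0) + abs(fz)) + 1e-25) {
      converged <- TRUE
      break
    }
    # Powell's direction replacement test on the extrapolated point
    ze <- 2 * z - z0
    fe <- f(ze)
    if (fe < f0) {
      tcrit <- 2 * (f0 - 2 * fz + fe) * ((f0 - fz) - del)^2 -
        del * (f0 - fe)^2
      if (tcrit < 0) {
        dnew <- z - z0
        if (sum(dnew^2) > 0) {
          res <- linmin(z, fz, dnew)
          z <- res$z; fz <- res$f
          dirs[, ibig] <- dnew
        }
      }
    }
  },
  drrreg_nonfinite_cost = function(e) aborted <<- TRUE)
  list(par = z * scales, value = fz, counts = evals, iterations = iter,
       converged = converged && !aborted, aborted = aborted, trace = trace)
}

#' L-BFGS minimization with numerical gradients
#'
#' Optional quasi-Newton mode: delegates to [stats::optim()]
#' (`method = "L-BFGS-B"`) on the scaled parameters with finite-difference
#' gradients.  Useful when the cost surface is smooth (ZNCC); the
#' histogram-based costs are better served by [powell_brent()].
#'
#' @inheritParams powell_brent
#' @param ... passed to [stats::optim()] `control`.
#' @return a list with `par`, `value`, `counts`, `converged`.
#' @export
lbfgs_minimize <- function(fn, x0, scales = rep(1, length(x0)),
                           tol = 1e-6, max_iter = 100, ...) {
  scales <- rep_len(scales, length(x0))
  res <- stats::optim(x0 / scales, function(z) fn(z * scales),
                      method = "L-BFGS-B",
                      control = list(factr = tol / .Machine$double.eps,
                                     maxit = max_iter, ...))
  list(par = res$par * scales, value = res$value,
       counts = unname(res$counts[1]), converged = res$convergence == 0)
}
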