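## Principal-axis (direction-set) derivative-free local minimizer.
##
## Powell-type conjugate direction search with Brent line minimization on
## each axis, in the spirit of Brent's PRAXIS.  Box bounds are imposed by a
## smooth logistic reparameterization of every coordinate onto (lo, hi), so
## the working objective stays smooth and every iterate is strictly
## feasible.  Fully deterministic given the start point and tolerances.

.z_cap <- 25  # logistic argument beyond which a coordinate sits at a bound

.to_z <- function(x, lo, hi) {
  u <- (x - lo) / (hi - lo)
  u <- pmin(pmax(u, 1e-10), 1 - 1e-10)
  stats::qlogis(u)
}

.from_z <- function(z, lo, hi) {
  lo + (hi - lo) * stats::plogis(pmin(pmax(z, -.z_cap - 12), .z_cap + 12))
}

#' Derivative-free bounded minimization by principal axes
#'
#' Minimizes `fn` inside a box using a direction-set method: each iteration
#' line-minimizes along a set of search directions (Brent's method via
#' [stats::optimize()]) and replaces the direction of largest decrease with
#' the overall displacement direction when Powell's acceptance test holds.
#' Bounds are enforced through a logistic transform of each coordinate, so
#' starts drawn uniformly inside the box remain meaningful and boundary
#' minima are approached smoothly.
#'
#' @param fn Objective, called with a numeric vector inside the box; must be
#'   finite at `x0`.
#' @param x0 Start point, within the bounds.
#' @param lower,upper Bound vectors (finite, `lower < upper`).
#' @param max_eval Budget of objective evaluations (default 3000).
#' @param tol Relative convergence tolerance on the objective decrease per
#'   cycle.
#' @param abs_tol Absolute target: stop (converged) as soon as the
#'   objective falls to or below this value (default 0, i.e. never).
#' @return A list of class `fit_result` with `par`, `value`, `n_eval`,
#'   `converged`.
#' @examples
#' r <- praxis_minimize(function(x) sum((x - c(1, 2))^2), c(0, 0),
#'                      lower = c(-5, -5), upper = c(5, 5))
#' r$par
#' @export
praxis_minimize <- function(fn, x0, lower, upper, max_eval = 3000,
                            tol = 1e-10, abs_tol = 0) {
  n <- length(x0)
  stopifnot(length(lower) == n, length(upper) == n, all(lower < upper))
  if (any(x0 < lower | x0 > upper))
    stop("start point outside bounds", call. = FALSE)
  if (max_eval < 1) stop("max_eval must be >= 1", call. = FALSE)

  st <- new.env(parent = emptyenv())
  st$count <- 0L
  st$best_f <- Inf
  st$best_z <- .to_z(x0, lower, upper)

  F <- function(z) {
    if (st$count >= max_eval)
      stop(structure(class = c("praxis_budget", "condition"),
                     list(message = "budget", call = NULL)))
    st$count <- st$count + 1L
    v <- fn(.from_z(z, lower, upper))
    if (!is.finite(v)) v <- 1e300
    if (v < st$best_f) {
      st$best_f <- v
      st$best_z <- z
    }
    if (v <= abs_tol)
      stop(structure(class = c("praxis_target", "condition"),
                     list(message = "target", call = NULL)))
    v
  }

  run <- function() {
    z <- st$best_z
    f <- F(z)
    if (f >= 1e300)
      stop("objective not finite at the start point", call. = FALSE)
    dirs <- diag(n)
    step <- rep(1, n)      # per-direction bracket scale in z-space
    cycle <- 0L
    repeat {
      cycle <- cycle + 1L
      line_tol <- max(1e-7, 1e-3 * 0.25^min(cycle, 8))
      f_start <- f
      z_start <- z
      big_dec <- 0
      big_i <- 1L
      for (i in seq_len(n)) {
        d <- dirs[, i]
        res <- .line_min(F, z, d, f, step[i], line_tol)
        if (f - res$f > big_dec) {
          big_dec <- f - res$f
          big_i <- i
        }
        step[i] <- max(abs(res$alpha) * 2, step[i] * 0.5, 1e-6)
        z <- res$z
        f <- res$f
      }
      # Powell direction replacement with extrapolation test
      dz <- z - z_start
      if (sqrt(sum(dz^2)) > 1e-12) {
        f_e <- F(2 * z - z_start)
        if (f_e < f_start) {
          t <- 2 * (f_start - 2 * f + f_e) *
            (f_start - f - big_dec)^2 - big_dec * (f_start - f_e)^2
          if (t < 0) {
            d_new <- dz / sqrt(sum(dz^2))
            res <- .line_min(F, z, d_new, f, sqrt(sum(dz^2)), line_tol)
            z <- res$z
            f <- res$f
            dirs[, big_i] <- d_new
          }
        }
      }
      if (2 * (f_start - f) <= tol * (abs(f_start) + abs(f)) + 1e-300)
        return(TRUE)
    }
  }

  converged <- tryCatch(run(),
                        praxis_budget = function(e) FALSE,
                        praxis_target = function(e) TRUE)
  structure(list(par = .from_z(st$best_z, lower, upper),
                 value = st$best_f,
                 n_eval = st$count,
                 converged = isTRUE(converged)),
            class = "fit_result")
}

# line minimization of F along direction d from z (value f0 there):
# bracket by doubling, then Brent via stats::optimize
.line_min <- function(F, z, d, f0, s, line_tol) {
  phi <- function(a) F(z + a * d)
  a <- 0; fa <- f0
  b <- s; fb <- phi(b)
  if (fb > fa) {
    b <- -s
    fb <- phi(b)
  }
  if (fb > fa) {
    lo <- -abs(s); hi <- abs(s)
  } else {
    repeat {
      cc <- 2 * b
      if (abs(cc) > 2 * .z_cap) { cc <- sign(b) * 2 * .z_cap; fc <- phi(cc); break }
      fc <- phi(cc)
      if (fc > fb) break
      b <- cc; fb <- fc
    }
    lo <- min(0, cc); hi <- max(0, cc)
  }
  opt <- stats::optimize(phi, lower = lo, upper = hi,
                         tol = max(line_tol, .Machine$double.eps^0.5))
  if (opt$objective <= min(fa, fb)) {
    alpha <- opt$minimum; fmin <- opt$objective
  } else if (fb < fa) {
    alpha <- b; fmin <- fb
  } else {
    alpha <- 0; fmin <- fa
  }
  list(z = z + alpha * d, f = fmin, alpha = alpha)
}
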