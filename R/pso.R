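# Upper-level optimizer: global-best particle swarm with linearly decreasing
# inertia weight, applied to the three learner hyperparameters
# K = [lambda, rho, beta].

#' Define a box-constrained search space
#'
#' Dimensions marked `"log"` are searched on a log10 scale, so magnitudes are
#' explored uniformly; `"linear"` dimensions are searched directly.
#'
#' @param lower,upper Numeric bound vectors (lower < upper elementwise).
#' @param scale Character vector, `"linear"` or `"log"` per dimension.
#' @param names Optional dimension names.
#' @return A `SearchSpace` object.
#' @export
search_space <- function(lower, upper, scale = rep("linear", length(lower)),
                         names = NULL) {
  stopifnot(length(lower) == length(upper), length(scale) == length(lower),
            all(lower < upper), all(scale %in% c("linear", "log")))
  if (any(scale == "log") && any(lower[scale == "log"] <= 0)) {
    stop("log-scaled dimensions need positive bounds")
  }
  structure(list(lower = lower, upper = upper, scale = scale,
                 names = names), class = "SearchSpace")
}

#' Default hyperparameter space for the RBF learner
#'
#' `lambda` in \[1e-7, 1\] (log), `rho` in \[1, 220\] (linear), `beta` in
#' \[1e-7, 1\] (log).
#'
#' @return A [search_space()] over `c(lambda, rho, beta)`.
#' @export
default_hyper_space <- function() {
  search_space(lower = c(1e-7, 1, 1e-7), upper = c(1, 220, 1),
               scale = c("log", "linear", "log"),
               names = c("lambda", "rho", "beta"))
}

space_to_internal <- function(space, x) {
  ifelse(space$scale == "log", log10(x), x)
}
space_from_internal <- function(space, z) {
  x <- ifelse(space$scale == "log", 10^z, z)
  if (!is.null(space$names)) names(x) <- space$names
  x
}

#' Particle swarm optimization
#'
#' Global-best topology with inertia weight linearly decreasing from
#' `inertia[1]` to `inertia[2]` over the iterations and acceleration
#' coefficients `c1` (personal best) and `c2` (global best). Velocities are
#' clamped to `vmax_frac` of each dimension's range; positions are clamped to
#' the bounds with the velocity zeroed on the clamped dimension. A single RNG
#' stream, seeded explicitly, is consumed in fixed particle order, so runs
#' are bit-reproducible. Exactly `p` fitness evaluations are spent on
#' initialization and `p * iterations` afterwards.
#'
#' @param fitness Function mapping a position (natural scale) to a scalar to
#'   minimize. Non-finite values are treated as `+Inf` with a warning.
#' @param space A [search_space()].
#' @param p Swarm size (default 15).
#' @param iterations Number of iterations T (default 30).
#' @param seed Integer RNG seed.
#' @param inertia Start and end inertia weights (default `c(0.9, 0.4)`).
#' @param c1,c2 Acceleration coefficients (default 2.0).
#' @param vmax_frac Velocity clamp as a fraction of each range (default 0.2).
#' @return List with `par` (best position, natural scale), `value` (best
#'   fitness), `history` (data frame of global-best fitness per iteration,
#'   iteration 0 = after initialization), and `counts` (list with `init` and
#'   `iteration` evaluation totals).
#' @export
pso_optimize <- function(fitness, space, p = 15L, iterations = 30L, seed = 1L,
                         inertia = c(0.9, 0.4), c1 = 2, c2 = 2,
                         vmax_frac = 0.2) {
  stopifnot(inherits(space, "SearchSpace"), p >= 2L, iterations >= 1L)
  lo <- space_to_internal(space, space$lower)
  hi <- space_to_internal(space, space$upper)
  d <- length(lo)
  rng <- hi - lo
  vmax <- vmax_frac * rng

  eval_fit <- function(z) {
    v <- fitness(space_from_internal(space, z))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v)) {
      if (!identical(v, Inf)) warning("non-finite fitness treated as +Inf")
      v <- Inf
    }
    v
  }

  with_seed(seed, {
    X <- matrix(stats::runif(p * d, rep(lo, each = p), rep(hi, each = p)), p, d)
    V <- matrix(0, p, d)
    fit <- apply(X, 1L, eval_fit)
    Pb <- X
    pb_fit <- fit
    gi <- which.min(pb_fit)
    gb <- Pb[gi, ]
    gb_fit <- pb_fit[gi]
    hist_fit <- numeric(iterations + 1L)
    hist_fit[1L] <- gb_fit

    for (t in seq_len(iterations)) {
      w <- if (iterations > 1L) {
        inertia[1] + (inertia[2] - inertia[1]) * (t - 1) / (iterations - 1)
      } else inertia[1]
      for (i in seq_len(p)) {          # fixed particle order for determinism
        r1 <- stats::runif(d)
        r2 <- stats::runif(d)
        v <- w * V[i, ] + c1 * r1 * (Pb[i, ] - X[i, ]) + c2 * r2 * (gb - X[i, ])
        v <- pmin(pmax(v, -vmax), vmax)
        x <- X[i, ] + v
        below <- x < lo; above <- x > hi
        x[below] <- lo[below]; x[above] <- hi[above]
        v[below | above] <- 0
        X[i, ] <- x
        V[i, ] <- v
        f <- eval_fit(x)
        if (f < pb_fit[i]) {
          pb_fit[i] <- f
          Pb[i, ] <- x
        }
        if (f < gb_fit) {
          gb_fit <- f
          gb <- x
        }
      }
      hist_fit[t + 1L] <- gb_fit
    }

    list(par = space_from_internal(space, gb),
         value = gb_fit,
         history = data.frame(iteration = 0:iterations,
                              best_fitness = hist_fit),
         counts = list(init = p, iteration = p * iterations))
  })
}
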