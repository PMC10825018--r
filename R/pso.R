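# Global-best particle swarm optimiser over a box.  Written here because
# the search itself is part of the fitting workflow contract (seeded,
# reproducible, trace-recording); hyperparameters follow the standard
# constricted PSO of Clerc & Kennedy.

#' Particle swarm optimiser settings
#'
#' @param n_particles swarm size
#' @param n_iter number of iterations
#' @param inertia inertia weight
#' @param c_cog,c_soc cognitive and social acceleration coefficients
#' @param v_max_frac velocity clamp as a fraction of the box width
#' @return list of settings
#' @export
pso_settings <- function(n_particles = 60, n_iter = 300, inertia = 0.729,
                         c_cog = 1.49445, c_soc = 1.49445,
                         v_max_frac = 0.5) {
  list(n_particles = n_particles, n_iter = n_iter, inertia = inertia,
       c_cog = c_cog, c_soc = c_soc, v_max_frac = v_max_frac)
}

#' Global-best particle swarm minimisation over a box
#'
#' @param fn objective, called with a numeric vector; must return a scalar
#'   (may be `Inf` for invalid points)
#' @param lower,upper box bounds (finite)
#' @param settings a [pso_settings()] list
#' @param seed integer seed; the run is fully determined by it
#' @return list with `par`, `value`, `trace` (best value per iteration) and
#'   `n_evals`
#' @export
pso_optim <- function(fn, lower, upper, settings = pso_settings(),
                      seed = 1L) {
  stopifnot(length(lower) == length(upper), all(is.finite(lower)),
            all(is.finite(upper)), all(upper > lower))
  d <- length(lower)
  np <- settings$n_particles
  width <- upper - lower
  vmax <- settings$v_max_frac * width
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  X <- matrix(stats::runif(np * d), np, d)
  X <- sweep(sweep(X, 2, width, "*"), 2, lower, "+")
  V <- matrix(stats::runif(np * d, -1, 1), np, d)
  V <- sweep(V, 2, vmax, "*")
  pbest <- X
  pval <- apply(X, 1, fn)
  g <- which.min(pval)
  gbest <- X[g, ]
  gval <- pval[g]
  trace <- numeric(settings$n_iter)
  for (it in seq_len(settings$n_iter)) {
    r1 <- matrix(stats::runif(np * d), np, d)
    r2 <- matrix(stats::runif(np * d), np, d)
    V <- settings$inertia * V +
      settings$c_cog * r1 * (pbest - X) +
      settings$c_soc * r2 * sweep(X, 2, gbest, function(x, g) g - x)
    V <- pmin(pmax(V, matrix(-vmax, np, d, byrow = TRUE)),
              matrix(vmax, np, d, byrow = TRUE))
    X <- X + V
    # reflect at the bounds
    for (j in seq_len(d)) {
      lo <- X[, j] < lower[j]
      hi <- X[, j] > upper[j]
      X[lo, j] <- lower[j]
      X[hi, j] <- upper[j]
      V[lo | hi, j] <- -0.5 * V[lo | hi, j]
    }
    val <- apply(X, 1, fn)
    imp <- val < pval
    pbest[imp, ] <- X[imp, , drop = FALSE]
    pval[imp] <- val[imp]
    g <- which.min(pval)
    if (pval[g] < gval) {
      gval <- pval[g]
      gbest <- pbest[g, ]
    }
    trace[it] <- gval
  }
  list(par = gbest, value = gval, trace = trace,
       n_evals = np * (settings$n_iter + 1L))
}
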