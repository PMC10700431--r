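# Draws from order-constrained prior/posterior Dirichlet and beta densities.
#
# Multinomial: a Dirichlet vector is a normalized vector of independent
# gammas, and order constraints among the proportions are equivalent to the
# same order among the gammas (shared normalizer). The Gibbs sweep therefore
# samples each gamma from its full conditional truncated to the interval set
# by its chain neighbours; the stationary law of the normalized vector is the
# constrained Dirichlet. Binomial: the coordinates are independent betas, so
# the full conditionals are truncated betas directly.

# per-coordinate truncation neighbours implied by a restriction list:
# lower = members of the previous chain element, upper = members of the next.
# Free-group peers do not bound each other.
neighbour_bounds <- function(restriction, K) {
  lower <- vector("list", K)
  upper <- vector("list", K)
  for (sec in restriction$sections) {
    members <- purrr::map(sec, ~ as.integer(unlist(.x, use.names = FALSE)))
    E <- length(members)
    for (e in seq_len(E)) {
      for (k in members[[e]]) {
        if (e > 1L) lower[[k]] <- members[[e - 1L]]
        if (e < E) upper[[k]] <- members[[e + 1L]]
      }
    }
  }
  list(lower = lower, upper = upper)
}

# Order comparisons act on the per-original-category proportion: a merged
# equality group of m categories with total probability theta competes at
# theta / m. Binomial collapsed categories carry the shared proportion
# itself, so no scaling applies there.
comparison_scale <- function(problem) {
  if (problem$family == "multinomial") problem$group_sizes else rep(1, length(problem$x))
}

# strict satisfaction of every inequality, vectorized over rows of `draws`
satisfies_restriction <- function(draws, problem) {
  draws <- rbind(draws)
  draws <- sweep(draws, 2L, comparison_scale(problem), "/")
  ok <- rep(TRUE, nrow(draws))
  for (sec in problem$restriction$sections) {
    members <- purrr::map(sec, ~ as.integer(unlist(.x, use.names = FALSE)))
    for (e in seq_len(length(members) - 1L)) {
      lo <- draws[, members[[e]], drop = FALSE]
      hi <- draws[, members[[e + 1L]], drop = FALSE]
      ok <- ok & (apply(lo, 1L, max) < apply(hi, 1L, min))
    }
  }
  ok
}

target_shapes <- function(problem, target) {
  target <- match.arg(target, c("prior", "posterior"))
  if (problem$family == "multinomial") {
    sh <- if (target == "prior") problem$a else problem$a + problem$x
    list(shape1 = sh, shape2 = NULL)
  } else {
    if (target == "prior") {
      list(shape1 = problem$a, shape2 = problem$b)
    } else {
      list(shape1 = problem$a + problem$x, shape2 = problem$b + problem$n - problem$x)
    }
  }
}

#' Gibbs sampler for order-constrained Dirichlet / beta densities
#'
#' Draws from the prior or posterior density of a [split_restriction()]
#' collapsed problem, restricted to its order constraints. Full conditionals
#' are truncated gammas (multinomial, via the gamma representation of the
#' Dirichlet) or truncated betas (binomial), sampled by inverse CDF with
#' tail-switching guards. The chain is initialized deterministically at a
#' feasible point and is reproducible given `seed`.
#'
#' @param problem A `collapsed_problem`.
#' @param target `"prior"` or `"posterior"`.
#' @param n_draws Number of retained draws (>= 2).
#' @param n_burn Burn-in sweeps discarded before retention; default 500.
#' @param thin Keep every `thin`-th sweep; default 1.
#' @param seed Optional integer seed.
#'
#' @return A `constrained_samples` object: list with `draws` (n_draws x K'
#'   matrix on the probability scale, labelled columns), `target`, `problem`,
#'   `seed`, `n_burn`, `thin`.
#' @export
sample_constrained <- function(problem, target = c("prior", "posterior"),
                               n_draws = 12000, n_burn = 500, thin = 1,
                               seed = NULL) {
  target <- match.arg(target)
  stopifnot(inherits(problem, "collapsed_problem"))
  if (n_draws < 2L) stop("`n_draws` must be at least 2.", call. = FALSE)
  if (n_burn < 0L) stop("`n_burn` must be non-negative.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  K <- length(problem$x)
  sh <- target_shapes(problem, target)
  nb <- neighbour_bounds(problem$restriction, K)
  multinomial <- problem$family == "multinomial"
  sc <- comparison_scale(problem)

  # deterministic feasible start: element rank within each section orders the
  # constrained coordinates; unconstrained coordinates start at their mean
  if (multinomial) {
    g <- sh$shape1 / mean(sh$shape1)  # unconstrained start, positive scale
  } else {
    g <- sh$shape1 / (sh$shape1 + sh$shape2)
  }
  for (sec in problem$restriction$sections) {
    members <- purrr::map(sec, ~ as.integer(unlist(.x, use.names = FALSE)))
    E <- length(members)
    for (e in seq_len(E)) {
      m <- members[[e]]
      g[m] <- if (multinomial) e * sc[m] else e / (E + 1)
    }
  }

  draws <- matrix(NA_real_, n_draws, K)
  colnames(draws) <- problem$labels
  kept <- 0L
  sweep <- 0L
  while (kept < n_draws) {
    sweep <- sweep + 1L
    for (k in seq_len(K)) {
      lo <- if (is.null(nb$lower[[k]])) 0 else sc[k] * max(g[nb$lower[[k]]] / sc[nb$lower[[k]]])
      if (multinomial) {
        up <- if (is.null(nb$upper[[k]])) Inf else sc[k] * min(g[nb$upper[[k]]] / sc[nb$upper[[k]]])
        g[k] <- rtrunc_invcdf(
          function(q, lower.tail) pgamma(q, shape = sh$shape1[k], lower.tail = lower.tail),
          function(p, lower.tail) qgamma(p, shape = sh$shape1[k], lower.tail = lower.tail),
          lo, up
        )
      } else {
        up <- if (is.null(nb$upper[[k]])) 1 else min(g[nb$upper[[k]]])
        g[k] <- rtrunc_invcdf(
          function(q, lower.tail) pbeta(q, sh$shape1[k], sh$shape2[k], lower.tail = lower.tail),
          function(p, lower.tail) qbeta(p, sh$shape1[k], sh$shape2[k], lower.tail = lower.tail),
          lo, up
        )
      }
    }
    if (sweep > n_burn && (sweep - n_burn) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- if (multinomial) g / sum(g) else g
    }
  }

  structure(
    list(
      draws = draws, target = target, problem = problem,
      seed = seed, n_burn = n_burn, thin = thin
    ),
    class = "constrained_samples"
  )
}

#' @export
print.constrained_samples <- function(x, ...) {
  cat(nrow(x$draws), " draws from the constrained ", x$target, " density (",
      x$problem$family, ", K' = ", ncol(x$draws), ")\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.constrained_samples <- function(x, ...) {
  as_tibble(as.data.frame(x$draws))
}

#' Monte Carlo constraint fraction from unconstrained draws
#'
#' Estimates the prior or posterior probability mass of the constrained
#' region by naive rejection: the fraction of unconstrained conjugate draws
#' satisfying every inequality. Inefficient for tight constraints, but an
#' unbiased, assumption-free reference for validating the bridge estimator.
#'
#' @inheritParams sample_constrained
#' @param n_draws Number of unconstrained Monte Carlo draws.
#'
#' @return One-row tibble: `proportion`, `se` (binomial standard error),
#'   `n_draws`, `n_inside`.
#' @export
naive_constraint_fraction <- function(problem, target = c("prior", "posterior"),
                                      n_draws = 1e5, seed = NULL) {
  target <- match.arg(target)
  if (!is.null(seed)) set.seed(seed)
  K <- length(problem$x)
  sh <- target_shapes(problem, target)
  if (problem$family == "multinomial") {
    g <- matrix(rgamma(n_draws * K, shape = rep(sh$shape1, each = n_draws)), n_draws, K)
    draws <- g / rowSums(g)
  } else {
    draws <- matrix(rbeta(n_draws * K, rep(sh$shape1, each = n_draws),
                          rep(sh$shape2, each = n_draws)), n_draws, K)
  }
  inside <- satisfies_restriction(draws, problem)
  p <- mean(inside)
  tibble(
    proportion = p,
    se = sqrt(p * (1 - p) / n_draws),
    n_draws = n_draws,
    n_inside = sum(inside)
  )
}

#' Effective sample size of constrained Gibbs draws
#'
#' Per-coordinate effective sample size `n / rho`, where `rho` is the ratio
#' of the spectral density at frequency zero to the draw variance (AR fit).
#'
#' @param samples A `constrained_samples` object.
#' @return Tibble with columns `label` and `ess`.
#' @export
effective_sample_size <- function(samples) {
  stopifnot(inherits(samples, "constrained_samples"))
  n <- nrow(samples$draws)
  tibble(
    label = colnames(samples$draws),
    ess = apply(samples$draws, 2L, function(col) n / spectrum0_ratio(col))
  )
}
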