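# Bijective stick-breaking / probit map between the order-constrained
# probability space and the real line, with log-Jacobian. The map processes
# coordinates from the smallest chain element to the largest:
#
#   theta_k = (u_k - l_k) * Phi(xi_k) + l_k
#
# Lower bound: 0 for the smallest element, otherwise the largest member of
# the previous element. Upper bound: 1 for binomial coordinates; for
# multinomial coordinates the remaining stick R is shared with the p not yet
# placed peers of the current free element (each of which must exceed the
# same lower bound l) and the M members of strictly higher elements (each of
# which must exceed every member of the current element — both the current
# coordinate and the largest already-placed peer A). Two inequalities hold
# everywhere on the constrained region:
#   theta < (R - p*l) / (1 + M)        (higher members exceed theta itself)
#   theta < R - p*l - M*max(A, l)      (higher members exceed A and l)
# and u is their minimum. For a pure chain (no free groups) this reduces to
# the familiar remaining-stick / remaining-count bound, e.g. u = 1/3 for the
# smallest of three ordered proportions. Because both inequalities hold on
# the region, the inverse map is defined for every constrained draw; for
# free-group problems the forward image can still exceed the region (or hit
# an empty interval), which the indicator in the target density absorbs.
# The largest multinomial coordinate is the remainder of the stick and
# carries no xi coordinate.
#
# Bounds depend only on earlier coordinates, so the Jacobian is triangular:
# log|det J| = sum_k [ log(u_k - l_k) + log phi(xi_k) ].

# flatten a single-section restriction into per-coordinate metadata, in
# transform order (elements ascending, members in stored order)
transform_layout <- function(problem) {
  sections <- problem$restriction$sections
  if (length(sections) != 1L) {
    stop("The stick-breaking transform needs a single independent constraint; split the problem by section first.", call. = FALSE)
  }
  members <- purrr::map(sections[[1L]], ~ as.integer(unlist(.x, use.names = FALSE)))
  coord <- unlist(members, use.names = FALSE)
  if (length(coord) != length(problem$x) || !setequal(coord, seq_along(problem$x))) {
    stop("The constraint must cover every category of the subproblem.", call. = FALSE)
  }
  elem <- rep(seq_along(members), lengths(members))
  K <- length(coord)
  # multiplicity of each collapsed category: order comparisons and stick
  # accounting act on the per-original-category proportion theta / m
  mult <- comparison_scale(problem)
  elem_mult <- purrr::map_dbl(members, ~ sum(mult[.x]))  # total multiplicity per element
  w_above <- rev(cumsum(rev(elem_mult)))                 # incl. own element
  list(
    members = members,
    coord = coord,           # category index at transform position j
    elem = elem,             # element rank at transform position j
    mult = mult,
    w_above = c(w_above[-1L], 0)[elem],  # multiplicity mass of higher elements
    K = K,
    d = if (problem$family == "multinomial") K - 1L else K
  )
}

#' Map order-constrained draws to the real line
#'
#' Applies the inverse stick-breaking probit transform to every row of a
#' [sample_constrained()] result, returning unconstrained real coordinates
#' and the log-Jacobian of the forward map at each draw.
#'
#' @param samples A `constrained_samples` object whose problem has a single
#'   independent constraint covering all its categories.
#'
#' @return List of class `transformed_draws`: `xi` (n x d matrix),
#'   `log_jacobian` (length n), `problem`, `target`.
#' @export
to_real <- function(samples) {
  stopifnot(inherits(samples, "constrained_samples"))
  problem <- samples$problem
  lay <- transform_layout(problem)
  theta <- samples$draws
  n <- nrow(theta)
  multinomial <- problem$family == "multinomial"

  # psi: per-original-category proportion, the scale the order acts on
  psi_all <- sweep(theta, 2L, lay$mult, "/")
  xi <- matrix(NA_real_, n, lay$d)
  logj <- numeric(n)
  R <- rep(1, n)
  prev_max <- rep(0, n)  # max psi of previous element's members, per draw
  pos <- 0L
  for (e in seq_along(lay$members)) {
    mem <- lay$members[[e]]
    lower <- if (e == 1L) rep(0, n) else prev_max
    peer_max <- rep(-Inf, n)  # largest already-placed psi of this element
    for (j in seq_along(mem)) {
      pos <- pos + 1L
      if (multinomial && pos > lay$d) break  # last coordinate is the remainder
      k <- mem[j]
      m_k <- lay$mult[k]
      psi <- psi_all[, k]
      if (multinomial) {
        # multiplicity mass of unplaced peers and of higher elements
        P <- if (j < length(mem)) sum(lay$mult[mem[(j + 1L):length(mem)]]) else 0
        Q <- lay$w_above[pos]
        u <- pmin(
          (R - P * lower) / (m_k + Q),
          (R - P * lower - Q * pmax(peer_max, lower)) / m_k
        )
      } else {
        u <- rep(1, n)
      }
      z <- (psi - lower) / (u - lower)
      bad <- which(z <= 0 | z >= 1 | !is.finite(z))
      if (length(bad) > 0L) {
        stop(sprintf("Draw %d lies on a transform boundary and cannot be mapped.", bad[1L]), call. = FALSE)
      }
      xi[, pos] <- qnorm(z)
      logj <- logj + log(m_k) + log(u - lower) + dnorm(xi[, pos], log = TRUE)
      if (multinomial) R <- R - theta[, k]
      peer_max <- pmax(peer_max, psi)
    }
    prev_max <- apply(psi_all[, mem, drop = FALSE], 1L, max)
  }

  structure(
    list(xi = xi, log_jacobian = logj, problem = problem, target = samples$target),
    class = "transformed_draws"
  )
}

#' Map real-line coordinates back to the constrained probability space
#'
#' Forward stick-breaking probit transform: reconstructs probability-scale
#' draws from real coordinates, together with the log-Jacobian of the map.
#' Every output row of a binomial problem satisfies the order constraints by
#' construction; multinomial free-group configurations can land outside the
#' region (see `in_region`).
#'
#' @param xi Numeric matrix (n x d) of real coordinates.
#' @param problem A single-section `collapsed_problem`.
#'
#' @return List: `theta` (n x K' matrix), `log_jacobian` (length n),
#'   `in_region` (logical, strict constraint satisfaction per row).
#' @export
to_probability <- function(xi, problem) {
  xi <- rbind(xi)
  lay <- transform_layout(problem)
  if (ncol(xi) != lay$d) stop(sprintf("`xi` must have %d columns.", lay$d), call. = FALSE)
  n <- nrow(xi)
  multinomial <- problem$family == "multinomial"

  theta <- matrix(NA_real_, n, lay$K)
  colnames(theta) <- problem$labels
  psi_mat <- matrix(NA_real_, n, lay$K)
  logj <- numeric(n)
  R <- rep(1, n)
  prev_max <- rep(0, n)
  feasible <- rep(TRUE, n)  # rows where every stick interval stayed non-empty
  pos <- 0L
  for (e in seq_along(lay$members)) {
    mem <- lay$members[[e]]
    lower <- if (e == 1L) rep(0, n) else prev_max
    peer_max <- rep(-Inf, n)
    for (j in seq_along(mem)) {
      pos <- pos + 1L
      k <- mem[j]
      m_k <- lay$mult[k]
      if (multinomial && pos > lay$d) {
        theta[, k] <- R  # remainder of the stick
        psi_mat[, k] <- R / m_k
        break
      }
      if (multinomial) {
        P <- if (j < length(mem)) sum(lay$mult[mem[(j + 1L):length(mem)]]) else 0
        Q <- lay$w_above[pos]
        u <- pmin(
          (R - P * lower) / (m_k + Q),
          (R - P * lower - Q * pmax(peer_max, lower)) / m_k
        )
        # an empty interval means this real point has no constrained image;
        # keep constructing with a token interval and zero it via the indicator
        feasible <- feasible & (u > lower)
        u <- pmax(u, lower + 1e-12)
      } else {
        u <- rep(1, n)
      }
      psi <- (u - lower) * pnorm(xi[, pos]) + lower
      psi_mat[, k] <- psi
      theta[, k] <- m_k * psi
      logj <- logj + log(m_k) + log(u - lower) + dnorm(xi[, pos], log = TRUE)
      if (multinomial) R <- R - theta[, k]
      peer_max <- pmax(peer_max, psi)
    }
    prev_max <- apply(psi_mat[, mem, drop = FALSE], 1L, max)
  }

  list(
    theta = theta,
    log_jacobian = logj,
    in_region = feasible & satisfies_restriction(theta, problem)
  )
}

#' Unnormalized log target density on the real line
#'
#' Evaluates, per row of `xi`, the log of the conjugate prior or posterior
#' density at the back-transformed point (normalized Dirichlet/beta density,
#' i.e. not normalized by the constrained-region mass), plus the
#' log-Jacobian of the transform, with `-Inf` where the point violates the
#' constraints. The normalizing constant of this density over the real line
#' is exactly the prior/posterior probability mass of the constrained
#' region — the quantity the bridge sampler estimates.
#'
#' @inheritParams to_probability
#' @param target `"prior"` or `"posterior"`.
#' @return Numeric vector of per-row log densities.
#' @export
log_target_density_real <- function(xi, problem, target = c("prior", "posterior")) {
  target <- match.arg(target)
  fwd <- to_probability(xi, problem)
  sh <- target_shapes(problem, target)
  theta <- fwd$theta
  if (problem$family == "multinomial") {
    ld <- as.numeric(log(theta) %*% (sh$shape1 - 1)) - lmbeta(sh$shape1)
  } else {
    ld <- numeric(nrow(theta))
    for (k in seq_len(ncol(theta))) {
      ld <- ld + dbeta(theta[, k], sh$shape1[k], sh$shape2[k], log = TRUE)
    }
  }
  out <- as.numeric(ld + fwd$log_jacobian)
  out[!fwd$in_region] <- -Inf
  out
}
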