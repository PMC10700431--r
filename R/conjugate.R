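# Closed-form Bayes factors for equality-constrained models. All marginal
# likelihoods are computed in the natural-log domain via log-gamma; observed
# constraint masses in realistic problems reach exp(-480).

# log BF_0e for the multinomial test of predicted proportions p0:
#   B(alpha) / B(alpha + x) * prod_k theta_0k^{x_k}
log_mult_bf_equality <- function(x, a, p0) {
  stopifnot(length(x) == length(a), length(p0) == length(x))
  check_positive(a, "a")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-12) {
    stop("`p` must be a probability vector summing to 1.", call. = FALSE)
  }
  lp <- ifelse(x == 0, 0, x * log(p0))  # 0 * log(0) = 0; x>0 with p0=0 -> -Inf
  lmbeta(a) - lmbeta(a + x) + sum(lp)
}

# log BF_0e for equality of K binomial proportions: the individual
# Beta(alpha_k, beta_k) priors collapse onto the shared proportion with a
# -(K-1) correction on both parameter sums.
log_binom_bf_equality <- function(x, n, a, b) {
  K <- length(x)
  stopifnot(length(n) == K, length(a) == K, length(b) == K)
  check_positive(a, "a")
  check_positive(b, "b")
  if (K == 1L) return(0)
  a0 <- sum(a) - (K - 1)
  b0 <- sum(b) - (K - 1)
  if (a0 <= 0 || b0 <= 0) {
    stop("Collapsed prior parameters must stay positive: sum(a) and sum(b) must exceed K - 1.", call. = FALSE)
  }
  xp <- sum(x)
  np <- sum(n)
  lbeta(xp + a0, np - xp + b0) - sum(lbeta(x + a, n - x + b)) +
    sum(lbeta(a, b)) - lbeta(a0, b0)
}

# log BF_02e for the point null theta_k = theta0 for all k: the null prior is
# a point mass, so its marginal likelihood is the likelihood itself.
log_binom_bf_equality_point <- function(x, n, a, b, theta0) {
  stopifnot(length(theta0) == 1L)
  if (theta0 <= 0 || theta0 >= 1) {
    stop("`p` must lie strictly inside (0, 1).", call. = FALSE)
  }
  check_positive(a, "a")
  check_positive(b, "b")
  xp <- sum(x)
  np <- sum(n)
  sum(lbeta(a, b)) - sum(lbeta(a + x, b + n - x)) +
    xp * log(theta0) + (np - xp) * log1p(-theta0)
}

# log BF_1e for equality within one group of categories (Savage-Dickey).
# Multinomial: by Dirichlet aggregation the within-group composition is
# Dirichlet(a_g); the equality null is the uniform composition point, so the
# BF is the posterior/prior density ratio there. Binomial: the all-equal
# formula restricted to the group.
log_equality_group_bf <- function(x, a, group, n = NULL, b = NULL,
                                  family = c("multinomial", "binomial")) {
  family <- match.arg(family)
  group <- as.integer(group)
  m <- length(group)
  if (m < 2L) stop("An equality group needs at least two categories.", call. = FALSE)
  if (family == "binomial") {
    log_binom_bf_equality(x[group], n[group], a[group], b[group])
  } else {
    xg <- x[group]
    ag <- a[group]
    lmbeta(ag) - lmbeta(ag + xg) + sum(xg) * log(1 / m)
  }
}

#' Bayesian multinomial test of predicted proportions
#'
#' Computes the Bayes factor comparing the null hypothesis that the category
#' proportions equal `p` (default: all equal) against the encompassing
#' hypothesis that they vary freely under a Dirichlet(`a`) prior.
#'
#' @param data Data frame with a column `x` of observed counts (one row per
#'   category) and optionally `label`.
#' @param a Dirichlet concentration parameters; scalar or length-K. Default 1.
#' @param p Predicted category proportions under the null; default `1/K`.
#'
#' @return A one-row tibble with `log_bf_0e`, `bf_0e`, and `log_bf_e0`.
#'
#' @examples
#' d <- tibble::tibble(x = c(3, 4, 10, 11))
#' mult_bf_equality(d)
#' mult_bf_equality(d, p = c(0.1, 0.1, 0.3, 0.5))
#' @export
mult_bf_equality <- function(data, a = 1, p = NULL) {
  data <- as.data.frame(data)
  x <- as.numeric(data$x)
  K <- length(x)
  a <- rep_len(as.numeric(a), K)
  if (is.null(p)) p <- rep(1 / K, K)
  lbf <- log_mult_bf_equality(x, a, p)
  tibble(log_bf_0e = lbf, bf_0e = exp(lbf), log_bf_e0 = -lbf)
}

#' Bayes factor for equality of independent binomial proportions
#'
#' Tests the null that all binomial success probabilities are equal (shared
#' unknown value), or — when `p` is supplied — equal to the single predicted
#' value `p`, against the encompassing hypothesis of free, independent
#' Beta(`a`, `b`) proportions. Only one shared predicted value is supported.
#'
#' @param data Data frame with columns `x` (successes) and `n` (trials).
#' @param a,b Beta prior parameters; scalar or length-K. Default 1.
#' @param p Optional predicted value in (0, 1) shared by all proportions.
#'
#' @return A one-row tibble with `log_bf_0e`, `bf_0e`, and `log_bf_e0`.
#'
#' @examples
#' d <- tibble::tibble(x = c(3, 4, 10, 11), n = c(15, 12, 12, 12))
#' binom_bf_equality(d)
#' binom_bf_equality(d, p = 0.5)
#' @export
binom_bf_equality <- function(data, a = 1, b = 1, p = NULL) {
  data <- as.data.frame(data)
  x <- as.numeric(data$x)
  n <- as.numeric(data$n)
  K <- length(x)
  a <- rep_len(as.numeric(a), K)
  b <- rep_len(as.numeric(b), K)
  lbf <- if (is.null(p)) {
    log_binom_bf_equality(x, n, a, b)
  } else {
    log_binom_bf_equality_point(x, n, a, b, p)
  }
  tibble(log_bf_0e = lbf, bf_0e = exp(lbf), log_bf_e0 = -lbf)
}

#' Posterior medians and credible intervals under the encompassing model
#'
#' For binomial models each proportion has an independent
#' Beta(`a + x`, `b + n - x`) posterior. For multinomial models the marginal
#' posterior of each proportion is Beta(`a_k + x_k`, `a_+ + x_+ - a_k - x_k`).
#'
#' @param data Data frame with columns `x` (and `n` for binomial models),
#'   optionally `label`.
#' @param a,b Prior parameters; scalar or length-K.
#' @param family `"multinomial"` or `"binomial"`; guessed from the presence
#'   of an `n` column when missing.
#' @param level Central credible-interval coverage in (0, 1); default 0.95.
#'
#' @return Tibble with one row per category: `label`, `median`, `lower`,
#'   `upper`.
#'
#' @examples
#' posterior_summary(tibble::tibble(x = 39, n = 80))
#' @export
posterior_summary <- function(data, a = 1, b = 1, family = NULL, level = 0.95) {
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1).", call. = FALSE)
  data <- as.data.frame(data)
  x <- as.numeric(data$x)
  K <- length(x)
  a <- rep_len(as.numeric(a), K)
  if (is.null(family)) family <- if (is.null(data$n)) "multinomial" else "binomial"
  family <- match.arg(family, c("multinomial", "binomial"))
  labels <- if (!is.null(data$label)) as.character(data$label) else as.character(seq_len(K))
  if (family == "binomial") {
    n <- as.numeric(data$n)
    b <- rep_len(as.numeric(b), K)
    sh1 <- a + x
    sh2 <- b + n - x
  } else {
    sh1 <- a + x
    sh2 <- sum(a) + sum(x) - sh1
  }
  lo <- (1 - level) / 2
  tibble(
    label = labels,
    median = qbeta(0.5, sh1, sh2),
    lower = qbeta(lo, sh1, sh2),
    upper = qbeta(1 - lo, sh1, sh2)
  )
}
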