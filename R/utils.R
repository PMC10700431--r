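# Numeric helpers shared across modules. Everything that can live on the log
# scale does: constraint masses in realistic problems go down to exp(-480).

# log of the multivariate beta function B(a) = prod Gamma(a_k) / Gamma(sum a)
lmbeta <- function(a) {
  sum(lgamma(a)) - lgamma(sum(a))
}

logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logmeanexp <- function(x) {
  logsumexp(x) - log(length(x))
}

# elementwise log(exp(a) + exp(b))
logaddexp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  # if both are -Inf the pmin term is NaN; the sum is -Inf
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Deterministic sub-stream seeds for per-section sampling runs. Kept well
# below 2^31 and exactly representable in doubles.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) %% 1e6) * 2017 + k * 7919) %% 2147483647L
}

#' @noRd
check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive and finite.", name), call. = FALSE)
  }
  invisible(x)
}

# Inverse-CDF draw from a distribution truncated to (lower, upper), with
# tail switching: when both truncation points sit in the upper tail the
# complementary CDF keeps the interval mass representable.
rtrunc_invcdf <- function(pfun, qfun, lower, upper) {
  p_lo <- pfun(lower, lower.tail = TRUE)
  use_upper_tail <- is.finite(p_lo) && p_lo > 0.5
  if (use_upper_tail) {
    s_lo <- pfun(lower, lower.tail = FALSE)
    s_up <- pfun(upper, lower.tail = FALSE)
    # interval survival mass (s_up, s_lo); draw uniformly inside it
    if (s_lo - s_up > 1e-300) {
      u <- runif(1L, s_up, s_lo)
      val <- qfun(u, lower.tail = FALSE)
    } else {
      val <- NA_real_
    }
  } else {
    p_up <- pfun(upper, lower.tail = TRUE)
    if (p_up - p_lo > 1e-300) {
      u <- runif(1L, p_lo, p_up)
      val <- qfun(u, lower.tail = TRUE)
    } else {
      val <- NA_real_
    }
  }
  # Numerical fallback when the conditional mass underflows or the quantile
  # collapses onto a bound: place the draw just inside the interval.
  if (!is.finite(val) || val <= lower || (is.finite(upper) && val >= upper)) {
    if (is.finite(upper)) {
      val <- lower + (upper - lower) * runif(1L, 0.25, 0.75)
    } else {
      val <- lower * (1 + 1e-8) + 1e-12
    }
  }
  val
}

# Ratio of the spectral density at frequency zero to the sample variance of a
# (possibly autocorrelated) series, estimated from an AIC-selected AR fit.
# Equals 1 for iid draws; inflates the MC variance of an MCMC average.
spectrum0_ratio <- function(x) {
  x <- as.numeric(x)
  v <- var(x)
  if (!is.finite(v) || v <= 0) return(1)
  fit <- tryCatch(
    ar(x, aic = TRUE, order.max = min(50L, floor(length(x) / 4)), method = "yule-walker"),
    error = function(e) NULL
  )
  if (is.null(fit) || length(fit$ar) == 0L) return(1)
  s0 <- fit$var.pred / (1 - sum(fit$ar))^2
  max(s0 / v, 1e-12)
}
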