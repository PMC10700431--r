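greek <- tibble::tibble(
  label = as.character(1:9),
  x = c(509, 353, 177, 114, 77, 77, 53, 73, 64)
)
benford <- log10((1:9 + 1) / (1:9))

test_that("multinomial equality Bayes factor matches closed-form arithmetic", {
  # x=(1,1), a=(1,1), p=(1/2,1/2): B(1,1)/B(2,2) * (1/4) = 6/4
  d <- tibble::tibble(x = c(1, 1))
  expect_equal(mult_bf_equality(d, a = 1, p = c(0.5, 0.5))$log_bf_0e, log(1.5), tolerance = 1e-12)
  # empty data: prior predictive equals null predictive exactly
  expect_equal(mult_bf_equality(tibble::tibble(x = c(0, 0, 0)), a = c(2, 1, 3))$log_bf_0e, 0)
  # a zero predicted proportion with observed counts sinks the null
  expect_equal(
    mult_bf_equality(tibble::tibble(x = c(2, 1)), a = 1, p = c(1, 0))$log_bf_0e,
    -Inf
  )
})

test_that("binomial equality Bayes factors match closed-form arithmetic", {
  # x=(1,1), n=(2,2), uniform priors: B(3,3)/B(2,2)^2 = 36/30
  d <- tibble::tibble(x = c(1, 1), n = c(2, 2))
  expect_equal(binom_bf_equality(d)$log_bf_0e, log(1.2), tolerance = 1e-12)
  # K = 1: collapsing a single category is the identity
  expect_equal(binom_bf_equality(tibble::tibble(x = 3, n = 10))$log_bf_0e, 0)
  # the formula is symmetric in the categories
  d2 <- tibble::tibble(x = c(5, 1, 3), n = c(9, 4, 12))
  perm <- c(3, 1, 2)
  expect_equal(
    binom_bf_equality(d2, a = c(1, 2, 3), b = c(2, 1, 1))$log_bf_0e,
    binom_bf_equality(d2[perm, ], a = c(1, 2, 3)[perm], b = c(2, 1, 1)[perm])$log_bf_0e,
    tolerance = 1e-12
  )
})

test_that("point-null binomial Bayes factor matches quadrature-checked values", {
  # x=1, n=2, theta0=1/2: (1/B(2,2)) * 1/4 = 6/4
  expect_equal(
    binom_bf_equality(tibble::tibble(x = 1, n = 2), p = 0.5)$log_bf_0e,
    log(1.5), tolerance = 1e-12
  )
  expect_equal(
    binom_bf_equality(tibble::tibble(x = 0, n = 1), p = 0.5)$log_bf_0e,
    0, tolerance = 1e-12
  )
  # a near-1 predicted value with zero successes is overwhelmingly refuted
  lbf <- binom_bf_equality(tibble::tibble(x = 0, n = 200), p = 0.999)$log_bf_0e
  expect_lt(lbf, -100)
  expect_error(binom_bf_equality(tibble::tibble(x = 1, n = 2), p = 1.2), "inside")
})

test_that("point-null Bayes factor is maximized at the pooled MLE", {
  x <- c(7, 9); n <- c(20, 21)
  mle <- sum(x) / sum(n)
  f <- function(t) ordbf:::log_binom_bf_equality_point(x, n, c(1, 1), c(1, 1), t)
  eps <- 1e-4
  expect_gt(f(mle), f(mle - eps))
  expect_gt(f(mle), f(mle + eps))
})

test_that("group equality BF over all categories reduces to the uniform-null test", {
  set.seed(42)
  for (rep in 1:5) {
    K <- sample(3:6, 1)
    x <- as.numeric(rpois(K, 20))
    a <- runif(K, 0.5, 3)
    via_group <- ordbf:::log_equality_group_bf(x, a, seq_len(K), family = "multinomial")
    via_null <- ordbf:::log_mult_bf_equality(x, a, rep(1 / K, K))
    expect_equal(via_group, via_null, tolerance = 1e-10)
  }
  # zero counts in the group: prior equals posterior, BF = 1
  expect_equal(ordbf:::log_equality_group_bf(c(0, 0, 5), c(1, 1, 1), 1:2), 0)
  # K = 2 binomial group equals the all-equal binomial formula
  x <- c(4, 6); n <- c(10, 12); a <- c(1, 1); b <- c(1, 1)
  expect_equal(
    ordbf:::log_equality_group_bf(x, a, 1:2, n = n, b = b, family = "binomial"),
    ordbf:::log_binom_bf_equality(x, n, a, b)
  )
})

test_that("printed Benford-test values are reproduced analytically", {
  expect_equal(mult_bf_equality(greek, a = 1, p = benford)$log_bf_0e, -17.67, tolerance = 0.01 / 17.67)
  expect_equal(
    mult_bf_equality(greek, a = c(16, 10, 7, 5, 4, 3, 3, 3, 2), p = benford)$log_bf_0e,
    -26.00, tolerance = 0.01 / 26
  )
  expect_equal(mult_bf_equality(greek, a = 1, p = rep(1 / 9, 9))$log_bf_0e, -479.73, tolerance = 0.01 / 479.73)
  # remaining sensitivity rows
  expect_equal(
    mult_bf_equality(greek, a = c(10, 9, 8, 7, 6, 5, 4, 3, 2), p = benford)$log_bf_0e,
    -20.94, tolerance = 0.001
  )
  expect_equal(mult_bf_equality(greek, a = 6, p = benford)$log_bf_0e, -11.35, tolerance = 0.001)
  expect_equal(
    mult_bf_equality(greek, a = c(12, 6, 6, 6, 6, 6, 6, 3, 3), p = benford)$log_bf_0e,
    -18.62, tolerance = 0.001
  )
})

test_that("log-domain computation survives counts in the millions", {
  x <- c(2e6, 1e6, 5e5, 25e4)
  out <- mult_bf_equality(tibble::tibble(x = x), a = 1, p = rep(0.25, 4))$log_bf_0e
  expect_true(is.finite(out))
  out2 <- binom_bf_equality(tibble::tibble(x = x, n = x * 2))$log_bf_0e
  expect_true(is.finite(out2))
})

test_that("posterior summaries are conjugate beta quantiles", {
  ps <- posterior_summary(tibble::tibble(x = 39, n = 80), level = 0.95)
  expect_equal(ps$median, qbeta(0.5, 40, 42))
  expect_equal(ps$lower, qbeta(0.025, 40, 42))
  expect_equal(ps$upper, qbeta(0.975, 40, 42))
  # symmetry: equal shape parameters center the posterior at 1/2
  ps2 <- posterior_summary(tibble::tibble(x = 10, n = 20), a = 2, b = 2)
  expect_equal(ps2$median, 0.5)
  expect_error(posterior_summary(tibble::tibble(x = 1, n = 2), level = 1.2), "level")
})

test_that("three of nine Benford proportions fall inside the 95% intervals", {
  ps <- posterior_summary(greek, a = 1, level = 0.95)
  inside <- benford > ps$lower & benford < ps$upper
  expect_equal(sum(inside), 3L)
})
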