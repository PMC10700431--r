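test_that("pure equality hypotheses use the analytic path only", {
  d <- tibble::tibble(label = c("1", "2"), x = c(5, 5))
  fit <- mult_bf_informed(d, "1 = 2", bf_type = "LogBFre", seed = 1)
  expect_equal(fit$log_bf_2e, 0)
  expect_equal(nrow(fit$sections), 0L)
  expect_equal(
    fit$log_bf_re,
    ordbf:::log_equality_group_bf(c(5, 5), c(1, 1), 1:2, family = "multinomial")
  )
  expect_equal(fit$percentage_error, 0)
})

test_that("mixed hypotheses factor into equality and conditional order parts", {
  d <- tibble::tibble(label = as.character(1:4), x = c(20, 8, 8, 2))
  fit <- mult_bf_informed(d, "1 > 2 = 3 > 4", bf_type = "LogBFre",
                          seed = 5, n_draws = 4000)
  # the combined factor is exactly the sum of its parts
  expect_equal(fit$log_bf_re, fit$log_bf_1e + fit$log_bf_2e)
  # equality part computed independently
  expect_equal(
    fit$log_bf_1e,
    ordbf:::log_equality_group_bf(c(20, 8, 8, 2), rep(1, 4), 2:3, family = "multinomial")
  )
  # order part equals the sum over independent bridge sections
  expect_equal(fit$log_bf_2e, sum(fit$sections$log_bf))
})

test_that("independent sections multiply (sum on the log scale)", {
  d <- tibble::tibble(label = as.character(1:5), x = c(12, 5, 2, 9, 3))
  fit <- mult_bf_informed(d, "1 > 2 > 3 & 4 > 5", bf_type = "LogBFre",
                          seed = 9, n_draws = 4000)
  expect_equal(nrow(fit$sections), 2L)
  expect_equal(fit$log_bf_re, sum(fit$sections$log_bf))

  # against a joint rejection estimate of the same quantity
  pr <- fit$problem
  np <- naive_constraint_fraction(pr, "prior", 3e5, seed = 10)
  nq <- naive_constraint_fraction(pr, "posterior", 3e5, seed = 11)
  joint <- log(nq$proportion) - log(np$proportion)
  se <- sqrt((np$se / np$proportion)^2 + (nq$se / nq$proportion)^2 +
               (fit$percentage_error / 100)^2)
  expect_lt(abs(fit$log_bf_re - joint), 4 * se)
})

test_that("bf_type conversions are consistent and involutive", {
  d <- tibble::tibble(label = as.character(1:3), x = c(12, 5, 2))
  base <- mult_bf_informed(d, "1 > 2 > 3", bf_type = "LogBFre", seed = 3, n_draws = 3000)
  lre <- base$log_bf_re
  l0e <- base$log_bf_0e
  for (tp in c("BFre", "BFer", "LogBFre", "LogBFer", "BFr0", "BF0r", "LogBFr0", "LogBF0r")) {
    fit <- mult_bf_informed(d, "1 > 2 > 3", bf_type = tp, seed = 3, n_draws = 3000)
    expected <- switch(tp,
      BFre = exp(lre), BFer = exp(-lre), LogBFre = lre, LogBFer = -lre,
      BFr0 = exp(lre - l0e), BF0r = exp(l0e - lre),
      LogBFr0 = lre - l0e, LogBF0r = l0e - lre
    )
    expect_equal(fit$bf, expected, info = tp)
  }
})

test_that("end-to-end runs are reproducible given the seed", {
  d <- tibble::tibble(label = as.character(1:3), x = c(12, 5, 2))
  f1 <- mult_bf_informed(d, "1 > 2 > 3", seed = 77, n_draws = 2000)
  f2 <- mult_bf_informed(d, "1 > 2 > 3", seed = 77, n_draws = 2000)
  expect_identical(f1$log_bf_re, f2$log_bf_re)
  expect_identical(f1$sections, f2$sections)

  b <- tibble::tibble(label = c("a", "b"), x = c(2, 8), n = c(10, 10))
  g1 <- binom_bf_informed(b, "a < b", seed = 78, n_draws = 2000)
  g2 <- binom_bf_informed(b, "a < b", seed = 78, n_draws = 2000)
  expect_identical(g1$log_bf_re, g2$log_bf_re)
})

test_that("binomial informed Bayes factor matches the rejection identity", {
  d <- tibble::tibble(label = c("a", "b", "c"), x = c(2, 5, 9), n = c(10, 10, 12))
  fit <- binom_bf_informed(d, "a < b < c", bf_type = "LogBFre", seed = 12, n_draws = 5000)
  np <- naive_constraint_fraction(fit$problem, "prior", 3e5, seed = 13)
  nq <- naive_constraint_fraction(fit$problem, "posterior", 3e5, seed = 14)
  joint <- log(nq$proportion) - log(np$proportion)
  se <- sqrt((np$se / np$proportion)^2 + (nq$se / nq$proportion)^2 +
               (fit$percentage_error / 100)^2)
  expect_lt(abs(fit$log_bf_re - joint), 4 * se)
})

test_that("posterior model probabilities normalize correctly", {
  # equal evidence, uniform prior: 1/M each
  d <- tibble::tibble(hypothesis = c("A", "B", "C"), log_bf = c(1, 1, 1))
  out <- posterior_model_probabilities(d)
  expect_equal(out$posterior_prob, rep(1 / 3, 3))
  # extreme log BFs survive the log-sum-exp
  d2 <- tibble::tibble(hypothesis = c("A", "B"), log_bf = c(-500, 7))
  out2 <- posterior_model_probabilities(d2)
  expect_equal(sum(out2$posterior_prob), 1)
  expect_lt(out2$posterior_prob[1], 1e-200)
  expect_error(posterior_model_probabilities(d2, prior_prob = c(0.4, 0.4)), "sum to 1")
})

test_that("Bayes factor ratios are transitive and antisymmetric", {
  expect_equal(bf_ratio(log(22.36), log(17.82), log = FALSE), 22.36 / 17.82)
  expect_equal(bf_ratio(2.5, 2.5), 0)
  expect_equal(bf_ratio(1.2, 0.7), -bf_ratio(0.7, 1.2))
})

test_that("tidy and glance expose the factorization", {
  d <- tibble::tibble(label = as.character(1:4), x = c(20, 8, 8, 2))
  fit <- mult_bf_informed(d, "1 > 2 = 3 > 4", bf_type = "BFre", seed = 5, n_draws = 3000)
  td <- tidy(fit)
  expect_setequal(unique(td$component), c("equality", "order", "combined"))
  comb <- td$log_bf[td$component == "combined"]
  expect_equal(comb, sum(td$log_bf[td$component != "combined"]))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$bf, fit$bf)
  expect_equal(gl$log_bf_re, comb)
})

test_that("results serialize to JSON with an input echo", {
  d <- tibble::tibble(label = c("1", "2"), x = c(5, 5))
  fit <- mult_bf_informed(d, "1 = 2", seed = 1)
  js <- jsonlite::fromJSON(informed_bf_json(fit))
  expect_equal(js$bf, fit$bf)
  expect_equal(js$input$data$x, c(5, 5))
  expect_equal(js$hypothesis, fit$hypothesis)
})

test_that("autoplot returns a ggplot of posterior intervals", {
  d <- tibble::tibble(label = c("1", "2"), x = c(5, 5))
  fit <- mult_bf_informed(d, "1 = 2", seed = 1)
  p <- ggplot2::autoplot(fit, expected = c(0.5, 0.5))
  expect_s3_class(p, "ggplot")
})
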