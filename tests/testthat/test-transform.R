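test_that("probit map basics: zero real coordinates hit interval midpoints", {
  # single unconstrained binomial coordinate: Phi(0) = 0.5
  pr <- make_problem("1 < 2 < 3", x = c(0, 0, 0), n = c(1, 1, 1))
  fwd <- to_probability(matrix(0, 1, 3), pr)
  # each theta is the midpoint of (previous theta, 1)
  expect_equal(unname(as.numeric(fwd$theta)), c(0.5, 0.75, 0.875))
  expect_true(all(fwd$in_region))
})

test_that("multinomial stick bounds: smallest of three ordered proportions is below 1/3", {
  pr <- make_problem("1 < 2 < 3", x = c(0, 0, 0))
  # push the first coordinate to +infinity: theta1 approaches its upper bound 1/3
  fwd <- to_probability(cbind(8, 0), pr)
  expect_equal(unname(fwd$theta[1, 1]), 1 / 3, tolerance = 1e-6)
  # and the second coordinate approaches its bound (1 - theta1)/2
  fwd2 <- to_probability(cbind(0, 8), pr)
  u2 <- unname((1 - fwd2$theta[1, 1]) / 2)
  expect_equal(unname(fwd2$theta[1, 2]), u2, tolerance = 1e-6)
})

test_that("round trip is the identity on constrained draws", {
  problems <- list(
    make_problem("1 < 2 < 3", x = c(5, 10, 20)),
    make_problem("1 , 2 < 3 , 4", x = c(2, 3, 9, 8)),
    make_problem("1 = 2 < 3 , 4", x = c(6, 3, 9, 8)),
    make_problem("1 < 2 = 3 < 4", x = c(2, 9, 9, 20)),
    make_problem("1 , 2 < 3 , 4", x = c(2, 3, 9, 8), n = c(10, 10, 12, 12)),
    make_problem("1 < 2 < 3 < 4", x = c(1, 3, 6, 9), n = rep(12, 4))
  )
  for (pr in problems) {
    for (target in c("prior", "posterior")) {
      s <- sample_constrained(pr, target, n_draws = 2500, n_burn = 200, seed = 13)
      tr <- to_real(s)
      expect_true(all(is.finite(tr$xi)))
      back <- to_probability(tr$xi, pr)
      expect_lt(max(abs(back$theta - s$draws)), 1e-8)
      expect_true(all(back$in_region))
      expect_equal(back$log_jacobian, tr$log_jacobian, tolerance = 1e-8)
    }
  }
})

test_that("any finite real point maps into the constraint for chain problems", {
  pr <- make_problem("1 < 2 < 3", x = c(1, 2, 3))
  # coordinates bounded: beyond |xi| ~ 8 the probit saturates in double
  # precision and the image lands exactly on the region boundary
  set.seed(17)
  xi <- matrix(pmax(pmin(rnorm(600, sd = 2.5), 6), -6), ncol = 2)
  fwd <- to_probability(xi, pr)
  expect_true(all(fwd$in_region))
  expect_true(all(abs(rowSums(fwd$theta) - 1) < 1e-12))
  # extreme negative coordinates collapse towards the lower bounds, still ordered
  low <- to_probability(cbind(-30, -30), pr)
  expect_true(all(low$in_region))
  expect_lt(low$theta[1, 1], 1e-8)
})

test_that("free-group density is invariant under member relabelling", {
  # exchangeable prior: writing the free pair as "1 , 2" or "2 , 1" is the
  # same density on the real line, coordinate for coordinate
  pr_a <- make_problem("1 , 2 < 3", x = c(0, 0, 0))
  pr_b <- make_problem("2 , 1 < 3", x = c(0, 0, 0))
  set.seed(31)
  xi <- matrix(rnorm(40), ncol = 2)
  expect_equal(
    log_target_density_real(xi, pr_a, "prior"),
    log_target_density_real(xi, pr_b, "prior"),
    tolerance = 1e-12
  )
})

test_that("transformed target integrates to the constrained-region mass", {
  # binomial K=2, uniform priors, theta1 < theta2: mass exactly 1/2
  pr <- make_problem("1 < 2", x = c(0, 0), n = c(1, 1))
  expect_equal(quad_region_mass(pr, "prior"), 0.5, tolerance = 1e-4)

  # same problem, posterior target with x=(2,1), n=(10,7): mass 0.42570
  pr2 <- make_problem("1 < 2", x = c(2, 1), n = c(10, 7))
  expect_equal(quad_region_mass(pr2, "posterior"), 0.42570, tolerance = 2e-4)

  # multinomial K=3 ordered, uniform Dirichlet: mass 1/3! both prior and a
  # nonuniform prior checked against rejection
  pr3 <- make_problem("1 < 2 < 3", x = c(0, 0, 0))
  expect_equal(quad_region_mass(pr3, "prior"), 1 / 6, tolerance = 1e-4)

  pr4 <- make_problem("1 , 2 < 3", x = c(0, 0, 0))
  expect_equal(quad_region_mass(pr4, "prior"), 1 / 3, tolerance = 1e-4)

  # merged equality group of multiplicity 2 competing at theta/2:
  # region theta1/2 < theta2 under Dirichlet(a) <=> theta1 < 2/3
  pr5 <- make_problem("1 = 2 < 3", x = c(0, 0, 0), a = c(1.5, 1.5, 2))
  expect_equal(length(pr5$x), 2L)
  expect_equal(pr5$group_sizes, c(2L, 1L))
  expect_equal(quad_region_mass(pr5, "prior"), pbeta(2 / 3, 2, 2), tolerance = 1e-4)
})

test_that("boundary draws are rejected with the offending index", {
  pr <- make_problem("1 < 2", x = c(0, 0), n = c(1, 1))
  s <- sample_constrained(pr, "prior", n_draws = 10, seed = 1)
  s$draws[3, 1] <- 0
  expect_error(to_real(s), "Draw 3")
})

test_that("log target density at the origin matches the closed form", {
  # unconstrained Beta(1,1): density 1, Jacobian phi(xi); at xi = 0
  d <- tibble::tibble(label = "a", x = 0, n = 1)
  rl <- parse_hypothesis("a", d$label)
  pr <- split_restriction(rl, d, a = 1, b = 1, family = "binomial")$problem
  pr$restriction$sections <- list(list(list(1L)))  # single free element
  expect_equal(
    log_target_density_real(matrix(0, 1, 1), pr, "prior"),
    dnorm(0, log = TRUE)
  )
})
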