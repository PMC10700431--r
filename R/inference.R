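# Top-level assembly: parse -> split -> analytic equality Bayes factors ->
# per-section bridge estimates of the conditional order-constraint Bayes
# factor -> combined Bayes factor, on the requested scale.

bf_types <- c("BFre", "BFer", "LogBFre", "LogBFer",
              "BFr0", "BF0r", "LogBFr0", "LogBF0r")

convert_bf <- function(log_bf_re, log_bf_0e, bf_type) {
  log_r0 <- log_bf_re - log_bf_0e
  switch(bf_type,
    BFre = exp(log_bf_re),
    BFer = exp(-log_bf_re),
    LogBFre = log_bf_re,
    LogBFer = -log_bf_re,
    BFr0 = exp(log_r0),
    BF0r = exp(-log_r0),
    LogBFr0 = log_r0,
    LogBF0r = -log_r0
  )
}

informed_bf_pipeline <- function(data, hypothesis, a, b, family, bf_type,
                                 seed, n_draws, n_burn, thin) {
  bf_type <- match.arg(bf_type, bf_types)
  data <- as.data.frame(data)
  K <- nrow(data)
  if (is.null(data$label)) data$label <- as.character(seq_len(K))
  labels <- as.character(data$label)
  x <- as.numeric(data$x)
  a <- rep_len(as.numeric(a), K)
  if (family == "binomial") {
    n <- as.numeric(data$n)
    b <- rep_len(as.numeric(b), K)
  } else {
    n <- NULL
    b <- NULL
  }

  rl <- parse_hypothesis(hypothesis, labels)
  sp <- split_restriction(rl, data, a = a, b = b, family = family)
  problem <- sp$problem

  # analytic part: one Savage-Dickey factor per equality-tied group
  log_bf_1e <- sum(purrr::map_dbl(
    sp$equality_groups,
    ~ log_equality_group_bf(x, a, .x, n = n, b = b, family = family)
  ))

  # order-constraint part: independent bridge runs per section
  sections <- seq_along(problem$restriction$sections)
  section_tbl <- tibble(
    section = integer(), logml_prior = double(), logml_posterior = double(),
    log_bf = double(), re2 = double(), converged = logical()
  )
  bridges <- list()
  log_bf_2e <- 0
  for (s in sections) {
    sub <- section_subproblem(problem, s)
    pri_s <- sample_constrained(sub, "prior", n_draws = n_draws, n_burn = n_burn,
                                thin = thin, seed = derive_seed(seed, 4L * s + 0L))
    pri_b <- bridge_logml(pri_s, seed = derive_seed(seed, 4L * s + 1L))
    pos_s <- sample_constrained(sub, "posterior", n_draws = n_draws, n_burn = n_burn,
                                thin = thin, seed = derive_seed(seed, 4L * s + 2L))
    pos_b <- bridge_logml(pos_s, seed = derive_seed(seed, 4L * s + 3L))
    log_bf_2e <- log_bf_2e + (pos_b$logml - pri_b$logml)
    section_tbl <- dplyr::bind_rows(section_tbl, tibble(
      section = s,
      logml_prior = pri_b$logml,
      logml_posterior = pos_b$logml,
      log_bf = pos_b$logml - pri_b$logml,
      re2 = pri_b$re2 + pos_b$re2,
      converged = pri_b$converged && pos_b$converged
    ))
    bridges[[s]] <- list(prior = pri_b, posterior = pos_b)
  }

  log_bf_re <- log_bf_1e + log_bf_2e
  log_bf_0e <- if (family == "binomial") {
    log_binom_bf_equality(x, n, a, b)
  } else {
    log_mult_bf_equality(x, a, rep(1 / K, K))
  }

  # independent bridge errors combine in quadrature on the log scale
  pe <- if (nrow(section_tbl)) 100 * sqrt(sum(section_tbl$re2)) else 0

  structure(
    list(
      family = family,
      data = as_tibble(data[, intersect(c("label", "x", "n"), names(data))]),
      a = a, b = b,
      hypothesis = rl$hypothesis,
      restriction = rl,
      equality_groups = sp$equality_groups,
      problem = problem,
      log_bf_1e = log_bf_1e,
      log_bf_2e = log_bf_2e,
      log_bf_re = log_bf_re,
      log_bf_0e = log_bf_0e,
      bf_type = bf_type,
      bf = convert_bf(log_bf_re, log_bf_0e, bf_type),
      sections = section_tbl,
      bridges = bridges,
      percentage_error = pe,
      converged = all(section_tbl$converged),
      seed = seed,
      n_draws = n_draws
    ),
    class = "informed_bf"
  )
}

#' Evaluate an informed hypothesis on multinomial proportions
#'
#' Computes the Bayes factor for an informed hypothesis — equality
#' constraints, order constraints, free parameters, and `&`-separated
#' independent combinations thereof — against the encompassing hypothesis
#' (all proportions free under a Dirichlet(`a`) prior) or the null hypothesis
#' of equal proportions. Equality constraints are evaluated analytically;
#' order constraints by bridge-sampling the normalizing constants of the
#' constrained prior and posterior densities, whose ratio is the conditional
#' Bayes factor for the order constraints given the equalities.
#'
#' @param data Data frame with a column `x` of counts and optionally `label`
#'   (category labels, used in hypothesis strings).
#' @param hypothesis Constraint string or token vector, e.g.
#'   `"1 > 2 = 3 > 4 , 5"`; see [parse_hypothesis()].
#' @param a Dirichlet concentration parameters; scalar or length-K.
#' @param bf_type One of `"BFre"`, `"BFer"`, `"LogBFre"`, `"LogBFer"`,
#'   `"BFr0"`, `"BF0r"`, `"LogBFr0"`, `"LogBF0r"`. The `r0` types compare
#'   against the equal-proportions null.
#' @param seed Optional integer seed; per-section sampler and proposal seeds
#'   are derived deterministically from it.
#' @param n_draws Retained constrained draws per density (half fit the
#'   proposal, half enter the bridge); default 12000.
#' @param n_burn,thin Gibbs burn-in and thinning; defaults 500 and 1.
#'
#' @return An `informed_bf` object; see [tidy.informed_bf()],
#'   [glance.informed_bf()], [autoplot.informed_bf()].
#'
#' @examples
#' d <- tibble::tibble(label = as.character(1:3), x = c(20, 10, 5))
#' fit <- mult_bf_informed(d, "1 > 2 > 3", seed = 1, n_draws = 2000)
#' glance(fit)
#' @export
mult_bf_informed <- function(data, hypothesis, a = 1, bf_type = "BFre",
                             seed = NULL, n_draws = 12000, n_burn = 500,
                             thin = 1) {
  informed_bf_pipeline(data, hypothesis, a = a, b = NULL,
                       family = "multinomial", bf_type = bf_type,
                       seed = seed, n_draws = n_draws, n_burn = n_burn,
                       thin = thin)
}

#' Evaluate an informed hypothesis on independent binomial proportions
#'
#' Binomial counterpart of [mult_bf_informed()]: each category has an
#' independent Beta(`a`, `b`) prior on its success probability.
#'
#' @inheritParams mult_bf_informed
#' @param data Data frame with columns `x` (successes), `n` (trials), and
#'   optionally `label`.
#' @param b Beta prior beta parameters; scalar or length-K.
#'
#' @return An `informed_bf` object.
#'
#' @examples
#' d <- tibble::tibble(label = c("lo", "hi"), x = c(2, 8), n = c(10, 10))
#' fit <- binom_bf_informed(d, "lo < hi", seed = 1, n_draws = 2000)
#' glance(fit)
#' @export
binom_bf_informed <- function(data, hypothesis, a = 1, b = 1,
                              bf_type = "BFre", seed = NULL, n_draws = 12000,
                              n_burn = 500, thin = 1) {
  informed_bf_pipeline(data, hypothesis, a = a, b = b,
                       family = "binomial", bf_type = bf_type,
                       seed = seed, n_draws = n_draws, n_burn = n_burn,
                       thin = thin)
}

#' Posterior model probabilities from Bayes factors against a common reference
#'
#' Normalizes a set of log Bayes factors — all against the same encompassing
#' hypothesis and prior — into posterior model probabilities via log-sum-exp.
#' Include the encompassing hypothesis itself as `log_bf = 0`.
#'
#' @param data Data frame with columns `hypothesis` (labels) and `log_bf`
#'   (log Bayes factors vs the common reference), optionally `prior_prob`.
#' @param prior_prob Prior model probabilities (summing to 1); default equal.
#'
#' @return The input tibble with a `posterior_prob` column.
#'
#' @examples
#' d <- tibble::tibble(hypothesis = c("H0", "Hr", "He"), log_bf = c(-3, 2, 0))
#' posterior_model_probabilities(d)
#' @export
posterior_model_probabilities <- function(data, prior_prob = NULL) {
  data <- as_tibble(data)
  M <- nrow(data)
  if (is.null(prior_prob) && "prior_prob" %in% names(data)) prior_prob <- data$prior_prob
  if (is.null(prior_prob)) prior_prob <- rep(1 / M, M)
  if (any(prior_prob < 0) || abs(sum(prior_prob) - 1) > 1e-8) {
    stop("`prior_prob` must be non-negative and sum to 1.", call. = FALSE)
  }
  lw <- data$log_bf + log(prior_prob)
  data$prior_prob <- prior_prob
  data$posterior_prob <- exp(lw - logsumexp(lw))
  data
}

#' Bayes factor between two informed hypotheses
#'
#' By transitivity, two informed hypotheses evaluated against the same
#' encompassing hypothesis (same prior) compare as the ratio of their Bayes
#' factors: `log BF_r1r2 = log BF_r1e - log BF_r2e`.
#'
#' @param log_bf1,log_bf2 Log Bayes factors of the two hypotheses against the
#'   common encompassing hypothesis.
#' @param log Return the log Bayes factor (default) or the plain ratio.
#' @return `log BF_r1r2` (or `BF_r1r2` when `log = FALSE`).
#' @examples
#' bf_ratio(log(22.36), log(17.82), log = FALSE)
#' @export
bf_ratio <- function(log_bf1, log_bf2, log = TRUE) {
  out <- log_bf1 - log_bf2
  if (log) out else exp(out)
}
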