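# Shared builders for small constrained problems used across test files.

make_problem <- function(hypothesis, x, a = 1, n = NULL, b = 1,
                         family = if (is.null(n)) "multinomial" else "binomial",
                         labels = as.character(seq_along(x))) {
  d <- if (is.null(n)) tibble::tibble(label = labels, x = x)
       else tibble::tibble(label = labels, x = x, n = n)
  rl <- parse_hypothesis(hypothesis, labels)
  split_restriction(rl, d, a = a, b = b, family = family)$problem
}

# region mass of a single-section problem by quadrature over the transformed
# real coordinates (d = 1 or 2): independent check of the transform's
# normalization, and of bridge estimates on tiny problems
quad_region_mass <- function(problem, target, lim = 9) {
  d <- if (problem$family == "multinomial") length(problem$x) - 1L else length(problem$x)
  if (d == 1L) {
    f <- function(x1) exp(log_target_density_real(matrix(x1, ncol = 1L), problem, target))
    stats::integrate(f, -lim, lim, rel.tol = 1e-9)$value
  } else if (d == 2L) {
    inner <- function(x1) {
      vapply(x1, function(v) {
        f2 <- function(x2) exp(log_target_density_real(cbind(v, x2), problem, target))
        stats::integrate(f2, -lim, lim, rel.tol = 1e-7)$value
      }, numeric(1L))
    }
    stats::integrate(inner, -lim, lim, rel.tol = 1e-6)$value
  } else {
    stop("quadrature helper supports d <= 2")
  }
}
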