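#' @export
print.informed_bf <- function(x, ...) {
  cat("Informed-hypothesis Bayes factor (", x$family, " model)\n", sep = "")
  cat("  Hr: ", x$hypothesis, "\n", sep = "")
  cat("  counts: ", paste(x$data$x, collapse = ", "), "\n", sep = "")
  cat(sprintf("  %s = %.4f", x$bf_type, x$bf))
  if (nrow(x$sections)) {
    cat(sprintf("  (bridge %%err %.3f%%%s)", x$percentage_error,
                if (x$converged) "" else ", NOT converged"))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.informed_bf <- function(object, ...) {
  print(object)
  cat(sprintf("  log BF (equality part):   %.4f\n", object$log_bf_1e))
  cat(sprintf("  log BF (order part):      %.4f\n", object$log_bf_2e))
  cat(sprintf("  log BF_re:                %.4f\n", object$log_bf_re))
  cat(sprintf("  log BF_0e (equal null):   %.4f\n", object$log_bf_0e))
  invisible(object)
}

#' Component-level view of an informed Bayes factor
#'
#' One row per Bayes factor component: each equality-tied group (analytic),
#' each independent order-constraint section (bridge-estimated, with its
#' relative error), and the combined informed-vs-encompassing factor.
#'
#' @param x An `informed_bf` object.
#' @param ... Unused.
#' @return A tibble with columns `component`, `term`, `log_bf`,
#'   `percentage_error`, `converged`.
#' @exportS3Method generics::tidy
tidy.informed_bf <- function(x, ...) {
  rows <- list()
  labs <- x$restriction$labels
  for (g in x$equality_groups) {
    lbf <- log_equality_group_bf(
      as.numeric(x$data$x), x$a, g,
      n = if (x$family == "binomial") as.numeric(x$data$n) else NULL,
      b = x$b, family = x$family
    )
    rows[[length(rows) + 1L]] <- tibble(
      component = "equality",
      term = paste(labs[g], collapse = " = "),
      log_bf = lbf, percentage_error = 0, converged = TRUE
    )
  }
  if (nrow(x$sections)) {
    sec_terms <- purrr::map_chr(
      seq_len(nrow(x$sections)),
      ~ section_subproblem(x$problem, .x)$restriction$hypothesis
    )
    rows[[length(rows) + 1L]] <- tibble(
      component = "order",
      term = sec_terms,
      log_bf = x$sections$log_bf,
      percentage_error = 100 * sqrt(x$sections$re2),
      converged = x$sections$converged
    )
  }
  rows[[length(rows) + 1L]] <- tibble(
    component = "combined",
    term = x$hypothesis,
    log_bf = x$log_bf_re,
    percentage_error = x$percentage_error,
    converged = x$converged
  )
  dplyr::bind_rows(rows)
}

#' One-row summary of an informed Bayes factor
#'
#' @param x An `informed_bf` object.
#' @param ... Unused.
#' @return A one-row tibble: `bf_type`, `bf`, `log_bf_re`, `log_bf_1e`,
#'   `log_bf_2e`, `log_bf_0e`, `percentage_error`, `converged`, `n_draws`,
#'   `seed`.
#' @exportS3Method generics::glance
glance.informed_bf <- function(x, ...) {
  tibble(
    bf_type = x$bf_type,
    bf = x$bf,
    log_bf_re = x$log_bf_re,
    log_bf_1e = x$log_bf_1e,
    log_bf_2e = x$log_bf_2e,
    log_bf_0e = x$log_bf_0e,
    percentage_error = x$percentage_error,
    converged = x$converged,
    n_draws = x$n_draws,
    seed = if (is.null(x$seed)) NA_integer_ else as.integer(x$seed)
  )
}

#' Plot posterior medians and credible intervals under the encompassing model
#'
#' @param object An `informed_bf` object.
#' @param level Credible-interval coverage; default 0.95.
#' @param expected Optional numeric vector of expected proportions to overlay
#'   (e.g. predicted category proportions under a point null).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.informed_bf <- function(object, level = 0.95, expected = NULL, ...) {
  ps <- posterior_summary(object$data, a = object$a, b = object$b,
                          family = object$family, level = level)
  ps$label <- factor(ps$label, levels = ps$label)
  p <- ggplot2::ggplot(ps, ggplot2::aes(x = .data$label, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::labs(
      x = "Category",
      y = if (object$family == "binomial") "Success probability" else "Proportion",
      title = sprintf("Posterior medians and %d%% credible intervals", round(level * 100))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(expected)) {
    ps$expected <- expected
    p <- p + ggplot2::geom_point(
      data = ps, ggplot2::aes(y = .data$expected),
      colour = "#d55e00", shape = 4, size = 3
    )
  }
  p
}

#' @export
plot.informed_bf <- function(x, ...) print(autoplot(x, ...))

#' Serialize an informed Bayes factor result to JSON
#'
#' Emits all scalar result fields, the per-component breakdown, and an echo
#' of the inputs (counts, priors, hypothesis, seed).
#'
#' @param x An `informed_bf` object.
#' @param pretty Pretty-print the JSON; default TRUE.
#' @return A JSON string (class `json`).
#' @export
informed_bf_json <- function(x, pretty = TRUE) {
  stopifnot(inherits(x, "informed_bf"))
  payload <- list(
    family = x$family,
    hypothesis = x$hypothesis,
    bf_type = x$bf_type,
    bf = x$bf,
    log_bf_re = x$log_bf_re,
    log_bf_1e = x$log_bf_1e,
    log_bf_2e = x$log_bf_2e,
    log_bf_0e = x$log_bf_0e,
    percentage_error = x$percentage_error,
    converged = x$converged,
    components = tidy(x),
    input = list(
      data = x$data,
      a = x$a,
      b = x$b,
      seed = x$seed,
      n_draws = x$n_draws
    )
  )
  jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = pretty, null = "null")
}
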