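#' Parse an informed hypothesis into a restriction list
#'
#' Informed hypotheses constrain category proportions with `<` / `>`
#' (inequality), `=` (equality), `,` (free parameters within a constraint),
#' and `&` (independent constraints). Categories are referenced by their
#' labels in `factor_levels` or by 1-based indices. Within each independent
#' constraint all elements must form a linear chain ("stick" hypotheses);
#' partial orders (branched hypotheses) are not representable in this grammar
#' and are therefore unsupported.
#'
#' `=` binds tighter than `,`: in `"4 , 5 = 6"` the free element has two
#' members, the singleton `4` and the equality-tied pair `{5, 6}`, with no
#' order between them. Descending chains (`>`) are stored in ascending
#' canonical form.
#'
#' @param hypothesis A string such as `"t1 > t2 > t3"` or an equivalent
#'   character vector of tokens, e.g. `c("t1", ">", "t2", ">", "t3")`.
#' @param factor_levels Character vector of unique category labels, in the
#'   order of the data vector.
#'
#' @return An object of class `restriction_list`: a list with `sections`
#'   (each section a list of elements, ascending; each element a list of
#'   integer "units" — singletons or equality-tied index groups),
#'   `labels`, and the canonical hypothesis string.
#'
#' @examples
#' parse_hypothesis("t1 > t2 > t3", c("t1", "t2", "t3"))
#' parse_hypothesis("1 > 2 > 3 & 4 , 5 = 6", as.character(1:6))
#' @export
parse_hypothesis <- function(hypothesis, factor_levels) {
  factor_levels <- as.character(factor_levels)
  if (anyDuplicated(factor_levels)) {
    stop("`factor_levels` must be unique.", call. = FALSE)
  }
  if (!is.character(hypothesis) || length(hypothesis) < 1L) {
    stop("`hypothesis` must be a string or character token vector.", call. = FALSE)
  }
  txt <- paste(hypothesis, collapse = " ")
  # pad operators so the stream splits on whitespace
  txt <- gsub("([<>=,&])", " \\1 ", txt)
  tokens <- strsplit(trimws(txt), "\\s+")[[1]]
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) {
    stop("Empty hypothesis.", call. = FALSE)
  }

  ops <- c("<", ">", "=", ",", "&")
  resolve <- function(tok) {
    i <- match(tok, factor_levels)
    if (!is.na(i)) return(i)
    if (grepl("^[0-9]+$", tok)) {
      i <- as.integer(tok)
      if (i >= 1L && i <= length(factor_levels)) return(i)
    }
    stop(sprintf("Unknown category label or index: '%s'.", tok), call. = FALSE)
  }

  # token stream -> sections -> chains of elements -> free units -> indices
  split_on <- function(toks, op) {
    idx <- which(toks == op)
    starts <- c(1L, idx + 1L)
    ends <- c(idx - 1L, length(toks))
    purrr::map2(starts, ends, function(s, e) {
      if (s > e) stop(sprintf("Malformed hypothesis near '%s'.", op), call. = FALSE)
      toks[s:e]
    })
  }

  parse_unit <- function(toks) {
    if (any(toks %in% ops[ops != "="])) {
      stop("Malformed hypothesis: misplaced operator inside an element.", call. = FALSE)
    }
    parts <- split_on(toks, "=")
    idx <- purrr::map_int(parts, function(p) {
      if (length(p) != 1L) stop("Malformed hypothesis: expected a single category per term.", call. = FALSE)
      as.integer(resolve(p))
    })
    idx
  }

  parse_element <- function(toks) {
    units <- purrr::map(split_on(toks, ","), parse_unit)
    units
  }

  parse_section <- function(toks) {
    signs <- unique(toks[toks %in% c("<", ">")])
    if (length(signs) > 1L) {
      stop("Mixed '<' and '>' within one constraint; use a single direction.", call. = FALSE)
    }
    chain_toks <- if (length(signs) == 1L) split_on(toks, signs) else list(toks)
    elements <- purrr::map(chain_toks, parse_element)
    if (identical(signs, ">")) elements <- rev(elements)
    elements
  }

  sections <- purrr::map(split_on(tokens, "&"), parse_section)

  all_idx <- unlist(sections, use.names = FALSE)
  dup <- all_idx[duplicated(all_idx)]
  if (length(dup) > 0L) {
    stop(sprintf(
      "Category '%s' is used more than once; an index or category label can appear only once in a hypothesis.",
      factor_levels[dup[1L]]
    ), call. = FALSE)
  }

  rl <- structure(
    list(sections = sections, labels = factor_levels),
    class = "restriction_list"
  )
  rl$hypothesis <- format(rl)
  rl
}

#' @export
format.restriction_list <- function(x, ...) {
  fmt_unit <- function(u) paste(x$labels[u], collapse = " = ")
  fmt_element <- function(el) paste(purrr::map_chr(el, fmt_unit), collapse = " , ")
  fmt_section <- function(sec) paste(purrr::map_chr(sec, fmt_element), collapse = " < ")
  paste(purrr::map_chr(x$sections, fmt_section), collapse = " & ")
}

#' @export
print.restriction_list <- function(x, ...) {
  cat("Restriction list (", length(x$sections), " independent constraint",
      if (length(x$sections) > 1L) "s", "):\n  ", format(x), "\n", sep = "")
  invisible(x)
}

element_kind <- function(el) {
  if (length(el) > 1L) "free_group"
  else if (length(el[[1L]]) > 1L) "equality_group"
  else "singleton"
}

# all category indices mentioned in a restriction list, in chain order
restriction_indices <- function(rl) {
  as.integer(unlist(rl$sections, use.names = FALSE))
}

#' Split a restriction into its equality part and a collapsed order problem
#'
#' Mixed hypotheses factor into an analytic Bayes factor for the equality
#' constraints and a conditional Bayes factor for the order constraints given
#' the equalities. This function extracts the equality-tied groups and builds
#' the collapsed problem on which the order constraints act: each
#' equality-tied group of m categories is merged into a single category whose
#' count is the member sum and whose concentration parameter is the member
#' sum minus (m - 1), the correction for the reduction in the number of
#' categories. For binomial models both the alpha and beta parameters (and
#' the trial counts) are merged the same way.
#'
#' @param rl A `restriction_list` from [parse_hypothesis()].
#' @param data Data frame with one row per category: column `x` (counts /
#'   successes), optionally `n` (trials; required for binomial), optionally
#'   `label`.
#' @param a Prior concentration parameters (Dirichlet, or beta alpha);
#'   scalar or length-K vector. Default 1.
#' @param b Beta prior beta parameters (binomial only); scalar or vector.
#' @param family `"multinomial"` or `"binomial"`.
#'
#' @return A list with `equality_groups` (list of original index vectors,
#'   size >= 2) and `problem`, a `collapsed_problem` carrying the collapsed
#'   counts, priors, group sizes, and an inequality-only restriction over
#'   the collapsed categories (`trivial = TRUE` when no order constraint
#'   remains).
#' @export
split_restriction <- function(rl, data, a = 1, b = 1,
                              family = c("multinomial", "binomial")) {
  family <- match.arg(family)
  stopifnot(inherits(rl, "restriction_list"))
  data <- as.data.frame(data)
  K <- nrow(data)
  if (length(rl$labels) != K) {
    stop("Restriction labels and data have different numbers of categories.", call. = FALSE)
  }
  x <- as.numeric(data$x)
  if (any(x < 0) || any(x != round(x))) stop("Counts `x` must be non-negative integers.", call. = FALSE)
  a <- rep_len(as.numeric(a), K)
  check_positive(a, "a")
  if (family == "binomial") {
    if (is.null(data$n)) stop("Binomial models need a column `n` of trial counts.", call. = FALSE)
    n <- as.numeric(data$n)
    if (any(x > n)) stop("Successes cannot exceed trials.", call. = FALSE)
    b <- rep_len(as.numeric(b), K)
    check_positive(b, "b")
  } else {
    n <- NULL
    b <- NULL
  }

  # each unit (singleton or equality group) becomes one collapsed category;
  # categories not mentioned in the hypothesis stay free and unconstrained
  units <- list()
  new_sections <- list()
  for (s in seq_along(rl$sections)) {
    sec <- rl$sections[[s]]
    new_sec <- list()
    for (e in seq_along(sec)) {
      new_el <- list()
      for (u in seq_along(sec[[e]])) {
        units[[length(units) + 1L]] <- sec[[e]][[u]]
        new_el[[length(new_el) + 1L]] <- length(units)
      }
      new_sec[[e]] <- new_el
    }
    new_sections[[s]] <- new_sec
  }
  mentioned <- unlist(units, use.names = FALSE)
  for (k in setdiff(seq_len(K), mentioned)) {
    units[[length(units) + 1L]] <- k
  }

  equality_groups <- purrr::keep(units, ~ length(.x) > 1L)
  m <- purrr::map_int(units, length)
  x2 <- purrr::map_dbl(units, ~ sum(x[.x]))
  a2 <- purrr::map_dbl(units, ~ sum(a[.x])) - (m - 1)
  if (any(a2 <= 0)) {
    stop("Collapsed concentration parameter <= 0; increase the prior counts of the equality-tied categories.", call. = FALSE)
  }
  labels2 <- purrr::map_chr(units, ~ paste(rl$labels[.x], collapse = "="))
  if (family == "binomial") {
    n2 <- purrr::map_dbl(units, ~ sum(n[.x]))
    b2 <- purrr::map_dbl(units, ~ sum(b[.x])) - (m - 1)
    if (any(b2 <= 0)) {
      stop("Collapsed beta parameter <= 0; increase the prior counts of the equality-tied categories.", call. = FALSE)
    }
  } else {
    n2 <- NULL
    b2 <- NULL
  }

  # only sections with at least two chain elements impose order constraints
  ineq_sections <- purrr::keep(new_sections, ~ length(.x) > 1L)
  restriction <- structure(
    list(sections = ineq_sections, labels = labels2),
    class = "restriction_list"
  )
  restriction$hypothesis <- if (length(ineq_sections)) format(restriction) else ""

  problem <- structure(
    list(
      family = family,
      x = x2, n = n2, a = a2, b = b2,
      group_sizes = m,
      labels = labels2,
      restriction = restriction,
      trivial = length(ineq_sections) == 0L
    ),
    class = "collapsed_problem"
  )

  list(equality_groups = equality_groups, problem = problem)
}

#' @export
print.collapsed_problem <- function(x, ...) {
  cat("Collapsed ", x$family, " problem: K' = ", length(x$x), "\n", sep = "")
  cat("  counts: ", paste(x$x, collapse = ", "), "\n", sep = "")
  if (x$trivial) cat("  no order constraints (trivial)\n")
  else cat("  restriction: ", x$restriction$hypothesis, "\n", sep = "")
  invisible(x)
}

# Extract the single-section subproblem on which one independent constraint
# acts. For multinomial models the within-subset composition of a Dirichlet
# vector is itself Dirichlet with the subset's concentrations (aggregation /
# neutrality), and order constraints among subset members are invariant to
# the renormalization, so each section reduces to a self-contained simplex
# problem. Binomial coordinates are independent to begin with.
section_subproblem <- function(problem, section_index) {
  sec <- problem$restriction$sections[[section_index]]
  idx <- as.integer(unlist(sec, use.names = FALSE))
  remap <- match(seq_along(problem$x), idx)
  new_sec <- purrr::map(sec, function(el) purrr::map(el, ~ remap[.x]))
  restriction <- structure(
    list(sections = list(new_sec), labels = problem$labels[idx]),
    class = "restriction_list"
  )
  restriction$hypothesis <- format(restriction)
  structure(
    list(
      family = problem$family,
      x = problem$x[idx],
      n = problem$n[idx],
      a = problem$a[idx],
      b = problem$b[idx],
      group_sizes = problem$group_sizes[idx],
      labels = problem$labels[idx],
      restriction = restriction,
      trivial = FALSE
    ),
    class = "collapsed_problem"
  )
}
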