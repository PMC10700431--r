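# Packaged worked-example datasets. Both are small published count tables
# that ship as code; no downloads.

#' Packaged example datasets
#'
#' * `greek_fiscal` — first digits of N = 1497 figures from Greek fiscal
#'   statistics (1999-2010, Eurostat budget-deficit reporting), the classic
#'   Benford's-law audit setting: counts of leading digits 1-9.
#' * `benford_proportions` — the Benford first-digit law,
#'   `log10((d + 1) / d)` for digits 1-9.
#' * `birnbaum` — stochastic-dominance violations from an online gambling
#'   experiment (N = 1212 valid responses), split by gender (m/f) and
#'   education level (1 = doctorate ... 4 = less than bachelor's):
#'   violations `x` out of `n` respondents per cell.
#'
#' Each fixture returns its count table as a tibble plus the default uniform
#' prior and the informed hypothesis strings studied with it.
#'
#' @param name One of `"greek_fiscal"`, `"birnbaum"`,
#'   `"benford_proportions"`.
#'
#' @return A list with elements `name`, `family`, `data` (tibble), `a` (and
#'   `b` for binomial fixtures), and `hypotheses` (named character vector;
#'   empty for `benford_proportions`).
#'
#' @examples
#' fx <- load_fixture("greek_fiscal")
#' sum(fx$data$x)  # 1497
#' @export
load_fixture <- function(name = c("greek_fiscal", "birnbaum", "benford_proportions")) {
  name <- match.arg(name)
  switch(name,
    greek_fiscal = list(
      name = "greek_fiscal",
      family = "multinomial",
      data = tibble(
        label = as.character(1:9),
        x = c(509, 353, 177, 114, 77, 77, 53, 73, 64)
      ),
      a = rep(1, 9),
      hypotheses = c(
        decreasing = "1 > 2 > 3 > 4 > 5 > 6 > 7 > 8 > 9",
        fraud_pattern = "1 > 2 = 3 = 4 = 5 = 6 = 7 > 8 , 9"
      )
    ),
    birnbaum = list(
      name = "birnbaum",
      family = "binomial",
      data = tibble(
        label = paste0(rep(c("m", "f"), each = 4), 1:4),
        x = c(39, 42, 102, 98, 22, 60, 134, 198),
        n = c(80, 88, 195, 163, 54, 108, 206, 318)
      ),
      a = rep(1, 8),
      b = rep(1, 8),
      hypotheses = c(
        gender = "m1 , m2 , m3 , m4 < f1 , f2 , f3 , f4",
        education = "m1 , f1 < m2 , f2 < m3 , f3 < m4 , f4",
        interleaved = "m1 < f1 < m2 < f2 < m3 < f3 < m4 < f4"
      )
    ),
    benford_proportions = list(
      name = "benford_proportions",
      family = "multinomial",
      data = tibble(
        label = as.character(1:9),
        proportion = log10((1:9 + 1) / (1:9))
      ),
      hypotheses = character()
    )
  )
}

#' Simulate multinomial or independent-binomial counts
#'
#' Property-test generator: draws one count table from known category
#' proportions, deterministically given `seed`.
#'
#' @param theta Probability vector (multinomial: sums to 1; binomial:
#'   per-category success probabilities).
#' @param n Total count (multinomial) or per-category trial counts
#'   (binomial; scalar recycled).
#' @param family `"multinomial"` or `"binomial"`.
#' @param seed Optional integer seed.
#' @param labels Optional category labels.
#'
#' @return Tibble with columns `label`, `x` (and `n` for binomial).
#'
#' @examples
#' simulate_counts(c(0.5, 0.3, 0.2), n = 100, seed = 1)
#' @export
simulate_counts <- function(theta, n, family = c("multinomial", "binomial"),
                            seed = NULL, labels = NULL) {
  family <- match.arg(family)
  if (!is.null(seed)) set.seed(seed)
  K <- length(theta)
  if (any(theta < 0) || any(theta > 1)) stop("`theta` must be probabilities.", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_len(K))
  if (family == "multinomial") {
    if (abs(sum(theta) - 1) > 1e-8) stop("Multinomial `theta` must sum to 1.", call. = FALSE)
    if (length(n) != 1L || n < 1) stop("`n` must be a single positive total.", call. = FALSE)
    tibble(label = labels, x = as.numeric(rmultinom(1L, size = n, prob = theta)))
  } else {
    n <- rep_len(as.numeric(n), K)
    if (any(n < 1)) stop("`n` must be positive trial counts.", call. = FALSE)
    tibble(label = labels, x = as.numeric(rbinom(K, size = n, prob = theta)), n = n)
  }
}

#' Read a count table from CSV
#'
#' Expects columns `label,x` (multinomial) or `label,x,n` (binomial), the
#' schema used by the packaged CSV template
#' (`system.file("extdata", "journals_template.csv", package = "ordbf")`).
#'
#' @param path Path to a CSV file.
#' @return A tibble with the validated columns.
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "x") %in% names(df))) {
    stop("CSV must have columns `label,x` and optionally `n`.", call. = FALSE)
  }
  as_tibble(df[, intersect(c("label", "x", "n"), names(df))])
}
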