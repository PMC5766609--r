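#' Mutation-class fraction of a doped library
#'
#' Probability that a library member carries exactly `k` mutations across the
#' `m` randomized positions. Each randomized position mutates independently
#' with probability `1 - p_wt`, so the class sizes are binomial:
#' `choose(m, k) * (1 - p_wt)^k * p_wt^(m - k)`.
#'
#' @param design A [doped_design()].
#' @param k Mutation count(s), `0 <= k <= m`.
#' @return Probability of class `k` (vectorized over `k`).
#' @export
mutation_class_fraction <- function(design, k) {
  stopifnot(inherits(design, "doped_design"))
  m <- n_randomized(design)
  k <- as.integer(k)
  if (anyNA(k) || any(k < 0L) || any(k > m))
    stop("k must lie in [0, ", m, "]")
  stats::dbinom(k, size = m, prob = 1 - design$p_wt)
}

#' Theoretical diversity of a mutation class
#'
#' Number of distinct sequences with exactly `k` mutations:
#' `choose(m, k) * a^k`, with `a` alternatives per position. Exact integer
#' arithmetic in doubles (exact below 2^53; ample for `m <= 12`, `a = 18`).
#'
#' @inheritParams mutation_class_fraction
#' @return Distinct-variant count (vectorized over `k`).
#' @export
theoretical_diversity <- function(design, k) {
  stopifnot(inherits(design, "doped_design"))
  m <- n_randomized(design)
  k <- as.integer(k)
  if (anyNA(k) || any(k < 0L) || any(k > m))
    stop("k must lie in [0, ", m, "]")
  choose(m, k) * design$n_alternatives^k
}

#' Poisson coverage estimate
#'
#' Expected fraction of a diversity `D` observed when `n` clones are drawn
#' uniformly at random with replacement: `1 - exp(-n/D)` (the Poisson
#' occupancy approximation). The exact finite-pool expectation
#' `1 - (1 - 1/D)^n` is available as [exact_occupancy()]; the two agree
#' closely once `D` is more than a few dozen.
#'
#' @param n Expected number of clones sampled (may be fractional).
#' @param D Theoretical diversity (`>= 1`).
#' @return Coverage fraction in `[0, 1)`.
#' @export
poisson_coverage <- function(n, D) {
  if (any(n < 0)) stop("n must be nonnegative")
  if (any(D < 1)) stop("D must be >= 1")
  -expm1(-n / D)
}

#' Exact occupancy coverage
#'
#' @inheritParams poisson_coverage
#' @return Exact expected coverage `1 - (1 - 1/D)^n`.
#' @export
exact_occupancy <- function(n, D) {
  if (any(n < 0)) stop("n must be nonnegative")
  if (any(D < 1)) stop("D must be >= 1")
  -expm1(n * log1p(-1 / D))
}

#' Expected unique clones and average duplication
#'
#' `expected_unique()` returns `D * coverage`, the expected number of
#' distinct variants present among `n` sampled clones; `average_duplicates()`
#' returns `n / unique`, the mean number of physical copies per distinct
#' variant present.
#'
#' @inheritParams poisson_coverage
#' @param estimator Coverage estimator, `"poisson"` (default) or `"exact"`.
#' @return Expected count of distinct variants.
#' @export
expected_unique <- function(n, D, estimator = c("poisson", "exact")) {
  estimator <- match.arg(estimator)
  cov <- switch(estimator, poisson = poisson_coverage(n, D),
                exact = exact_occupancy(n, D))
  D * cov
}

#' @rdname expected_unique
#' @param unique Expected distinct-variant count (`> 0`).
#' @export
average_duplicates <- function(n, unique) {
  if (any(n < 0)) stop("n must be nonnegative")
  if (any(unique <= 0)) stop("average duplicates undefined for unique <= 0")
  n / unique
}

#' Mutation-class table of a doped library
#'
#' Builds the per-class breakdown of a doped design: for every mutation count
#' `k = 0..m`, the class fraction, its cumulative sum, the expected physical
#' clone count `n_k = N * fraction`, the theoretical diversity `D_k`, the
#' Poisson coverage `1 - exp(-n_k / D_k)`, the expected number of unique
#' clones `U_k = D_k * coverage`, and the average duplication `n_k / U_k`.
#' Expectations are kept at full precision (never rounded to integers), so
#' downstream ratios are exact.
#'
#' @param design A [doped_design()].
#' @return A data frame of class `design_table` with one row per mutation
#'   class and attributes `design` and `totals` (fraction, physical clones,
#'   unique clones).
#' @examples
#' d <- doped_design(glucagon_wt(), c(1:7, 27, 28))
#' tab <- build_design_table(d)
#' tab
#' @export
build_design_table <- function(design) {
  stopifnot(inherits(design, "doped_design"))
  m <- n_randomized(design)
  k <- 0:m
  frac <- mutation_class_fraction(design, k)
  div <- theoretical_diversity(design, k)
  n_k <- design$library_size * frac
  cov <- poisson_coverage(n_k, div)
  uniq <- div * cov
  dup <- ifelse(uniq > 0, n_k / uniq, NA_real_)
  tab <- data.frame(
    k = k,
    fraction = frac,
    cumulative = cumsum(frac),
    physical_clones = n_k,
    diversity = div,
    coverage = cov,
    unique_clones = uniq,
    avg_duplicates = dup)
  structure(tab,
            design = design,
            totals = c(fraction = sum(frac),
                       physical_clones = sum(n_k),
                       unique_clones = sum(uniq)),
            class = c("design_table", "data.frame"))
}

## Printed-precision formatters (match the conventions of published doped
## library tables: percentages to 2 decimals, counts to 3 significant
## figures in scientific notation, duplicates to 2 decimals with "<<1" for
## values rounding to <= 1.00).
fmt_pct <- function(x) sprintf("%.2f%%", 100 * x)

fmt_count <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(NA_character_)
    if (abs(v) < 100) return(sprintf("%.2f", v))
    e <- floor(log10(abs(v)))
    mant <- signif(v / 10^e, 3)
    if (mant >= 10) { mant <- mant / 10; e <- e + 1 }
    sprintf("%.2f x 10^%d", mant, e)
  }, character(1))
}

fmt_dup <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v)) return(NA_character_)
    if (round(v, 2) <= 1) "<<1" else sprintf("%.2f", v)
  }, character(1))
}

#' Format a design table at printed precision
#'
#' Renders every cell of a [build_design_table()] result as it would appear
#' in a published library-design table: fractions and coverages as
#' percentages to two decimals, clone and diversity counts to three
#' significant figures in scientific notation, duplication to two decimals
#' (`"<<1"` when it rounds to at most 1.00), plus a totals row.
#'
#' The totals row sums the per-class cells at their displayed precision
#' (round-then-sum), the convention of published library tables; the
#' full-precision totals stay available as `attr(tab, "totals")`.
#'
#' @param tab A `design_table`.
#' @return A character data frame of formatted cells (last row = totals).
#' @export
format_design_table <- function(tab) {
  stopifnot(inherits(tab, "design_table"))
  tot <- attr(tab, "totals")
  tot[["unique_clones"]] <- sum(signif(tab$unique_clones, 3))
  out <- data.frame(
    k = c(ifelse(tab$k == 0, "0 (wt)", as.character(tab$k)), "Sum:"),
    fraction = c(fmt_pct(tab$fraction),
                 sprintf("%.0f%%", 100 * tot[["fraction"]])),
    cumulative = c(fmt_pct(tab$cumulative), ""),
    physical_clones = c(fmt_count(tab$physical_clones),
                        fmt_count(tot[["physical_clones"]])),
    diversity = c(fmt_count(tab$diversity), ""),
    coverage = c(fmt_pct(tab$coverage), ""),
    unique_clones = c(fmt_count(tab$unique_clones),
                      fmt_count(tot[["unique_clones"]])),
    avg_duplicates = c(fmt_dup(tab$avg_duplicates), ""),
    stringsAsFactors = FALSE)
  names(out) <- c("No. of Mutations", "Fraction", "Cumulative Fraction",
                  "No. of physical clones", "Theor. Diversity",
                  "Poisson estimate coverage", "Number unique clones",
                  "Average No. of duplicates")
  out
}

#' @export
print.design_table <- function(x, ...) {
  d <- attr(x, "design")
  cat(sprintf(
    "Doped library mutation-class table (m = %d, p_wt = %.2f, a = %d, N = %.3g)\n\n",
    n_randomized(d), d$p_wt, d$n_alternatives, d$library_size))
  print(format_design_table(x), row.names = FALSE, right = TRUE)
  invisible(x)
}
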