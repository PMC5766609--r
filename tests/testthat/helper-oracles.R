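## The standard doped sub-library design: nine randomized positions on the
## glucagon backbone, 45% wt retention, 18 alternatives, 6e7 clones.
paper_design <- function(positions = c(1:7, 27, 28)) {
  doped_design(glucagon_wt(), randomized_positions = positions)
}

## Brute-force oracle for site_probability: exhaustive enumeration over all
## codon combinations of the variable positions (use only on specs with a
## handful of variable codons).
brute_site_prob <- function(spec, sites = cloning_sites()) {
  pats <- vapply(sites, function(s) s$recognition, character(1))
  fixed <- vapply(spec$body, function(el)
    if (inherits(el, "codon_mixture")) NA_character_ else toupper(el),
    character(1))
  var_idx <- which(is.na(fixed))
  grids <- lapply(spec$body[var_idx], function(mx) seq_along(mx$codons))
  combos <- if (length(grids)) expand.grid(grids) else data.frame(row.names = 1)
  total <- 0
  for (r in seq_len(nrow(combos))) {
    parts <- fixed
    w <- 1
    for (j in seq_along(var_idx)) {
      mx <- spec$body[[var_idx[j]]]
      ci <- combos[r, j]
      parts[var_idx[j]] <- mx$codons[ci]
      w <- w * mx$weights[ci]
    }
    full <- paste0(spec$five_prime_flank, paste(parts, collapse = ""),
                   spec$three_prime_flank)
    if (any(vapply(pats, function(p) grepl(p, full, fixed = TRUE),
                   logical(1))))
      total <- total + w
  }
  total
}

## Naive position-by-position substring scan (0-based), the digest oracle.
naive_scan <- function(seq, pattern) {
  np <- nchar(pattern)
  hits <- integer(0)
  for (i in seq_len(nchar(seq) - np + 1L))
    if (substr(seq, i, i + np - 1L) == pattern) hits <- c(hits, i - 1L)
  hits
}

## Exact expected number of distinct variants seen when sampling n clones
## from a doped design with per-variant probabilities from the binomial
## doping model (small designs only: enumerates variant classes).
exact_expected_unique <- function(m, p_wt, a, n) {
  total <- 0
  for (k in 0:m) {
    n_variants <- choose(m, k) * a^k
    p_variant <- (1 - p_wt)^k * p_wt^(m - k) / a^k
    total <- total + n_variants * (1 - (1 - p_variant)^n)
  }
  total
}

## 4PL response generator used by the dose-response tests.
four_pl <- function(dose, bottom, top, ec50, hill = 1) {
  bottom + (top - bottom) / (1 + (ec50 / dose)^hill)
}
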