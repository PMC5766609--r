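#' Parameters of the latent two-receptor activity model
#'
#' Generative model assigning each library variant a latent log10 EC50 (nM)
#' on two receptors, A and B. The model is additive on the log scale: each
#' (position, residue) mutation draws one effect per receptor from a normal
#' distribution, cached so identical mutations act identically in every
#' variant; a fraction of mutations grant binding without activation
#' ("binder-only"), reproducing clones that bind but do not activate.
#'
#' The default anchors make the parent potent on receptor A (0.02 nM, the
#' hormone's own receptor) and weak on receptor B (10 nM), so selection must
#' discover mutations installing receptor-B potency.
#'
#' @param anchor_a,anchor_b Parent log10 EC50 (nM) on receptors A and B.
#' @param effect_mean,effect_sd Per-mutation effect distribution on log10
#'   EC50 (positive mean = deleterious on average).
#' @param binder_only_fraction Fraction of mutations that abolish activation
#'   while leaving binding intact.
#' @param inactive_log10 Activation log10 EC50 assigned to binder-only
#'   variants (finite; default 3, i.e. 1000 nM).
#' @param seed Seed for the cached effect draws.
#' @return An object of class `activity_model_params`.
#' @export
activity_model_params <- function(anchor_a = log10(0.02), anchor_b = log10(10),
                                  effect_mean = 0.5, effect_sd = 1.5,
                                  binder_only_fraction = 0.15,
                                  inactive_log10 = 3, seed = 1L) {
  stopifnot(effect_sd >= 0, binder_only_fraction >= 0,
            binder_only_fraction <= 1, is.finite(inactive_log10))
  structure(list(anchor_a = anchor_a, anchor_b = anchor_b,
                 effect_mean = effect_mean, effect_sd = effect_sd,
                 binder_only_fraction = binder_only_fraction,
                 inactive_log10 = inactive_log10, seed = as.integer(seed)),
            class = "activity_model_params")
}

#' Parameters of one biopanning round
#'
#' Stochastic round model: each phage survives depletion on naive cells,
#' is captured on the target-receptor cells with a probability logistic in
#' its binding strength, survives washing, plus a small nonspecific
#' carryover; survivors are amplified by multinomial resampling to a fixed
#' pool size.
#'
#' @param depletion Probability that a nonspecific phage is removed during
#'   depletion (default 0.9).
#' @param capture_x50,capture_scale Logistic capture curve in binding
#'   strength `-log10 EC50(nM)`: midpoint and scale (defaults 0 and 0.5,
#'   i.e. half-capture at 1 nM binding).
#' @param wash_binder,wash_nonbinder Wash survival for captured binders vs
#'   others (defaults 0.5 and 0.01).
#' @param carryover Nonspecific carryover probability (default 1e-4).
#' @param amplification Post-round pool size (default 1e6).
#' @param rounds Number of selection rounds (default 4).
#' @param potent_log10 Log10 EC50 (nM) bound below which a variant counts as
#'   potent in pool summaries (default `log10(20)`).
#' @return An object of class `panning_params`.
#' @export
panning_params <- function(depletion = 0.9, capture_x50 = 0,
                           capture_scale = 0.5, wash_binder = 0.5,
                           wash_nonbinder = 0.01, carryover = 1e-4,
                           amplification = 1e6, rounds = 4L,
                           potent_log10 = log10(20)) {
  for (p in c(depletion, wash_binder, wash_nonbinder, carryover))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  stopifnot(rounds >= 0L, amplification >= 1, capture_scale > 0)
  structure(list(depletion = depletion, capture_x50 = capture_x50,
                 capture_scale = capture_scale, wash_binder = wash_binder,
                 wash_nonbinder = wash_nonbinder, carryover = carryover,
                 amplification = as.numeric(amplification),
                 rounds = as.integer(rounds), potent_log10 = potent_log10),
            class = "panning_params")
}

new_pool_state <- function(variants, round = 0L, design = NULL) {
  stopifnot(all(variants$count > 0))
  structure(list(round = as.integer(round), variants = variants,
                 total = sum(variants$count), design = design),
            class = "pool_state")
}

#' @export
print.pool_state <- function(x, ...) {
  cat(sprintf("Pool state: round %d, %d distinct variants, %.4g phage\n",
              x$round, nrow(x$variants), x$total))
  invisible(x)
}

## mutation signature: "" for wt, else "16I|17G" (position then residue),
## sorted by position; negative labels allowed ("-2K").
sig_to_calls <- function(sig) {
  if (!nchar(sig)) return(data.frame(pos = integer(0), res = character(0)))
  parts <- strsplit(sig, "|", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(-?[0-9]+)([A-Z])$", parts))
  data.frame(pos = as.integer(vapply(m, `[`, character(1), 2)),
             res = vapply(m, `[`, character(1), 3))
}

#' Sample a physical library from a doped design
#'
#' Draws `n` clones realizing the doped distribution: each non-extension
#' randomized position mutates independently with probability `1 - p_wt`,
#' substituted residues uniform over the non-wt, non-Cys alternatives;
#' extension slots (which have no wild-type) always carry a residue drawn
#' uniformly from the non-Cys alphabet. The pool is returned aggregated as a
#' multiset of variants keyed by mutation signature.
#'
#' @param design A [doped_design()].
#' @param n Number of clones to draw (default `design$library_size`).
#' @param seed Integer seed; sampling is fully seed-deterministic.
#' @return A `pool_state` (round 0) whose `variants` data frame has columns
#'   `sig`, `count`, `k`.
#' @export
sample_library <- function(design, n = design$library_size, seed = 1L) {
  stopifnot(inherits(design, "doped_design"))
  n <- as.integer(n)
  set.seed(as.integer(seed))
  pos <- design$randomized_positions
  cols <- vector("list", length(pos))
  for (j in seq_along(pos)) {
    p <- pos[j]
    if (p > 0) {
      wt <- substr(design$parent, p, p)
      alts <- design_alternatives(design, wt)
      mut <- stats::runif(n) < (1 - design$p_wt)
      idx <- floor(stats::runif(n) * length(alts)) + 1L
      cols[[j]] <- ifelse(mut, paste0(p, alts[idx]), "")
    } else {
      alphabet <- setdiff(AA20, "C")
      idx <- floor(stats::runif(n) * length(alphabet)) + 1L
      cols[[j]] <- paste0(p, alphabet[idx])
    }
  }
  sig <- do.call(paste, c(cols, sep = "|"))
  sig <- gsub("\\|{2,}", "|", sig)
  sig <- gsub("^\\||\\|$", "", sig)
  kclone <- rowSums(vapply(cols, nzchar, logical(n)))
  lev <- unique(sig)
  counts <- tabulate(match(sig, lev), nbins = length(lev))
  k <- kclone[match(lev, sig)]
  variants <- data.frame(sig = lev, count = counts, k = k,
                         stringsAsFactors = FALSE)
  new_pool_state(variants, round = 0L, design = design)
}

## enumerate every possible single mutation of a design
design_mutation_space <- function(design) {
  out <- lapply(design$randomized_positions, function(p) {
    if (p > 0) {
      wt <- substr(design$parent, p, p)
      res <- design_alternatives(design, wt)
    } else res <- setdiff(AA20, "C")
    data.frame(pos = p, res = res)
  })
  do.call(rbind, out)
}

#' Assign latent potencies to a sampled pool
#'
#' Draws one cached effect per (mutation, receptor) and one binder-only flag
#' per mutation, then scores every variant additively:
#' `log10EC50_r = anchor_r + sum of its mutations' effects on r`. Binding
#' potency always follows the additive model; activation potency equals
#' binding potency unless the variant carries a binder-only mutation, in
#' which case activation is set to `inactive_log10`. The wild-type variant
#' receives exactly the anchors. Deterministic given `params$seed`.
#'
#' @param pool A `pool_state` from [sample_library()].
#' @param params An [activity_model_params()].
#' @return The pool with per-variant columns `bind_a`, `bind_b` (binding
#'   log10 EC50) and `act_a`, `act_b` (activation log10 EC50), plus a
#'   `binder_only` flag.
#' @export
assign_potencies <- function(pool, params = activity_model_params()) {
  stopifnot(inherits(pool, "pool_state"),
            inherits(params, "activity_model_params"))
  design <- pool$design
  space <- design_mutation_space(design)
  set.seed(params$seed)
  space$eff_a <- stats::rnorm(nrow(space), params$effect_mean, params$effect_sd)
  space$eff_b <- stats::rnorm(nrow(space), params$effect_mean, params$effect_sd)
  space$binder_only <- stats::runif(nrow(space)) < params$binder_only_fraction
  key <- paste0(space$pos, space$res)
  v <- pool$variants
  parts_list <- strsplit(v$sig, "|", fixed = TRUE)
  lens <- lengths(parts_list)
  idx <- match(unlist(parts_list), key)
  if (anyNA(idx)) stop("pool contains mutations outside the design space")
  grp <- rep.int(seq_along(lens), lens)
  sum_by <- function(x) {
    out <- numeric(nrow(v))
    if (length(idx)) {
      s <- rowsum(x[idx], grp)
      out[as.integer(rownames(s))] <- s[, 1]
    }
    out
  }
  v$bind_a <- params$anchor_a + sum_by(space$eff_a)
  v$bind_b <- params$anchor_b + sum_by(space$eff_b)
  v$binder_only <- sum_by(as.numeric(space$binder_only)) > 0
  v$act_a <- ifelse(v$binder_only, params$inactive_log10, v$bind_a)
  v$act_b <- ifelse(v$binder_only, params$inactive_log10, v$bind_b)
  pool$variants <- v
  pool$model <- params
  pool
}

capture_prob <- function(bind_log10, params) {
  stats::plogis((-bind_log10 - params$capture_x50) / params$capture_scale)
}

#' Simulate one biopanning round
#'
#' Per clone, the survival probability is
#' `depletion_pass * capture * wash + carryover`, where `depletion_pass`
#' is `1 - depletion * (1 - max capture on either receptor)` (specific
#' binders escape depletion), `capture` is logistic in binding strength on
#' the target receptor, and `wash` differs for captured binders vs others.
#' Survivor counts are binomial; survivors are then amplified by multinomial
#' resampling to exactly `params$amplification` phage.
#'
#' @param pool A potency-assigned `pool_state`.
#' @param receptor `"A"` or `"B"`: the receptor panned against this round.
#' @param params A [panning_params()].
#' @param seed Integer seed for the round's randomness.
#' @return The post-round `pool_state` (round index incremented).
#' @export
panning_round <- function(pool, receptor = c("A", "B"),
                          params = panning_params(), seed = 1L) {
  receptor <- match.arg(receptor)
  stopifnot(inherits(pool, "pool_state"), inherits(params, "panning_params"))
  v <- pool$variants
  if (!nrow(v)) stop("pool is extinguished")
  if (is.null(v$bind_a)) stop("pool has no potencies; run assign_potencies()")
  set.seed(as.integer(seed))
  cap_a <- capture_prob(v$bind_a, params)
  cap_b <- capture_prob(v$bind_b, params)
  cap_t <- if (receptor == "A") cap_a else cap_b
  depl_pass <- 1 - params$depletion * (1 - pmax(cap_a, cap_b))
  wash <- ifelse(cap_t >= 0.5, params$wash_binder, params$wash_nonbinder)
  s <- pmin(depl_pass * cap_t * wash + params$carryover, 1)
  surv <- stats::rbinom(nrow(v), v$count, s)
  if (all(surv == 0)) stop("pool extinguished: no phage survived the round")
  amp <- stats::rmultinom(1, size = params$amplification, prob = surv)[, 1]
  keep <- amp > 0
  v <- v[keep, , drop = FALSE]
  v$count <- amp[keep]
  rownames(v) <- NULL
  out <- new_pool_state(v, round = pool$round + 1L, design = pool$design)
  out$model <- pool$model
  out
}

pool_summary_row <- function(pool, params) {
  v <- pool$variants
  w <- v$count / sum(v$count)
  pot_a <- v$act_a <= params$potent_log10
  pot_b <- v$act_b <= params$potent_log10
  binds <- pmin(v$bind_a, v$bind_b) <= params$potent_log10
  data.frame(
    round = pool$round,
    dual_potent = sum(w[pot_a & pot_b]),
    single_potent = sum(w[xor(pot_a, pot_b)]),
    binder_only = sum(w[!pot_a & !pot_b & binds]),
    inert = sum(w[!pot_a & !pot_b & !binds]),
    mean_bind_a = sum(w * v$bind_a),
    mean_bind_b = sum(w * v$bind_b))
}

#' Run an alternating two-receptor selection scheme
#'
#' Scheme 1 pans receptors in order A, B, A, B, ...; Scheme 2 inverts the
#' order (B, A, B, A, ...). Returns every round's pool plus a per-round
#' summary of pool-weighted variant classes (dual-potent, single-potent,
#' binder-only, inert) and mean binding strengths.
#'
#' @param design A [doped_design()].
#' @param model An [activity_model_params()].
#' @param panning A [panning_params()].
#' @param scheme 1 (receptor A first) or 2 (receptor B first).
#' @param n_sample Number of clones sampled from the design (default 1e6).
#' @param seed Master seed; round seeds are derived deterministically.
#' @return A list with `pools` (round 0..rounds), `summary` (data frame),
#'   and `receptor_order`.
#' @export
run_scheme <- function(design, model = activity_model_params(),
                       panning = panning_params(), scheme = 1L,
                       n_sample = 1e6, seed = 1L) {
  stopifnot(scheme %in% c(1L, 2L))
  seed <- as.integer(seed)
  order0 <- rep(c("A", "B"), length.out = panning$rounds)
  if (scheme == 2L) order0 <- rep(c("B", "A"), length.out = panning$rounds)
  pool <- sample_library(design, n = n_sample, seed = seed)
  pool <- assign_potencies(pool, model)
  pools <- list(pool)
  summary <- pool_summary_row(pool, panning)
  summary$receptor <- NA_character_
  for (r in seq_len(panning$rounds)) {
    pool <- panning_round(pool, order0[r], panning,
                          seed = (seed + 7919L * r) %% .Machine$integer.max)
    pools[[r + 1L]] <- pool
    row <- pool_summary_row(pool, panning)
    row$receptor <- order0[r]
    summary <- rbind(summary, row)
  }
  list(pools = pools, summary = summary, receptor_order = order0)
}

#' Reconstruct peptide sequences of pool variants
#'
#' @param pool A `pool_state`.
#' @return Character vector of peptides (parent with each variant's
#'   mutations applied; extension residues prepended).
#' @export
pool_peptides <- function(pool) {
  stopifnot(inherits(pool, "pool_state"))
  design <- pool$design
  vapply(pool$variants$sig, function(sig) {
    calls <- sig_to_calls(sig)
    apply_mutations(design$parent, calls_from_sig(calls))
  }, character(1), USE.NAMES = FALSE)
}

calls_from_sig <- function(df) {
  if (!nrow(df)) return(mutation_calls())
  mutation_calls(position = df$pos, observed = df$res)
}
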