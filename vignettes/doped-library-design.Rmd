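---
title: "Doped peptide libraries: design statistics, oligo optimization, and selection simulation"
author: "pdlkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doped peptide libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdlkit)
```

## The problem

A doped (soft-randomized) phage-display library keeps a parent hormone
backbone — here the 29-residue glucagon sequence — and randomizes a chosen
set of positions so that each retains the wild-type residue with probability
`p_wt` and otherwise substitutes one of `a` alternatives (by convention the
18 residues that are neither wild type nor Cys). With `p_wt = 0.45` over
`m = 9` positions, most library members carry only 1–3 mutations, which is
what makes selection for a second receptor activity tractable: the parent's
"message" (activation) and "address" (selectivity) regions stay largely
intact. This package implements the statistics, oligo design, selection
simulation and downstream analysis for such a campaign.

## Library statistics

The number of mutations per clone is binomial,
$P(k) = \binom{m}{k}(1-p_{wt})^k p_{wt}^{m-k}$, and the number of distinct
sequences with exactly $k$ mutations is $D_k = \binom{m}{k} a^k$ (exact
integer arithmetic; exactness holds comfortably to $m = 12$, $a = 18$ in
doubles). Sampling $n_k = N\,P(k)$ clones from class $k$ covers an expected
fraction $c_k = 1 - e^{-n_k/D_k}$ of it (Poisson occupancy), giving
$U_k = D_k c_k$ expected unique variants and $r_k = n_k / U_k$ mean copies
per variant present.

```{r}
d <- doped_design(glucagon_wt(), c(1:7, 27, 28))
build_design_table(d)
```

Numerical conventions, fixed once:

* The engine keeps full precision everywhere; expected clone counts are
  real-valued (never pre-rounded), which is what makes small-class
  duplication values such as `3082.77` reproducible.
* `format_design_table()` renders percentages to two decimals, counts to
  three significant figures in scientific notation, duplication to two
  decimals with `<<1` shown when the value rounds to at most 1.00, and a
  coverage of `100.00%` whenever it rounds there.
* The displayed totals row sums the per-class cells *at displayed
  precision* (round-then-sum), the convention of published library tables;
  full-precision totals remain in `attr(tab, "totals")`.
* The Poisson estimator is the default; the exact finite-pool occupancy
  $1-(1-1/D)^n$ is exported (`exact_occupancy()`) and used as the test
  oracle. The two agree within 0.01 once $D$ is beyond a few dozen (the
  deviation scales like $1/(2D)$), so the approximation is immaterial at
  library scale but checked explicitly in the tests.

## Trimer-codon oligo design and restriction-site avoidance

Each randomized position is synthesized as a mixture of trimer codon
blocks: the wild-type codon at weight `p_wt` and each alternative residue's
codon at `(1-p_wt)/a` (one codon per amino acid, no stops). N-terminal
extension slots, which have no wild-type residue, get an equal mixture over
the 19 non-Cys residues. The insert must not contain internal NcoI
(`CCATGG`) or NotI (`GCGGCCGC`) sites, which are reserved for cloning.

`site_probability()` computes the *exact* probability that a random library
member contains at least one such site: an Aho–Corasick-style automaton over
the recognition-sequence prefixes is pushed through the oligo left to right,
fixed bases as deterministic transitions and mixture codons as weighted
three-step transitions, with one absorbing "hit" state. This is linear in
oligo length and exact because synthesis makes positions independent.
Scanning is single-strand by default — both default sites are palindromic —
with a flag for both strands.

`optimize_codons()` minimizes that probability by deterministic coordinate
descent: every codon coordinate (the fixed wild-type codons and each residue
of each mixture) is swept in order, trying each synonymous candidate codon
and keeping strict improvements, until a sweep changes nothing. Ties break
lexicographically, so results are reproducible. Candidate sets default to
all synonymous codons per residue; the starting assignment is the
highest-usage human codon. On the glucagon sub-libraries the optimizer
reaches probability 0 exactly — every amino acid has a synonymous codon that
avoids the critical junctions (e.g. Pro has non-`CCA` codons, and any codon
ending in `CC` before the obligatory Met `ATG` can be swapped) — well below
the 0.13% design bound, which the result object reports via `feasible`.
Infeasibility is reported, never raised.

Duplex assembly (`assemble_duplex()`) models primer extension by locating
the longest complementary 3'-terminal overlap of the two oligos;
`digest_check()` reports all site occurrences (0-based, top strand) and a
clonability verdict (exactly one NcoI 5' of exactly one NotI). Peptide
positions are 1-based with extensions at −2/−1; DNA coordinates are 0-based.

## Window layout

The default layout mirrors the five sub-libraries: four seven-residue
windows (1–7, 8–14, 15–21, 22–28) each sharing C-terminal positions
{27, 28}, plus an extension library {−2, −1, 1–5, 27, 28}. Read literally,
the fourth window already contains 27 and 28 and deduplicates to seven
positions; since the true published boundaries cannot be recovered (several
observed clones, e.g. one with substitutions at 11, 16, 18 and 20, fit no
single window, and position-29 substitutions also occur), the layout is a
plain configurable object, `validate_layout()` warns rather than errors on
position-count mismatches, and `assign_sublibrary()` returns the compatible
set — empty means "inconsistent with the declared layout", flagged and never
silently reassigned.

## The selection simulator

The simulator exists so the screening and enrichment analyses are testable
without wet-lab data; the selection experiment it emulates published no
quantitative enrichment model, so the generative model below is the
package's own, with every parameter explicit.

* **Sampling** (`sample_library()`): clones realize the doping distribution
  exactly (binomial mutation counts, uniform position and residue choice).
  Pools are aggregated multisets keyed by mutation signature.
* **Latent activity** (`assign_potencies()`): additive on log10 EC50 (nM).
  Each (position, residue) mutation draws one effect per receptor from
  Normal(`effect_mean` = 0.5, `effect_sd` = 1.5) — deleterious on average,
  occasionally strongly beneficial — cached so identical mutations act
  identically across variants. Anchors: the parent is potent on its own
  receptor A (0.02 nM) and weak on receptor B (10 nM), so co-agonism must
  be discovered. A fraction (default 0.15) of mutations grant binding
  without activation; variants carrying one keep model binding but are
  assigned an inactive activation EC50 (1000 nM), reproducing the
  binder-not-activator clones seen at screening. The additive model is the
  simplest consistent with the observation that few mutations switch
  receptor selectivity; epistasis is deliberately out of scope.
* **Rounds** (`panning_round()`): survival = depletion pass × logistic
  capture in binding strength × wash survival + carryover, then binomial
  survival and multinomial re-amplification to a fixed pool size. Defaults:
  depletion 0.9 (specific binders escape it in proportion to their best
  capture probability), capture midpoint at 1 nM with scale 0.5 log10
  units, wash survival 0.5 for captured binders vs 0.01 otherwise,
  carryover 1e-4, amplification 1e6, four rounds.
* **Schemes** (`run_scheme()`): scheme 1 pans A, B, A, B; scheme 2 inverts
  the order. Summaries report pool-weighted dual-potent / single-potent /
  binder-only / inert fractions from the latent truth (a noisy readout
  layer is available separately through the screen-analysis thresholds).

All randomness is seed-deterministic; per-round seeds derive from the
master seed. What the simulator does *not* emulate: phage biology
(valency, titers, helper phage), growth-rate bias between clones (the
amplification is unbiased multinomial, with the resampling step the natural
place to add bias), cell-number effects, and any quantitative match to the
published pool-activity magnitudes — those are figure-only and the
simulator targets qualitative trajectory shapes (enrichment of dual
binders within 2–3 rounds; decline of activating fraction when binder-only
variants dominate). Passing simulation tests therefore validate the
package's own model, not the wet-lab process.

## Screen analysis and pharmacology

`call_mutations()` aligns a clone to the parent: equal lengths compare
position-wise; a clone longer by at most two residues assigns the leading
residues to extension labels −e…−1. `apply_mutations()` is its exact
inverse, and the pair round-trips on every packaged phage-derived peptide
and on randomized call sets. Positivity is an explicit threshold (the
screen's own threshold was arbitrary), and `hit_summary()` formats counts
as `n/N (p%)` with nearest-integer percentages.

Activity records carry explicit censoring (`">20"` stays a bound, never an
imputed number). The GCGR/GLP1R EC50 ratio follows the activity table's
column direction; because the source computed ratios from unrounded means,
recomputed ratios from printed means can differ from the printed ratio by
one unit in the last digit, and that is the agreement the tests assert.
Classification applies thresholds inclusively to printed means
(potency sub-tiers at 0.030 and 0.080 nM, inactivity above 20 nM, balance
window [0.5, 1.5] inclusive — a row printing exactly 1.50 is balanced).
`summarize_activity()` reports the balance count in both ratio directions,
since published prose and table headers disagree on the direction; on the
packaged table the GCGR/GLP1R direction yields 11 balanced peptides of the
18 dual-potent ones, and the 30 pM count is 7 on printed means (one row
prints 0.031, so the count is reported, not asserted, at 8).

DPP-IV liability is positional: an L-configured Ser/Ala/Pro at position 2
of a free N-terminus. The default engineering rule set substitutes D-Ser at
position 2 and Lys(γEγEC16) at position 10; serialization is lowercase for
D-residues with parenthesized modifiers, and C-terminal amidation is
metadata. `fit_dose_response()` is a 4PL Levenberg–Marquardt fit
(minpack.lm) that flags rather than raises non-convergence.

## Problem sizes and test design

The test suite checks closed forms against independent oracles (exhaustive
codon enumeration for site probabilities on up to three variable positions;
exact occupancy and small Monte-Carlo replicates for coverage; a naive
substring scan for digestion; full exhaustive assignment search for a
two-position optimizer toy). Stochastic properties use fixed seeds: the
mutation-class goodness of fit samples 1e6 clones; panning toys use 1e5
phage; scheme-level enrichment uses ten seeds at 2e4 clones per pool, sizes
at which the asserted effects are far larger than sampling noise while the
suite stays quick. The packaged activity tables are verbatim
transcriptions, integrity-checked by checksum; the two tables disagree with
each other at one position of one peptide (position 18 of peptide 16), so
the engineering round-trip is checked within the self-consistent
comparison table.

## Limitations

* The closed-form table ignores cloning efficiency, transformation loss and
  amplification bias; those belong to the simulator's parameters, not the
  design statistics.
* The optimizer's candidate codons default to one-per-amino-acid synonymous
  sets; the actual trimer-block catalogue of any given vendor is not
  modeled, nor are synthesis error rates.
* The activity model is additive with a single binder-only flag; no
  separate binding-affinity scale, no epistasis, no display-valency
  effects.
* Wet-lab clone counts (e.g. hit rates of a particular screen) are not
  reproducible quantities; only their counting and formatting logic is.
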