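# pdlkit

Computational backbone for a **doped ("soft-randomized") phage-display
campaign** aimed at discovering dual-receptor peptide agonists — the setting
in which a glucagon-backbone peptide library is selected alternately on
GCGR- and GLP1R-overexpressing cells to find GCG/GLP-1 receptor co-agonists.
The package is for computational biologists and peptide chemists who need to
design such a library, predict its statistics, simulate its selection, and
analyze the clones that come out.

It covers five stages:

1. **Library-design statistics** — closed forms for a doped design with `m`
   randomized positions, wild-type retention `p_wt`, and `a` alternatives
   per position:
   - mutation-class fraction `P(k) = C(m,k) (1-p_wt)^k p_wt^(m-k)`,
   - theoretical diversity `D_k = C(m,k) a^k` (exact integers),
   - Poisson coverage `c = 1 - exp(-n/D)` of a class sampled by `n` clones,
   - expected unique clones `U = D c` and mean duplication `r = n/U`.
2. **Trimer-codon oligo design** — per-position codon mixtures
   (wt codon at weight `p_wt`, each alternative at `(1-p_wt)/a`), the
   **exact** probability that a random library member contains an unwanted
   restriction site (NcoI `CCATGG`, NotI `GCGGCCGC`), computed by a finite
   automaton over the mixture distribution, and a deterministic
   coordinate-descent codon optimizer against that probability; plus
   primer-extension duplex assembly and NcoI/NotI digestion checks.
3. **Selection simulation** — a seed-deterministic generative model: sample
   a physical library from the doped distribution, assign latent
   two-receptor potencies (additive on log10 EC50 with cached per-mutation
   effects and binder-only mutations), and run alternating rounds of
   depletion / logistic capture / wash / multinomial amplification.
4. **Screen analysis** — mutation calling against the parent backbone
   (including two-residue N-terminal extensions), sub-library assignment
   under a configurable window layout, positivity thresholds, hit
   summaries, and per-round enrichment tables.
5. **Pharmacology** — peptides with D-residues and side-chain modifiers
   (e.g. `γEγEC16`), GCGR/GLP1R EC50 ratios with explicit censoring,
   potency/balance classification (balanced = ratio in `[0.5, 1.5]`,
   inclusive), DPP-IV liability detection, the standard engineering
   transformations (Ser2 → D-Ser, Tyr10 → Lys(γEγEC16)), and 4PL
   dose-response fitting.

## Worked example

```r
library(pdlkit)

## the standard sub-library: 9 doped positions, 45% wt, 6e7 clones
d <- doped_design(glucagon_wt(), c(1:7, 27, 28), name = "sub1")
build_design_table(d)
```

The table prints one row per mutation class; for example class `k = 4`
prints fraction `21.28%`, diversity `1.32 x 10^7`, coverage `61.91%`,
unique clones `8.19 x 10^6` and `1.56` average duplicates: with 6e7 physical
clones the library saturates all 1-3-mutation variants (coverage 100.00%)
but samples only ~62% of the 4-mutation class.

```r
## codon optimization against NcoI/NotI for the same design
opt <- optimize_codons(d)
opt$probability     # 0 — no codon path can spell either site
opt$feasible        # TRUE (below the 0.13% design bound)

## classify the packaged 35-peptide activity table
s <- summarize_activity(pdl_table2())
s$potent_80                  # 18 peptides with both EC50 means <= 0.080 nM
s$potent_30                  # 7 with both <= 0.030 nM on printed means
s$nd_ratio                   # 6 rows with censored (nd) ratios
s$balanced_gcgr_over_glp1r   # 11 peptides in the 0.5-1.5 balance window

## engineering a lead for drug-likeness
dppiv_liability(glucagon_wt())$site   # "H1-S2 (cleavage after residue 2)"
format_peptide(apply_engineering("HSQGTFTSDYSKYLDSRRAHDFVQWLLNT"))
# "HsQGTFTSDK(γEγEC16)SKYLDSRRAHDFVQWLLNT"
```

A thin command-line dispatcher mirrors these stages
(`design-stats`, `design-oligos`, `simulate-selection`, `call-mutations`,
`classify-activity`):

```sh
Rscript inst/cli/pdl.R design-stats --config design.yaml --format csv
```

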