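test_that("doped codon mixtures carry the 45/55 weights", {
  d <- paper_design()
  mixes <- build_codon_mixtures(d)
  expect_length(mixes, 9)
  for (mx in mixes) {
    expect_equal(sum(mx$weights), 1, tolerance = 1e-12)
    expect_equal(mx$weights[1], 0.45)
    expect_equal(unique(round(mx$weights[-1], 10)), round(0.55 / 18, 10))
    expect_length(mx$codons, 19)
    expect_false("C" %in% mx$residues)
  }
  ## no doping collapses to a single wt codon
  m1 <- build_codon_mixtures(doped_design(glucagon_wt(), c(1:7, 27, 28),
                                          p_wt = 1))
  expect_length(m1[[1]]$codons, 1)
  expect_equal(m1[[1]]$weights, 1)
  ## extension slots: equal mixture over the 19 non-Cys residues
  ext <- build_codon_mixtures(doped_design(glucagon_wt(),
                                           c(-2, -1, 1:5, 27, 28)))
  expect_equal(ext[[1]]$weights, rep(1 / 19, 19))
})

test_that("codon mixture invariants are enforced", {
  expect_error(codon_mixture(1, c("TAA", "GCC"), c(0.5, 0.5)), "stop codons")
  expect_error(codon_mixture(1, c("GCC", "GCT"), c(0.5, 0.5)), "distinct")
  expect_error(codon_mixture(1, c("GCC", "TGG"), c(0.6, 0.6)), "sum to 1")
  expect_error(build_codon_mixtures(doped_design("ACA", 2)), "Cys")
})

test_that("site probability is exact on fully fixed specs", {
  hit <- oligo_spec("hit", "CC", list("ATG", "GAA"))  # CCATGGAA
  expect_equal(site_probability(hit), 1)
  clean <- oligo_spec("clean", "AAA", list("TTT", "AAA"))
  expect_equal(site_probability(clean), 0)
})

test_that("site probability equals exhaustive enumeration on toy specs", {
  ## single mixture completing CCATGG with weight w
  mx <- codon_mixture(1, c("TGG", "AAA", "CTG"), c(0.3, 0.5, 0.2))
  spec <- oligo_spec("toy", "CCA", list(mx))
  expect_equal(site_probability(spec), 0.3, tolerance = 1e-12)
  expect_equal(site_probability(spec), brute_site_prob(spec),
               tolerance = 1e-12)
  ## randomized toy specs with up to 3 variable codons, overlap-prone flanks
  set.seed(202)
  codon_pool <- c("TGG", "CCA", "GCG", "GCC", "AAA", "ATG", "GGA", "CGC")
  for (rep in 1:12) {
    nvar <- sample(1:3, 1)
    body <- list()
    for (i in seq_len(nvar)) {
      cods <- sample(codon_pool, sample(2:4, 1))
      ## keep residues distinct within a mixture
      cods <- cods[!duplicated(codon_to_aa(cods))]
      w <- stats::runif(length(cods)); w <- w / sum(w)
      body <- c(body, list(codon_mixture(i, cods, w)),
                list(sample(c("GCC", "CAT", "GGC"), 1)))
    }
    spec <- oligo_spec("rand", sample(c("", "CC", "GCGG"), 1), body,
                       sample(c("", "GG", "CCGC"), 1))
    expect_equal(site_probability(spec), brute_site_prob(spec),
                 tolerance = 1e-12)
  }
})

test_that("site probability is monotone in site-completing codon weight", {
  probs <- vapply(c(0.4, 0.3, 0.2, 0.1, 0), function(w) {
    mx <- codon_mixture(1, c("TGG", "AAA"), c(w, 1 - w))
    site_probability(oligo_spec("t", "CCA", list(mx)))
  }, numeric(1))
  expect_false(is.unsorted(rev(probs)))
})

test_that("optimizer matches exhaustive search on a two-position toy", {
  ## design with 2 doped positions on a Trp-Pro parent: NcoI spans the
  ## P-W junction for codon choice CCA+TGG
  d <- doped_design("PW", c(1, 2), p_wt = 0.5, n_alternatives = 1)
  opt <- optimize_codons(d)
  ## full exhaustive oracle over every codon assignment of every residue
  res1 <- names(opt$codon_choice[["1"]])
  res2 <- names(opt$codon_choice[["2"]])
  grid <- expand.grid(c(lapply(res1, synonymous_codons),
                        lapply(res2, synonymous_codons)),
                      stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    ch <- list("1" = setNames(unlist(grid[r, seq_along(res1)]), res1),
               "2" = setNames(unlist(grid[r, length(res1) + seq_along(res2)]),
                              res2))
    best <- min(best, site_probability(design_oligo_spec(d, ch)))
  }
  expect_equal(opt$probability, best, tolerance = 1e-12)
})

test_that("optimizer reaches the site-probability bound on all sub-libraries", {
  layout <- default_window_layout()
  achieved <- vapply(names(layout), function(w) {
    d <- doped_design(glucagon_wt(), layout[[w]], name = w)
    opt <- optimize_codons(d)
    expect_true(opt$feasible)
    opt$probability
  }, numeric(1))
  expect_true(all(achieved < 0.0013))
})

test_that("duplex assembly finds the complementary 3' overlap", {
  dup <- assemble_duplex("AAAACCCGGG", "TTTTCCCGGG")
  expect_equal(dup$overlap, 6)
  expect_equal(dup$length, 14)
  expect_equal(dup$duplex, "AAAACCCGGGAAAA")
  ## symmetric up to strand orientation
  rev <- assemble_duplex("TTTTCCCGGG", "AAAACCCGGG")
  expect_equal(rev$overlap, dup$overlap)
  expect_equal(rev$duplex,
               paste(rev(strsplit(chartr("ACGT", "TGCA", dup$duplex),
                                  "")[[1]]), collapse = ""))
  ## identical self-complementary 3' ends: length = 2 len - overlap
  self <- assemble_duplex("AAAGAATTC", "AAAGAATTC")
  expect_equal(self$length, 2 * 9 - self$overlap)
  expect_error(assemble_duplex("AAAAAAA", "AAAAAAA"), "overlap")
})

test_that("digestion check matches the naive scan oracle", {
  d1 <- digest_check("AACCATGGTTTTGCGGCCGCAA")
  expect_true(d1$clonable)
  expect_equal(d1$positions$NcoI, 2L)
  expect_equal(d1$positions$NotI, 12L)
  ## internal extra NcoI site spoils clonability, position reported
  d2 <- digest_check("AACCATGGTTCCATGGTTGCGGCCGCAA")
  expect_false(d2$clonable)
  expect_equal(d2$positions$NcoI, c(2L, 10L))
  ## wrong order is not clonable
  expect_false(digest_check("GCGGCCGCTTTTCCATGG")$clonable)
  ## random 10 kb sequence against the naive scan
  set.seed(77)
  big <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
  d3 <- digest_check(big)
  expect_identical(d3$positions$NcoI, naive_scan(big, "CCATGG"))
  expect_identical(d3$positions$NotI, naive_scan(big, "GCGGCCGC"))
})

test_that("mixture draws translate inside the design's randomized positions", {
  d <- paper_design(c(8:14, 27, 28))
  spec <- design_oligo_spec(d)
  set.seed(5)
  for (rep in 1:20) {
    dna <- vapply(spec$body, function(el) {
      if (inherits(el, "codon_mixture"))
        sample(el$codons, 1, prob = el$weights)
      else el
    }, character(1))
    pep <- paste(codon_to_aa(dna), collapse = "")
    calls <- call_mutations(pep, glucagon_wt())
    expect_true(all(calls$position %in% d$randomized_positions))
  }
})
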