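test_that("library sampling is seed-deterministic and realizes the doping", {
  d <- paper_design(c(8:14, 27, 28))
  p1 <- sample_library(d, 5e4, seed = 9)
  p2 <- sample_library(d, 5e4, seed = 9)
  expect_identical(p1$variants, p2$variants)
  p3 <- sample_library(d, 5e4, seed = 10)
  expect_false(identical(p1$variants, p3$variants))
  expect_equal(p1$total, 5e4)
  ## empirical 3-mutation class within 3 binomial SE of 11.60%
  n <- 2e5
  pool <- sample_library(d, n, seed = 4)
  frac3 <- sum(pool$variants$count[pool$variants$k == 3]) / n
  p3exp <- mutation_class_fraction(d, 3)
  se <- sqrt(p3exp * (1 - p3exp) / n)
  expect_lt(abs(frac3 - p3exp), 3 * se)
  ## no doping: every clone is wild type
  wtpool <- sample_library(doped_design(glucagon_wt(), c(1:7, 27, 28),
                                        p_wt = 1), 1000, seed = 2)
  expect_identical(wtpool$variants$sig, "")
  expect_equal(wtpool$variants$count, 1000)
})

test_that("unique-variant counts match the exact occupancy oracle", {
  d <- doped_design("AAAA", c(1, 2), p_wt = 0.45, n_alternatives = 2)
  n <- 1e4
  uniq <- vapply(1:10, function(s)
    nrow(sample_library(d, n, seed = 100 + s)$variants), numeric(1))
  expected <- exact_expected_unique(m = 2, p_wt = 0.45, a = 2, n = n)
  se <- stats::sd(uniq) / sqrt(length(uniq))
  expect_lt(abs(mean(uniq) - expected), 3 * se + 0.5)
})

test_that("potency assignment anchors wt and caches per-mutation effects", {
  d <- paper_design(c(8:14, 27, 28))
  v <- data.frame(sig = c("", "9I", "27L", "9I|27L"),
                  count = c(10L, 10L, 10L, 10L), k = c(0L, 1L, 1L, 2L))
  pool <- pdlkit:::new_pool_state(v, design = d)
  params <- activity_model_params(seed = 33)
  pool <- assign_potencies(pool, params)
  v <- pool$variants
  expect_equal(v$bind_a[v$sig == ""], params$anchor_a)
  expect_equal(v$bind_b[v$sig == ""], params$anchor_b)
  ## additivity: shared mutations contribute identically
  eff_9I_a <- v$bind_a[v$sig == "9I"] - params$anchor_a
  eff_27L_a <- v$bind_a[v$sig == "27L"] - params$anchor_a
  expect_equal(v$bind_a[v$sig == "9I|27L"],
               params$anchor_a + eff_9I_a + eff_27L_a, tolerance = 1e-12)
  ## deterministic given the seed
  pool2 <- assign_potencies(pdlkit:::new_pool_state(v[1:4, 1:3], design = d),
                            params)
  expect_equal(pool2$variants$bind_b, v$bind_b)
  ## a fixed single-mutation effect of -1 makes EC50 10-fold lower
  sharp <- activity_model_params(effect_mean = -1, effect_sd = 0,
                                 binder_only_fraction = 0, seed = 1)
  pool3 <- assign_potencies(pdlkit:::new_pool_state(v[1:2, 1:3], design = d),
                            sharp)
  expect_equal(pool3$variants$bind_b[pool3$variants$sig == "9I"],
               sharp$anchor_b - 1)
})

test_that("a panning round reproduces hand-computed enrichment", {
  d <- paper_design(c(8:14, 27, 28))
  ## binding strengths chosen so capture probabilities are exactly 0.8/0.2
  b1 <- -0.5 * log(0.8 / 0.2); b2 <- +0.5 * log(0.8 / 0.2)
  v <- data.frame(sig = c("9I", "9L"), count = c(5e4L, 5e4L), k = 1L,
                  bind_a = c(b1, b2), bind_b = c(0, 0),
                  binder_only = FALSE, act_a = c(b1, b2), act_b = c(0, 0))
  pool <- pdlkit:::new_pool_state(v, design = d)
  pars <- panning_params(depletion = 0, wash_binder = 1, wash_nonbinder = 1,
                         carryover = 0, amplification = 1e5)
  out <- panning_round(pool, "A", pars, seed = 21)
  expect_equal(out$total, 1e5)  # conservation to the amplification target
  freq1 <- out$variants$count[out$variants$sig == "9I"] / out$total
  ## expected 4:1, i.e. freq 0.8; binomial SE on ~5e4 survivors
  expect_lt(abs(freq1 - 0.8), 3 * sqrt(0.8 * 0.2 / 4e4))
  ## full carryover leaves composition unchanged in expectation
  pars2 <- panning_params(depletion = 1, wash_binder = 0, wash_nonbinder = 0,
                          carryover = 1, amplification = 1e5)
  out2 <- panning_round(pool, "A", pars2, seed = 22)
  f2 <- out2$variants$count[out2$variants$sig == "9I"] / out2$total
  expect_lt(abs(f2 - 0.5), 3 * sqrt(0.25 / 1e5))
  ## hopeless parameters extinguish the pool
  dead <- panning_params(depletion = 1, wash_binder = 0, wash_nonbinder = 0,
                         carryover = 0)
  small <- pdlkit:::new_pool_state(v[1, ], design = d)
  small$variants$count <- 10L
  expect_error(panning_round(small, "B", dead, seed = 1), "extinguished")
})

test_that("idealized capture keeps only target binders after one round", {
  d <- paper_design(c(8:14, 27, 28))
  strong <- -3; weak <- 3  # log10 EC50: 1 pM binder vs 1 uM non-binder
  v <- data.frame(sig = c("9I", "9L"), count = c(1000L, 1000L), k = 1L,
                  bind_a = c(strong, weak), bind_b = c(weak, weak),
                  binder_only = FALSE,
                  act_a = c(strong, weak), act_b = c(weak, weak))
  pool <- pdlkit:::new_pool_state(v, design = d)
  pars <- panning_params(depletion = 0, capture_scale = 0.05,
                         wash_binder = 1, wash_nonbinder = 1,
                         carryover = 0, amplification = 1000)
  out <- panning_round(pool, "A", pars, seed = 5)
  expect_identical(out$variants$sig, "9I")
})

test_that("alternating selection enriches and conserves pool size", {
  d <- paper_design(c(8:14, 27, 28))
  pars <- panning_params(amplification = 5e4, rounds = 4)
  run <- run_scheme(d, panning = pars, scheme = 1, n_sample = 5e4, seed = 3)
  expect_length(run$pools, 5)
  expect_identical(run$receptor_order, c("A", "B", "A", "B"))
  for (p in run$pools[-1]) expect_equal(p$total, 5e4)
  ## determinism of the full scheme
  run2 <- run_scheme(d, panning = pars, scheme = 1, n_sample = 5e4, seed = 3)
  expect_identical(run$summary, run2$summary)
  ## scheme 2 inverts the receptor order
  run3 <- run_scheme(d, panning = panning_params(amplification = 2e4,
                                                 rounds = 2),
                     scheme = 2, n_sample = 2e4, seed = 3)
  expect_identical(run3$receptor_order, c("B", "A"))
  ## zero rounds returns the initial sample untouched
  run0 <- run_scheme(d, panning = panning_params(rounds = 0,
                                                 amplification = 1e4),
                     scheme = 1, n_sample = 1e4, seed = 8)
  expect_length(run0$pools, 1)
  expect_equal(run0$pools[[1]]$round, 0L)
})

test_that("mean binding strength to the panned receptor is non-decreasing", {
  ## with no carryover and monotone capture, each round targeting a fixed
  ## receptor should raise the pool's mean binding strength (sign test)
  d <- paper_design(c(8:14, 27, 28))
  pars <- panning_params(carryover = 0, amplification = 2e4, rounds = 2)
  wins <- 0L
  for (s in 1:6) {
    run <- run_scheme(d, panning = pars, scheme = 1, n_sample = 2e4,
                      seed = 400 + s)
    ## round 1 pans receptor A: mean bind_a must improve (decrease in log EC50)
    wins <- wins + (run$summary$mean_bind_a[2] < run$summary$mean_bind_a[1])
  }
  expect_gte(wins, 5L)
})
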