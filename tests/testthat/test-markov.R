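test_that("a degenerate corpus gives a deterministic model", {
  reads <- rep(strrep("A", 12), 50)
  mod <- fit_markov(reads, m = 6, alpha = 0, strand_mode = "single")
  ctxA <- 1L                                  # AAAAAA is index 0
  expect_identical(mod$trans[ctxA, 1], 1)     # P(A | AAAAAA) = 1
  expect_identical(kmer_prob(mod, strrep("A", 10)), 1)
})

test_that("pseudocount-0 model reproduces empirical word frequencies on its training frame", {
  reads <- random_reads(200, 40, seed = 31)
  mod <- fit_markov(reads, m = 6, alpha = 0, strand_mode = "single")
  for (j in 5:7) {
    emp <- naive_frame_freq(reads, j)
    expect_lt(max(abs(implied_marginal(mod, j) - emp)), 1e-12)
  }
  # j = m+1 coincides with the ordinary full-window frame, so count_kmers is
  # a second, independent oracle there
  emp7 <- kmer_frequencies(count_kmers(reads, k = 7, strand_mode = "single"))
  expect_lt(max(abs(expected_kmer_table(mod, 7, collapse = FALSE)$freq - emp7)),
            1e-12)
})

test_that("an analytic uniform model gives closed-form probabilities", {
  mod <- structure(
    list(order = 6L, alpha = 0, strand_mode = "single",
         initial_frame = "prefix", initial = rep(1 / 4^6, 4^6),
         trans = matrix(0.25, nrow = 4^6, ncol = 4), n_train_windows = 0L),
    class = "markov_model")
  words <- random_reads(20, 10, seed = 32)
  expect_equal(kmer_prob(mod, words), rep(0.25^10, 20), tolerance = 1e-15)
  # k = m: the chain is an empty product and returns the initial entry
  expect_identical(kmer_prob(mod, "ACGTAC"), mod$initial[1])
  expect_error(kmer_prob(mod, "ACG"), "at least")
})

test_that("fitted transition rows are stochastic and near-uniform on uniform data", {
  reads <- random_reads(5000, 40, seed = 33)
  mod <- fit_markov(reads, m = 6, alpha = 1)
  expect_lt(max(abs(rowSums(mod$trans) - 1)), 1e-12)
  expect_lt(abs(sum(mod$initial) - 1), 1e-12)
  # ~87 observations per context after strand collapse: per-cell SE ~ 0.046,
  # so 99% of cells lie within ~2.6 SE and the extreme of 65k cells within ~5 SE
  expect_lt(unname(stats::quantile(abs(mod$trans - 0.25), 0.99)), 0.15)
  expect_lt(max(abs(mod$trans - 0.25)), 0.3)
  expect_lt(abs(mean(mod$trans) - 0.25), 1e-12)
})

test_that("chain-rule probabilities are normalized and match the dense expansion", {
  reads <- random_reads(500, 40, seed = 34)
  mod <- fit_markov(reads, m = 6, alpha = 1)
  q <- expected_kmer_table(mod, 8, collapse = FALSE)$freq
  expect_lt(abs(sum(q) - 1), 1e-9)
  set.seed(35)
  idx <- sample.int(4^8, 100) - 1
  expect_equal(kmer_prob(mod, index_to_kmer(idx, 8)), q[idx + 1],
               tolerance = 1e-12)
  # collapsed folding preserves total mass and zeroes non-canonical entries
  qc <- expected_kmer_table(mod, 8, collapse = TRUE)$freq
  expect_lt(abs(sum(qc) - 1), 1e-9)
  rc <- selexr:::rc_index_map(8)
  expect_true(all(qc[(0:(4^8 - 1)) > rc] == 0))
})

test_that("collapsed training gives exactly strand-symmetric word probabilities at k = m+1", {
  reads <- random_reads(300, 40, seed = 36)
  mod <- fit_markov(reads, m = 6, alpha = 0, strand_mode = "collapsed")
  q7 <- expected_kmer_table(mod, 7, collapse = FALSE)$freq
  rc <- selexr:::rc_index_map(7)
  # exact in exact arithmetic; a few ulp of slack for the two divisions
  expect_lt(max(abs(q7 - q7[rc + 1])), 1e-16)
})

test_that("a known sixth-order model is recovered within binomial sampling error", {
  set.seed(37)
  true_trans <- matrix(stats::rgamma(4^6 * 4, shape = 2), ncol = 4)
  true_trans <- true_trans / rowSums(true_trans)
  truth <- structure(
    list(order = 6L, alpha = 0, strand_mode = "single",
         initial_frame = "prefix", initial = rep(1 / 4^6, 4^6),
         trans = true_trans, n_train_windows = 0L),
    class = "markov_model")
  reads <- sample_markov(truth, n = 20000, L = 40, seed = 38)
  fit <- fit_markov(reads, m = 6, alpha = 0, strand_mode = "single")
  n_ctx <- rowSums(matrix(tabulate(
    as.integer(selexr:::window_index(selexr:::dna_codes(reads), 7)) + 1L,
    nbins = 4^7), ncol = 4, byrow = TRUE))
  use <- n_ctx >= 50
  err <- abs(fit$trans[use, ] - true_trans[use, ])
  se <- sqrt(true_trans[use, ] * (1 - true_trans[use, ]) / n_ctx[use])
  # ~170 observations per context: per-cell SE ~ 0.03, so the mean absolute
  # error is ~0.8 SE and essentially no cell sits beyond 5 SE
  expect_lt(mean(err), 0.04)
  expect_lt(mean(err > 5 * se), 1e-3)
})

test_that("Markov models round-trip through their TSV serialization", {
  reads <- random_reads(100, 40, seed = 39)
  mod <- fit_markov(reads, m = 6, alpha = 1)
  d <- withr::local_tempdir()
  path <- write_markov_model(mod, file.path(d, "m.tsv"))
  back <- read_markov_model(path)
  expect_identical(back$order, mod$order)
  expect_identical(back$strand_mode, mod$strand_mode)
  expect_equal(back$initial, mod$initial, tolerance = 1e-15)
  expect_equal(back$trans, mod$trans, tolerance = 1e-15)
})
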