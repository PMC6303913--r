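# A tiny deterministic final-round "experiment": single-base reads so each
# read is exactly one window, counted on the given strand.
toy_affinity <- function(reads, bg, min_count = 1L, mode = "ratio") {
  tbl <- count_kmers(reads, k = 1, strand_mode = "single")
  relative_affinity(tbl, bg, min_count = min_count, exponent_mode = mode,
                    final_round_index = 1L)
}

test_that("relative affinity is the max-normalized frequency/background ratio", {
  # f = {A: .5, C: .5}, bg = {A: .25, C: .5} -> raw {2, 1} -> rel {1, .5}
  bg <- c(0.25, 0.5, 0.125, 0.125)
  at <- toy_affinity(c("A", "A", "C", "C"), bg)
  expect_identical(affinity_of(at, c("A", "C")), c(1, 0.5))
  expect_identical(at$normalization_word, "A")
  expect_identical(max(at$rel_affinity), 1)
  expect_identical(at$raw_ratio[1:2], c(2, 1))
})

test_that("relative affinity is invariant under rescaling all counts", {
  bg <- rep(0.25, 4)
  a <- toy_affinity(c("A", "A", "A", "C", "G"), bg)
  b <- toy_affinity(rep(c("A", "A", "A", "C", "G"), 7), bg)
  expect_equal(a$rel_affinity, b$rel_affinity, tolerance = 1e-15)
})

test_that("words below min_count are flagged out rather than given ratios", {
  bg <- rep(0.25, 4)
  at <- toy_affinity(c("A", "A", "A", "C"), bg, min_count = 2L)
  expect_identical(at$n_observed, 1L)
  expect_identical(affinity_of(at, "C"), 0)        # filtered
  expect_error(toy_affinity("A", bg, min_count = -1L), "min_count")
})

test_that("collapsed-mode affinities are exactly strand-coherent", {
  rec <- list(reads = random_reads(3000, 40, seed = 41))
  tbl <- count_kmers(rec$reads, k = 10, strand_mode = "collapsed")
  mod <- fit_markov(rec$reads, m = 6, alpha = 1, strand_mode = "collapsed")
  at <- relative_affinity(tbl, mod, min_count = 1L, final_round_index = 1L)
  words <- random_reads(500, 10, seed = 42)
  expect_identical(affinity_of(at, words), affinity_of(at, revcomp(words)))
})

test_that("ratio and per-round-root modes induce the same word ranking", {
  reads <- sample(c("A", "C", "G", "T"), 500, replace = TRUE,
                  prob = c(0.4, 0.3, 0.2, 0.1))
  bg <- rep(0.25, 4)
  tbl <- count_kmers(reads, k = 1, strand_mode = "single")
  a <- relative_affinity(tbl, bg, min_count = 1L, exponent_mode = "ratio",
                         final_round_index = 3L)
  b <- relative_affinity(tbl, bg, min_count = 1L,
                         exponent_mode = "per_round_root",
                         final_round_index = 3L)
  expect_identical(order(-a$rel_affinity), order(-b$rel_affinity))
  expect_identical(max(b$rel_affinity), 1)
  # the root mode compresses the dynamic range
  expect_true(all(b$rel_affinity[a$observed] >= a$rel_affinity[a$observed]))
})

test_that("raw ratios recompute from first principles", {
  reads <- random_reads(500, 40, seed = 43)
  tbl <- count_kmers(reads, k = 10)
  mod <- fit_markov(reads, m = 6, alpha = 1)
  at <- relative_affinity(tbl, mod, min_count = 2L, final_round_index = 1L)
  idx <- which(at$observed)
  manual <- (tbl$counts[idx] / tbl$total_windows) / at$bg_freq[idx]
  expect_equal(at$raw_ratio[idx], manual, tolerance = 1e-12)
  expect_equal(at$rel_affinity[idx], manual / max(at$raw_ratio),
               tolerance = 1e-12)
})

test_that("a table compared with itself is perfectly concordant", {
  reads <- random_reads(1000, 40, seed = 44)
  tbl <- count_kmers(reads, k = 10)
  mod <- fit_markov(reads, m = 6, alpha = 1)
  at <- relative_affinity(tbl, mod, min_count = 2L, final_round_index = 1L)
  cmp <- compare_affinities(at, at)
  expect_equal(cmp$pearson, 1, tolerance = 1e-12)
  expect_equal(cmp$spearman, 1, tolerance = 1e-12)
  expect_true(all(cmp$data$log_ratio == 0))
  expect_identical(cmp$n_common, at$n_observed)
})

sim_affinity <- function(seed, consensus = "CCWWWWWWGG", factor = 0.3,
                         n = 20000L, R = 2L, s = 2) {
  land <- make_landscape(consensus, factor)
  cfg <- sim_config(n_reads_per_round = n, n_rounds = R, stringency = s,
                    seed = seed)
  res <- run_selex(cfg, land)
  mod <- fit_markov(res$rounds[[1]], m = 6, alpha = 1)
  tbl <- count_kmers(res$rounds[[R + 1]], k = 10)
  relative_affinity(tbl, mod, min_count = 2L, final_round_index = R)
}

test_that("independent replicate simulations give consistent affinity tables", {
  a <- sim_affinity(21L)
  b <- sim_affinity(22L)
  cmp <- compare_affinities(a, b)
  expect_gt(cmp$n_common, 10000)
  expect_gt(cmp$pearson, 0.8)
  expect_gt(cmp$spearman, 0.4)
  # the well-measured words agree tightly in rank too
  keep <- a$counts >= 10 & b$counts >= 10
  expect_gt(stats::cor(a$rel_affinity[keep], b$rel_affinity[keep],
                       method = "spearman"), 0.5)
})

test_that("discordant words between contrasting landscapes are consensus-specific", {
  a <- sim_affinity(21L, consensus = "CCWWWWWWGG")
  b <- sim_affinity(23L, consensus = "GCWWWWWWGG")
  cmp <- compare_affinities(a, b)
  dat <- cmp$data
  top <- utils::head(dat[order(-abs(dat$log_ratio), dat$word), ], 200)
  specific <- grepl("^CC[AT]{6}GG$", dat$word) |
    grepl("^GC[AT]{6}GG$", dat$word) | grepl("^CC[AT]{6}GC$", dat$word)
  in_top <- dat$word %in% top$word
  ft <- stats::fisher.test(table(in_top, specific))
  expect_lt(ft$p.value, 1e-10)
  expect_gt(sum(in_top & specific), 20)
  # and the direction is right: CC-consensus words favor condition a
  cc_words <- dat$word[grepl("^CC[AT]{6}GG$", dat$word)]
  expect_gt(median(dat$log_ratio[dat$word %in% cc_words]), 0)
})
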