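# Small deterministic affinity table over 1-mers for selection-rule tests:
# counts chosen so rel_affinity is {A:1, C:.75, G:.75, T:.25}.
tiny_table <- function() {
  reads <- c(rep("A", 8), rep("C", 6), rep("G", 6), rep("T", 2))
  relative_affinity(count_kmers(reads, k = 1, strand_mode = "single"),
                    rep(0.25, 4), min_count = 1L, final_round_index = 1L)
}

test_that("top-kmer selection takes the highest-affinity fraction with lexicographic ties", {
  at <- tiny_table()
  top <- top_kmers(at, fraction = 0.5)            # 2 of 4 observed words
  expect_identical(top$n_top, 2L)
  expect_identical(top$words, c("A", "C"))        # C beats G on the tie
  all4 <- top_kmers(at, fraction = 1)
  expect_identical(all4$words, c("A", "C", "G", "T"))
  expect_true(!is.unsorted(rev(all4$rel_affinity)))
  expect_error(top_kmers(at, fraction = 0), "fraction")
})

test_that("top-kmer selection is invariant under global affinity rescaling", {
  at <- tiny_table()
  scaled <- at
  scaled$rel_affinity <- at$rel_affinity * 0.2    # same ranking, different scale
  expect_identical(top_kmers(at, 0.5)$words, top_kmers(scaled, 0.5)$words)
})

test_that("the possible-word universe sizes the selection against 4^k", {
  at <- tiny_table()
  top <- top_kmers(at, fraction = 0.5, universe = "possible")
  expect_identical(top$n_top, 2L)                 # ceil(0.5 * 4) = 2
})

test_that("representative sequence is the most recurrent read containing the word", {
  a <- paste0("CCATATATGG", strrep("A", 30))
  b <- paste0(strrep("A", 30), "CCATATATGG")
  reads <- c(rep(a, 3), b, random_reads(10, 40, seed = 51))
  res <- representative_sequences("CCATATATGG", reads)
  expect_true(res$found)
  expect_identical(res$representative, a)
  expect_identical(res$multiplicity, 3L)
  # absent word is flagged, and the scalar wrapper warns
  res2 <- representative_sequences(strrep("G", 10), reads)
  expect_false(res2$found)
  expect_warning(representative_sequence(strrep("G", 10), reads), "no read")
  # multiplicity tie: lexicographically smaller read wins
  res3 <- representative_sequences("CCATATATGG", c(a, b))
  expect_identical(res3$representative, min(a, b))
})

test_that("reverse-strand matches are reported on the forward-oriented copy", {
  a <- paste0("CCAAAATTGG", strrep("C", 30))      # contains word forward
  word_rc_only <- revcomp(a)                      # contains it on the minus strand only
  res <- representative_sequences("CCAAAATTGG", word_rc_only, collapse = TRUE)
  expect_true(res$found)
  expect_identical(res$representative, a)         # re-oriented
  res_single <- representative_sequences("CCAAAATTGG", word_rc_only,
                                         collapse = FALSE)
  expect_false(res_single$found)
})

test_that("anchored PFM one-hot encodes a single representative", {
  at <- tiny_table()
  land_word <- "CCATATATGG"
  rep_seq <- paste0("GGGGG", land_word, strrep("T", 25))
  top <- structure(list(words = land_word, rel_affinity = 1,
                        indices = 0, k = 10, fraction = 1,
                        universe = "observed", n_top = 1L, tie_policy = ""),
                   class = "top_kmer_set")
  reps <- data.frame(word = land_word, representative = rep_seq,
                     multiplicity = 1L, found = TRUE)
  pfm <- build_anchored_pfm(top, at, reps, flank = 5)
  expect_identical(pfm$width, 20L)
  expect_identical(pfm$anchor_offset, 5L)
  expect_equal(colSums(pfm$counts), rep(1, 20), tolerance = 1e-9)
  # the window is read positions 1..20: GGGGG CCATATATGG TTTTT
  expect_identical(unname(pfm$counts["G", 1:5]), rep(1, 5))
  expect_identical(unname(pfm$counts["C", 6]), 1)
  expect_identical(unname(pfm$counts["T", 16:20]), rep(1, 5))
  # anchoring near the read edge pads with equal-weight background
  reps2 <- data.frame(word = land_word,
                      representative = paste0(land_word, strrep("T", 30)),
                      multiplicity = 1L, found = TRUE)
  pfm2 <- build_anchored_pfm(top, at, reps2, flank = 5)
  expect_equal(unname(pfm2$counts[, 1]), rep(0.25, 4))
  expect_equal(colSums(pfm2$counts), rep(1, 20), tolerance = 1e-9)
  expect_error(build_anchored_pfm(top, at, reps, flank = -1), "flank")
})

test_that("PFM accumulation is linear in the contribution weights", {
  at <- tiny_table()
  w <- "CCATATATGG"
  rep_seq <- paste0("GGGGG", w, strrep("T", 25))
  reps <- data.frame(word = c(w, w), representative = rep_seq,
                     multiplicity = 1L, found = TRUE)
  half <- structure(list(words = c(w, w), rel_affinity = c(0.5, 0.5),
                         indices = c(0, 0), k = 10, fraction = 1,
                         universe = "observed", n_top = 2L, tie_policy = ""),
                    class = "top_kmer_set")
  one <- structure(list(words = w, rel_affinity = 1, indices = 0, k = 10,
                        fraction = 1, universe = "observed", n_top = 1L,
                        tie_policy = ""),
                   class = "top_kmer_set")
  pfm_half <- build_anchored_pfm(half, at, reps, flank = 3)
  pfm_one <- build_anchored_pfm(one, at, reps[1, ], flank = 3)
  expect_equal(motif_probabilities(pfm_half), motif_probabilities(pfm_one),
               tolerance = 1e-12)
})

meme_grammar_ok <- function(lines) {
  # grammar checker written from the MEME-minimal format description
  i_ver <- grep("^MEME version [0-9]+$", lines)
  i_alpha <- grep("^ALPHABET= ACGT$", lines)
  i_motif <- grep("^MOTIF \\S+$", lines)
  i_mat <- grep("^letter-probability matrix: alength= 4 w= [0-9]+ nsites= [0-9]+ E= \\S+$",
                lines)
  if (length(i_ver) != 1 || length(i_alpha) != 1 ||
      length(i_motif) != 1 || length(i_mat) != 1) return(FALSE)
  if (!(i_ver < i_alpha && i_alpha < i_motif && i_motif < i_mat)) return(FALSE)
  w <- as.integer(sub(".* w= ([0-9]+) .*", "\\1", lines[i_mat]))
  rows <- lines[(i_mat + 1):(i_mat + w)]
  if (!all(grepl("^[01]\\.[0-9]{6}( [01]\\.[0-9]{6}){3}$", rows))) return(FALSE)
  sums <- vapply(strsplit(rows, " "), function(x) sum(as.numeric(x)), numeric(1))
  all(abs(sums - 1) < 1e-4)
}

test_that("motif export round-trips and satisfies the MEME-minimal grammar", {
  at <- tiny_table()
  w <- "CCATATATGG"
  top <- structure(list(words = w, rel_affinity = 1, indices = 0, k = 10,
                        fraction = 1, universe = "observed", n_top = 1L,
                        tie_policy = ""),
                   class = "top_kmer_set")
  reps <- data.frame(word = w, representative = paste0("GGGGG", w, strrep("T", 25)),
                     multiplicity = 1L, found = TRUE)
  pfm <- build_anchored_pfm(top, at, reps, flank = 2)
  d <- withr::local_tempdir()

  meme1 <- file.path(d, "m1.meme")
  export_motif(pfm, meme1, "meme", name = "toy")
  expect_true(meme_grammar_ok(readLines(meme1)))
  back <- read_motif(meme1, "meme")
  meme2 <- file.path(d, "m2.meme")
  export_motif(back, meme2, "meme", name = "toy")
  expect_identical(readLines(meme1), readLines(meme2))

  jas1 <- file.path(d, "m1.jaspar")
  export_motif(pfm, jas1, "jaspar", name = "toy")
  backj <- read_motif(jas1, "jaspar")
  expect_equal(backj$counts, unname(pfm$counts), ignore_attr = TRUE,
               tolerance = 1e-6)
  jas2 <- file.path(d, "m2.jaspar")
  export_motif(backj, jas2, "jaspar", name = "toy")
  expect_identical(readLines(jas1), readLines(jas2))
  # hand-written expectation for a one-hot column layout
  expect_match(readLines(jas1)[1], "^>toy$")
  expect_match(readLines(jas1)[2], "^A \\[ 0\\.000000")
  expect_error(export_motif(pfm, file.path(d, "x"), "pwm"), "arg")
})

test_that("identical inputs produce byte-identical FASTA and motif files", {
  rec <- c(paste0("CCATATATGG", strrep("A", 30)),
           paste0("GGGGG", "CCATATATGG", strrep("T", 25)))
  at <- tiny_table()
  top <- structure(list(words = "CCATATATGG", rel_affinity = 1, indices = 0,
                        k = 10, fraction = 1, universe = "observed",
                        n_top = 1L, tie_policy = ""),
                   class = "top_kmer_set")
  d <- withr::local_tempdir()
  files <- lapply(1:2, function(i) {
    reps <- representative_sequences(top$words, rec)
    fa <- file.path(d, sprintf("r%d.fasta", i))
    write_representatives_fasta(top, reps, fa)
    mm <- file.path(d, sprintf("r%d.meme", i))
    export_motif(build_anchored_pfm(top, at, reps, flank = 4), mm, "meme")
    c(fa, mm)
  })
  expect_identical(readLines(files[[1]][1]), readLines(files[[2]][1]))
  expect_identical(readLines(files[[1]][2]), readLines(files[[2]][2]))
})
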