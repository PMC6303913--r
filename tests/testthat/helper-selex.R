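# Shared fixtures. All fixtures are generated in code under fixed seeds; the
# expensive parameter-recovery simulation is memoized so the acceptance tests
# that share it (recovery, strand symmetry, motif) run it once.

.fixture_cache <- new.env(parent = emptyenv())

random_reads <- function(n, L, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

# The parameter-recovery study: uniform 40N library, CArG mismatch landscape
# (factor 0.3), stringency 2, 50,000 reads/round, 4 rounds, fixed seed.
recovery_fixture <- function() {
  if (is.null(.fixture_cache$rec)) {
    land <- make_landscape("CCWWWWWWGG", 0.3)
    cfg <- sim_config(n_reads_per_round = 50000L, n_rounds = 4L,
                      stringency = 2, seed = 11L)
    res <- run_selex(cfg, land)
    model <- fit_markov(res$rounds[[1]], m = 6L, alpha = 1)
    tbl <- count_kmers(res$rounds[[5]], k = 10L)
    at <- relative_affinity(tbl, model, min_count = 2L, final_round_index = 4L)
    .fixture_cache$rec <- list(landscape = land, rounds = res$rounds,
                               model = model, table = tbl, affinity = at)
  }
  .fixture_cache$rec
}

# Independent naive oracle: j-mer frequencies tabulated by substring
# extraction on the Markov training frame (window starts 1..L-m), with no
# package index machinery.
naive_frame_freq <- function(reads, j, m = 6L) {
  L <- nchar(reads[1])
  starts <- 1:(L - m)
  words <- unlist(lapply(starts, function(p) substr(reads, p, p + j - 1L)))
  tab <- table(words)
  v <- numeric(4^j)
  pos <- vapply(strsplit(names(tab), ""), function(ch) {
    sum((match(ch, c("A", "C", "G", "T")) - 1) * 4^(rev(seq_along(ch)) - 1))
  }, numeric(1))
  v[pos + 1] <- as.integer(tab)
  v / sum(v)
}

# Brute-force window scorer (independent of the package's index machinery):
# per-position IUPAC comparison over every window of the sequence and of its
# reverse complement.
brute_score <- function(seq, consensus, factor) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", W = c("A", "T"),
               S = c("C", "G"), R = c("A", "G"), Y = c("C", "T"),
               K = c("G", "T"), M = c("A", "C"), N = c("A", "C", "G", "T"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"))
  cons <- strsplit(consensus, "")[[1]]
  k <- length(cons)
  one <- function(s) {
    best <- 0
    for (p in 1:(nchar(s) - k + 1)) {
      win <- strsplit(substr(s, p, p + k - 1), "")[[1]]
      mm <- sum(!mapply(function(b, cc) b %in% sets[[cc]], win, cons))
      best <- max(best, factor^mm)
    }
    best
  }
  max(one(seq), one(revcomp(seq)))
}

# Small FASTQ built in code: CASAVA-style headers with a chosen filter flag.
make_fastq_df <- function(seqs, flags = rep("N", length(seqs))) {
  data.frame(
    header = sprintf("SIM:1:FC:1:1:%d:%d 1:%s:0:1", seq_along(seqs),
                     seq_along(seqs), flags),
    sequence = seqs,
    quality = strrep("I", nchar(seqs)),
    stringsAsFactors = FALSE
  )
}

write_fastq_df <- function(df, path) {
  out <- character(4L * nrow(df))
  out[seq(1, by = 4, length.out = nrow(df))] <- paste0("@", df$header)
  out[seq(2, by = 4, length.out = nrow(df))] <- df$sequence
  out[seq(3, by = 4, length.out = nrow(df))] <- "+"
  out[seq(4, by = 4, length.out = nrow(df))] <- df$quality
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(out, con)
  close(con)
  path
}

# Build, via the simulator, a small two-condition on-disk experiment and its
# manifest (used by the pipeline and determinism tests).
small_manifest_fixture <- function(dir, n_reads = 3000L, n_rounds = 2L) {
  land_a <- make_landscape("CCWWWWWWGG", 0.3)
  land_b <- make_landscape("GCWWWWWWGG", 0.3)
  cfg_a <- sim_config(n_reads_per_round = n_reads, n_rounds = n_rounds,
                      stringency = 2, seed = 31L, left_flank = "TGGTAGG",
                      right_flank = "CCTACCA")
  cfg_b <- sim_config(n_reads_per_round = n_reads, n_rounds = n_rounds,
                      stringency = 2, seed = 32L, left_flank = "TGGTAGG",
                      right_flank = "CCTACCA")
  a <- run_selex(cfg_a, land_a, output_dir = file.path(dir, "simA"),
                 condition_label = "condA")
  b <- run_selex(cfg_b, land_b, output_dir = file.path(dir, "simB"),
                 condition_label = "condB")
  list(
    conditions = list(
      list(label = "condA", round0 = unname(a$files["round0"]),
           final = unname(a$files[sprintf("round%d", n_rounds)]),
           final_round_index = n_rounds, truth = unname(a$files["truth"])),
      list(label = "condB", round0 = unname(b$files["round0"]),
           final = unname(b$files[sprintf("round%d", n_rounds)]),
           final_round_index = n_rounds, truth = unname(b$files["truth"]))
    ),
    left_flank = "TGGTAGG", right_flank = "CCTACCA",
    variable_length = 40L, output_dir = file.path(dir, "out"),
    min_count = 2L, fraction = 0.001, seed = 1L
  )
}
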