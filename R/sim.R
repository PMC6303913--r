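# Synthetic SELEX-seq generator. Emulates the library design of a typical
# MADS-domain SELEX-seq experiment: a 40-nt randomized variable region flanked
# by fixed barcode/adapter sequence, iterated over rounds of affinity-based
# capture with PCR resampling in between. The generative truth (an
# affinity_landscape) is known, so every downstream estimator can be validated
# by parameter recovery.

#' Container for one round's variable-region reads
#'
#' @param sequences character vector of variable-region sequences (ACGT only,
#'   equal length).
#' @param round_index integer >= 0 (0 = unselected library).
#' @param condition_label protein-condition label.
#' @param source provenance note (`"simulated"` or a file path).
#' @return A `round_reads` object.
#' @export
round_reads <- function(sequences, round_index = 0L,
                        condition_label = "condition", source = "simulated") {
  if (length(sequences) == 0L) stop("empty read set")
  if (any(grepl("[^ACGT]", sequences))) stop("round_reads sequences must be over ACGT")
  if (length(unique(nchar(sequences))) != 1L)
    stop("round_reads sequences must have equal length")
  structure(
    list(sequences = sequences, round_index = as.integer(round_index),
         condition_label = condition_label, source = source),
    class = "round_reads"
  )
}

#' @export
print.round_reads <- function(x, ...) {
  cat(sprintf("Round %d [%s]: %d reads of length %d (%s)\n",
              x$round_index, x$condition_label, length(x$sequences),
              nchar(x$sequences[1]), x$source))
  invisible(x)
}

#' Simulation configuration
#'
#' @param variable_length length L of the randomized variable region
#'   (default 40 nt).
#' @param left_flank,right_flank fixed flanking sequence written around the
#'   variable region in FASTQ output (barcode/adapter context).
#' @param n_reads_per_round reads sequenced (and retained) per round.
#' @param n_rounds number of selection rounds R (Round 0 is always emitted).
#' @param stringency positive exponent s applied to binding scores before
#'   affinity-proportional sampling; larger values emulate harsher washing.
#' @param pcr_noise nonnegative overdispersion of the PCR resampling step:
#'   selection weights are multiplied by Gamma(1/pcr_noise, 1/pcr_noise)
#'   variates (mean 1, variance pcr_noise), i.e. Dirichlet-multinomial
#'   resampling. 0 disables the noise.
#' @param seed integer seed; all simulator randomness derives from it.
#' @param base_weights optional Round-0 synthesis bias: a length-4 vector
#'   (A,C,G,T) or a 4 x L matrix of per-position base weights. Default uniform.
#' @param pool `"infinite"` (default) or `"finite"`. A physical SELEX pool
#'   (tens of nanograms of dsDNA, ~1e11 molecules) is effectively
#'   inexhaustible relative to sequencing depth, so in infinite mode each
#'   round's reads are independent draws from the selection-tilted population
#'   `pi_r(x) propto score(x)^(stringency * r)`. Finite mode instead chains
#'   [simulate_round()] on the previous round's sequenced reads; it models a
#'   severely bottlenecked pool whose clonal collapse degrades k-mer
#'   estimation, and exists for studying exactly that.
#' @param proposal_factor (infinite mode) proposals drawn per retained read in
#'   the importance-resampling sampler; larger values reduce residual
#'   resampling duplication.
#' @return A `sim_config` object.
#' @export
sim_config <- function(variable_length = 40L, left_flank = "TGGTAGG",
                       right_flank = "CCTACCA", n_reads_per_round = 50000L,
                       n_rounds = 5L, stringency = 1, pcr_noise = 0,
                       seed = 1L, base_weights = NULL,
                       pool = c("infinite", "finite"), proposal_factor = 8L) {
  pool <- match.arg(pool)
  if (proposal_factor < 2L) stop("proposal_factor must be >= 2")
  if (variable_length < 1L) stop("variable_length must be positive")
  if (n_reads_per_round < 1L) stop("n_reads_per_round must be positive")
  if (n_rounds < 0L) stop("n_rounds must be >= 0")
  if (stringency <= 0) stop("stringency must be > 0")
  if (pcr_noise < 0) stop("pcr_noise must be >= 0")
  if (!is.null(base_weights)) {
    bw <- as.matrix(base_weights)
    if (nrow(bw) == 1L) bw <- t(bw)
    if (nrow(bw) != 4L) stop("base_weights must have 4 rows (A,C,G,T)")
    if (!ncol(bw) %in% c(1L, variable_length))
      stop("base_weights must have 1 or variable_length columns")
    if (any(bw <= 0)) stop("base_weights must be positive")
    base_weights <- bw
  }
  structure(
    list(variable_length = as.integer(variable_length),
         left_flank = left_flank, right_flank = right_flank,
         n_reads_per_round = as.integer(n_reads_per_round),
         n_rounds = as.integer(n_rounds), stringency = stringency,
         pcr_noise = pcr_noise, seed = as.integer(seed),
         base_weights = base_weights, pool = pool,
         proposal_factor = as.integer(proposal_factor)),
    class = "sim_config"
  )
}

# One i.i.d. draw of n reads from pi(x) propto score(x)^E (uniform base
# measure), by sampling-importance-resampling. Proposal: a 50/50 mixture of
# (a) uniform reads and (b) reads with a word planted at a uniform position,
# the word drawn from g(w) propto strand-max-affinity(w)^E. The proposal
# density is computed exactly, so the resample targets pi itself; residual
# duplication is O(1/proposal_factor).
draw_round_iid <- function(config, landscape, E) {
  n <- config$n_reads_per_round
  L <- config$variable_length
  k <- landscape$k
  W <- L - k + 1L
  rc <- rc_index_map(k)
  aff2 <- pmax(landscape$affinity, landscape$affinity[rc + 1])
  if (E == 0 || max(aff2) == min(aff2)) {
    codes <- matrix(sample.int(4L, n * L, replace = TRUE) - 1L, nrow = n, ncol = L)
    return(codes_to_dna(codes))
  }
  bw <- config$base_weights
  if (!is.null(bw) && ncol(bw) > 1L)
    stop("per-position base_weights require pool = \"finite\"")
  p4 <- if (is.null(bw)) rep(0.25, 4) else bw[, 1] / sum(bw[, 1])
  M <- config$proposal_factor * n
  g <- aff2^E
  g <- g / sum(g)
  # base-measure probability of each k-mer word (uniform: 4^-k)
  ub_word <- rep(1, 4^k)
  x <- 0:(4^k - 1)
  for (t in seq_len(k)) {
    ub_word <- ub_word * p4[(x %% 4) + 1]
    x <- x %/% 4
  }
  codes <- matrix(sample.int(4L, M * L, replace = TRUE, prob = p4) - 1L,
                  nrow = M, ncol = L)
  planted <- which(stats::runif(M) < 0.5)
  widx_plant <- sample.int(length(g), length(planted), replace = TRUE, prob = g) - 1
  pos <- sample.int(W, length(planted), replace = TRUE)
  x <- widx_plant
  for (t in k:1) {
    codes[cbind(planted, pos + t - 1L)] <- as.integer(x %% 4)
    x <- x %/% 4
  }
  widx <- window_index(codes, k)
  score <- row_max(matrix(aff2[widx + 1], nrow = M))
  # q(x)/base = 0.5 + 0.5 * mean_p g(x_p)/ub_word(x_p); weight = score^E / (q/base)
  grel <- g / ub_word
  gsum <- rowSums(matrix(grel[widx + 1], nrow = M))
  wgt <- score^E / (0.5 + 0.5 * gsum / W)
  if (config$pcr_noise > 0) {
    shape <- 1 / config$pcr_noise
    wgt <- wgt * stats::rgamma(M, shape = shape, rate = shape)
  }
  pick <- sample.int(M, n, replace = TRUE, prob = wgt)
  codes_to_dna(codes[pick, , drop = FALSE])
}

#' Draw the unselected Round-0 library
#'
#' i.i.d. bases, uniform by default or biased per `config$base_weights`
#' (emulating skewed oligo synthesis, which the Markov background model is
#' designed to absorb).
#' @keywords internal
draw_round0 <- function(config, condition_label = "condition") {
  n <- config$n_reads_per_round
  L <- config$variable_length
  if (is.null(config$base_weights)) {
    codes <- matrix(sample.int(4L, n * L, replace = TRUE) - 1L, nrow = n, ncol = L)
  } else {
    bw <- config$base_weights
    if (ncol(bw) == 1L) {
      codes <- matrix(sample.int(4L, n * L, replace = TRUE, prob = bw[, 1]) - 1L,
                      nrow = n, ncol = L)
    } else {
      codes <- matrix(0L, nrow = n, ncol = L)
      for (j in seq_len(L))
        codes[, j] <- sample.int(4L, n, replace = TRUE, prob = bw[, j]) - 1L
    }
  }
  round_reads(codes_to_dna(codes), 0L, condition_label, "simulated")
}

#' Simulate one SELEX round (capture + PCR resampling)
#'
#' Samples `config$n_reads_per_round` sequences with replacement from the pool
#' with probability proportional to `score_sequence(seq)^stringency`, the
#' weights optionally perturbed by Dirichlet-multinomial PCR noise.
#'
#' @param pool a `round_reads` object (the previous round).
#' @param landscape the generative `affinity_landscape`.
#' @param config a `sim_config`.
#' @param seed optional integer; when supplied the round is reproducible in
#'   isolation ([run_selex()] supplies a per-round seed derived from
#'   `config$seed`).
#' @return A `round_reads` object with `round_index` incremented.
#' @export
simulate_round <- function(pool, landscape, config, seed = NULL) {
  stopifnot(inherits(pool, "round_reads"), inherits(landscape, "affinity_landscape"))
  if (!is.null(seed)) set.seed(seed)
  seqs <- pool$sequences
  uniq <- unique(seqs)
  sc <- score_sequence(uniq, landscape)
  w <- sc[match(seqs, uniq)]^config$stringency
  if (config$pcr_noise > 0) {
    shape <- 1 / config$pcr_noise
    w <- w * stats::rgamma(length(w), shape = shape, rate = shape)
  }
  pick <- sample.int(length(seqs), config$n_reads_per_round, replace = TRUE, prob = w)
  round_reads(seqs[pick], pool$round_index + 1L, pool$condition_label, "simulated")
}

#' Run a full synthetic SELEX experiment
#'
#' Generates Round 0 as an i.i.d. randomized library and applies
#' [simulate_round()] iteratively. Optionally writes one FASTQ file per round
#' (variable region embedded in the configured flanks, CASAVA-1.8-style
#' headers with filter flag "N", constant high quality) plus the ground-truth
#' landscape description and the configuration, for downstream recovery tests.
#'
#' Per-round randomness uses seeds `config$seed + round_index`, so reruns with
#' an identical configuration are byte-identical.
#'
#' @param config a `sim_config`.
#' @param landscape an `affinity_landscape`.
#' @param output_dir optional directory for FASTQ/ground-truth output.
#' @param condition_label label recorded on every round.
#' @param gzip write FASTQ gzipped.
#' @return Invisibly, a list with `rounds` (list of `round_reads`, Round 0
#'   first), `landscape`, and `files` (named paths when `output_dir` given).
#' @export
run_selex <- function(config, landscape, output_dir = NULL,
                      condition_label = "condition", gzip = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(landscape, "affinity_landscape"))
  if (config$variable_length < landscape$k)
    stop("variable_length must be >= landscape k")
  set.seed(config$seed)
  rounds <- vector("list", config$n_rounds + 1L)
  rounds[[1]] <- draw_round0(config, condition_label)
  for (r in seq_len(config$n_rounds)) {
    if (config$pool == "infinite") {
      set.seed(config$seed + r)
      rounds[[r + 1L]] <- round_reads(
        draw_round_iid(config, landscape, E = config$stringency * r),
        r, condition_label, "simulated")
    } else {
      rounds[[r + 1L]] <- simulate_round(rounds[[r]], landscape, config,
                                         seed = config$seed + r)
    }
  }
  files <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(output_dir)) stop("cannot create output directory: ", output_dir)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    files <- character(0)
    for (rr in rounds) {
      path <- file.path(output_dir,
                        sprintf("%s_round%d%s", condition_label, rr$round_index, ext))
      write_fastq(rr, path, left_flank = config$left_flank,
                  right_flank = config$right_flank)
      files[sprintf("round%d", rr$round_index)] <- path
    }
    meta <- list(
      condition_label = condition_label,
      landscape = list(k = landscape$k, consensus = landscape$consensus,
                       mismatch_factor = landscape$mismatch_factor,
                       strand_symmetric = landscape$strand_symmetric),
      config = unclass(config)[setdiff(names(config), "base_weights")]
    )
    truth_json <- file.path(output_dir, sprintf("%s_truth.json", condition_label))
    jsonlite::write_json(meta, truth_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files["truth"] <- truth_json
  }
  invisible(list(rounds = rounds, landscape = landscape, files = files))
}

#' Write ground-truth affinities as TSV
#'
#' One row per k-mer with its generative relative affinity. Intended for small
#' k or for subsets; at k = 10 the full table has ~1.05 million rows.
#'
#' @param landscape an `affinity_landscape`.
#' @param path output TSV.
#' @param words optional subset of k-mers; default all `4^k`.
#' @export
write_truth_table <- function(landscape, path, words = NULL) {
  if (is.null(words)) words <- index_to_kmer(0:(4^landscape$k - 1), landscape$k)
  aff <- landscape_affinity(landscape, words)
  utils::write.table(data.frame(word = words, affinity = aff),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a round as CASAVA-style FASTQ
#'
#' 4-line records; the variable region is embedded between the fixed flanks;
#' headers follow the Illumina/CASAVA-1.8 layout with the read-filter field
#' set to `"N"` (pass); qualities are constant high quality.
#'
#' @param reads a `round_reads` object.
#' @param path output path (`.gz` suffix triggers gzip).
#' @param left_flank,right_flank fixed sequence around the variable region.
#' @export
write_fastq <- function(reads, path, left_flank = "", right_flank = "") {
  stopifnot(inherits(reads, "round_reads"))
  seqs <- paste0(left_flank, reads$sequences, right_flank)
  n <- length(seqs)
  headers <- sprintf("@SIM:1:FCSIM1:1:1:%d:%d %s:N:0:1",
                     reads$round_index + 1L, seq_len(n), "1")
  qual <- strrep("I", nchar(seqs))
  out <- character(4L * n)
  out[seq(1L, by = 4L, length.out = n)] <- headers
  out[seq(2L, by = 4L, length.out = n)] <- seqs
  out[seq(3L, by = 4L, length.out = n)] <- "+"
  out[seq(4L, by = 4L, length.out = n)] <- qual
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(out, con)
  invisible(path)
}
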