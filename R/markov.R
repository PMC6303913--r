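# Sixth-order Markov background model of the unselected Round-0 library.
#
# Round 0 is too complex for direct 10-mer frequency estimation (most 10-mers
# are seen 0-2 times at realistic depth), so the background frequency of any
# k-mer is computed from an order-m Markov chain fitted to Round-0 reads:
#
#   P(w) = P0(w[1..m]) * prod_{i=m+1..k} P(w[i] | w[i-m..i-1])
#
# Estimation is exact by the chain rule; no stochastic sampling is involved.
#
# Window-frame convention: the transition row for context c is estimated from
# (m+1)-mer window counts, and the initial m-mer distribution is, by default,
# estimated on the same frame -- the m-prefix of every (m+1)-window (every
# m-window that has an observed successor). Sharing one frame is what makes
# the pseudocount-0 model reproduce empirical j-mer frequencies (j <= m+1)
# exactly rather than up to O(1/read-length) end effects; `initial_frame =
# "all"` (every m-window, including each read's final one) is available.

#' Fit an order-m Markov background model
#'
#' @param reads Round-0 reads: a `round_reads` or character vector of
#'   equal-length ACGT sequences (length >= m+1).
#' @param m model order (default 6).
#' @param alpha pseudocount added to every (m+1)-mer and m-mer cell
#'   (default 1); guarantees strictly positive probabilities. `alpha = 0`
#'   gives the pure maximum-likelihood model used by the marginal-consistency
#'   oracles.
#' @param strand_mode `"collapsed"` trains on both strands of every read;
#'   `"single"` on the given strand only.
#' @param initial_frame `"prefix"` (default; see note above) or `"all"`.
#' @return A `markov_model`: `order`, `alpha`, `strand_mode`,
#'   `initial_frame`, `initial` (length `4^m`, sums to 1), `trans`
#'   (`4^m` x 4 row-stochastic matrix), `n_train_windows`.
#' @export
fit_markov <- function(reads, m = 6L, alpha = 1,
                       strand_mode = c("collapsed", "single"),
                       initial_frame = c("prefix", "all")) {
  strand_mode <- match.arg(strand_mode)
  initial_frame <- match.arg(initial_frame)
  if (is.character(reads)) reads <- round_reads(reads)
  stopifnot(inherits(reads, "round_reads"))
  if (m < 1L) stop("order m must be >= 1")
  if (alpha < 0) stop("alpha must be >= 0")
  codes <- dna_codes(reads$sequences)
  if (ncol(codes) < m + 1L) stop("reads must be at least m+1 long")

  idx7 <- as.integer(window_index(codes, m + 1L))
  c7 <- tabulate(idx7 + 1L, nbins = 4^(m + 1L))
  if (strand_mode == "collapsed") {
    rc <- rc_index_map(m + 1L)
    c7 <- c7 + c7[rc + 1]
  }
  M7 <- matrix(c7, nrow = 4^m, ncol = 4L, byrow = TRUE)  # rows = contexts
  c6pre <- rowSums(M7)
  trans <- (M7 + alpha) / (c6pre + 4 * alpha)
  if (alpha == 0 && any(c6pre == 0))
    trans[c6pre == 0, ] <- 0.25            # unseen context: uninformative row

  if (initial_frame == "prefix") {
    c6 <- c6pre
  } else {
    idx6 <- as.integer(window_index(codes, m))
    c6 <- tabulate(idx6 + 1L, nbins = 4^m)
    if (strand_mode == "collapsed") {
      rc6 <- rc_index_map(m)
      c6 <- c6 + c6[rc6 + 1]
    }
  }
  initial <- (c6 + alpha) / (sum(c6) + 4^m * alpha)

  structure(
    list(order = as.integer(m), alpha = alpha, strand_mode = strand_mode,
         initial_frame = initial_frame, initial = initial, trans = trans,
         n_train_windows = sum(c7)),
    class = "markov_model"
  )
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("markov_model: order %d, alpha=%g, %s strand, %s initial frame, %d training windows\n",
              x$order, x$alpha, x$strand_mode, x$initial_frame, x$n_train_windows))
  invisible(x)
}

#' Model probability of k-mers (chain rule)
#'
#' `P(w) = P0(w[1..m]) * prod P(w[i] | preceding m bases)`; strictly positive
#' when the model was fitted with `alpha > 0`. Words may have any length
#' `>= m`; mixed lengths are allowed.
#'
#' @param model a `markov_model`.
#' @param words character vector of ACGT words.
#' @return numeric vector of probabilities.
#' @export
kmer_prob <- function(model, words) {
  stopifnot(inherits(model, "markov_model"))
  m <- model$order
  if (any(nchar(words) < m)) stop("words must be at least as long as the model order")
  out <- numeric(length(words))
  for (L in unique(nchar(words))) {
    sel <- nchar(words) == L
    codes <- dna_codes(words[sel])
    ctx <- 0
    for (t in seq_len(m)) ctx <- ctx * 4 + codes[, t]
    p <- model$initial[ctx + 1]
    if (L > m) {
      modl <- 4^(m - 1)
      for (i in (m + 1L):L) {
        b <- codes[, i]
        p <- p * model$trans[cbind(ctx + 1, b + 1)]
        ctx <- (ctx %% modl) * 4 + b
      }
    }
    out[sel] <- p
  }
  out
}

# Dense chain-rule extension of the initial distribution to all 4^k words.
kmer_prob_dense <- function(model, k) {
  m <- model$order
  if (k < m) stop("k must be >= model order")
  q <- model$initial
  if (k > m) {
    for (j in seq.int(m + 1L, k)) {
      ctx <- (seq_along(q) - 1) %% 4^m
      q <- rep(q, each = 4L) * as.vector(t(model$trans[ctx + 1, , drop = FALSE]))
    }
  }
  q
}

#' Model-implied frequency table for all k-mers
#'
#' Evaluates the chain rule exhaustively over all `4^k` words (vectorized
#' dynamic programming over prefixes). With `collapse = TRUE` the
#' probabilities of a word and its reverse complement are folded onto the
#' canonical word, matching `count_kmers(strand_mode = "collapsed")`.
#' Frequencies sum to 1 either way.
#'
#' @param model a `markov_model`.
#' @param k word length (>= model order).
#' @param total_windows optional; when given, expected counts
#'   `frequency * total_windows` are included.
#' @param collapse fold onto canonical k-mers (default: model was trained
#'   collapsed).
#' @return list with `k`, `freq` (dense vector), `expected_counts` (or
#'   `NULL`), `collapse`.
#' @export
expected_kmer_table <- function(model, k, total_windows = NULL,
                                collapse = model$strand_mode == "collapsed") {
  q <- kmer_prob_dense(model, k)
  if (collapse) q <- fold_canonical(q, k)
  list(k = as.integer(k), freq = q,
       expected_counts = if (!is.null(total_windows)) q * total_windows else NULL,
       collapse = collapse)
}

#' Model-implied marginal distribution of j-mers (j <= order + 1)
#'
#' For `j == m+1` this is one chain-rule extension of the initial
#' distribution; for `j <= m` it marginalizes the initial distribution over
#' trailing bases. On the model's training frame these equal the empirical
#' j-mer frequencies exactly when `alpha = 0` (`initial_frame = "prefix"`).
#'
#' @param model a `markov_model`.
#' @param j word length, `1 <= j <= order + 1`.
#' @return dense numeric vector over `4^j` words, summing to 1.
#' @export
implied_marginal <- function(model, j) {
  m <- model$order
  if (j < 1L || j > m + 1L) stop("j must be in 1..order+1")
  if (j == m + 1L) return(kmer_prob_dense(model, j))
  # the last base is the fastest-varying index digit, so marginalizing it
  # sums each consecutive block of 4 entries
  v <- model$initial
  for (t in seq_len(m - j)) v <- colSums(matrix(v, nrow = 4L))
  v
}

#' Serialize a Markov model as TSV
#'
#' A metadata header block, the initial m-mer distribution, and one
#' row-stochastic transition row per context.
#'
#' @param model a `markov_model`.
#' @param path output path.
#' @export
write_markov_model <- function(model, path) {
  m <- model$order
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# order=%d", m),
               sprintf("# alpha=%.17g", model$alpha),
               sprintf("# strand_mode=%s", model$strand_mode),
               sprintf("# initial_frame=%s", model$initial_frame),
               sprintf("# n_train_windows=%d", model$n_train_windows)), con)
  ctxs <- index_to_kmer(0:(4^m - 1), m)
  writeLines("section\tcontext\tA\tC\tG\tT", con)
  ini <- matrix(model$initial, nrow = 4^(m - 1), ncol = 4, byrow = TRUE)
  pre <- index_to_kmer(0:(4^(m - 1) - 1), m - 1L)
  writeLines(sprintf("initial\t%s\t%.17g\t%.17g\t%.17g\t%.17g",
                     pre, ini[, 1], ini[, 2], ini[, 3], ini[, 4]), con)
  writeLines(sprintf("transition\t%s\t%.17g\t%.17g\t%.17g\t%.17g",
                     ctxs, model$trans[, 1], model$trans[, 2],
                     model$trans[, 3], model$trans[, 4]), con)
  invisible(path)
}

#' Read a Markov model written by [write_markov_model()]
#'
#' @param path TSV path.
#' @return A `markov_model`.
#' @export
read_markov_model <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key) sub(sprintf("^# %s=", key), "", grep(sprintf("^# %s=", key), meta, value = TRUE))
  m <- as.integer(get_meta("order"))
  body <- utils::read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  ini_rows <- body[body$section == "initial", ]
  ini_rows <- ini_rows[order(kmer_index(ini_rows$context)), ]
  initial <- as.vector(t(as.matrix(ini_rows[, c("A", "C", "G", "T")])))
  tr_rows <- body[body$section == "transition", ]
  tr_rows <- tr_rows[order(kmer_index(tr_rows$context)), ]
  trans <- as.matrix(tr_rows[, c("A", "C", "G", "T")])
  dimnames(trans) <- NULL
  structure(
    list(order = m, alpha = as.numeric(get_meta("alpha")),
         strand_mode = get_meta("strand_mode"),
         initial_frame = get_meta("initial_frame"),
         initial = initial, trans = trans,
         n_train_windows = as.integer(get_meta("n_train_windows"))),
    class = "markov_model"
  )
}

#' Sample reads from a Markov model
#'
#' Draws sequences of length `L` from the model's generative process (initial
#' m-mer, then conditional next bases). Used by the model-recovery tests.
#'
#' @param model a `markov_model`.
#' @param n number of sequences.
#' @param L sequence length (>= order).
#' @param seed optional integer seed.
#' @return character vector of sequences.
#' @export
sample_markov <- function(model, n, L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- model$order
  if (L < m) stop("L must be >= model order")
  codes <- matrix(0L, nrow = n, ncol = L)
  ctx <- sample.int(4^m, n, replace = TRUE, prob = model$initial) - 1
  x <- ctx
  for (t in m:1) {
    codes[, t] <- as.integer(x %% 4)
    x <- x %/% 4
  }
  if (L > m) {
    modl <- 4^(m - 1)
    u_all <- matrix(stats::runif(n * (L - m)), nrow = n)
    for (i in (m + 1L):L) {
      rows <- model$trans[ctx + 1, , drop = FALSE]
      cum <- rows[, 1]
      u <- u_all[, i - m]
      b <- integer(n)
      b[u >= cum] <- 1L
      cum <- cum + rows[, 2]
      b[u >= cum] <- 2L
      cum <- cum + rows[, 3]
      b[u >= cum] <- 3L
      codes[, i] <- b
      ctx <- (ctx %% modl) * 4 + b
    }
  }
  codes_to_dna(codes)
}
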