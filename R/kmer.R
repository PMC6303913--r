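# k-mer counting over variable regions. Counts are dense over all 4^k words
# (2-bit-packed lexicographic indices), which keeps the 4^10 ~ 1.05M-word
# universe cheap (one numeric vector) and makes the collapsed-strand
# canonicalization a pure index permutation.

#' Count all length-k windows in a round's reads
#'
#' In `single` mode every window on the given strand is counted. In
#' `collapsed` mode (the default: the library is double-stranded and MADS
#' dimers bind duplex DNA) each window is mapped to the lexicographically
#' smaller of the word and its reverse complement before counting, so counts
#' live on canonical k-mers only. In both modes `total_windows` is the number
#' of windows counted, `sum(reads length - k + 1)`, and frequencies sum to 1.
#'
#' @param reads a `round_reads` object (or character vector of equal-length
#'   ACGT sequences).
#' @param k word length (default 10).
#' @param strand_mode `"collapsed"` or `"single"`.
#' @return A `kmer_table`: dense `counts` vector over all `4^k` words
#'   (lexicographic order), `total_windows`, `n_reads`, `k`, `strand_mode`,
#'   plus round/condition provenance.
#' @export
count_kmers <- function(reads, k = 10L, strand_mode = c("collapsed", "single")) {
  strand_mode <- match.arg(strand_mode)
  if (is.character(reads)) reads <- round_reads(reads)
  stopifnot(inherits(reads, "round_reads"))
  codes <- dna_codes(reads$sequences)
  if (k > ncol(codes)) stop("k exceeds read length")
  widx <- window_index(codes, k)
  idx <- as.vector(widx)
  if (strand_mode == "collapsed") idx <- canonical_index_map(k)[idx + 1]
  counts <- tabulate(as.integer(idx) + 1L, nbins = 4^k)
  structure(
    list(k = as.integer(k), strand_mode = strand_mode, counts = counts,
         total_windows = length(idx), n_reads = length(reads$sequences),
         round_index = reads$round_index, condition_label = reads$condition_label),
    class = "kmer_table"
  )
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k=%d, %s strand, %d windows from %d reads (round %s, %s)\n",
              x$k, x$strand_mode, x$total_windows, x$n_reads,
              x$round_index, x$condition_label))
  cat(sprintf("  %d distinct words observed\n", sum(x$counts > 0)))
  invisible(x)
}

#' Per-word frequencies of a k-mer table
#'
#' @param table a `kmer_table`.
#' @return dense numeric vector summing to 1.
#' @export
kmer_frequencies <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  table$counts / table$total_windows
}

#' Observed words of a k-mer table as a data.frame
#'
#' @param x a `kmer_table`.
#' @param min_count keep words with at least this count.
#' @param ... unused.
#' @return data.frame with `word`, `count`, `frequency` sorted by word.
#' @export
as.data.frame.kmer_table <- function(x, min_count = 1L, ...) {
  keep <- which(x$counts >= min_count)
  data.frame(word = index_to_kmer(keep - 1, x$k),
             count = x$counts[keep],
             frequency = x$counts[keep] / x$total_windows,
             stringsAsFactors = FALSE)
}

#' Write a k-mer table as TSV with a metadata header block
#'
#' @param table a `kmer_table`.
#' @param path output path.
#' @param min_count only words with at least this count are written.
#' @export
write_kmer_table <- function(table, path, min_count = 1L) {
  hdr <- c(sprintf("# k=%d", table$k),
           sprintf("# strand_mode=%s", table$strand_mode),
           sprintf("# total_windows=%d", table$total_windows),
           sprintf("# n_reads=%d", table$n_reads),
           sprintf("# round_index=%s", table$round_index),
           sprintf("# condition_label=%s", table$condition_label))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- as.data.frame(table, min_count = min_count)
  writeLines("word\tcount\tfrequency", con)
  writeLines(sprintf("%s\t%d\t%.10g", df$word, df$count, df$frequency), con)
  invisible(path)
}

# the 64 concrete perfect CArG-box variants CC[A/T]{6}GG
carg_variants <- function() {
  key <- "carg_words"
  cached <- .selexr_cache[[key]]
  if (!is.null(cached)) return(cached)
  mid <- do.call(expand.grid, c(rep(list(c("A", "T")), 6), stringsAsFactors = FALSE))
  words <- sort(paste0("CC", do.call(paste0, mid), "GG"))
  .selexr_cache[[key]] <- words
  words
}

#' Perfect CArG-box prevalence of a read set
#'
#' Fraction of reads containing at least one window matching the perfect
#' CArG box CC\[A/T\]6GG, plus per-variant window counts over the 64 concrete
#' variants. A single strand scan suffices because the degenerate motif is
#' its own degenerate reverse complement (asserted internally).
#'
#' @param reads a `round_reads` object or character vector of equal-length
#'   ACGT sequences (length >= 10).
#' @return list with `prevalence` (fraction of reads in \[0,1\]), `n_reads`,
#'   `n_hit`, and `variant_counts` (named window counts over the 64 variants).
#' @export
carg_prevalence <- function(reads) {
  if (is.character(reads)) reads <- round_reads(reads)
  stopifnot(inherits(reads, "round_reads"))
  k <- 10L
  words <- carg_variants()
  idx <- kmer_index(words)
  rc <- rc_index_map(k)
  stopifnot(setequal(idx, rc[idx + 1]))    # motif set closed under revcomp
  codes <- dna_codes(reads$sequences)
  if (ncol(codes) < k) stop("reads shorter than 10 nt")
  widx <- window_index(codes, k)
  lut <- logical(4^k)
  lut[idx + 1] <- TRUE
  hitm <- matrix(lut[widx + 1], nrow = nrow(widx))
  hit <- rowSums(hitm) > 0
  match_idx <- as.vector(widx)[as.vector(hitm)]
  vc <- tabulate(match(match_idx, idx), nbins = length(idx))
  names(vc) <- words
  list(prevalence = mean(hit), n_reads = length(hit), n_hit = sum(hit),
       variant_counts = vc)
}
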