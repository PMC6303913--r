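# Affinity landscapes: the simulator's generative ground truth. A landscape
# assigns every k-mer a relative affinity in (0, 1] with maximum exactly 1.
# The default family is mismatch-energetic: affinity = factor^(#mismatches to
# a degenerate consensus), with the CArG box CC[A/T]6GG as the canonical
# MADS-domain example ("CCWWWWWWGG" in IUPAC notation).

#' Build a mismatch-energy affinity landscape
#'
#' Every k-mer `w` receives affinity `mismatch_factor ^ d(w)`, where `d(w)` is
#' the number of positions at which `w` fails the degenerate IUPAC consensus.
#' Words matching the consensus therefore have affinity exactly 1, and all
#' affinities are strictly positive. The landscape is flagged strand-symmetric
#' when the degenerate consensus equals its own degenerate reverse complement
#' (true for the CArG box), in which case `affinity(w) == affinity(revcomp(w))`
#' for every word.
#'
#' @param consensus IUPAC degenerate DNA word of length `k`
#'   (default `"CCWWWWWWGG"`, the perfect CArG box CC\[A/T\]6GG).
#' @param mismatch_factor per-position mismatch penalty in (0, 1).
#' @param k word length; must equal `nchar(consensus)`.
#' @return An object of class `affinity_landscape` with elements `k`,
#'   `affinity` (dense vector over all `4^k` words in lexicographic order),
#'   `consensus`, `mismatch_factor` and `strand_symmetric`.
#' @examples
#' land <- make_landscape("CCWWWWWWGG", 0.1)
#' landscape_affinity(land, c("CCATATATGG", "GCATATATGG"))
#' @export
make_landscape <- function(consensus = "CCWWWWWWGG", mismatch_factor = 0.1,
                           k = nchar(consensus)) {
  consensus <- toupper(consensus)
  if (nchar(consensus) != k) stop("consensus length must equal k")
  if (!is.numeric(mismatch_factor) || mismatch_factor <= 0 || mismatch_factor >= 1)
    stop("mismatch_factor must lie in (0, 1)")
  letters_ <- strsplit(consensus, "")[[1]]
  if (!all(letters_ %in% names(IUPAC_SETS)))
    stop("non-IUPAC characters in consensus: ",
         paste(setdiff(letters_, names(IUPAC_SETS)), collapse = ", "))
  i <- 0:(4^k - 1)
  mismatches <- numeric(length(i))
  for (t in seq_len(k)) {
    ok <- logical(4)
    ok[match(IUPAC_SETS[[letters_[t]]], DNA_BASES)] <- TRUE
    d <- (i %/% 4^(k - t)) %% 4
    mismatches <- mismatches + as.numeric(!ok[d + 1])
  }
  aff <- mismatch_factor^mismatches
  rc_consensus <- revcomp(consensus)
  structure(
    list(k = k, affinity = aff, consensus = consensus,
         mismatch_factor = mismatch_factor,
         strand_symmetric = identical(rc_consensus, consensus)),
    class = "affinity_landscape"
  )
}

#' Build a constant (neutral) affinity landscape
#'
#' All `4^k` words receive affinity 1; selection under this landscape is
#' neutral, so enriched rounds are statistically exchangeable with Round 0.
#' Used for null calibration.
#'
#' @param k word length.
#' @return An `affinity_landscape`.
#' @export
make_constant_landscape <- function(k = 10) {
  structure(
    list(k = k, affinity = rep(1, 4^k), consensus = strrep("N", k),
         mismatch_factor = NA_real_, strand_symmetric = TRUE),
    class = "affinity_landscape"
  )
}

#' Build a landscape from an explicit affinity table
#'
#' @param affinity named numeric vector (names = k-mers) or dense vector of
#'   length `4^k` in lexicographic word order. Values must be strictly
#'   positive; they are rescaled so the maximum is exactly 1.
#' @param k word length.
#' @param strand_symmetric flag asserted by the caller; checked when `TRUE`.
#' @return An `affinity_landscape`.
#' @export
make_table_landscape <- function(affinity, k, strand_symmetric = FALSE) {
  if (!is.null(names(affinity))) {
    dense <- rep(min(affinity) * 1e-6, 4^k)   # unlisted words: negligible but positive
    dense[kmer_index(names(affinity)) + 1] <- unname(affinity)
    affinity <- dense
  }
  if (length(affinity) != 4^k) stop("affinity table must cover all 4^k words")
  if (any(affinity <= 0)) stop("all affinities must be strictly positive")
  affinity <- affinity / max(affinity)
  if (strand_symmetric) {
    rc <- rc_index_map(k)
    if (max(abs(affinity - affinity[rc + 1])) > 1e-12)
      stop("landscape declared strand-symmetric but affinity(w) != affinity(revcomp(w))")
  }
  structure(
    list(k = k, affinity = affinity, consensus = NA_character_,
         mismatch_factor = NA_real_, strand_symmetric = strand_symmetric),
    class = "affinity_landscape"
  )
}

#' Look up landscape affinities for k-mer strings
#'
#' @param landscape an `affinity_landscape`.
#' @param words character vector of k-mers (length `landscape$k`).
#' @return numeric vector of affinities in (0, 1].
#' @export
landscape_affinity <- function(landscape, words) {
  stopifnot(inherits(landscape, "affinity_landscape"))
  if (any(nchar(words) != landscape$k)) stop("words must have length k")
  landscape$affinity[kmer_index(words) + 1]
}

#' Binding score of full-length sequences under a landscape
#'
#' The score of a sequence is the maximum landscape affinity over all
#' length-k windows of the sequence and of its reverse complement (duplex
#' binding: either strand can present the site). Always in (0, 1].
#'
#' @param seqs character vector of equal-length DNA sequences, each at least
#'   `k` long.
#' @param landscape an `affinity_landscape`.
#' @return numeric vector of scores.
#' @export
score_sequence <- function(seqs, landscape) {
  stopifnot(inherits(landscape, "affinity_landscape"))
  k <- landscape$k
  if (any(nchar(seqs) < k)) stop("sequences shorter than k cannot be scored")
  rc <- rc_index_map(k)
  both <- pmax(landscape$affinity, landscape$affinity[rc + 1])
  codes <- dna_codes(seqs)
  widx <- window_index(codes, k)
  vals <- matrix(both[widx + 1], nrow = nrow(widx))
  row_max(vals)
}

#' @export
print.affinity_landscape <- function(x, ...) {
  cat("Affinity landscape: k =", x$k, "\n")
  if (!is.na(x$consensus))
    cat("  consensus:", x$consensus,
        if (!is.na(x$mismatch_factor)) paste0("(mismatch factor ", x$mismatch_factor, ")"),
        "\n")
  cat("  strand-symmetric:", x$strand_symmetric, "\n")
  invisible(x)
}
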