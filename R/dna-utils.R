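# Low-level DNA / k-mer index machinery shared by all modules.
#
# k-mers are represented as base-4 integers (A=0, C=1, G=2, T=3, most
# significant digit first), so the index order coincides with lexicographic
# order over {A,C,G,T} words. Indices are stored as doubles; 4^10 ~ 1.05e6 is
# far below the exact-integer range of a double.

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate codes -> the set of concrete bases they admit
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

.selexr_cache <- new.env(parent = emptyenv())

#' Encode equal-length DNA strings as a base-code matrix
#'
#' @param seqs character vector of equal-length DNA strings over ACGT.
#' @return integer matrix (`length(seqs)` x width) with A=0, C=1, G=2, T=3.
#' @keywords internal
dna_codes <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences supplied")
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must all have the same length")
  if (L == 0L) stop("sequences are empty")
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A") + 1L] <- 0L
  lut[utf8ToInt("C") + 1L] <- 1L
  lut[utf8ToInt("G") + 1L] <- 2L
  lut[utf8ToInt("T") + 1L] <- 3L
  raw <- utf8ToInt(paste(seqs, collapse = ""))
  codes <- lut[raw + 1L]
  if (anyNA(codes)) stop("non-ACGT character in sequence")
  matrix(codes, nrow = length(seqs), ncol = L, byrow = TRUE)
}

#' Decode a base-code matrix back to DNA strings
#' @keywords internal
codes_to_dna <- function(codes) {
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = 1L)
  cols <- lapply(seq_len(ncol(codes)), function(j) DNA_BASES[codes[, j] + 1L])
  do.call(paste0, cols)
}

#' Indices of all length-k windows of each sequence
#'
#' @param codes matrix from [dna_codes()].
#' @param k word length.
#' @return numeric matrix (reads x (L-k+1)) of k-mer indices.
#' @keywords internal
window_index <- function(codes, k) {
  L <- ncol(codes)
  if (k > L) stop("k exceeds sequence length")
  W <- L - k + 1L
  idx <- matrix(0, nrow = nrow(codes), ncol = W)
  first <- 0
  for (t in seq_len(k)) first <- first * 4 + codes[, t]
  idx[, 1L] <- first
  if (W > 1L) {
    modl <- 4^(k - 1)
    for (p in 2:W) idx[, p] <- (idx[, p - 1L] %% modl) * 4 + codes[, p + k - 1L]
  }
  idx
}

#' Convert between k-mer strings and lexicographic indices
#'
#' Dense tables in this package (k-mer counts, affinities, landscapes) are
#' indexed by the base-4 encoding of the word (A=0, C=1, G=2, T=3, first base
#' most significant), which coincides with lexicographic word order.
#' `kmer_index` maps words to 0-based indices; `index_to_kmer` inverts it.
#'
#' @param words character vector of equal-length ACGT words.
#' @return `kmer_index`: numeric vector of 0-based indices.
#' @export
kmer_index <- function(words) {
  codes <- dna_codes(words)
  idx <- 0
  for (t in seq_len(ncol(codes))) idx <- idx * 4 + codes[, t]
  idx
}

#' @rdname kmer_index
#' @param idx numeric vector of 0-based word indices.
#' @param k word length.
#' @return `index_to_kmer`: character vector of words.
#' @export
index_to_kmer <- function(idx, k) {
  cols <- vector("list", k)
  x <- idx
  for (t in k:1) {
    cols[[t]] <- DNA_BASES[(x %% 4) + 1L]
    x <- x %/% 4
  }
  do.call(paste0, cols)
}

#' Reverse-complement map over all k-mer indices (cached)
#'
#' `rc_index_map(k)[i + 1]` is the index of the reverse complement of the
#' k-mer with index `i`.
#' @keywords internal
rc_index_map <- function(k) {
  key <- paste0("rc", k)
  cached <- .selexr_cache[[key]]
  if (!is.null(cached)) return(cached)
  x <- 0:(4^k - 1)
  rc <- numeric(length(x))
  for (t in seq_len(k)) {
    d <- x %% 4
    x <- x %/% 4
    rc <- rc * 4 + (3 - d)
  }
  .selexr_cache[[key]] <- rc
  rc
}

#' Canonical (strand-collapsed) index map: min(word, revcomp(word))
#' @keywords internal
canonical_index_map <- function(k) {
  key <- paste0("canon", k)
  cached <- .selexr_cache[[key]]
  if (!is.null(cached)) return(cached)
  cm <- pmin(0:(4^k - 1), rc_index_map(k))
  .selexr_cache[[key]] <- cm
  cm
}

#' Reverse complement of DNA strings (IUPAC-aware)
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Row-wise maximum of a numeric matrix
#' @keywords internal
row_max <- function(m) {
  out <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2:ncol(m)) out <- pmax(out, m[, j])
  out
}

#' Fold a dense per-index vector onto canonical k-mer indices
#'
#' Adds each non-palindromic value to its reverse complement's and keeps the
#' result only at canonical indices (zero elsewhere).
#' @keywords internal
fold_canonical <- function(v, k) {
  rc <- rc_index_map(k)
  i <- seq_along(v) - 1
  out <- v + v[rc + 1]
  pal <- rc == i
  out[pal] <- v[pal]
  out[i > rc] <- 0
  out
}
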