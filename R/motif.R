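# Motif construction from top-affinity k-mers: select the top fraction of
# k-mers, recover each k-mer's most recurrent full-length bound sequence
# (the faithful input for external motif discovery, e.g. MEME), and build an
# anchored, affinity-weighted position-frequency matrix as a self-contained
# motif summary.

#' Select the top-affinity k-mers
#'
#' Takes the `ceiling(fraction * universe size)` highest-affinity words.
#' `universe = "observed"` (default) counts only words passing the table's
#' count filter -- consistent with condition-dependent top-set sizes at a fixed
#' fraction; `"possible"` uses all `4^k` words. Boundary ties are broken
#' lexicographically (smaller word kept).
#'
#' @param table an `affinity_table`.
#' @param fraction selection fraction in (0, 1] (default 0.001, i.e. the top
#'   0.1%).
#' @param universe `"observed"` or `"possible"`.
#' @return A `top_kmer_set`: `words` (affinity-sorted), `rel_affinity`,
#'   `indices`, `fraction`, `universe`, `n_top`.
#' @export
top_kmers <- function(table, fraction = 0.001,
                      universe = c("observed", "possible")) {
  universe <- match.arg(universe)
  stopifnot(inherits(table, "affinity_table"))
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (table$n_observed == 0L) stop("empty affinity table")
  usize <- if (universe == "observed") table$n_observed else 4^table$k
  n_top <- ceiling(fraction * usize)
  cand <- which(table$observed)
  ord <- cand[order(-table$rel_affinity[cand], cand)]
  if (universe == "possible" && n_top > length(ord)) n_top <- length(ord)
  sel <- ord[seq_len(min(n_top, length(ord)))]
  structure(
    list(words = index_to_kmer(sel - 1, table$k),
         rel_affinity = table$rel_affinity[sel],
         indices = sel - 1, k = table$k,
         fraction = fraction, universe = universe, n_top = length(sel),
         tie_policy = "boundary ties broken lexicographically"),
    class = "top_kmer_set"
  )
}

#' @export
print.top_kmer_set <- function(x, ...) {
  cat(sprintf("top_kmer_set: %d words (fraction %g of %s universe)\n",
              x$n_top, x$fraction, x$universe))
  utils::head(data.frame(word = x$words, rel_affinity = x$rel_affinity), 5)
  invisible(x)
}

#' Most recurrent full-length sequence containing each k-mer
#'
#' For each word, among the reads containing it (on either strand when
#' `collapse = TRUE`), returns the read with the highest multiplicity in the
#' read set; multiplicity ties are broken lexicographically (smaller
#' sequence). The returned sequence is oriented so the word occurs on the
#' forward strand. Words contained in no read are flagged.
#'
#' @param words character vector of k-mers (equal length).
#' @param reads a `round_reads` (typically the final enrichment round).
#' @param collapse match on both strands (default TRUE).
#' @return data.frame with `word`, `representative` (`NA` when absent),
#'   `multiplicity`, `found`.
#' @export
representative_sequences <- function(words, reads, collapse = TRUE) {
  if (is.character(reads)) reads <- round_reads(reads)
  stopifnot(inherits(reads, "round_reads"))
  k <- unique(nchar(words))
  if (length(k) != 1L) stop("words must have equal length")
  L <- nchar(reads$sequences[1])
  if (k > L) stop("words longer than the reads")

  seqs <- reads$sequences
  tab <- table(seqs)
  uniq <- names(tab)
  mult <- as.integer(tab)

  codes <- dna_codes(uniq)
  widx <- window_index(codes, k)
  widx_key <- if (collapse) {
    matrix(canonical_index_map(k)[widx + 1], nrow = nrow(widx))
  } else widx

  tgt <- kmer_index(words)
  tgt_key <- if (collapse) canonical_index_map(k)[tgt + 1] else tgt
  rank_lut <- rep(NA_integer_, 4^k)
  rank_lut[tgt_key + 1] <- seq_along(words)

  hit_rank <- matrix(rank_lut[widx_key + 1], nrow = nrow(widx_key))
  pos <- which(!is.na(hit_rank))
  out <- data.frame(word = words, representative = NA_character_,
                    multiplicity = NA_integer_, found = FALSE,
                    stringsAsFactors = FALSE)
  if (length(pos)) {
    read_i <- (pos - 1L) %% nrow(hit_rank) + 1L
    wrank <- hit_rank[pos]
    pairs <- unique(data.frame(read_i = read_i, wrank = wrank))
    pairs$mult <- mult[pairs$read_i]
    pairs$seq <- uniq[pairs$read_i]
    # orient: forward if the read contains the word as given, else revcomp
    fwd_lut <- logical(4^k)
    fwd_lut[tgt + 1] <- TRUE
    has_fwd <- rowSums(matrix(fwd_lut[widx[pairs$read_i, , drop = FALSE] + 1],
                              nrow = nrow(pairs))) > 0
    # per target word (by original index), does the read contain *that* word forward?
    fwd_rank_lut <- rep(NA_integer_, 4^k)
    fwd_rank_lut[tgt + 1] <- seq_along(words)
    fwd_hit <- matrix(fwd_rank_lut[widx + 1], nrow = nrow(widx))
    fwd_pairs <- unique(data.frame(
      read_i = (which(!is.na(fwd_hit)) - 1L) %% nrow(fwd_hit) + 1L,
      wrank = fwd_hit[which(!is.na(fwd_hit))]))
    fwd_key <- paste(fwd_pairs$read_i, fwd_pairs$wrank)
    pairs$forward <- paste(pairs$read_i, pairs$wrank) %in% fwd_key
    pairs$oriented <- ifelse(pairs$forward, pairs$seq, revcomp(pairs$seq))
    ord <- order(pairs$wrank, -pairs$mult, pairs$oriented)
    pairs <- pairs[ord, , drop = FALSE]
    best <- pairs[!duplicated(pairs$wrank), , drop = FALSE]
    out$representative[best$wrank] <- best$oriented
    out$multiplicity[best$wrank] <- best$mult
    out$found[best$wrank] <- TRUE
  }
  out
}

#' Most recurrent sequence for a single k-mer
#'
#' Scalar convenience wrapper around [representative_sequences()].
#'
#' @inheritParams representative_sequences
#' @param word a single k-mer.
#' @return the representative sequence, or `NA` (with a warning) when no read
#'   contains the word.
#' @export
representative_sequence <- function(word, reads, collapse = TRUE) {
  res <- representative_sequences(word, reads, collapse = collapse)
  if (!res$found[1]) warning("no read contains word ", word)
  res$representative[1]
}

#' Build an anchored position-frequency matrix
#'
#' Each top word's representative sequence is aligned by anchoring the first
#' forward occurrence of the word at a fixed offset, extended by `flank`
#' bases on both sides; positions falling outside the read contribute
#' equal-weight background (0.25 per base). Contributions are weighted by
#' relative affinity (or 1 when `weighted = FALSE`), so every column sums to
#' the total contributed weight.
#'
#' @param top a `top_kmer_set`.
#' @param table the `affinity_table` the top set came from (affinity weights).
#' @param reps data.frame from [representative_sequences()] for `top$words`.
#' @param flank bases added on each side of the k-mer (default 5).
#' @param weighted weight contributions by relative affinity (default TRUE).
#' @return A `motif_matrix`: `counts` (4 x width, rows A,C,G,T), `width`,
#'   `anchor_offset` (0-based k-mer start within the window),
#'   `n_contributing`, `type = "counts"`.
#' @export
build_anchored_pfm <- function(top, table, reps, flank = 5L, weighted = TRUE) {
  stopifnot(inherits(top, "top_kmer_set"))
  if (flank < 0L) stop("flank must be >= 0")
  k <- top$k
  width <- as.integer(k + 2L * flank)
  counts <- matrix(0, nrow = 4L, ncol = width, dimnames = list(DNA_BASES, NULL))
  reps <- reps[match(top$words, reps$word), , drop = FALSE]
  use <- which(reps$found)
  if (length(use) < length(top$words))
    warning(sprintf("%d top word(s) have no representative and are skipped",
                    length(top$words) - length(use)))
  n_used <- 0L
  for (i in use) {
    rep_seq <- reps$representative[i]
    at <- regexpr(top$words[i], rep_seq, fixed = TRUE)[1]
    if (at < 0) next                       # defensive; reps are oriented forward
    w <- if (weighted) top$rel_affinity[i] else 1
    Lr <- nchar(rep_seq)
    qpos <- (at - flank):(at + k - 1L + flank)   # read positions per column
    inside <- qpos >= 1L & qpos <= Lr
    if (any(inside)) {
      b <- match(strsplit(substr(rep_seq, min(qpos[inside]), max(qpos[inside])),
                          "")[[1]], DNA_BASES)
      cols <- which(inside)
      counts[cbind(b, cols)] <- counts[cbind(b, cols)] + w
    }
    if (any(!inside)) counts[, which(!inside)] <- counts[, which(!inside)] + w / 4
    n_used <- n_used + 1L
  }
  structure(
    list(counts = counts, width = width, anchor_offset = as.integer(flank),
         k = k, n_contributing = n_used, weighted = weighted, type = "counts"),
    class = "motif_matrix"
  )
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix: width %d, anchor offset %d, %d contributing words (%s)\n",
              x$width, x$anchor_offset, x$n_contributing,
              if (x$weighted %||% TRUE) "affinity-weighted" else "unweighted"))
  print(round(x$counts, 3))
  invisible(x)
}

#' Column-normalized probability matrix of a motif
#'
#' @param matrix_ a `motif_matrix`.
#' @return 4 x width matrix with columns summing to 1.
#' @export
motif_probabilities <- function(matrix_) {
  stopifnot(inherits(matrix_, "motif_matrix"))
  if (identical(matrix_$type, "probability")) return(matrix_$counts)
  sweep(matrix_$counts, 2, colSums(matrix_$counts), "/")
}

#' Export a motif as MEME-minimal or JASPAR text
#'
#' MEME-minimal writes a version line, alphabet, strand and background
#' declarations, and a `letter-probability matrix` block; JASPAR writes the
#' `>name` header and per-base bracketed count rows. Both round-trip through
#' [read_motif()] within float print precision.
#'
#' @param matrix_ a `motif_matrix`.
#' @param path output path.
#' @param format `"meme"` or `"jaspar"`.
#' @param name motif name.
#' @return the path, invisibly.
#' @export
export_motif <- function(matrix_, path, format = c("meme", "jaspar"),
                         name = "motif1") {
  format <- match.arg(format)
  stopifnot(inherits(matrix_, "motif_matrix"))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "meme") {
    pr <- motif_probabilities(matrix_)
    nsites <- max(1L, matrix_$n_contributing)
    writeLines(c("MEME version 4", "",
                 "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 "Background letter frequencies",
                 "A 0.25 C 0.25 G 0.25 T 0.25", "",
                 sprintf("MOTIF %s", name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         matrix_$width, nsites)), con)
    writeLines(apply(pr, 2, function(col) paste(sprintf("%.6f", col), collapse = " ")),
               con)
  } else {
    writeLines(sprintf(">%s", name), con)
    for (b in DNA_BASES)
      writeLines(sprintf("%s [ %s ]", b,
                         paste(sprintf("%.6f", matrix_$counts[b, ]), collapse = " ")),
                 con)
  }
  invisible(path)
}

#' Read a motif written by [export_motif()]
#'
#' @param path file path.
#' @param format `"meme"` or `"jaspar"`.
#' @return A `motif_matrix` (`type = "probability"` for MEME input, whose
#'   matrix stores the letter probabilities; `type = "counts"` for JASPAR).
#' @export
read_motif <- function(path, format = c("meme", "jaspar")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "meme") {
    hdr <- grep("^letter-probability matrix:", lines)
    if (!length(hdr)) stop("not a MEME-minimal motif file: ", path)
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr[1]]))
    nsites <- as.integer(sub(".*nsites= *([0-9]+).*", "\\1", lines[hdr[1]]))
    rows <- lines[(hdr[1] + 1L):(hdr[1] + w)]
    pr <- t(vapply(strsplit(trimws(rows), "[ \t]+"),
                   function(x) as.numeric(x), numeric(4)))
    counts <- t(pr)
    rownames(counts) <- DNA_BASES
    structure(list(counts = counts, width = w, anchor_offset = NA_integer_,
                   k = NA_integer_, n_contributing = nsites, weighted = NA,
                   type = "probability"),
              class = "motif_matrix")
  } else {
    base_lines <- grep("^[ACGT] *\\[", lines, value = TRUE)
    if (length(base_lines) != 4L) stop("not a JASPAR motif file: ", path)
    bases <- substr(base_lines, 1, 1)
    vals <- lapply(base_lines, function(l) {
      as.numeric(strsplit(trimws(sub(".*\\[(.*)\\].*", "\\1", l)), "[ \t]+")[[1]])
    })
    counts <- do.call(rbind, vals)[order(match(bases, DNA_BASES)), , drop = FALSE]
    rownames(counts) <- DNA_BASES
    structure(list(counts = counts, width = ncol(counts),
                   anchor_offset = NA_integer_, k = NA_integer_,
                   n_contributing = NA_integer_, weighted = NA, type = "counts"),
              class = "motif_matrix")
  }
}

#' Write representative sequences as MEME-ready FASTA
#'
#' One record per top word that has a representative; headers carry the word
#' and its relative affinity. This file is the faithful input for external
#' motif discovery.
#'
#' @param top a `top_kmer_set`.
#' @param reps data.frame from [representative_sequences()].
#' @param path output FASTA path.
#' @export
write_representatives_fasta <- function(top, reps, path) {
  reps <- reps[match(top$words, reps$word), , drop = FALSE]
  use <- which(reps$found)
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in use) {
    writeLines(sprintf(">%s rel_affinity=%.6g multiplicity=%d",
                       top$words[i], top$rel_affinity[i], reps$multiplicity[i]), con)
    writeLines(reps$representative[i], con)
  }
  invisible(path)
}
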