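# Relative affinity estimation: the enrichment of each k-mer in the final
# selection round over its model-implied Round-0 background frequency,
# rescaled so the best k-mer scores exactly 1:
#
#   raw_ratio(w)    = f_R(w) / P_bg(w)
#   rel_affinity(w) = raw_ratio(w) / max_w raw_ratio(w)
#
# The denominator always comes from the Markov background model (Round 0
# cannot support direct 10-mer frequencies). Because conditions may be
# sequenced at different rounds, the per-round-root mode replaces the ratio
# by ratio^(1/R) before normalization; both modes induce the same ranking.

#' Per-k-mer relative affinities for one condition
#'
#' @param final_table `kmer_table` of the final enrichment round.
#' @param background a `markov_model` fitted on Round 0 with `alpha > 0`, or
#'   a dense numeric frequency vector over all `4^k` words (already strand-
#'   collapsed when the final table is; mainly for tests and alternative
#'   backgrounds).
#' @param min_count words with final-round count below this threshold are
#'   assigned ratio 0 and flagged unobserved rather than given unstable
#'   ratios (default 2).
#' @param exponent_mode `"ratio"` (the direct frequency ratio, default) or
#'   `"per_round_root"` (ratio^(1/R), comparable across final rounds).
#' @param final_round_index round R; defaults to the table's `round_index`.
#' @return An `affinity_table` with dense `counts`, `raw_ratio`,
#'   `rel_affinity` and `observed` vectors over all `4^k` words (canonical
#'   words only in collapsed mode), the background frequencies `bg_freq`,
#'   `normalization_word`, and the recorded parameters.
#' @export
relative_affinity <- function(final_table, background, min_count = 2L,
                              exponent_mode = c("ratio", "per_round_root"),
                              final_round_index = NULL) {
  exponent_mode <- match.arg(exponent_mode)
  stopifnot(inherits(final_table, "kmer_table"))
  if (min_count < 0L) stop("min_count must be >= 0")
  k <- final_table$k
  collapsed <- final_table$strand_mode == "collapsed"
  if (inherits(background, "markov_model")) {
    if (k < background$order) stop("k must be >= background model order")
    if (background$alpha <= 0)
      stop("background model must be fitted with alpha > 0 (positive denominators)")
    if (background$strand_mode != final_table$strand_mode)
      warning("background and final table use different strand modes")
    bg <- expected_kmer_table(background, k, collapse = collapsed)$freq
  } else {
    bg <- as.numeric(background)
    if (length(bg) != 4^k) stop("background frequency vector must cover all 4^k words")
  }
  R <- final_round_index %||% final_table$round_index
  if (is.null(R) || is.na(R) || R < 1L)
    stop("final round index unknown; supply final_round_index >= 1")

  f <- kmer_frequencies(final_table)
  observed <- final_table$counts >= max(min_count, 1L)
  if (min_count == 0L && collapsed) {
    cm <- canonical_index_map(k)
    observed <- (cm == (seq_along(f) - 1))   # every canonical word
  } else if (min_count == 0L) {
    observed <- rep(TRUE, length(f))
  }
  raw <- numeric(length(f))
  raw[observed] <- f[observed] / bg[observed]
  val <- raw
  if (exponent_mode == "per_round_root") val[observed] <- raw[observed]^(1 / R)
  mx <- max(val)
  if (mx <= 0) stop("no word passes min_count; cannot normalize")
  rel <- val / mx
  norm_idx <- which(val == mx)[1]            # first = lexicographically smallest
  structure(
    list(k = k, condition_label = final_table$condition_label,
         final_round_index = as.integer(R), strand_mode = final_table$strand_mode,
         counts = final_table$counts, total_windows = final_table$total_windows,
         bg_freq = bg, raw_ratio = raw, rel_affinity = rel, observed = observed,
         min_count = as.integer(min_count), exponent_mode = exponent_mode,
         normalization_word = index_to_kmer(norm_idx - 1, k),
         n_observed = sum(observed)),
    class = "affinity_table"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.affinity_table <- function(x, ...) {
  cat(sprintf("affinity_table: k=%d, condition %s, round %d, %s strand, mode %s\n",
              x$k, x$condition_label, x$final_round_index, x$strand_mode,
              x$exponent_mode))
  cat(sprintf("  %d words pass min_count=%d; best word %s\n",
              x$n_observed, x$min_count, x$normalization_word))
  invisible(x)
}

#' Relative affinity of specific words
#'
#' Looks up words in an affinity table; in collapsed mode a word and its
#' reverse complement resolve to the same canonical entry, so
#' `affinity_of(t, w) == affinity_of(t, revcomp(w))` exactly.
#'
#' @param table an `affinity_table`.
#' @param words character vector of k-mers.
#' @return numeric vector of relative affinities (0 for filtered words).
#' @export
affinity_of <- function(table, words) {
  stopifnot(inherits(table, "affinity_table"))
  idx <- kmer_index(words)
  if (table$strand_mode == "collapsed") idx <- canonical_index_map(table$k)[idx + 1]
  table$rel_affinity[idx + 1]
}

#' Observed words of an affinity table as a data.frame
#'
#' @param x an `affinity_table`.
#' @param ... unused.
#' @return data.frame with `word`, `count`, `frequency`, `raw_ratio`,
#'   `rel_affinity`, sorted by decreasing affinity then word.
#' @export
as.data.frame.affinity_table <- function(x, ...) {
  keep <- which(x$observed)
  df <- data.frame(word = index_to_kmer(keep - 1, x$k),
                   count = x$counts[keep],
                   frequency = x$counts[keep] / x$total_windows,
                   raw_ratio = x$raw_ratio[keep],
                   rel_affinity = x$rel_affinity[keep],
                   stringsAsFactors = FALSE)
  df[order(-df$rel_affinity, df$word), , drop = FALSE]
}

#' Write an affinity table as TSV with metadata sidecar
#'
#' @param table an `affinity_table`.
#' @param path TSV path; a `.json` metadata sidecar is written next to it.
#' @export
write_affinity_table <- function(table, path) {
  df <- as.data.frame(table)
  con <- file(path, "wb")
  writeLines("word\tcount\tfrequency\traw_ratio\trel_affinity", con)
  writeLines(sprintf("%s\t%d\t%.10g\t%.10g\t%.10g", df$word, df$count,
                     df$frequency, df$raw_ratio, df$rel_affinity), con)
  close(con)
  meta <- list(k = table$k, condition_label = table$condition_label,
               final_round_index = table$final_round_index,
               strand_mode = table$strand_mode, min_count = table$min_count,
               exponent_mode = table$exponent_mode,
               normalization_word = table$normalization_word,
               n_observed = table$n_observed,
               total_windows = table$total_windows)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Compare affinity tables between two conditions
#'
#' Inner-joins the words passing both tables' count filters, computes Pearson
#' and Spearman correlations of the relative affinities, and ranks the most
#' discordant words by `|log(rel_a / rel_b)|` (the dotplot's off-diagonal
#' outliers).
#'
#' @param table_a,table_b `affinity_table`s with equal `k`.
#' @param n_discordant how many top-discordant words to report.
#' @return An `affinity_comparison`: `data` (word, rel_a, rel_b, log_ratio),
#'   `pearson`, `spearman`, `n_common`, `n_only_a`, `n_only_b`,
#'   `discordant` (top rows by |log ratio|), condition labels.
#' @export
compare_affinities <- function(table_a, table_b, n_discordant = 25L) {
  stopifnot(inherits(table_a, "affinity_table"), inherits(table_b, "affinity_table"))
  if (table_a$k != table_b$k) stop("tables have different k")
  if (table_a$strand_mode != table_b$strand_mode)
    stop("tables have different strand modes")
  common <- table_a$observed & table_b$observed
  if (!any(common)) stop("no words pass both tables' count filters")
  idx <- which(common)
  ra <- table_a$rel_affinity[idx]
  rb <- table_b$rel_affinity[idx]
  df <- data.frame(word = index_to_kmer(idx - 1, table_a$k),
                   rel_a = ra, rel_b = rb,
                   log_ratio = log(ra / rb), stringsAsFactors = FALSE)
  ord <- order(-abs(df$log_ratio), df$word)
  structure(
    list(data = df,
         pearson = stats::cor(ra, rb, method = "pearson"),
         spearman = stats::cor(ra, rb, method = "spearman"),
         n_common = length(idx),
         n_only_a = sum(table_a$observed & !common),
         n_only_b = sum(table_b$observed & !common),
         discordant = df[utils::head(ord, n_discordant), , drop = FALSE],
         condition_a = table_a$condition_label,
         condition_b = table_b$condition_label),
    class = "affinity_comparison"
  )
}

#' @export
print.affinity_comparison <- function(x, ...) {
  cat(sprintf("affinity_comparison: %s vs %s over %d shared words\n",
              x$condition_a, x$condition_b, x$n_common))
  cat(sprintf("  Pearson r = %.4f, Spearman rho = %.4f\n", x$pearson, x$spearman))
  invisible(x)
}

#' Write a comparison as TSV (and optionally a dotplot)
#'
#' @param cmp an `affinity_comparison`.
#' @param path TSV path for the per-word dotplot data.
#' @param plot_path optional PNG path for the dotplot (skipped with a message
#'   if no graphics device is available).
#' @export
write_comparison <- function(cmp, path, plot_path = NULL) {
  df <- cmp$data[order(cmp$data$word), , drop = FALSE]
  con <- file(path, "wb")
  writeLines(sprintf("word\trel_%s\trel_%s\tlog_ratio", cmp$condition_a, cmp$condition_b), con)
  writeLines(sprintf("%s\t%.10g\t%.10g\t%.10g", df$word, df$rel_a, df$rel_b,
                     df$log_ratio), con)
  close(con)
  if (!is.null(plot_path)) {
    ok <- tryCatch({
      grDevices::png(plot_path, width = 900, height = 900, res = 150)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot(cmp$data$rel_a, cmp$data$rel_b, pch = 16, cex = 0.4,
           col = grDevices::rgb(0, 0, 0, 0.3),
           xlab = paste("relative affinity,", cmp$condition_a),
           ylab = paste("relative affinity,", cmp$condition_b),
           main = sprintf("r=%.3f rho=%.3f (n=%d)", cmp$pearson, cmp$spearman,
                          cmp$n_common))
      graphics::abline(0, 1, col = "red", lty = 2)
      TRUE
    }, error = function(e) {
      message("dotplot skipped: ", conditionMessage(e))
      FALSE
    })
  }
  invisible(path)
}
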