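# Read preparation: FASTQ parsing, CASAVA filter-flag screening, contaminant
# (phiX-style) screening by shared exact words, and flank-anchored extraction
# of the randomized variable region.

#' Read-preparation configuration
#'
#' @param left_flank,right_flank fixed flanking sequence; the variable region
#'   is the `variable_length` bases immediately following `left_flank`. Empty
#'   flanks mean the read starts with the variable region.
#' @param variable_length length L of the variable region.
#' @param max_flank_mismatches mismatch budget when locating `left_flank`.
#' @param drop_filter_flagged drop reads whose CASAVA header filter field is
#'   `"Y"` (did not pass the instrument quality filter).
#' @param contaminant_screen_word_length word length for the exact-word
#'   contaminant screen (default 25); a read sharing any exact word of this
#'   length with the contaminant (either strand) is dropped.
#' @return A `prep_config` object.
#' @export
prep_config <- function(left_flank = "", right_flank = "",
                        variable_length = 40L, max_flank_mismatches = 0L,
                        drop_filter_flagged = TRUE,
                        contaminant_screen_word_length = 25L) {
  if (variable_length < 1L) stop("variable_length must be positive")
  if (max_flank_mismatches < 0L) stop("max_flank_mismatches must be >= 0")
  if (contaminant_screen_word_length < 1L)
    stop("contaminant_screen_word_length must be positive")
  if (grepl("[^ACGT]", left_flank) || grepl("[^ACGT]", right_flank))
    stop("flanks must be ACGT strings")
  structure(
    list(left_flank = left_flank, right_flank = right_flank,
         variable_length = as.integer(variable_length),
         max_flank_mismatches = as.integer(max_flank_mismatches),
         drop_filter_flagged = isTRUE(drop_filter_flagged),
         contaminant_screen_word_length = as.integer(contaminant_screen_word_length)),
    class = "prep_config"
  )
}

#' Strict 4-line FASTQ reader
#'
#' Reads plain or gzipped FASTQ. Malformed records (truncated files, missing
#' `@`/`+` markers, length mismatch between sequence and quality) raise an
#' error naming the offending record index.
#'
#' @param path FASTQ(.gz) path.
#' @return data.frame with columns `header` (without the leading `@`),
#'   `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L)
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4 (record %d truncated)",
                 path, length(lines), length(lines) %/% 4L + 1L))
  n <- length(lines) %/% 4L
  if (n == 0L) stop("empty FASTQ file: ", path)
  h <- lines[seq(1L, by = 4L, length.out = n)]
  s <- lines[seq(2L, by = 4L, length.out = n)]
  p <- lines[seq(3L, by = 4L, length.out = n)]
  q <- lines[seq(4L, by = 4L, length.out = n)]
  bad <- which(!startsWith(h, "@"))
  if (length(bad)) stop(sprintf("malformed FASTQ record %d: header does not start with '@'", bad[1]))
  bad <- which(!startsWith(p, "+"))
  if (length(bad)) stop(sprintf("malformed FASTQ record %d: separator line does not start with '+'", bad[1]))
  bad <- which(nchar(s) != nchar(q))
  if (length(bad)) stop(sprintf("malformed FASTQ record %d: sequence/quality length mismatch", bad[1]))
  data.frame(header = substring(h, 2L), sequence = toupper(s), quality = q,
             stringsAsFactors = FALSE)
}

# CASAVA-1.8 header: "<id> <read>:<is_filtered>:<control>:<index>"; the
# is_filtered field is "Y" for reads that failed the instrument filter.
casava_filter_flag <- function(headers) {
  hits <- regexpr(" [0-9]+:[YN]:", headers)
  flag <- rep(NA_character_, length(headers))
  has <- hits > 0
  m <- regmatches(headers, hits)
  flag[has] <- substr(m, nchar(m) - 1L, nchar(m) - 1L)
  flag
}

# All distinct words of length w in `seqs` and their reverse complements.
contaminant_words <- function(seqs, w) {
  words <- character(0)
  for (s in c(seqs, revcomp(seqs))) {
    n <- nchar(s)
    if (n >= w) words <- c(words, substring(s, 1:(n - w + 1L), w:n))
  }
  unique(words[!grepl("[^ACGT]", words)])
}

# TRUE for reads sharing any exact length-w word with the contaminant set.
matches_contaminant <- function(seqs, words, w) {
  if (length(words) == 0L) return(rep(FALSE, length(seqs)))
  n <- nchar(seqs)
  hit <- rep(FALSE, length(seqs))
  idx <- which(n >= w)
  if (!length(idx)) return(hit)
  starts <- lapply(n[idx], function(len) 1:(len - w + 1L))
  nw <- lengths(starts)
  all_words <- substring(rep(seqs[idx], nw), unlist(starts), unlist(starts) + w - 1L)
  word_hit <- all_words %in% words
  hit[idx] <- vapply(split(word_hit, rep(seq_along(idx), nw)), any, logical(1))
  hit
}

#' Locate the left flank and extract the variable region
#'
#' Finds the first occurrence of `config$left_flank` in each read allowing up
#' to `config$max_flank_mismatches` mismatches (Biostrings pattern matching)
#' and returns the `variable_length` bases immediately following it. With an
#' empty left flank the first `variable_length` bases are returned.
#' Coordinates are 0-based half-open internally; reads too short to supply a
#' full variable region are rejected rather than padded.
#'
#' @param sequences character vector of read sequences.
#' @param config a `prep_config`.
#' @return list with `region` (character, `NA` where extraction failed) and
#'   `reason` (`NA`, `"flank_not_found"` or `"too_short"`).
#' @export
extract_variable_region <- function(sequences, config) {
  stopifnot(inherits(config, "prep_config"))
  L <- config$variable_length
  n <- length(sequences)
  region <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  if (nchar(config$left_flank) == 0L) {
    ok <- nchar(sequences) >= L
    region[ok] <- substr(sequences[ok], 1L, L)
    reason[!ok] <- "too_short"
    return(list(region = region, reason = reason))
  }
  fl <- nchar(config$left_flank)
  long_enough <- nchar(sequences) >= fl + L
  reason[!long_enough] <- "too_short"
  if (any(long_enough)) {
    subj <- Biostrings::DNAStringSet(sequences[long_enough])
    m <- Biostrings::vmatchPattern(config$left_flank, subj,
                                   max.mismatch = config$max_flank_mismatches,
                                   fixed = TRUE)
    starts <- Biostrings::startIndex(m)
    first <- vapply(starts, function(s) if (is.null(s) || !length(s)) NA_integer_ else s[1],
                    integer(1))
    sub_seqs <- sequences[long_enough]
    from <- first + fl                       # 1-based start of variable region
    ok <- !is.na(first) & (from + L - 1L) <= nchar(sub_seqs)
    r <- rep(NA_character_, length(sub_seqs))
    r[ok] <- substr(sub_seqs[ok], from[ok], from[ok] + L - 1L)
    rs <- rep(NA_character_, length(sub_seqs))
    rs[is.na(first)] <- "flank_not_found"
    rs[!is.na(first) & !ok] <- "too_short"
    region[long_enough] <- r
    reason[long_enough] <- rs
  }
  list(region = region, reason = reason)
}

#' Filter raw reads and extract clean variable regions
#'
#' Applies, in order: the CASAVA filter-flag screen, the exact-word
#' contaminant screen on the full read (both strands), flank-anchored
#' variable-region extraction, and an ambiguous-base screen on the variable
#' region. Each read is dropped for at most one (the first applicable)
#' reason, so kept + dropped reads always equals the input count.
#'
#' @param fastq a data.frame from [read_fastq()] or a FASTQ(.gz) path.
#' @param config a `prep_config`.
#' @param contaminant optional FASTA path or character vector of contaminant
#'   sequences (e.g. phiX174).
#' @param round_index,condition_label provenance recorded on the result.
#' @return list with `reads` (a `round_reads`, or `NULL` when nothing
#'   survives) and `report` (a `prep_report`: per-reason drop counts).
#' @export
filter_reads <- function(fastq, config, contaminant = NULL,
                         round_index = 0L, condition_label = "condition") {
  stopifnot(inherits(config, "prep_config"))
  if (is.character(fastq) && length(fastq) == 1L) fastq <- read_fastq(fastq)
  if (!all(c("header", "sequence") %in% names(fastq)))
    stop("fastq must have 'header' and 'sequence' columns")
  n <- nrow(fastq)
  reason <- rep(NA_character_, n)

  if (config$drop_filter_flagged) {
    flag <- casava_filter_flag(fastq$header)
    reason[!is.na(flag) & flag == "Y"] <- "casava_filter"
  }

  if (!is.null(contaminant)) {
    seqs <- contaminant
    if (length(seqs) == 1L && file.exists(seqs))
      seqs <- as.character(Biostrings::readDNAStringSet(seqs))
    words <- contaminant_words(toupper(seqs), config$contaminant_screen_word_length)
    todo <- is.na(reason)
    hit <- matches_contaminant(fastq$sequence[todo], words,
                               config$contaminant_screen_word_length)
    reason[todo][hit] <- "contaminant"
  }

  todo <- is.na(reason)
  ext <- extract_variable_region(fastq$sequence[todo], config)
  reason[todo] <- ext$reason               # NA where extraction succeeded
  region <- rep(NA_character_, n)
  region[todo] <- ext$region

  todo <- is.na(reason)
  amb <- todo & grepl("[^ACGT]", region)
  reason[amb] <- "ambiguous_base"

  kept <- is.na(reason)
  reasons_tab <- table(factor(reason[!kept],
                              levels = c("casava_filter", "contaminant",
                                         "flank_not_found", "too_short",
                                         "ambiguous_base")))
  report <- structure(
    list(total = n, kept = sum(kept),
         dropped = as.integer(reasons_tab),
         reasons = data.frame(reason = names(reasons_tab),
                              count = as.integer(reasons_tab),
                              stringsAsFactors = FALSE)),
    class = "prep_report"
  )
  reads <- if (any(kept)) {
    round_reads(region[kept], round_index, condition_label, "filtered")
  } else NULL
  list(reads = reads, report = report)
}

#' @export
print.prep_report <- function(x, ...) {
  cat(sprintf("Prep report: %d reads in, %d kept, %d dropped\n",
              x$total, x$kept, x$total - x$kept))
  keep <- x$reasons$count > 0
  if (any(keep)) print(x$reasons[keep, ], row.names = FALSE)
  invisible(x)
}

#' Write a prep report as TSV
#' @param report a `prep_report`.
#' @param path output path.
#' @param round_index,condition_label echoed into the table.
#' @export
write_prep_report <- function(report, path, round_index = NA_integer_,
                              condition_label = NA_character_) {
  df <- rbind(
    data.frame(condition = condition_label, round = round_index,
               reason = "kept", count = report$kept),
    data.frame(condition = condition_label, round = round_index,
               reason = report$reasons$reason, count = report$reasons$count)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
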