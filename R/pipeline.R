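# Pipeline orchestration: a run manifest maps each protein condition to its
# Round-0 and final-round FASTQ files; run_pipeline() executes prep ->
# counting -> background -> affinity -> (comparison) -> motif and writes all
# artifacts plus a machine-readable JSON report. All outputs are
# deterministic functions of the manifest (the analysis stages draw no random
# numbers), so reruns are byte-identical.

MANIFEST_DEFAULTS <- list(
  k = 10L, order = 6L, strand_mode = "collapsed", min_count = 2L,
  fraction = 0.001, exponent_mode = "ratio", flank = 5L,
  left_flank = "", right_flank = "", variable_length = 40L,
  max_flank_mismatches = 0L, drop_filter_flagged = TRUE,
  contaminant_screen_word_length = 25L, seed = 1L
)

#' Validate a run manifest
#'
#' Accepts a YAML/JSON path or a list. All invariants are checked and errors
#' aggregated (not first-fail): each condition needs a `label`, an existing
#' `round0` file, an existing `final` file and a `final_round_index >= 1`;
#' shared parameters must satisfy the stage preconditions. Missing parameters
#' take package defaults.
#'
#' @param manifest path to a YAML or JSON manifest, or an equivalent list
#'   with elements `conditions` (list of condition entries), optional
#'   parameter overrides, and `output_dir`.
#' @return A `run_manifest` when valid; otherwise an object of class
#'   `manifest_errors` whose `errors` element names every violation.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (!file.exists(manifest)) stop("manifest file not found: ", manifest)
    manifest <- if (grepl("\\.json$", manifest, ignore.case = TRUE)) {
      jsonlite::read_json(manifest, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(manifest)
    }
  }
  errors <- character(0)
  err <- function(...) errors <<- c(errors, sprintf(...))
  if (!is.list(manifest)) {
    return(structure(list(errors = "manifest is not a list"), class = "manifest_errors"))
  }
  conds <- manifest$conditions
  if (is.null(conds) || !length(conds)) {
    err("conditions: at least one condition is required")
    conds <- list()
  }
  for (i in seq_along(conds)) {
    cc <- conds[[i]]
    label <- cc[["label"]] %||% sprintf("condition %d", i)
    if (is.null(cc[["label"]])) err("conditions[%d]: missing label", i)
    if (is.null(cc[["round0"]])) {
      err("conditions[%d] (%s): missing round0 file entry", i, label)
    } else if (!file.exists(cc[["round0"]])) {
      err("conditions[%d] (%s): round0 file not found: %s", i, label, cc[["round0"]])
    }
    if (is.null(cc[["final"]])) {
      err("conditions[%d] (%s): missing final-round file entry", i, label)
    } else if (!file.exists(cc[["final"]])) {
      err("conditions[%d] (%s): final file not found: %s", i, label, cc[["final"]])
    }
    if (is.null(cc[["final_round_index"]])) {
      err("conditions[%d] (%s): missing final_round_index", i, label)
    } else if (cc[["final_round_index"]] < 1) {
      err("conditions[%d] (%s): final_round_index must be >= 1", i, label)
    }
    if (!is.null(cc[["truth"]]) && !file.exists(cc[["truth"]]))
      err("conditions[%d] (%s): truth file not found: %s", i, label, cc[["truth"]])
  }
  params <- MANIFEST_DEFAULTS
  for (nm in names(MANIFEST_DEFAULTS))
    if (!is.null(manifest[[nm]])) params[[nm]] <- manifest[[nm]]
  if (params$k < 1) err("k must be >= 1")
  if (params$order < 1) err("order must be >= 1")
  if (params$k < params$order) err("k must be >= order")
  if (!params$strand_mode %in% c("collapsed", "single"))
    err("strand_mode must be 'collapsed' or 'single'")
  if (params$min_count < 0) err("min_count must be >= 0")
  if (params$fraction <= 0 || params$fraction > 1)
    err("fraction must be in (0, 1]")
  if (!params$exponent_mode %in% c("ratio", "per_round_root"))
    err("exponent_mode must be 'ratio' or 'per_round_root'")
  if (params$flank < 0) err("flank must be >= 0")
  if (is.null(manifest$output_dir)) err("output_dir is required")
  if (length(errors)) {
    return(structure(list(errors = errors), class = "manifest_errors"))
  }
  structure(c(list(conditions = conds, output_dir = manifest$output_dir,
                   contaminant = manifest$contaminant), params),
            class = "run_manifest")
}

#' @export
print.manifest_errors <- function(x, ...) {
  cat("Invalid manifest:\n")
  for (e in x$errors) cat("  -", e, "\n")
  invisible(x)
}

#' Write a manifest back to YAML
#'
#' @param manifest a `run_manifest` (or plain list).
#' @param path output YAML path.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

run_stage <- function(stage, expr, log) {
  log(sprintf("stage %s: start", stage))
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full SELEX-seq analysis pipeline
#'
#' For every condition in the manifest: read and filter both FASTQ files,
#' report perfect-CArG-box prevalence per round, fit the Markov background on
#' Round 0, count final-round k-mers, compute relative affinities, select the
#' top k-mers, recover representative sequences and build the anchored PFM
#' (exported as MEME-minimal and JASPAR). With two or more conditions, all
#' consecutive pairs are compared. When a condition carries a `truth` entry
#' (the landscape JSON written by [run_selex()]), the report includes the
#' Spearman recovery correlation against the generative landscape over words
#' with count >= 10.
#'
#' A stage failure aborts with the stage name and cause; partial outputs stay
#' on disk next to a `FAILED` marker.
#'
#' @param manifest a `run_manifest` from [validate_manifest()], or a path /
#'   list accepted by it.
#' @param quiet suppress progress messages.
#' @return Invisibly, the run report (also written as `report.json`).
#' @export
run_pipeline <- function(manifest, quiet = FALSE) {
  if (!inherits(manifest, "run_manifest")) manifest <- validate_manifest(manifest)
  if (inherits(manifest, "manifest_errors")) {
    stop("invalid manifest:\n", paste(" -", manifest$errors, collapse = "\n"))
  }
  log <- if (quiet) function(...) invisible() else function(msg) message("[selexr] ", msg)
  out <- manifest$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  on.exit({
    if (!isTRUE(get0("finished", ifnotfound = FALSE)))
      writeLines("pipeline did not finish; artifacts may be partial", failed_marker)
  })

  pcfg <- prep_config(left_flank = manifest$left_flank,
                      right_flank = manifest$right_flank,
                      variable_length = manifest$variable_length,
                      max_flank_mismatches = manifest$max_flank_mismatches,
                      drop_filter_flagged = manifest$drop_filter_flagged,
                      contaminant_screen_word_length = manifest$contaminant_screen_word_length)

  report <- list(
    parameters = manifest[names(MANIFEST_DEFAULTS)],
    conditions = list(), comparisons = list()
  )
  tables <- list()

  for (cc in manifest$conditions) {
    label <- cc[["label"]]
    cres <- list(label = label, final_round_index = cc[["final_round_index"]])

    prep0 <- run_stage(paste0(label, "/prep-round0"), {
      filter_reads(cc[["round0"]], pcfg, contaminant = manifest$contaminant,
                   round_index = 0L, condition_label = label)
    }, log)
    prepF <- run_stage(paste0(label, "/prep-final"), {
      filter_reads(cc[["final"]], pcfg, contaminant = manifest$contaminant,
                   round_index = cc[["final_round_index"]], condition_label = label)
    }, log)
    if (is.null(prep0$reads) || is.null(prepF$reads))
      stop(sprintf("pipeline stage '%s/prep' failed: no reads survive filtering", label))
    write_prep_report(prep0$report, file.path(out, sprintf("%s_prep_round0.tsv", label)),
                      0L, label)
    write_prep_report(prepF$report, file.path(out, sprintf("%s_prep_final.tsv", label)),
                      cc[["final_round_index"]], label)
    cres$reads_round0 <- prep0$report$kept
    cres$reads_final <- prepF$report$kept
    cres$dropped_round0 <- prep0$report$total - prep0$report$kept
    cres$dropped_final <- prepF$report$total - prepF$report$kept

    carg0 <- run_stage(paste0(label, "/carg"), carg_prevalence(prep0$reads), log)
    cargF <- carg_prevalence(prepF$reads)
    cres$carg_percent_round0 <- 100 * carg0$prevalence
    cres$carg_percent_final <- 100 * cargF$prevalence
    log(sprintf("%s: perfect CArG %% round0=%.3f final=%.2f", label,
                cres$carg_percent_round0, cres$carg_percent_final))

    model <- run_stage(paste0(label, "/background"), {
      fit_markov(prep0$reads, m = manifest$order, alpha = 1,
                 strand_mode = manifest$strand_mode)
    }, log)
    write_markov_model(model, file.path(out, sprintf("%s_markov.tsv", label)))

    tblF <- run_stage(paste0(label, "/count"), {
      count_kmers(prepF$reads, k = manifest$k, strand_mode = manifest$strand_mode)
    }, log)

    at <- run_stage(paste0(label, "/affinity"), {
      relative_affinity(tblF, model, min_count = manifest$min_count,
                        exponent_mode = manifest$exponent_mode,
                        final_round_index = cc[["final_round_index"]])
    }, log)
    write_affinity_table(at, file.path(out, sprintf("%s_affinity.tsv", label)))
    cres$n_observed_words <- at$n_observed
    cres$normalization_word <- at$normalization_word
    tables[[label]] <- at

    top <- run_stage(paste0(label, "/motif"), {
      top_kmers(at, fraction = manifest$fraction, universe = "observed")
    }, log)
    reps <- representative_sequences(top$words, prepF$reads,
                                     collapse = manifest$strand_mode == "collapsed")
    write_representatives_fasta(top, reps,
                                file.path(out, sprintf("%s_top_representatives.fasta", label)))
    pfm <- build_anchored_pfm(top, at, reps, flank = manifest$flank)
    export_motif(pfm, file.path(out, sprintf("%s_motif.meme", label)),
                 format = "meme", name = label)
    export_motif(pfm, file.path(out, sprintf("%s_motif.jaspar", label)),
                 format = "jaspar", name = label)
    cres$n_top_kmers <- top$n_top
    cres$n_top_with_representative <- sum(reps$found)

    if (!is.null(cc[["truth"]])) {
      cres$recovery_spearman <- run_stage(paste0(label, "/recovery"), {
        truth <- jsonlite::read_json(cc[["truth"]], simplifyVector = TRUE)
        land <- make_landscape(truth$landscape$consensus,
                               truth$landscape$mismatch_factor,
                               k = truth$landscape$k)
        recovery_spearman(at, land, min_count = 10L)
      }, log)
      log(sprintf("%s: recovery Spearman rho = %.3f", label, cres$recovery_spearman))
    }
    report$conditions[[label]] <- cres
  }

  labels <- names(tables)
  if (length(labels) >= 2L) {
    for (i in seq_len(length(labels) - 1L)) {
      a <- labels[i]; b <- labels[i + 1L]
      cmp <- run_stage(sprintf("compare %s vs %s", a, b),
                       compare_affinities(tables[[a]], tables[[b]]), log)
      write_comparison(cmp, file.path(out, sprintf("compare_%s_vs_%s.tsv", a, b)),
                       plot_path = file.path(out, sprintf("compare_%s_vs_%s.png", a, b)))
      report$comparisons[[sprintf("%s_vs_%s", a, b)]] <-
        list(condition_a = a, condition_b = b, pearson = cmp$pearson,
             spearman = cmp$spearman, n_common = cmp$n_common)
    }
  } else {
    report$comparisons_note <- "single condition: comparison stage skipped"
    log("single condition: comparison stage skipped")
  }

  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  finished <- TRUE
  log("pipeline finished")
  invisible(report)
}

#' Spearman correlation between estimated and generative affinities
#'
#' The parameter-recovery statistic: rank correlation between a table's
#' relative affinities and a known landscape's affinities over words whose
#' final-round count reaches `min_count`. In collapsed mode the landscape is
#' evaluated at the canonical word (for a strand-symmetric landscape the two
#' strands agree anyway).
#'
#' @param table an `affinity_table`.
#' @param landscape the generative `affinity_landscape`.
#' @param min_count count threshold for inclusion (default 10).
#' @return Spearman's rho.
#' @export
recovery_spearman <- function(table, landscape, min_count = 10L) {
  stopifnot(inherits(table, "affinity_table"),
            inherits(landscape, "affinity_landscape"))
  if (table$k != landscape$k) stop("table and landscape have different k")
  idx <- which(table$counts >= min_count & table$observed)
  if (length(idx) < 3L) stop("too few words pass min_count for a correlation")
  truth <- landscape$affinity[idx]
  if (table$strand_mode == "collapsed" && !landscape$strand_symmetric) {
    rc <- rc_index_map(table$k)
    truth <- pmax(truth, landscape$affinity[rc[idx - 1 + 1] + 1])
  }
  stats::cor(table$rel_affinity[idx], truth, method = "spearman")
}
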