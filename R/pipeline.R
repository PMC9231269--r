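# End-to-end orchestration: trait filtering -> instrument selection ->
# univariable screen -> multivariable model -> sensitivity estimators.

#' Build a pipeline configuration
#'
#' Inputs may be given as in-memory objects ([gwas_table()], [trait_info()],
#' [ld_matrix()], matrices) or as file paths understood by the readers in
#' this package; objects take precedence.
#'
#' @param metadata [trait_info()] or path to a metadata TSV.
#' @param exposures Named list of [gwas_table()] (or paths), the
#'   effect-extraction source for each trait.
#' @param outcome [gwas_table()] or path.
#' @param ld [ld_matrix()] or path to a square TSV.
#' @param rho Optional phenotypic correlation matrix over exposures (or
#'   path); identity with a warning if absent when MVMR runs.
#' @param selection_exposures Optional named list of [gwas_table()] (or
#'   paths) in which instruments are selected; defaults to `exposures`
#'   (single-source design). Traits absent from this list fall back to their
#'   `exposures` table.
#' @param p_instrument Genome-wide significance threshold (default 5e-8).
#' @param r2_clump LD clumping threshold (default 0.01).
#' @param maf_palindrome Palindrome ambiguity limit (default 0.42).
#' @param p_screen Univariable screening threshold for MVMR candidacy
#'   (default 0.05).
#' @param rg2_prune Squared genetic-correlation pruning limit (default
#'   0.985).
#' @param seed Seed for the bootstrap standard errors (default 1).
#' @param boot_reps Bootstrap replicates for median/mode (default 1000).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(metadata, exposures, outcome, ld, rho = NULL,
                            selection_exposures = NULL,
                            p_instrument = 5e-8, r2_clump = 0.01,
                            maf_palindrome = 0.42, p_screen = 0.05,
                            rg2_prune = 0.985, seed = 1L, boot_reps = 1000L) {
  stopifnot(p_instrument > 0, p_instrument < 1,
            r2_clump > 0, r2_clump <= 1,
            maf_palindrome > 0, maf_palindrome <= 0.5,
            p_screen > 0, p_screen < 1,
            rg2_prune > 0, rg2_prune <= 1)
  structure(list(metadata = metadata, exposures = exposures,
                 outcome = outcome, ld = ld, rho = rho,
                 selection_exposures = selection_exposures,
                 p_instrument = p_instrument, r2_clump = r2_clump,
                 maf_palindrome = maf_palindrome, p_screen = p_screen,
                 rg2_prune = rg2_prune, seed = seed, boot_reps = boot_reps),
            class = "pipeline_config")
}

resolve_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Screen univariable results for multivariable candidates
#'
#' @param results List of [mr_result()] objects (one per trait).
#' @param p_screen Inclusion threshold (default 0.05).
#' @return Character vector of exposure ids with p below the threshold, in
#'   input order.
#' @export
screen_uvmr <- function(results, p_screen = 0.05) {
  keep <- vapply(results, function(r) {
    !is.na(r$pvalue) && r$pvalue < p_screen
  }, logical(1))
  unname(vapply(results[keep], function(r) r$exposure_id, character(1)))
}

#' Run the full prioritisation pipeline
#'
#' Stages, in order: metadata filters (ratio/composite exclusion, lipoprotein
#' subclass selection); per-trait instrument selection (clump + harmonise,
#' two-source capable); genetic-correlation estimation over the instrument
#' union and near-duplicate pruning; univariable MR per trait with mean F and
#' leave-one-out diagnostics; screening at `p_screen`; multivariable MR on
#' the candidates (assembly, joint IVW, conditional F per exposure,
#' heterogeneity Q); pleiotropy-robust estimators on candidates with at least
#' three instruments. Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report` list with elements `filter` (stage reports +
#'   combined kept/excluded), `instruments` (named list of
#'   [harmonised_set()]), `uvmr` (tidy results table), `loo` (leave-one-out
#'   table), `candidates`, `mvmr` (an `mvmr_result` or `NULL` with a note),
#'   `sensitivity` (tidy table), `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notes <- character()

  metadata <- resolve_input(config$metadata, read_trait_metadata)
  outcome <- resolve_input(config$outcome, read_summary_table)
  ld <- resolve_input(config$ld, read_ld_matrix)
  exposures <- lapply(config$exposures, resolve_input, read_summary_table)
  names(exposures) <- vapply(exposures, trait_id, character(1))
  sel_tables <- config$selection_exposures
  if (!is.null(sel_tables)) {
    sel_tables <- lapply(sel_tables, resolve_input, read_summary_table)
    names(sel_tables) <- vapply(sel_tables, trait_id, character(1))
  }
  rho <- config$rho
  if (is.character(rho)) {
    rho <- as.matrix(utils::read.delim(rho, row.names = 1L,
                                       check.names = FALSE))
  }

  # Stage 1-2: metadata filters
  stage1 <- filter_ratios_composites(metadata)
  meta2 <- metadata[metadata$trait_id %in% stage1$kept, , drop = FALSE]
  stage2 <- select_lipoprotein_subset(meta2)
  panel <- stage2$kept

  missing_tables <- setdiff(panel, names(exposures))
  if (length(missing_tables) > 0L) {
    stop("no exposure table for retained trait(s): ",
         paste(missing_tables, collapse = ", "))
  }

  # Stage 3: instrument selection per trait (two-source capable)
  instruments <- lapply(panel, function(id) {
    sel <- if (!is.null(sel_tables) && id %in% names(sel_tables)) {
      sel_tables[[id]]
    } else NULL
    select_instruments(exposures[[id]], outcome, ld,
                       p_threshold = config$p_instrument,
                       r2_threshold = config$r2_clump,
                       maf_palindrome_limit = config$maf_palindrome,
                       selection_table = sel)
  })
  names(instruments) <- panel

  # Stage 4: genetic-correlation pruning over the instrument union
  union_snps <- unique(unlist(lapply(instruments,
                                     function(s) s$records$snp)))
  if (length(union_snps) > 0L && length(panel) >= 2L) {
    rg <- genetic_correlation_matrix(exposures[panel], union_snps)
    stage3 <- prune_genetic_correlation(rg, r2_limit = config$rg2_prune,
                                        priority = panel)
  } else {
    rg <- NULL
    stage3 <- filter_report(panel, empty_exclusions(), panel)
    notes <- c(notes, "genetic-correlation pruning skipped (no instruments or < 2 traits)")
  }
  analysed <- stage3$kept
  instruments <- instruments[analysed]

  # Stage 5: univariable MR + diagnostics
  uvmr_results <- lapply(instruments, run_uvmr)
  loo_rows <- lapply(analysed, function(id) {
    set <- instruments[[id]]
    if (nrow(set$records) < 3L) return(NULL)
    cbind(exposure = id, leave_one_out(set), stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, loo_rows[!vapply(loo_rows, is.null, logical(1))])

  # Stage 6: screen
  candidates <- screen_uvmr(uvmr_results, config$p_screen)

  # Stage 7: MVMR on candidates
  mvmr_res <- NULL
  if (length(candidates) == 0L) {
    notes <- c(notes, "no traits passed the univariable screen; MVMR skipped")
  } else if (length(candidates) == 1L) {
    notes <- c(notes,
               "single candidate trait; MVMR reduces to the univariable model and was skipped")
  } else {
    rho_cand <- if (!is.null(rho)) {
      rho[candidates, candidates, drop = FALSE]
    } else NULL
    mv_data <- tryCatch(
      assemble_mvmr(instruments[candidates], exposures[candidates], outcome,
                    ld, rho = rho_cand, r2_threshold = config$r2_clump,
                    maf_palindrome_limit = config$maf_palindrome),
      error = function(e) {
        notes <<- c(notes, paste("MVMR assembly failed:",
                                 conditionMessage(e)))
        NULL
      })
    if (!is.null(mv_data)) {
      mvmr_res <- run_mvmr(mv_data)
    }
  }

  # Stage 8: sensitivity estimators on candidates with K >= 3
  sens_rows <- list()
  for (id in candidates) {
    set <- instruments[[id]]
    if (nrow(set$records) < 3L) {
      notes <- c(notes, paste0("sensitivity estimators skipped for ", id,
                               " (fewer than 3 instruments)"))
      next
    }
    suite <- run_sensitivity(set, boot_reps = config$boot_reps,
                             seed = config$seed)
    tab <- mr_results_table(list(suite$mr_egger$slope,
                                 suite$weighted_median,
                                 suite$weighted_mode))
    tab$egger_intercept <- c(suite$mr_egger$intercept$estimate, NA, NA)
    tab$egger_intercept_p <- c(suite$mr_egger$intercept$pvalue, NA, NA)
    sens_rows[[id]] <- tab
  }
  sensitivity <- if (length(sens_rows) > 0L) do.call(rbind, sens_rows) else NULL
  if (!is.null(sensitivity)) rownames(sensitivity) <- NULL

  excluded <- rbind(stage1$excluded, stage2$excluded, stage3$excluded)
  report <- structure(list(
    filter = list(stage1 = stage1, stage2 = stage2, stage3 = stage3,
                  kept = analysed, excluded = excluded,
                  genetic_correlation = rg),
    instruments = instruments,
    uvmr = mr_results_table(uvmr_results),
    loo = loo,
    candidates = candidates,
    mvmr = mvmr_res,
    sensitivity = sensitivity,
    notes = notes,
    provenance = list(
      seed = config$seed, boot_reps = config$boot_reps,
      thresholds = list(p_instrument = config$p_instrument,
                        r2_clump = config$r2_clump,
                        maf_palindrome = config$maf_palindrome,
                        p_screen = config$p_screen,
                        rg2_prune = config$rg2_prune),
      n_traits_in = nrow(metadata),
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("metabomr")))),
    class = "pipeline_report")
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "Pipeline report: %d traits in, %d analysed, %d candidate(s): %s\n",
    x$provenance$n_traits_in, length(x$filter$kept),
    length(x$candidates), paste(x$candidates, collapse = ", ")))
  if (!is.null(x$mvmr)) print(x$mvmr)
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

#' Write all pipeline report tables to a directory
#'
#' Emits `filter_report.tsv`, `uvmr_results.tsv`, `loo_results.tsv`,
#' `candidates.tsv`, `mvmr_results.tsv`, `sensitivity_results.tsv` and
#' `provenance.json`.
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  filt <- rbind(
    data.frame(trait_id = report$filter$kept, stage = "kept", reason = "",
               stringsAsFactors = FALSE),
    report$filter$excluded)
  w(filt, "filter_report.tsv")
  w(report$uvmr, "uvmr_results.tsv")
  if (!is.null(report$loo)) w(report$loo, "loo_results.tsv")
  w(data.frame(trait_id = report$candidates), "candidates.tsv")
  if (!is.null(report$mvmr)) {
    mv <- report$mvmr$estimates
    mv$q_stat <- report$mvmr$q_stat
    mv$q_df <- report$mvmr$q_df
    mv$q_p <- report$mvmr$q_p
    w(mv, "mvmr_results.tsv")
  }
  if (!is.null(report$sensitivity)) {
    w(report$sensitivity, "sensitivity_results.tsv")
  }
  jsonlite::write_json(report$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
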