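# End-to-end orchestration over two cohorts: per-cohort preprocessing, DE
# screen, clock risk score, lincRNA correlation screen; cross-cohort
# overlap; then the pathway stage (gene-set variation scores, pathway DE,
# pathway correlation screen, pathway overlap) and a PCA of the common
# lincRNAs. Both cohorts are processed fully independently (own filters,
# TMM factors, panels, reflection constants) before any overlap.

default_thresholds <- function() {
  list(de_p = 0.05, de_fdr = 0.25, cor_p = 0.05, cor_fdr = 0.10)
}

stage_log <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run one cohort through the transcript-level stages
#'
#' De-duplication, CPM filter, TMM factors, log(CPM+1) matrix, precision
#' weights, moderated t-test, DE selection, partition of the DE set into
#' clock genes and lincRNAs, clock-gene risk score, and the Pearson screen
#' of DE lincRNAs against that score. If no clock gene is differentially
#' expressed the cohort result carries status `"empty_clock_panel"` instead
#' of raising an error.
#'
#' @param x A [cohort_counts()] object.
#' @param clock_genes Clock gene symbols defining the clock panel universe.
#' @param linc_ids Optional explicit lincRNA identifier list; if `NULL`,
#'   lincRNAs are recognized by `linc_pattern`.
#' @param linc_pattern Regular expression identifying lincRNA symbols.
#' @param thresholds List with `de_p`, `de_fdr`, `cor_p`, `cor_fdr`.
#' @param reflection Reflection-constant mode for [build_panel()].
#' @param verbose Log stage dimensions via [message()]?
#' @return A list of class `cohort_result` with all intermediate artifacts
#'   (`filtered`, `factors`, `logcpm`, `de_table`, `de`, `clock_panel`,
#'   `clock_score`, `linc_corr`, `sig_lincs`, `status`, ...).
#' @export
run_cohort <- function(x, clock_genes = clock_gene_symbols(),
                       linc_ids = NULL, linc_pattern = "^LINC",
                       thresholds = default_thresholds(),
                       reflection = "ceil_max", verbose = FALSE) {
  stopifnot(inherits(x, "cohort_counts"))
  th <- utils::modifyList(default_thresholds(), thresholds)

  deduped <- dedupe_transcripts(x)
  stage_log(verbose, "dedupe", "%d -> %d transcripts", nrow(x$counts),
            nrow(deduped$counts))
  filtered <- filter_low_expression(deduped)
  stage_log(verbose, "filter", "%d transcripts kept of %d",
            nrow(filtered$counts), nrow(deduped$counts))
  factors <- tmm_factors(filtered)
  logcpm <- log_cpm(filtered, factors)
  vm <- voom_weights(filtered, factors)
  de_table <- moderated_t_test(vm$expr_values, weights = vm$weights,
                               group = as.character(filtered$group),
                               display = logcpm)
  de <- select_de(de_table, p_cut = th$de_p, fdr_cut = th$de_fdr)
  stage_log(verbose, "de", "%d DE transcripts (%d down, %d up)",
            nrow(de), attr(de, "n_direction")["down"],
            attr(de, "n_direction")["up"])

  is_linc <- if (is.null(linc_ids)) grepl(linc_pattern, de$id) else
    de$id %in% linc_ids
  de_clock <- de[de$id %in% clock_genes, , drop = FALSE]
  de_lincs <- de[is_linc, , drop = FALSE]
  stage_log(verbose, "partition", "%d DE clock genes, %d DE lincRNAs",
            nrow(de_clock), nrow(de_lincs))

  res <- list(filtered = filtered, factors = factors, logcpm = logcpm,
              de_table = de_table, de = de, de_clock = de_clock,
              de_lincs = de_lincs, clock_panel = NULL, clock_score = NULL,
              linc_corr = NULL,
              sig_lincs = data.frame(id = character(0), sign = numeric(0)),
              thresholds = th, reflection = reflection, status = "ok")
  class(res) <- "cohort_result"

  if (nrow(de_clock) == 0) {
    res$status <- "empty_clock_panel"
    stage_log(verbose, "clock_score", "no DE clock gene; halting after DE stage")
    return(res)
  }
  res$clock_panel <- build_panel(de_clock, logcpm, reflection = reflection)
  res$clock_score <- compute_risk_score(logcpm, res$clock_panel)
  if (nrow(de_lincs) > 0) {
    res$linc_corr <- pearson_screen(res$clock_score,
                                    logcpm$values[de_lincs$id, , drop = FALSE],
                                    p_cut = th$cor_p, fdr_cut = th$cor_fdr)
    res$sig_lincs <- significant_features(res$linc_corr)
  }
  stage_log(verbose, "linc_screen", "%d score-correlated lincRNAs",
            nrow(res$sig_lincs))
  res
}

#' Run the full two-cohort discovery pipeline
#'
#' Each cohort runs independently through [run_cohort()]; significant
#' score-correlated lincRNAs are then overlapped across cohorts with sign
#' concordance to give the common circadian lincRNAs. If gene sets are
#' supplied the pathway stage follows: a per-cohort lincRNA-based risk score
#' over the common lincRNAs, gene-set variation scores, pathway DE and
#' correlation screens, and the cross-cohort pathway overlap. Finally a PCA
#' of the common lincRNAs is run per cohort.
#'
#' @param cohort1,cohort2 [cohort_counts()] objects (or `synthetic_cohort`s).
#' @param gene_sets Optional [gene_set_collection()]; `NULL` skips the
#'   pathway stage.
#' @param clock_genes,linc_ids,linc_pattern,thresholds,reflection,verbose
#'   Passed to [run_cohort()].
#' @return A list of class `study_report`; see [report_summary()] for the
#'   condensed counts.
#' @export
run_study <- function(cohort1, cohort2, gene_sets = NULL,
                      clock_genes = clock_gene_symbols(),
                      linc_ids = NULL, linc_pattern = "^LINC",
                      thresholds = default_thresholds(),
                      reflection = "ceil_max", verbose = FALSE) {
  if (inherits(cohort1, "synthetic_cohort")) cohort1 <- cohort1$counts
  if (inherits(cohort2, "synthetic_cohort")) cohort2 <- cohort2$counts
  th <- utils::modifyList(default_thresholds(), thresholds)

  r1 <- run_cohort(cohort1, clock_genes, linc_ids, linc_pattern, th,
                   reflection, verbose)
  r2 <- run_cohort(cohort2, clock_genes, linc_ids, linc_pattern, th,
                   reflection, verbose)
  overlap <- overlap_cohorts(r1$sig_lincs, r2$sig_lincs)
  common <- overlap$common_features
  stage_log(verbose, "overlap", "%d common circadian lincRNAs", length(common))

  report <- list(cohort1 = r1, cohort2 = r2, linc_overlap = overlap,
                 common_lincRNAs = common, linc_scores = NULL,
                 pathways = NULL, pca = NULL, thresholds = th,
                 status = if (r1$status != "ok") r1$status else r2$status)
  class(report) <- "study_report"
  if (length(common) == 0) return(report)

  # per-cohort lincRNA-based risk score over the common panel; the common
  # lincRNAs are down-regulated with negative score correlation, so each
  # cohort's own DE effect fixes the panel direction
  linc_score <- function(r) {
    panel <- build_panel(r$de_table[match(common, r$de_table$id), , drop = FALSE],
                         r$logcpm, reflection = reflection)
    compute_risk_score(r$logcpm, panel)
  }
  report$linc_scores <- list(cohort1 = linc_score(r1), cohort2 = linc_score(r2))

  report$pca <- list(cohort1 = if (length(common) >= 2) pca_features(r1$logcpm, common),
                     cohort2 = if (length(common) >= 2) pca_features(r2$logcpm, common))

  if (!is.null(gene_sets)) {
    ps1 <- gsva_matrix(r1$logcpm, gene_sets)
    ps2 <- gsva_matrix(r2$logcpm, gene_sets)
    stage_log(verbose, "gsva", "%d x %d and %d x %d pathway scores",
              nrow(ps1$values), ncol(ps1$values),
              nrow(ps2$values), ncol(ps2$values))
    report$pathways <- pathway_de_and_correlation(
      ps1, ps2, report$linc_scores$cohort1, report$linc_scores$cohort2,
      de_p = th$de_p, de_fdr = th$de_fdr,
      cor_p = th$cor_p, cor_fdr = th$cor_fdr)
    stage_log(verbose, "pathway_overlap", "%d common pathways",
              length(report$pathways$overlap$common_features))
  }
  report
}

#' Condensed counts from a study report
#'
#' @param report A `study_report` from [run_study()].
#' @return A list of stage-level counts: DE transcripts (down/up) per
#'   cohort, DE clock genes, DE lincRNAs, score-correlated lincRNAs, common
#'   circadian lincRNAs, and (if run) common pathways down/up.
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "study_report"))
  per_cohort <- function(r) {
    list(n_de = nrow(r$de), n_de_down = unname(attr(r$de, "n_direction")["down"]),
         n_de_up = unname(attr(r$de, "n_direction")["up"]),
         de_clock = r$de_clock$id, n_de_lincs = nrow(r$de_lincs),
         n_sig_lincs = nrow(r$sig_lincs), status = r$status)
  }
  out <- list(cohort1 = per_cohort(report$cohort1),
              cohort2 = per_cohort(report$cohort2),
              common_lincRNAs = report$common_lincRNAs,
              status = report$status)
  if (!is.null(report$pathways)) {
    out$common_pathways <- report$pathways$overlap$common_features
    out$n_common_pathways <- unname(report$pathways$n_common)
    names(out$n_common_pathways) <- c("down", "up")
  }
  out
}

#' @export
print.study_report <- function(x, ...) {
  s <- report_summary(x)
  cat("Two-cohort circadian lincRNA study\n")
  cat(sprintf("  cohort 1: %d DE (%d down/%d up), clock panel {%s}, %d sig lincRNAs\n",
              s$cohort1$n_de, s$cohort1$n_de_down, s$cohort1$n_de_up,
              paste(s$cohort1$de_clock, collapse = ", "), s$cohort1$n_sig_lincs))
  cat(sprintf("  cohort 2: %d DE (%d down/%d up), clock panel {%s}, %d sig lincRNAs\n",
              s$cohort2$n_de, s$cohort2$n_de_down, s$cohort2$n_de_up,
              paste(s$cohort2$de_clock, collapse = ", "), s$cohort2$n_sig_lincs))
  cat(sprintf("  common circadian lincRNAs: %s\n",
              if (length(s$common_lincRNAs)) paste(s$common_lincRNAs, collapse = ", ")
              else "(none)"))
  if (!is.null(s$common_pathways))
    cat(sprintf("  common pathways: %d (%d down, %d up)\n",
                length(s$common_pathways), s$n_common_pathways["down"],
                s$n_common_pathways["up"]))
  if (s$status != "ok") cat(sprintf("  status: %s\n", s$status))
  invisible(x)
}

#' Run the pipeline from a declarative JSON configuration
#'
#' The configuration lists the input files of both cohorts, an optional GMT
#' path, optional clock/lincRNA identifier files, thresholds, and the
#' reflection mode:
#' ```json
#' {
#'   "cohort1": {"counts": "c1.tsv", "metadata": "m1.tsv"},
#'   "cohort2": {"counts": "c2.tsv", "metadata": "m2.tsv"},
#'   "gmt": "sets.gmt",
#'   "thresholds": {"de_p": 0.05, "de_fdr": 0.25, "cor_p": 0.05, "cor_fdr": 0.10},
#'   "reflection": "ceil_max"
#' }
#' ```
#'
#' @param config Path to a JSON configuration file, or an equivalent list.
#' @param out_dir Optional output directory; when given, per-cohort DE and
#'   correlation tables, risk scores, PCA scores, pathway tables, and a JSON
#'   + Markdown report are written there.
#' @param verbose Log stage dimensions?
#' @return The `study_report`, invisibly if `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (ch in c("cohort1", "cohort2"))
    if (is.null(config[[ch]]$counts) || is.null(config[[ch]]$metadata))
      cl_stop(sprintf("config needs %s$counts and %s$metadata", ch, ch),
              "circlinc_validation_error")
  th <- utils::modifyList(default_thresholds(),
                          as.list(config$thresholds %||% list()))
  if (any(unlist(th) <= 0 | unlist(th) >= 1))
    cl_stop("thresholds must lie in (0, 1)", "circlinc_validation_error")

  c1 <- read_counts_tsv(config$cohort1$counts, config$cohort1$metadata)
  c2 <- read_counts_tsv(config$cohort2$counts, config$cohort2$metadata)
  gs <- if (!is.null(config$gmt)) read_gmt(config$gmt)
  clock <- if (!is.null(config$clock_genes)) readLines(config$clock_genes) else
    clock_gene_symbols()
  linc_ids <- if (!is.null(config$linc_ids)) readLines(config$linc_ids)

  report <- run_study(c1, c2, gene_sets = gs, clock_genes = clock,
                      linc_ids = linc_ids,
                      linc_pattern = config$linc_pattern %||% "^LINC",
                      thresholds = th,
                      reflection = config$reflection %||% "ceil_max",
                      verbose = verbose)
  if (is.null(out_dir)) return(report)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in 1:2) {
    r <- report[[paste0("cohort", i)]]
    write_table_tsv(r$de_table, file.path(out_dir, sprintf("cohort%d_de.tsv", i)))
    if (!is.null(r$linc_corr))
      write_table_tsv(r$linc_corr,
                      file.path(out_dir, sprintf("cohort%d_linc_corr.tsv", i)))
    if (!is.null(r$clock_score))
      write_table_tsv(data.frame(sample_id = names(r$clock_score$score),
                                 score = r$clock_score$score),
                      file.path(out_dir, sprintf("cohort%d_clock_score.tsv", i)))
  }
  if (!is.null(report$pathways)) {
    for (i in 1:2) {
      co <- report$pathways[[c("cohort_a", "cohort_b")[i]]]
      write_table_tsv(co$de, file.path(out_dir, sprintf("cohort%d_pathway_de.tsv", i)))
      if (!is.null(co$corr))
        write_table_tsv(co$corr,
                        file.path(out_dir, sprintf("cohort%d_pathway_corr.tsv", i)))
    }
  }
  s <- report_summary(report)
  jsonlite::write_json(s, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  md <- c("# Two-cohort circadian lincRNA report", "",
          sprintf("- cohort 1: %d DE transcripts (%d down, %d up); clock panel: %s",
                  s$cohort1$n_de, s$cohort1$n_de_down, s$cohort1$n_de_up,
                  paste(s$cohort1$de_clock, collapse = ", ")),
          sprintf("- cohort 2: %d DE transcripts (%d down, %d up); clock panel: %s",
                  s$cohort2$n_de, s$cohort2$n_de_down, s$cohort2$n_de_up,
                  paste(s$cohort2$de_clock, collapse = ", ")),
          sprintf("- common circadian lincRNAs: %s",
                  if (length(s$common_lincRNAs))
                    paste(s$common_lincRNAs, collapse = ", ") else "(none)"))
  if (!is.null(s$common_pathways))
    md <- c(md, sprintf("- common pathways: %d (%d down, %d up)",
                        length(s$common_pathways), s$n_common_pathways["down"],
                        s$n_common_pathways["up"]))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(report)
}
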