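# Plain-text readers and writers: counts TSV, sample metadata TSV, GMT gene
# sets, JSON ground truth, and generic result tables. Write -> read round
# trips are identity (up to storage mode).

#' Read a gene-by-sample count matrix from TSV
#'
#' First column is the gene identifier (duplicates allowed; resolve with
#' [dedupe_transcripts()]), header gives the sample identifiers.
#'
#' @param counts_path Path to the count TSV.
#' @param metadata_path Path to the two-column sample metadata TSV
#'   (`sample_id`, `group`).
#' @return A [cohort_counts()] object with samples ordered as in the counts
#'   file.
#' @export
read_counts_tsv <- function(counts_path, metadata_path) {
  if (!file.exists(counts_path))
    cl_stop(paste("no such file:", counts_path), "circlinc_io_error")
  tab <- utils::read.delim(counts_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    cl_stop("count table needs a gene column plus sample columns",
            "circlinc_io_error")
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat))
    cl_stop("non-numeric counts in count table", "circlinc_validation_error")
  rownames(mat) <- as.character(tab[[1]])
  meta <- read_sample_metadata(metadata_path)
  missing <- setdiff(colnames(mat), meta$sample_id)
  if (length(missing))
    cl_stop(sprintf("sample(s) missing from metadata: %s",
                    paste(missing, collapse = ", ")),
            "circlinc_validation_error")
  group <- meta$group[match(colnames(mat), meta$sample_id)]
  cohort_counts(mat, group)
}

#' Read sample metadata (sample_id, group)
#'
#' @param path Path to a two-column TSV with header `sample_id`, `group`;
#'   groups must be `sPTB` or `term` and sample identifiers unique.
#' @return Data frame with columns `sample_id` and `group`.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) cl_stop(paste("no such file:", path), "circlinc_io_error")
  meta <- utils::read.delim(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    cl_stop("metadata needs 'sample_id' and 'group' columns", "circlinc_io_error")
  if (anyDuplicated(meta$sample_id))
    cl_stop("duplicate sample identifiers in metadata",
            "circlinc_validation_error")
  bad <- setdiff(unique(meta$group), GROUP_LEVELS)
  if (length(bad))
    cl_stop(sprintf("unknown group label(s): %s", paste(bad, collapse = ", ")),
            "circlinc_validation_error")
  meta[, c("sample_id", "group")]
}

#' Write a cohort's counts and metadata as TSV
#'
#' @param x A [cohort_counts()] object.
#' @param counts_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_counts_tsv <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "cohort_counts"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- data.frame(sample_id = colnames(x$counts),
                     group = as.character(x$group))
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member gene
#' symbols, one set per line.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) cl_stop(paste("no such file:", path), "circlinc_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    cl_stop("malformed GMT line (need name, description, >= 1 member)",
            "circlinc_io_error")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  gene_set_collection(sets, vapply(parts, `[`, character(1), 2L))
}

#' Write a gene-set collection as GMT
#'
#' @param sets A [gene_set_collection()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, sets$descriptions[[nm]], sets$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write planted truth as JSON
#' @param truth A [planted_truth()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "planted_truth"))
  jsonlite::write_json(
    list(de_genes = as.list(truth$de_genes),
         planted_circadian_lincRNAs = truth$planted_circadian_lincRNAs,
         clock_effect_directions = as.list(truth$clock_effect_directions),
         correlation_strength = truth$correlation_strength,
         factor_genes = truth$factor_genes),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read planted truth from JSON
#' @param path Path written by [write_truth_json()].
#' @return A [planted_truth()].
#' @export
read_truth_json <- function(path) {
  if (!file.exists(path)) cl_stop(paste("no such file:", path), "circlinc_io_error")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  planted_truth(de_genes = unlist(x$de_genes) %||% numeric(0),
                lincRNAs = as.character(x$planted_circadian_lincRNAs %||% character(0)),
                correlation_strength = x$correlation_strength %||% 0,
                factor_genes = as.character(x$factor_genes %||% character(0)))
}

#' Write a synthetic study to a directory
#'
#' Emits per-cohort count and metadata TSVs, the shared truth as JSON, and
#' (if present) the gene sets as GMT.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_tsv(study$cohort1$counts,
                   file.path(dir, "cohort1_counts.tsv"),
                   file.path(dir, "cohort1_samples.tsv"))
  write_counts_tsv(study$cohort2$counts,
                   file.path(dir, "cohort2_counts.tsv"),
                   file.path(dir, "cohort2_samples.tsv"))
  write_truth_json(study$truth, file.path(dir, "truth.json"))
  if (!is.null(study$gene_sets))
    write_gmt(study$gene_sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}

#' Write a result table as TSV
#' @param tab A data frame (DE table, correlation table, ...).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_table_tsv <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
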