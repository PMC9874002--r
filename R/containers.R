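# Lightweight S3 containers. The pipeline deliberately uses plain matrices
# plus a per-sample group factor (limma-style) rather than heavier assay
# containers: every downstream operation is matrix algebra over one assay.

GROUP_LEVELS <- c("term", "sPTB")

as_group <- function(group, n) {
  if (is.factor(group)) group <- as.character(group)
  if (!is.character(group) || length(group) != n)
    cl_stop("'group' must be one label per sample", "circlinc_validation_error")
  bad <- setdiff(unique(group), GROUP_LEVELS)
  if (length(bad))
    cl_stop(sprintf("unknown group label(s): %s (expected %s)",
                    paste(bad, collapse = ", "),
                    paste(GROUP_LEVELS, collapse = ", ")),
            "circlinc_validation_error")
  factor(group, levels = GROUP_LEVELS)
}

#' Raw count matrix for one cohort
#'
#' Bundles an integer gene-by-sample read-count matrix with the per-sample
#' group label. Library sizes are always the current column sums. Duplicate
#' gene identifiers are permitted on input (real count tables carry them);
#' [dedupe_transcripts()] resolves them.
#'
#' @param counts Numeric matrix of non-negative integer read counts with
#'   gene identifiers as row names and unique sample identifiers as column
#'   names.
#' @param group Per-sample label, `"sPTB"` or `"term"`.
#' @return An object of class `cohort_counts`: a list with elements `counts`
#'   (integer matrix) and `group` (factor with levels `term`, `sPTB`).
#' @export
cohort_counts <- function(counts, group) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts))
    cl_stop("'counts' must be a numeric matrix", "circlinc_validation_error")
  if ((nrow(counts) > 0L && is.null(rownames(counts))) || is.null(colnames(counts)))
    cl_stop("'counts' needs gene row names and sample column names",
            "circlinc_validation_error")
  if (anyDuplicated(colnames(counts)))
    cl_stop("duplicate sample identifiers", "circlinc_validation_error")
  if (any(!is.finite(counts)) || any(counts < 0))
    cl_stop("counts must be finite and non-negative", "circlinc_validation_error")
  if (any(counts != round(counts)))
    cl_stop("counts must be integers", "circlinc_validation_error")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, group = as_group(group, ncol(counts))),
            class = "cohort_counts")
}

#' @export
print.cohort_counts <- function(x, ...) {
  cat(sprintf("cohort_counts: %d genes x %d samples (%d term, %d sPTB)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$group == "term"), sum(x$group == "sPTB")))
  invisible(x)
}

#' @export
dim.cohort_counts <- function(x) dim(x$counts)

#' Per-sample library sizes (column sums)
#' @param x A [cohort_counts()] object.
#' @return Named numeric vector of total counts per sample.
#' @export
lib_sizes <- function(x) colSums(x$counts)

#' Normalized log-scale expression matrix
#'
#' Gene-by-sample expression on the log(CPM + prior) scale (non-negative by
#' construction) with the per-sample group label.
#'
#' @param values Numeric matrix, genes x samples, finite and non-negative.
#' @param group Per-sample label, `"sPTB"` or `"term"`.
#' @return An object of class `cohort_expr`.
#' @export
cohort_expr <- function(values, group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    cl_stop("'values' needs gene row names and sample column names",
            "circlinc_validation_error")
  if (anyDuplicated(rownames(values)))
    cl_stop("duplicate gene identifiers in expression matrix",
            "circlinc_validation_error")
  if (any(!is.finite(values)) || any(values < 0))
    cl_stop("expression values must be finite and >= 0",
            "circlinc_validation_error")
  structure(list(values = values, group = as_group(group, ncol(values))),
            class = "cohort_expr")
}

#' @export
print.cohort_expr <- function(x, ...) {
  cat(sprintf("cohort_expr: %d genes x %d samples, range [%.2f, %.2f]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.cohort_expr <- function(x) dim(x$values)

#' Gene-set by sample enrichment score matrix
#'
#' Holds bounded per-sample gene-set variation scores (|score| <= 1).
#'
#' @param values Numeric matrix, gene sets x samples, finite with absolute
#'   value at most 1.
#' @param group Per-sample label, `"sPTB"` or `"term"`.
#' @return An object of class `pathway_scores`.
#' @export
pathway_scores <- function(values, group) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    cl_stop("'values' needs set row names and sample column names",
            "circlinc_validation_error")
  if (anyDuplicated(rownames(values)))
    cl_stop("duplicate gene-set names", "circlinc_validation_error")
  if (any(!is.finite(values)) || any(abs(values) > 1 + 1e-12))
    cl_stop("enrichment scores must be finite with |score| <= 1",
            "circlinc_validation_error")
  structure(list(values = values, group = as_group(group, ncol(values))),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat(sprintf("pathway_scores: %d sets x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

# Accept cohort_expr, pathway_scores, or a plain matrix (+ explicit group)
# and return list(values, group).
as_expr_input <- function(x, group = NULL) {
  if (inherits(x, c("cohort_expr", "pathway_scores")))
    return(list(values = x$values, group = x$group))
  if (is.matrix(x)) {
    if (is.null(group))
      cl_stop("'group' is required when passing a plain matrix",
              "circlinc_validation_error")
    return(list(values = x, group = as_group(group, ncol(x))))
  }
  cl_stop("expected a cohort_expr, pathway_scores, or matrix",
          "circlinc_validation_error")
}

#' Named gene-set collection
#'
#' @param sets Named list of character vectors of member gene symbols.
#' @param descriptions Optional character vector of set descriptions
#'   (recycled to length of `sets`).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    cl_stop("'sets' must be a fully named list", "circlinc_validation_error")
  if (anyDuplicated(names(sets)))
    cl_stop("duplicate gene-set names", "circlinc_validation_error")
  if (any(!vapply(sets, is.character, logical(1))) ||
      any(lengths(sets) == 0L))
    cl_stop("every set must be a non-empty character vector",
            "circlinc_validation_error")
  sets <- lapply(sets, unique)
  descriptions <- rep_len(descriptions %||% "na", length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)
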