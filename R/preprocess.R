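# Count preprocessing: transcript de-duplication, CPM filtering, TMM scaling
# factors, log-CPM transformation.

#' Resolve duplicated transcript identifiers
#'
#' Among rows sharing a gene identifier, keeps the row with the highest
#' total count across samples; ties are broken by first occurrence. Row
#' order is otherwise preserved.
#'
#' @param x A [cohort_counts()] object (duplicate row names allowed).
#' @return A [cohort_counts()] with unique gene identifiers.
#' @export
dedupe_transcripts <- function(x) {
  stopifnot(inherits(x, "cohort_counts"))
  ids <- rownames(x$counts)
  if (!anyDuplicated(ids)) return(x)
  totals <- rowSums(x$counts)
  keep <- vapply(split(seq_along(ids), ids)[unique(ids)],
                 function(idx) idx[which.max(totals[idx])], integer(1))
  keep <- sort(keep)
  cohort_counts(x$counts[keep, , drop = FALSE], as.character(x$group))
}

#' Counts-per-million on pre-normalization library sizes
#' @param x A [cohort_counts()] object; all library sizes must be positive.
#' @return Numeric matrix of CPM values.
#' @export
cpm_matrix <- function(x) {
  lib <- lib_sizes(x)
  if (any(lib <= 0))
    cl_stop("sample(s) with zero library size", "circlinc_validation_error")
  sweep(x$counts, 2, lib, "/") * 1e6
}

#' Filter low-expression transcripts
#'
#' Keeps gene `g` iff `cpm(g, j) > cpm_threshold` in at least
#' `ceiling(min_fraction * n_samples)` samples, with CPM computed on the
#' pre-filter library sizes and the sample count pooled over both groups.
#'
#' @param x A [cohort_counts()] object.
#' @param cpm_threshold CPM that a sample must exceed to count as expressed.
#' @param min_fraction Minimum fraction of samples that must exceed the
#'   threshold.
#' @return Filtered [cohort_counts()]; warns (and returns an empty matrix)
#'   if no gene survives.
#' @export
filter_low_expression <- function(x, cpm_threshold = 0.5, min_fraction = 0.70) {
  stopifnot(inherits(x, "cohort_counts"))
  need <- ceiling(min_fraction * ncol(x$counts))
  keep <- rowSums(cpm_matrix(x) > cpm_threshold) >= need
  if (!any(keep))
    warning("all genes removed by the expression filter")
  cohort_counts(x$counts[keep, , drop = FALSE], as.character(x$group))
}

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values normalization: per sample versus a reference
#' sample (the one whose upper-quartile CPM is closest to the mean
#' upper-quartile), gene-wise log2 ratios of proportions are doubly trimmed
#' by `trim_M` and `trim_A` quantiles and averaged with precision weights
#' from the binomial delta-method variances; factors are rescaled to have
#' geometric mean 1. Computed via [edgeR::calcNormFactors()], the standard
#' implementation of this estimator.
#'
#' @param x A filtered [cohort_counts()] with at least two samples.
#' @param trim_M Two-sided trim fraction on the log-ratio (M) scale.
#' @param trim_A Two-sided trim fraction on the absolute-intensity (A) scale.
#' @return An object of class `norm_factors`: list with `factors` (geometric
#'   mean 1) and `effective_lib_size` (`lib_size * factor`).
#' @export
tmm_factors <- function(x, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(inherits(x, "cohort_counts"))
  if (ncol(x$counts) < 2)
    cl_stop("TMM needs at least two samples", "circlinc_validation_error")
  lib <- lib_sizes(x)
  if (any(lib <= 0))
    cl_stop("sample(s) with zero library size", "circlinc_validation_error")
  f <- edgeR::calcNormFactors(x$counts, lib.size = lib, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  structure(list(factors = stats::setNames(as.numeric(f), colnames(x$counts)),
                 effective_lib_size = lib * as.numeric(f)),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat("TMM factors:\n"); print(round(x$factors, 4)); invisible(x)
}

resolve_factors <- function(x, factors) {
  lib <- lib_sizes(x)
  if (is.null(factors)) return(lib)
  if (inherits(factors, "norm_factors")) return(lib * factors$factors)
  if (is.numeric(factors) && length(factors) == ncol(x$counts))
    return(lib * factors)
  cl_stop("'factors' must be a norm_factors object or one factor per sample",
          "circlinc_validation_error")
}

#' log(CPM + prior) expression matrix
#'
#' `value(g, j) = log_base(counts(g, j) / effective_lib_size(j) * 1e6 + prior)`.
#' With `prior = 1` all values are finite and non-negative; a zero count maps
#' to 0 and a CPM of 1 maps to 1 (base 2).
#'
#' @param x A [cohort_counts()] object.
#' @param factors Optional [tmm_factors()] result (or numeric factors);
#'   `NULL` uses raw library sizes.
#' @param prior Offset added to CPM before the log (default 1).
#' @param base Logarithm base (default 2).
#' @return A [cohort_expr()] object.
#' @export
log_cpm <- function(x, factors = NULL, prior = 1, base = 2) {
  stopifnot(inherits(x, "cohort_counts"))
  eff <- resolve_factors(x, factors)
  if (any(eff <= 0))
    cl_stop("effective library sizes must be positive", "circlinc_validation_error")
  vals <- log(sweep(x$counts, 2, eff, "/") * 1e6 + prior, base = base)
  cohort_expr(vals, as.character(x$group))
}
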