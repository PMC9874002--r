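# From-scratch single-sample gene-set variation scoring: Gaussian kernel CDF
# per gene across samples, symmetric rank statistic per sample, and a
# weighted Kolmogorov-style random walk per set, with the bounded max-diff
# enrichment statistic.

#' Gaussian kernel CDF transform
#'
#' For each gene, estimates the within-gene cumulative distribution across
#' samples with a Gaussian kernel of bandwidth `sd / 4`:
#' `z(g, j) = mean_k Phi((x(g, j) - x(g, k)) / h_g)`. A zero-variance gene
#' gets a floored bandwidth (with a warning), making all its scores 0.5.
#'
#' @param expr A [cohort_expr()] or matrix (genes x samples, >= 2 samples).
#' @param bandwidth_floor Minimum bandwidth used for constant genes.
#' @return Matrix of cumulative scores in (0, 1), same dimensions as input.
#' @export
kcdf_transform <- function(expr, bandwidth_floor = 1e-8) {
  x <- if (inherits(expr, c("cohort_expr", "pathway_scores"))) expr$values else
    as.matrix(expr)
  if (ncol(x) < 2)
    cl_stop("kernel CDF needs >= 2 samples", "circlinc_validation_error")
  h <- apply(x, 1, stats::sd) / 4
  flat <- h <= 0
  if (any(flat)) {
    warning(sprintf("%d constant gene(s); bandwidth floored", sum(flat)))
    h[flat] <- bandwidth_floor
  }
  z <- x
  for (g in seq_len(nrow(x))) {
    xi <- x[g, ]
    z[g, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / h[g]))
  }
  z
}

#' Symmetric rank statistic per sample
#'
#' Within each sample, genes are ranked by decreasing cumulative score (rank
#' 1 = highest; ties broken by stable gene order) and the symmetric
#' statistic is `s(g, j) = |p/2 - rank(g, j)|` with `p` the gene count, so
#' both extremes of the ranking carry the largest weight.
#'
#' @param z Matrix of cumulative scores (genes x samples).
#' @return List with `s` (the statistic, genes x samples) and `rank`
#'   (integer ranks, genes x samples).
#' @export
rank_statistic <- function(z) {
  z <- as.matrix(z)
  p <- nrow(z)
  rk <- apply(z, 2, function(col) {
    ord <- order(-col)        # stable: ties keep gene order
    r <- integer(p); r[ord] <- seq_len(p); r
  })
  rk <- matrix(rk, nrow = p, dimnames = dimnames(z))
  list(s = abs(p / 2 - rk), rank = rk)
}

#' Enrichment score of one set in one sample
#'
#' Random walk down the ranked gene list: inside-set steps add
#' `s^tau / sum_set s^tau`, outside-set steps subtract `1 / (p - m)`. The
#' score is the maximum positive deviation plus the minimum negative
#' deviation of the walk (the signed "max-diff" form), bounded in [-1, 1].
#'
#' @param s Numeric vector of symmetric rank statistics for one sample
#'   (one value per gene, in gene order).
#' @param ranking Integer ranks of the genes in this sample (1 = first in
#'   the walk).
#' @param set_index Logical or integer index of the set members among the
#'   genes; must select at least one but not all genes.
#' @param tau Exponent on the rank statistic (default 1).
#' @return The enrichment score, a scalar in [-1, 1].
#' @export
enrichment_score <- function(s, ranking, set_index, tau = 1) {
  p <- length(s)
  inside <- rep(FALSE, p)
  inside[set_index] <- TRUE
  m <- sum(inside)
  if (m == 0 || m == p)
    cl_stop("set must contain some but not all genes", "circlinc_validation_error")
  ord <- order(ranking)
  w <- s[ord]^tau
  ins <- inside[ord]
  total <- sum(w[ins])
  step <- ifelse(ins, if (total > 0) w / total else 1 / m, -1 / (p - m))
  walk <- cumsum(step)
  max(0, walk) + min(0, walk)
}

#' Gene-set variation score matrix
#'
#' Composes [kcdf_transform()], [rank_statistic()], and [enrichment_score()]
#' over every sample and every set: a deterministic, unsupervised per-sample
#' pathway activity matrix. Sets are intersected with the expression
#' universe first; sets outside `[min_size, max_size]` after intersection
#' are reported in the `filtered_sets` attribute and not scored.
#'
#' @param expr A [cohort_expr()] (genes x samples).
#' @param sets A [gene_set_collection()].
#' @param min_size,max_size Post-intersection set-size filters.
#' @param tau Exponent on the rank statistic.
#' @return A [pathway_scores()] object (sets x samples) with attribute
#'   `filtered_sets`.
#' @export
gsva_matrix <- function(expr, sets, min_size = 2L, max_size = 500L, tau = 1) {
  stopifnot(inherits(expr, "cohort_expr"), inherits(sets, "gene_set_collection"))
  genes <- rownames(expr$values)
  members <- lapply(sets$sets, intersect, y = genes)
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size & sizes < length(genes)
  if (!any(keep))
    cl_stop("no gene set left after universe intersection and size filtering",
            "circlinc_validation_error")
  members <- members[keep]

  z <- kcdf_transform(expr)
  rs <- rank_statistic(z)
  p <- length(genes)
  n <- ncol(expr$values)
  idx <- lapply(members, match, table = genes)

  es <- matrix(NA_real_, length(members), n,
               dimnames = list(names(members), colnames(expr$values)))
  for (j in seq_len(n)) {
    ord <- order(rs$rank[, j])
    w <- rs$s[ord, j]^tau
    pos_in_walk <- integer(p); pos_in_walk[ord] <- seq_len(p)
    for (k in seq_along(members)) {
      ins <- logical(p)
      ins[pos_in_walk[idx[[k]]]] <- TRUE
      total <- sum(w[ins])
      m <- length(idx[[k]])
      step <- ifelse(ins, if (total > 0) w / total else 1 / m, -1 / (p - m))
      walk <- cumsum(step)
      es[k, j] <- max(0, walk) + min(0, walk)
    }
  }
  out <- pathway_scores(es, as.character(expr$group))
  attr(out, "filtered_sets") <- names(sets$sets)[!keep]
  out
}

#' Pathway-level differential and correlation screens across two cohorts
#'
#' Reuses the moderated t-test (unit weights; enrichment scores are not
#' counts) on each cohort's pathway score matrix, gates at the differential
#' cut-offs, Pearson-correlates the surviving pathways against the
#' lincRNA-based risk score at the correlation cut-offs, and overlaps the
#' two cohorts' significant pathways with sign concordance.
#'
#' @param scores_a,scores_b [pathway_scores()] from the two cohorts, built
#'   against the same gene-set collection.
#' @param linc_score_a,linc_score_b Per-cohort lincRNA-based risk scores
#'   ([compute_risk_score()] results or named numeric vectors).
#' @param de_p,de_fdr Differential-pathway cut-offs.
#' @param cor_p,cor_fdr Correlation cut-offs.
#' @return List with per-cohort `de` tables and selected subsets, `corr`
#'   tables, the `overlap` result, and down/up counts of common pathways.
#' @export
pathway_de_and_correlation <- function(scores_a, scores_b,
                                       linc_score_a, linc_score_b,
                                       de_p = 0.05, de_fdr = 0.25,
                                       cor_p = 0.05, cor_fdr = 0.10) {
  one <- function(scores, linc_score) {
    de <- moderated_t_test(scores)
    sel <- select_de(de, p_cut = de_p, fdr_cut = de_fdr)
    if (nrow(sel) == 0)
      return(list(de = de, selected = sel, corr = NULL,
                  significant = data.frame(id = character(0), sign = numeric(0))))
    corr <- pearson_screen(linc_score, scores$values[sel$id, , drop = FALSE],
                           p_cut = cor_p, fdr_cut = cor_fdr)
    list(de = de, selected = sel, corr = corr,
         significant = significant_features(corr))
  }
  a <- one(scores_a, linc_score_a)
  b <- one(scores_b, linc_score_b)
  ov <- overlap_cohorts(a$significant, b$significant)
  # down/up counts of common pathways by differential direction in sPTB
  dir_common <- a$de$direction[match(ov$common_features, a$de$id)]
  list(cohort_a = a, cohort_b = b, overlap = ov,
       n_common = c(down = sum(dir_common < 0), up = sum(dir_common > 0)))
}
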