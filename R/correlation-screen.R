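# Pearson correlation screen of a per-sample risk score against candidate
# features, BH-gated, plus sign-concordant cross-cohort overlap and a small
# PCA helper.

#' Pearson correlation screen against a risk score
#'
#' For each feature, the product-moment correlation with the score, a
#' two-sided p-value from `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, and a 95%
#' confidence interval by the Fisher z transform (`z +/- 1.96 / sqrt(n - 3)`,
#' clamped to +/-1 when `|r| = 1`). BH q-values are computed over the
#' screened feature family only (the features entering this call, e.g. the
#' DE lincRNAs), matching a screen that is run downstream of a DE gate.
#' Zero-variance features are flagged `degenerate`, excluded from the BH
#' family, and never significant.
#'
#' @param score A [compute_risk_score()] result or named numeric vector.
#' @param features A [cohort_expr()], [pathway_scores()], or matrix
#'   (features x samples), sample-aligned with the score.
#' @param p_cut,fdr_cut Joint significance cut-offs.
#' @return A `corr_table` data frame with columns `id`, `r`, `ci_low`,
#'   `ci_high`, `p`, `fdr`, `degenerate`, `significant`.
#' @export
pearson_screen <- function(score, features, p_cut = 0.05, fdr_cut = 0.10) {
  if (inherits(score, "risk_score")) score <- score$score
  if (inherits(features, c("cohort_expr", "pathway_scores")))
    features <- features$values
  features <- as.matrix(features)
  if (!is.null(names(score)) && !is.null(colnames(features))) {
    if (!setequal(names(score), colnames(features)))
      cl_stop("score and features cover different samples",
              "circlinc_validation_error")
    features <- features[, names(score), drop = FALSE]
  }
  n <- length(score)
  if (n < 4 || ncol(features) != n)
    cl_stop("need >= 4 aligned samples", "circlinc_validation_error")

  sd_score <- stats::sd(score)
  sd_feat <- apply(features, 1, stats::sd)
  degenerate <- sd_feat == 0 | sd_score == 0
  if (any(degenerate))
    warning(sprintf("%d zero-variance feature(s)/score flagged as degenerate",
                    sum(degenerate)))

  y <- score - mean(score)
  xc <- features - rowMeans(features)
  r <- as.numeric(xc %*% y) / sqrt(rowSums(xc^2) * sum(y^2))
  r[degenerate] <- NA_real_
  r <- pmin(1, pmax(-1, r))

  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  tstat[!degenerate & abs(r) >= 1] <- Inf * sign(r[!degenerate & abs(r) >= 1])
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)

  halfwidth <- 1.96 / sqrt(n - 3)
  z <- atanh(pmin(1 - 1e-15, pmax(-1 + 1e-15, r)))
  ci_low <- tanh(z - halfwidth); ci_high <- tanh(z + halfwidth)
  exact <- !is.na(r) & abs(r) >= 1
  ci_low[exact] <- r[exact]; ci_high[exact] <- r[exact]

  fdr <- rep(NA_real_, length(r))
  if (any(!degenerate)) fdr[!degenerate] <- bh_fdr(p[!degenerate])

  out <- data.frame(id = rownames(features) %||% seq_along(r),
                    r = r, ci_low = ci_low, ci_high = ci_high,
                    p = p, fdr = fdr, degenerate = degenerate,
                    significant = !degenerate & !is.na(p) &
                      p < p_cut & fdr < fdr_cut,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("corr_table", "data.frame")
  out
}

#' Significant features of a correlation screen, with signs
#'
#' @param tab A `corr_table` from [pearson_screen()].
#' @return Data frame with columns `id` and `sign`.
#' @export
significant_features <- function(tab) {
  stopifnot(is.data.frame(tab), all(c("id", "r", "significant") %in% names(tab)))
  sig <- tab[tab$significant, , drop = FALSE]
  data.frame(id = sig$id, sign = sign(sig$r),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Sign-concordant cross-cohort overlap
#'
#' Intersects two significant feature sets by identifier, requiring the
#' correlation sign to agree; output is ordered by identifier.
#'
#' @param a,b Data frames with columns `id` and `sign` (e.g. from
#'   [significant_features()]).
#' @return An object of class `overlap_result`: list with `common_features`
#'   (character), `signs` (named), and the two input sets.
#' @export
overlap_cohorts <- function(a, b) {
  stopifnot(all(c("id", "sign") %in% names(a)), all(c("id", "sign") %in% names(b)))
  common <- intersect(a$id, b$id)
  same <- common[a$sign[match(common, a$id)] == b$sign[match(common, b$id)]]
  same <- sort(same)
  structure(list(common_features = same,
                 signs = stats::setNames(a$sign[match(same, a$id)], same),
                 cohort_a = a, cohort_b = b),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of (%d, %d) significant features\n",
              length(x$common_features), nrow(x$cohort_a), nrow(x$cohort_b)))
  if (length(x$common_features))
    cat(" ", paste(x$common_features, collapse = ", "), "\n")
  invisible(x)
}

#' PCA of samples over a feature panel
#'
#' Centered (not variance-scaled) principal components of the samples over
#' the given features, with sample scores rescaled column-wise to unit norm
#' so coordinates land roughly in (-1, 1) -- the plotting convention of
#' standard PCA autoplots.
#'
#' @param expr A [cohort_expr()] or matrix (features x samples).
#' @param features Optional subset of row identifiers to use.
#' @return List with `scores` (samples x components, unit-norm columns),
#'   `explained` (variance fractions summing to 1), and `group` (if the
#'   input carried one).
#' @export
pca_features <- function(expr, features = NULL) {
  grp <- NULL
  if (inherits(expr, c("cohort_expr", "pathway_scores"))) {
    grp <- expr$group
    expr <- expr$values
  }
  expr <- as.matrix(expr)
  if (!is.null(features)) {
    missing <- setdiff(features, rownames(expr))
    if (length(missing))
      cl_stop(sprintf("feature(s) not found: %s", paste(missing, collapse = ", ")),
              "circlinc_validation_error")
    expr <- expr[features, , drop = FALSE]
  }
  if (nrow(expr) < 2 || ncol(expr) < 3)
    cl_stop("PCA needs >= 2 features and >= 3 samples", "circlinc_validation_error")
  if (any(apply(expr, 1, stats::sd) == 0))
    cl_stop("constant feature(s); PCA undefined", "circlinc_validation_error")
  pr <- stats::prcomp(t(expr), center = TRUE, scale. = FALSE)
  norms <- sqrt(colSums(pr$x^2))
  scores <- sweep(pr$x, 2, pmax(norms, 1e-300), "/")
  list(scores = scores, explained = pr$sdev^2 / sum(pr$sdev^2), group = grp)
}
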