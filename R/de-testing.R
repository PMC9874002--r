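# Two-group differential testing: precision weights from the fitted
# mean-variance trend, weighted least squares per gene, empirical-Bayes
# variance moderation, BH false discovery rates.

group_design <- function(group) {
  if (nlevels(droplevels(group)) != 2)
    cl_stop("exactly two groups required", "circlinc_validation_error")
  if (any(table(group) < 2))
    cl_stop("each group needs at least 2 samples", "circlinc_validation_error")
  group
}

# weighted two-group least squares, vectorized over genes
# returns means per group, effect (sPTB - term), residual variance, df,
# unscaled coefficient variance, and fitted values
wls_two_group <- function(values, group, weights) {
  n <- ncol(values)
  if (is.null(weights)) weights <- matrix(1, nrow(values), n)
  stopifnot(all(dim(weights) == dim(values)), all(weights > 0))
  i1 <- group == levels(group)[1]   # term
  i2 <- group == levels(group)[2]   # sPTB
  w1 <- weights[, i1, drop = FALSE]; w2 <- weights[, i2, drop = FALSE]
  sw1 <- rowSums(w1); sw2 <- rowSums(w2)
  m1 <- rowSums(w1 * values[, i1, drop = FALSE]) / sw1
  m2 <- rowSums(w2 * values[, i2, drop = FALSE]) / sw2
  fitted <- matrix(0, nrow(values), n, dimnames = dimnames(values))
  fitted[, i1] <- m1; fitted[, i2] <- m2
  resid <- values - fitted
  df <- n - 2L
  s2 <- rowSums(weights * resid^2) / df
  list(mean1 = m1, mean2 = m2, effect = m2 - m1, s2 = s2, df = df,
       v_coef = 1 / sw1 + 1 / sw2, fitted = fitted)
}

#' Precision weights from the log-count mean-variance trend
#'
#' Transforms counts to `log2((count + 0.5) / (effective_lib_size + 1) * 1e6)`,
#' fits the two-group model per gene, regresses the square root of the
#' residual standard deviations on average log2 count by lowess, and maps
#' each observation's fitted count through the trend to a predicted standard
#' deviation; the precision weight is its inverse fourth power. A degenerate
#' trend (all residual SDs equal, e.g. all zero) falls back to uniform
#' weights, preserving ordinary least squares.
#'
#' @param x A filtered [cohort_counts()] with at least two samples per group.
#' @param factors Optional [tmm_factors()] result (or numeric factors).
#' @param span Lowess span for the trend fit.
#' @return List with `expr_values` (matrix on the offset log2-CPM scale;
#'   values may be negative, so this is a plain matrix rather than a
#'   [cohort_expr()]), `weights` (positive finite matrix), and `group`.
#'   Pass `expr_values` and `weights` on to [moderated_t_test()].
#' @export
voom_weights <- function(x, factors = NULL, span = 0.5) {
  stopifnot(inherits(x, "cohort_counts"))
  group <- group_design(x$group)
  eff <- resolve_factors(x, factors)
  y <- t(log2((t(x$counts) + 0.5) / (eff + 1) * 1e6))
  fit <- wls_two_group(y, group, weights = NULL)
  sy <- sqrt(sqrt(fit$s2))

  degenerate <- all(fit$s2 < 1e-12) || diff(range(sy)) < 1e-10
  if (degenerate) {
    w <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
  } else {
    sx <- rowMeans(y) + mean(log2(eff + 1)) - log2(1e6)
    trend <- stats::lowess(sx, sy, f = span)
    pred <- stats::approxfun(trend, rule = 2, ties = mean)
    fitted_logcount <- sweep(fit$fitted, 2, log2(eff + 1), "+") - log2(1e6)
    w <- pred(fitted_logcount)^-4
    w <- matrix(w, nrow(y), ncol(y), dimnames = dimnames(y))
    if (any(!is.finite(w)) || any(w <= 0))
      cl_stop("non-finite precision weights from the mean-variance trend",
              "circlinc_error")
  }
  list(expr_values = y, weights = w, group = group)
}

# digamma/trigamma moment matching of log residual variances to a scaled F,
# as in empirical-Bayes variance moderation; returns prior df (possibly Inf)
# and prior variance
estimate_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) return(list(df_prior = Inf, s2_prior = max(mean(s2), 1e-8)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e)
  excess <- evar - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    # no detectable gene-to-gene variance heterogeneity: point-mass prior at
    # the mean sample variance
    list(df_prior = Inf, s2_prior = mean(s2[ok]))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    list(df_prior = d0, s2_prior = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

# Newton inversion of the trigamma function on (0, Inf)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Moderated two-group t-test per feature
#'
#' Weighted least-squares fit of expression on the group indicator, with the
#' residual variance shrunk toward an empirical-Bayes prior estimated by
#' moment matching of the log variances (digamma/trigamma inversion). The
#' moderated statistic is `effect / sqrt(s2_post * v)` referred to a
#' t-distribution on `df + df_prior` degrees of freedom. The effect is coded
#' sPTB minus term, so a negative statistic means down-regulated in sPTB.
#'
#' @param x A [cohort_expr()], [pathway_scores()], or plain matrix
#'   (features x samples).
#' @param group Required if `x` is a plain matrix.
#' @param weights Optional positive weight matrix matching `x` (e.g. from
#'   [voom_weights()]); `NULL` means unit weights.
#' @param display Optional [cohort_expr()] on the reporting scale
#'   (log(CPM+1)); per-group means and SDs in the output are computed from it
#'   rather than from the test-scale matrix.
#' @param prior Optional list `list(df_prior =, s2_prior =)` overriding the
#'   estimated moderation prior; `df_prior = 0` recovers the ordinary
#'   (weighted) t-test and `df_prior = Inf` fixes the variance at the prior.
#' @return A `de_table` data frame with columns `id`, `mean_term`, `sd_term`,
#'   `mean_sptb`, `sd_sptb`, `effect`, `moderated_t`, `df_total`, `p`, `fdr`,
#'   `direction`; the moderation prior is attached as attribute `prior`.
#' @export
moderated_t_test <- function(x, group = NULL, weights = NULL, display = NULL,
                             prior = NULL) {
  inp <- as_expr_input(x, group)
  grp <- group_design(inp$group)
  fit <- wls_two_group(inp$values, grp, weights)

  if (is.null(prior)) prior <- estimate_prior(fit$s2, fit$df)
  d0 <- prior$df_prior; s20 <- prior$s2_prior
  if (d0 < 0 || s20 <= 0)
    cl_stop("moderation prior needs df_prior >= 0 and s2_prior > 0",
            "circlinc_validation_error")
  s2_post <- if (is.infinite(d0)) rep(s20, length(fit$s2)) else
    (d0 * s20 + fit$df * fit$s2) / (d0 + fit$df)
  if (any(s2_post <= 0))
    cl_stop("non-positive posterior variance (constant features with no prior)",
            "circlinc_error")
  tstat <- fit$effect / sqrt(s2_post * fit$v_coef)
  # reference df: residual + prior, capped at the pooled residual df across
  # features (the prior cannot carry more information than the data it was
  # estimated from)
  df_total <- min(fit$df + d0, fit$df * length(fit$s2))
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  disp <- if (is.null(display)) inp$values else {
    dv <- as_expr_input(display)$values
    if (!all(rownames(inp$values) %in% rownames(dv)))
      cl_stop("'display' matrix is missing tested features",
              "circlinc_validation_error")
    dv[rownames(inp$values), colnames(inp$values), drop = FALSE]
  }
  i1 <- grp == levels(grp)[1]; i2 <- grp == levels(grp)[2]
  out <- data.frame(
    id = rownames(inp$values),
    mean_term = rowMeans(disp[, i1, drop = FALSE]),
    sd_term = apply(disp[, i1, drop = FALSE], 1, stats::sd),
    mean_sptb = rowMeans(disp[, i2, drop = FALSE]),
    sd_sptb = apply(disp[, i2, drop = FALSE], 1, stats::sd),
    effect = fit$effect,
    moderated_t = tstat,
    df_total = df_total,
    p = p,
    fdr = bh_fdr(p),
    direction = sign(tstat),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "prior") <- prior
  attr(out, "s2") <- unname(fit$s2)
  attr(out, "s2_post") <- unname(s2_post)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up q-values `q_(i) = min_{k >= i} p_(k) * m / k`, mapped back to the
#' input order (the standard BH adjustment as implemented by
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1))
    cl_stop("p-values must lie in [0, 1]", "circlinc_validation_error")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed features
#'
#' @param table A `de_table` from [moderated_t_test()].
#' @param p_cut,fdr_cut Significance cut-offs applied jointly
#'   (`p < p_cut` and `fdr < fdr_cut`).
#' @return The selected rows, with attribute `n_direction` giving the
#'   down/up counts.
#' @export
select_de <- function(table, p_cut = 0.05, fdr_cut = 0.25) {
  stopifnot(is.data.frame(table), all(c("p", "fdr", "direction") %in% names(table)))
  out <- table[table$p < p_cut & table$fdr < fdr_cut, , drop = FALSE]
  attr(out, "n_direction") <- c(down = sum(out$direction < 0),
                                up = sum(out$direction > 0))
  class(out) <- c("de_table", "data.frame")
  out
}
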