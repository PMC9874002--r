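# Independent brute-force oracles, coded directly from the published
# definitions of each estimator. They share no code with the package
# implementations they check.

# trimmed-mean-of-M-values scaling factors: doubly trimmed, precision-
# weighted mean of log2 ratios of proportions vs an upper-quartile reference
oracle_tmm <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  lib <- colSums(counts)
  uq <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  one <- function(j) {
    obs <- counts[, j]; rfc <- counts[, ref]
    nO <- lib[j]; nR <- lib[ref]
    keep <- obs > 0 & rfc > 0
    obs <- obs[keep]; rfc <- rfc[keep]
    logR <- log2((obs / nO) / (rfc / nR))
    absE <- (log2(obs / nO) + log2(rfc / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rfc) / (nR * rfc)
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
    keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }
  f <- vapply(seq_len(ncol(counts)), one, numeric(1))
  f / exp(mean(log(f)))
}

# Benjamini-Hochberg step-up by explicit minimum scan
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  run_min <- Inf
  for (i in m:1) {
    run_min <- min(run_min, p[o[i]] * m / i)
    q_sorted[i] <- min(run_min, 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# moderated t with a *given* prior, written in scalar arithmetic
oracle_mod_t <- function(expr, group, s2_prior, df_prior) {
  t(vapply(seq_len(nrow(expr)), function(g) {
    x1 <- expr[g, group == "term"]; x2 <- expr[g, group == "sPTB"]
    eff <- mean(x2) - mean(x1)
    df <- length(x1) + length(x2) - 2
    s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / df
    s2p <- if (is.infinite(df_prior)) s2_prior else
      (df_prior * s2_prior + df * s2) / (df_prior + df)
    v <- 1 / length(x1) + 1 / length(x2)
    tt <- eff / sqrt(s2p * v)
    c(t = tt, p = 2 * pt(-abs(tt), df = df + df_prior))
  }, numeric(2)))
}

# product-moment correlation, scalar formula
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# enrichment score by explicit loop, recomputed from the raw cumulative
# scores of one sample
oracle_es <- function(z_col, members, gene_ids, tau = 1) {
  p <- length(z_col)
  ord <- order(-z_col)
  ranks <- integer(p); ranks[ord] <- seq_len(p)
  s <- abs(p / 2 - ranks)
  inside <- gene_ids %in% members
  m <- sum(inside)
  denom <- sum(s[inside]^tau)
  cum <- 0; mx <- 0; mn <- 0
  for (pos in seq_len(p)) {
    g <- ord[pos]
    cum <- cum + if (inside[g]) {
      if (denom > 0) s[g]^tau / denom else 1 / m
    } else -1 / (p - m)
    mx <- max(mx, cum); mn <- min(mn, cum)
  }
  mx + mn
}
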