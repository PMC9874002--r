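make_expr <- function(n_genes = 20, n1 = 3, n2 = 3, seed = 7, shift = 0) {
  set.seed(seed)
  n <- n1 + n2
  vals <- matrix(abs(rnorm(n_genes * n, mean = 5)), n_genes, n,
                 dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                                 sprintf("S%02d", seq_len(n))))
  vals[, (n1 + 1):n] <- vals[, (n1 + 1):n] + shift
  group <- c(rep("term", n1), rep("sPTB", n2))
  list(vals = vals, group = group)
}

test_that("BH q-values match the hand step-up and p.adjust semantics", {
  expect_equal(bh_fdr(c(0.005, 0.01, 0.03, 0.04)), c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_fdr(0.37), 0.37)                       # singleton
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))         # constant vector
  expect_error(bh_fdr(c(0.1, 1.2)), class = "circlinc_validation_error")
  expect_error(bh_fdr(c(0.1, NA)), class = "circlinc_validation_error")

  set.seed(31)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])                 # permutation-invariant
  expect_true(all(diff(q[order(p)]) >= -1e-15))          # monotone in ranked p
})

test_that("moderated t matches the closed-form posterior-variance oracle", {
  e <- make_expr(20, 3, 3, shift = 0.5)
  prior <- list(df_prior = 4, s2_prior = 0.5)
  tab <- moderated_t_test(e$vals, group = e$group, prior = prior)
  orc <- oracle_mod_t(e$vals, e$group, s2_prior = 0.5, df_prior = 4)
  expect_equal(tab$moderated_t, unname(orc[, "t"]), tolerance = 1e-8)
  expect_equal(tab$p, unname(orc[, "p"]), tolerance = 1e-8)
  expect_equal(tab$direction, sign(tab$moderated_t))
})

test_that("prior limits recover the ordinary t and the fixed-variance z", {
  e <- make_expr(15, 4, 4, seed = 12, shift = 0.3)
  # d0 = 0: ordinary equal-variance two-sample t
  tab0 <- moderated_t_test(e$vals, group = e$group,
                           prior = list(df_prior = 0, s2_prior = 1))
  tcl <- apply(e$vals, 1, function(x) {
    unname(t.test(x[e$group == "sPTB"], x[e$group == "term"],
                  var.equal = TRUE)$statistic)
  })
  expect_equal(tab0$moderated_t, unname(tcl), tolerance = 1e-10)

  # d0 = Inf: statistic is effect / (s0 sqrt(v)) with a near-normal
  # reference (df capped at the pooled residual df, here 500 * 6)
  eI <- make_expr(500, 4, 4, seed = 13, shift = 0.3)
  tabI <- moderated_t_test(eI$vals, group = eI$group,
                           prior = list(df_prior = Inf, s2_prior = 0.25))
  eff <- rowMeans(eI$vals[, eI$group == "sPTB"]) -
    rowMeans(eI$vals[, eI$group == "term"])
  v <- 1 / 4 + 1 / 4
  expect_equal(tabI$moderated_t, unname(eff / sqrt(0.25 * v)), tolerance = 1e-10)
  expect_equal(tabI$p, unname(2 * pnorm(-abs(tabI$moderated_t))), tolerance = 1e-2)
})

test_that("estimated-prior moderated t agrees with the limma cross-check", {
  e <- make_expr(200, 5, 5, seed = 99, shift = 0.2)
  tab <- moderated_t_test(e$vals, group = e$group)
  design <- cbind(1, e$group == "sPTB")
  fit <- limma::eBayes(limma::lmFit(e$vals, design))
  expect_equal(attr(tab, "prior")$df_prior, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "prior")$s2_prior, fit$s2.prior, tolerance = 1e-6)
  expect_equal(tab$moderated_t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(tab$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderation shrinks each variance toward the prior, never past it", {
  e <- make_expr(100, 4, 4, seed = 3)
  tab <- moderated_t_test(e$vals, group = e$group)
  s2 <- attr(tab, "s2"); s2p <- attr(tab, "s2_post")
  s20 <- attr(tab, "prior")$s2_prior
  expect_true(all(s2p >= pmin(s2, s20) - 1e-12))
  expect_true(all(s2p <= pmax(s2, s20) + 1e-12))
})

test_that("weighted fits accept precision weights and match limma voom", {
  x <- toy_counts(60, n1 = 4, n2 = 4, seed = 21, lambda = 200)
  fac <- tmm_factors(x)
  vm <- voom_weights(x, fac)
  lv <- limma::voom(x$counts, design = cbind(1, x$group == "sPTB"),
                    lib.size = fac$effective_lib_size)
  expect_equal(vm$expr_values, lv$E, tolerance = 1e-10)
  expect_equal(vm$weights, lv$weights, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(vm$weights > 0) && all(is.finite(vm$weights)))

  tab <- moderated_t_test(vm$expr_values, group = as.character(x$group),
                          weights = vm$weights)
  fitw <- limma::eBayes(limma::lmFit(lv$E, cbind(1, x$group == "sPTB"),
                                     weights = lv$weights))
  expect_equal(tab$moderated_t, unname(fitw$t[, 2]), tolerance = 1e-6)
})

test_that("a degenerate mean-variance trend falls back to uniform weights", {
  counts <- matrix(rep(c(40, 80, 120, 160), each = 6), 4, 6, byrow = TRUE,
                   dimnames = list(sprintf("G%d", 1:4), sprintf("S%02d", 1:6)))
  x <- cohort_counts(counts, c(rep("term", 3), rep("sPTB", 3)))
  vm <- voom_weights(x)
  expect_true(all(vm$weights == 1))
})

test_that("group design is validated", {
  e <- make_expr(5, 2, 1)
  expect_error(moderated_t_test(e$vals, group = e$group),
               class = "circlinc_validation_error")
  x <- toy_counts(10, n1 = 1, n2 = 7)
  expect_error(voom_weights(x), class = "circlinc_validation_error")
})

test_that("select_de gates jointly on p and FDR and counts directions", {
  tab <- data.frame(id = letters[1:4], p = c(0.01, 0.04, 0.2, 0.001),
                    fdr = c(0.1, 0.3, 0.05, 0.2),
                    direction = c(-1, -1, 1, 1))
  sel <- select_de(tab, p_cut = 0.05, fdr_cut = 0.25)
  expect_setequal(sel$id, c("a", "d"))
  expect_equal(attr(sel, "n_direction"), c(down = 1L, up = 1L))
  empty <- select_de(tab[0, ], 0.05, 0.25)
  expect_equal(nrow(empty), 0)
})

test_that("published significance gates reproduce the two clock panels", {
  # per-gene moderated-t summaries of the 14 detectable clock transcripts in
  # the two cohorts (frozen reporting fixture), screened at p<.05, FDR<.25
  g <- clock_gene_symbols()
  cohort1 <- data.frame(
    id = g,
    moderated_t = c(1.25, -1.03, -0.66, -2.01, 0.92, -3.14, -1.59, -2.53,
                    -2.98, 2.06, -1.02, -3.37, -3.51, 0.83),
    p = c(0.2203, 0.3109, 0.5116, 0.0533, 0.3656, 0.0037, 0.1231, 0.0169,
          0.0056, 0.0484, 0.3145, 0.0020, 0.0014, 0.4148),
    fdr = c(0.5278, 0.6158, 0.7658, 0.2868, 0.6642, 0.0841, 0.4032, 0.1750,
            0.1003, 0.2759, 0.6193, 0.0615, 0.0535, 0.7028))
  cohort1$direction <- sign(cohort1$moderated_t)
  sel1 <- select_de(cohort1)
  expect_setequal(sel1$id, c("NPAS2", "NR1D1", "NR1D2", "PER3", "RORA"))
  expect_true(all(sel1$direction == -1))

  cohort2 <- data.frame(
    id = g,
    moderated_t = c(2.65, 0.17, 0.44, -3.05, -0.98, -1.51, -2.19, -0.54,
                    -0.12, -0.75, -3.65, 0.69, -2.28, 1.89),
    p = c(0.0120, 0.8630, 0.6639, 0.0043, 0.3319, 0.1408, 0.0357, 0.5932,
          0.9075, 0.4606, 0.0008, 0.4950, 0.0292, 0.0665),
    fdr = c(0.1475, 0.9393, 0.8366, 0.0975, 0.6087, 0.4114, 0.2257, 0.7987,
            0.9600, 0.7102, 0.0498, 0.7333, 0.2075, 0.2954))
  cohort2$direction <- sign(cohort2$moderated_t)
  sel2 <- select_de(cohort2)
  expect_setequal(sel2$id, c("ARNTL", "CRY1", "NPAS3", "PER2", "RORA"))
  expect_equal(sel2$direction[sel2$id == "ARNTL"], 1)
  expect_true(all(sel2$direction[sel2$id != "ARNTL"] == -1))
})
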