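test_that("kernel CDF reproduces the two-sample limits and is monotone", {
  # equal values: sd = 0, floored bandwidth, both samples at Phi(0) = .5
  flat <- matrix(c(3, 3), 1, dimnames = list("G1", c("S1", "S2")))
  expect_warning(zf <- kcdf_transform(flat), "constant")
  expect_equal(unname(zf[1, ]), c(0.5, 0.5))

  # two widely separated values: z -> (Phi(0) + Phi(-inf))/2 = .25 and .75
  far <- matrix(c(0, 1000, 1, 999), 2, byrow = TRUE,
                dimnames = list(c("G1", "G2"), c("S1", "S2")))
  z <- kcdf_transform(far)
  expect_equal(unname(z[1, ]), c(0.25, 0.75), tolerance = 1e-6)

  # strictly increasing in one sample's value, others held fixed
  g <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("G", sprintf("S%d", 1:5)))
  g2 <- g; g2[1, 3] <- 3.5
  expect_gt(kcdf_transform(g2)[1, 3], kcdf_transform(g)[1, 3])
  expect_true(all(z > 0 & z < 1))
})

test_that("symmetric rank statistic weights both extremes", {
  z <- matrix(c(0.9, 0.5, 0.1), 3, 1,
              dimnames = list(c("A", "B", "C"), "S1"))
  rs <- rank_statistic(z)
  expect_equal(unname(rs$rank[, 1]), c(1L, 2L, 3L))
  expect_equal(unname(rs$s[, 1]), c(0.5, 0.5, 1.5))   # |3/2 - rank|

  # both extremes out-weigh the middle; with integer ranks the two extreme
  # weights differ by exactly one rank unit
  z4 <- matrix(c(0.9, 0.6, 0.4, 0.1), 4, 1,
               dimnames = list(LETTERS[1:4], "S1"))
  s4 <- rank_statistic(z4)$s[, 1]
  expect_true(all(s4[c("A", "D")] >= max(s4[c("B", "C")])))
  expect_equal(abs(unname(s4["A"] - s4["D"])), 1)

  # permuting gene input order leaves each gene's statistic unchanged
  perm <- c(3, 1, 2)
  rsp <- rank_statistic(z[perm, , drop = FALSE])
  expect_equal(rsp$s[rownames(z), 1], rs$s[, 1])
})

test_that("enrichment score walks match hand values and the brute oracle", {
  z <- c(A = 0.9, B = 0.5, C = 0.1)
  rs <- rank_statistic(matrix(z, 3, 1, dimnames = list(names(z), "S1")))
  # singleton top-ranked set: walk (+1, -.5, -.5) -> ES = 1
  expect_equal(enrichment_score(rs$s[, 1], rs$rank[, 1], set_index = 1), 1)
  # singleton bottom-ranked set: mirrored walk -> ES = -1
  expect_equal(enrichment_score(rs$s[, 1], rs$rank[, 1], set_index = 3), -1)
  expect_error(enrichment_score(rs$s[, 1], rs$rank[, 1], set_index = 1:3),
               class = "circlinc_validation_error")
  expect_error(enrichment_score(rs$s[, 1], rs$rank[, 1], set_index = integer(0)),
               class = "circlinc_validation_error")

  # 6-gene toy, two sets, against the independent cumulative-walk oracle
  set.seed(5)
  z6 <- runif(6); names(z6) <- paste0("G", 1:6)
  rs6 <- rank_statistic(matrix(z6, 6, 1, dimnames = list(names(z6), "S1")))
  for (members in list(c("G2", "G5"), c("G1", "G3", "G6"))) {
    es <- enrichment_score(rs6$s[, 1], rs6$rank[, 1],
                           which(names(z6) %in% members))
    expect_equal(es, oracle_es(z6, members, names(z6)), tolerance = 1e-12)
  }
})

test_that("ES equals the exhaustive oracle for all small subsets", {
  set.seed(77)
  for (p in c(5, 8)) {
    z <- runif(p); names(z) <- paste0("G", seq_len(p))
    rs <- rank_statistic(matrix(z, p, 1, dimnames = list(names(z), "S1")))
    idx_all <- unlist(lapply(1:4, function(k) combn(p, k, simplify = FALSE)),
                      recursive = FALSE)
    for (idx in idx_all) {
      if (length(idx) == p) next
      expect_equal(enrichment_score(rs$s[, 1], rs$rank[, 1], idx),
                   oracle_es(z, names(z)[idx], names(z)), tolerance = 1e-12)
    }
  }
})

test_that("top-half/bottom-half partitions give mirrored extreme scores", {
  z <- c(G1 = 0.95, G2 = 0.8, G3 = 0.6, G4 = 0.4, G5 = 0.2, G6 = 0.05)
  rs <- rank_statistic(matrix(z, 6, 1, dimnames = list(names(z), "S1")))
  expect_equal(enrichment_score(rs$s[, 1], rs$rank[, 1], 1:3), 1)
  expect_equal(enrichment_score(rs$s[, 1], rs$rank[, 1], 4:6), -1)
})

test_that("gsva_matrix is bounded, deterministic, and permutation-invariant", {
  set.seed(9)
  vals <- matrix(abs(rnorm(40 * 6, 5)), 40, 6,
                 dimnames = list(sprintf("G%03d", 1:40), sprintf("S%02d", 1:6)))
  expr <- cohort_expr(vals, c(rep("term", 3), rep("sPTB", 3)))
  sets <- gene_set_collection(list(S1 = sprintf("G%03d", 1:8),
                                   S2 = sprintf("G%03d", 15:40),
                                   TINY = "G001",
                                   ALIEN = c("NOPE1", "NOPE2")))
  ps <- gsva_matrix(expr, sets, min_size = 2)
  expect_setequal(rownames(ps$values), c("S1", "S2"))
  expect_setequal(attr(ps, "filtered_sets"), c("TINY", "ALIEN"))
  expect_true(all(abs(ps$values) <= 1))
  expect_equal(ps$values, gsva_matrix(expr, sets)$values)

  # permuting genes and samples permutes the output accordingly
  gp <- sample(40); sp <- sample(6)
  exprp <- cohort_expr(vals[gp, sp], as.character(expr$group)[sp])
  psp <- gsva_matrix(exprp, sets)
  expect_equal(psp$values[, colnames(ps$values)], ps$values, tolerance = 1e-12)

  expect_error(gene_set_collection(list(S1 = "G001", S1 = "G002")),
               class = "circlinc_validation_error")
  expect_error(gsva_matrix(expr, gene_set_collection(list(A = "NOPE"))),
               class = "circlinc_validation_error")
})

test_that("bounds hold across random data", {
  set.seed(123)
  for (i in 1:25) {
    vals <- matrix(rnorm(30 * 4, 5), 30, 4,
                   dimnames = list(sprintf("G%03d", 1:30), sprintf("S%d", 1:4)))
    expr <- cohort_expr(abs(vals), c("term", "term", "sPTB", "sPTB"))
    sets <- gene_set_collection(list(
      A = sample(rownames(vals), 5), B = sample(rownames(vals), 12)))
    ps <- gsva_matrix(expr, sets)
    expect_true(all(abs(ps$values) <= 1))
  }
})

test_that("a jointly up-shifted set scores highest in the shifted sample", {
  set.seed(41)
  vals <- matrix(rnorm(30 * 5, 5, 0.3), 30, 5,
                 dimnames = list(sprintf("G%03d", 1:30), sprintf("S%d", 1:5)))
  members <- sprintf("G%03d", 1:6)
  vals[members, 5] <- vals[members, 5] + 3   # joint up-shift in sample 5
  expr <- cohort_expr(abs(vals), c(rep("term", 3), rep("sPTB", 2)))
  ps <- gsva_matrix(expr, gene_set_collection(list(UP = members)))
  expect_equal(which.max(ps$values["UP", ]), c(S5 = 5L))
})

test_that("pathway screens recover planted sets and respect idempotence", {
  # two small cohorts sharing planted structure
  truth <- small_truth()
  sc1 <- generate_cohort(small_spec(301), truth)
  sc2 <- generate_cohort(small_spec(302), truth)
  sets <- generate_gene_sets(gene_universe(small_spec(1)), truth,
                             n_sets = 30, n_enriched = 4, seed = 11)
  run_one <- function(sc) {
    r <- run_cohort(sc$counts)
    list(ps = gsva_matrix(r$logcpm, sets),
         linc = compute_risk_score(
           r$logcpm, build_panel(
             data.frame(id = truth$planted_circadian_lincRNAs,
                        effect = rep(-1, 5)), r$logcpm)))
  }
  a <- run_one(sc1); b <- run_one(sc2)
  res <- pathway_de_and_correlation(a$ps, b$ps, a$linc, b$linc)
  expect_true(all(attr(sets, "enriched") %in% res$overlap$common_features))
  expect_equal(sum(res$n_common), length(res$overlap$common_features))

  # identical cohorts: overlap equals each cohort's significant set
  res_same <- pathway_de_and_correlation(a$ps, a$ps, a$linc, a$linc)
  expect_setequal(res_same$overlap$common_features,
                  res_same$cohort_a$significant$id)
})
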