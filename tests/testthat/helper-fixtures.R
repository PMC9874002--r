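# Small fixtures built in code.

# deterministic toy count cohort: n_genes x (n1 term + n2 sPTB)
toy_counts <- function(n_genes = 20, n1 = 4, n2 = 4, seed = 101,
                       lambda = 80, gene_ids = NULL) {
  set.seed(seed)
  n <- n1 + n2
  counts <- matrix(rpois(n_genes * n, lambda), n_genes, n)
  rownames(counts) <- gene_ids %||% sprintf("G%03d", seq_len(n_genes))
  colnames(counts) <- sprintf("S%02d", seq_len(n))
  cohort_counts(counts, c(rep("term", n1), rep("sPTB", n2)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small planted truth for fast end-to-end runs
small_truth <- function(n_factor = 30) {
  clock <- c(NPAS2 = -1.5, NR1D1 = -1.5, NR1D2 = -1.5, PER3 = -1.5, RORA = -1.5)
  lincs <- sprintf("LINC%05d", 1:5)
  fact <- sprintf("GENE%04d", seq_len(n_factor))
  planted_truth(
    de_genes = c(clock, setNames(rep(-2, 5), lincs), setNames(rep(-1.5, n_factor), fact)),
    lincRNAs = lincs, correlation_strength = 0.6, factor_genes = fact)
}

small_spec <- function(seed, n_case = 8, n_control = 8, n_genes = 600,
                       n_lincRNAs = 40) {
  cohort_spec(n_case = n_case, n_control = n_control, n_genes = n_genes,
              n_lincRNAs = n_lincRNAs, lib_size_mean = 1e6, seed = seed)
}
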