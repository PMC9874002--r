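# Synthetic two-cohort study generator. Counts are negative-binomial around
# log-normal baseline abundances; planted effects are (i) group log-fold-
# changes on selected genes and (ii) a per-sample Gaussian latent factor
# loading, on the log2-mean scale, on the planted lincRNAs, the down-regulated
# clock genes, and a designated pool of "factor genes". The shared loading
# makes the lincRNAs co-vary with the clock genes, so they end up negatively
# correlated with the reflected clock-gene risk score, mirroring the
# structure the pipeline is designed to detect.

#' Specification of one synthetic cohort
#'
#' @param n_case Number of sPTB (case) samples, at least 2.
#' @param n_control Number of term (control) samples, at least 2.
#' @param n_genes Total number of genes in the universe (clock genes and
#'   lincRNAs included).
#' @param n_lincRNAs Number of lincRNA features (symbols `LINC00001`, ...).
#' @param clock_symbols Clock gene symbols present in the universe.
#' @param lib_size_mean Expected library size in reads.
#' @param lib_size_cv Coefficient of variation of library sizes; 0 gives
#'   equal target depths.
#' @param nb_dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be positive.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   gene abundances; the heavy right tail makes the CPM filter non-trivial.
#' @param seed Integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_case, n_control, n_genes = 2000L, n_lincRNAs = 100L,
                        clock_symbols = clock_gene_symbols(),
                        lib_size_mean = 2e6, lib_size_cv = 0.2,
                        nb_dispersion = 0.1,
                        baseline_meanlog = 2, baseline_sdlog = 2.5,
                        seed = 1L) {
  if (!is_count(n_case) || !is_count(n_control) || n_case < 2 || n_control < 2)
    cl_stop("need at least 2 case and 2 control samples", "circlinc_spec_error")
  if (!is_count(n_genes) || !is_count(n_lincRNAs))
    cl_stop("'n_genes' and 'n_lincRNAs' must be non-negative integers",
            "circlinc_spec_error")
  if (n_genes < n_lincRNAs + length(clock_symbols))
    cl_stop("'n_genes' must cover the lincRNAs and clock genes",
            "circlinc_spec_error")
  if (!is.numeric(nb_dispersion) || nb_dispersion <= 0)
    cl_stop("'nb_dispersion' must be positive", "circlinc_spec_error")
  if (!is.numeric(lib_size_mean) || lib_size_mean <= 0)
    cl_stop("'lib_size_mean' must be positive", "circlinc_spec_error")
  if (!is.numeric(lib_size_cv) || lib_size_cv < 0)
    cl_stop("'lib_size_cv' must be >= 0", "circlinc_spec_error")
  structure(list(n_case = as.integer(n_case), n_control = as.integer(n_control),
                 n_genes = as.integer(n_genes),
                 n_lincRNAs = as.integer(n_lincRNAs),
                 clock_symbols = clock_symbols,
                 lib_size_mean = lib_size_mean, lib_size_cv = lib_size_cv,
                 nb_dispersion = nb_dispersion,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Gene universe implied by a cohort specification
#'
#' Clock symbols first, then `LINC` symbols, then filler `GENE` symbols.
#'
#' @param spec A [cohort_spec()].
#' @return Character vector of `spec$n_genes` unique gene symbols.
#' @export
gene_universe <- function(spec) {
  n_other <- spec$n_genes - spec$n_lincRNAs - length(spec$clock_symbols)
  c(spec$clock_symbols,
    sprintf("LINC%05d", seq_len(spec$n_lincRNAs)),
    sprintf("GENE%04d", seq_len(n_other)))
}

#' Planted ground truth for a synthetic study
#'
#' @param de_genes Named numeric vector: signed log2 fold change (sPTB vs
#'   term) per planted gene; genes absent from the map have no group effect.
#' @param lincRNAs Character vector of planted "circadian" lincRNA symbols;
#'   each must appear in `de_genes` with a negative log2 fold change
#'   (down-regulated in sPTB).
#' @param correlation_strength Loading (in log2 units per factor SD) of the
#'   shared latent factor, in `[0, 1]`; 0 disables the factor.
#' @param factor_genes Additional (non-lincRNA) genes that carry the latent
#'   factor; gene sets seeded from this pool become score-correlated
#'   pathways.
#' @return An object of class `planted_truth` with fields `de_genes`,
#'   `planted_circadian_lincRNAs`, `clock_effect_directions`,
#'   `correlation_strength`, and `factor_genes`.
#' @export
planted_truth <- function(de_genes = numeric(0), lincRNAs = character(0),
                          correlation_strength = 0,
                          factor_genes = character(0)) {
  if (length(de_genes) && (is.null(names(de_genes)) || any(names(de_genes) == "")))
    cl_stop("'de_genes' must be a named numeric vector", "circlinc_spec_error")
  if (!is.numeric(correlation_strength) || correlation_strength < 0 ||
      correlation_strength > 1)
    cl_stop("'correlation_strength' must lie in [0, 1]", "circlinc_spec_error")
  if (length(lincRNAs)) {
    lfc <- de_genes[lincRNAs]
    if (any(is.na(lfc)) || any(lfc >= 0))
      cl_stop("every planted lincRNA needs a negative log2 fold change in 'de_genes'",
              "circlinc_spec_error")
  }
  clock_in <- intersect(names(de_genes), clock_gene_symbols())
  dirs <- ifelse(de_genes[clock_in] > 0, "up", "down")
  names(dirs) <- clock_in
  structure(list(de_genes = de_genes,
                 planted_circadian_lincRNAs = lincRNAs,
                 clock_effect_directions = dirs,
                 correlation_strength = correlation_strength,
                 factor_genes = factor_genes),
            class = "planted_truth")
}

#' Default planted truth used by the worked examples and recovery studies
#'
#' Plants five down-regulated clock genes (log2FC -1.5), five down-regulated
#' lincRNAs (log2FC -2), and a pool of 50 ordinary factor genes
#' (log2FC -1.5) that all share the latent factor with loading 0.6.
#'
#' @return A [planted_truth()] object.
#' @export
default_truth <- function() {
  clock <- c(NPAS2 = -1.5, NR1D1 = -1.5, NR1D2 = -1.5, PER3 = -1.5, RORA = -1.5)
  lincs <- sprintf("LINC%05d", 1:5)
  fact <- sprintf("GENE%04d", 1:50)
  de <- c(clock,
          stats::setNames(rep(-2, length(lincs)), lincs),
          stats::setNames(rep(-1.5, length(fact)), fact))
  planted_truth(de_genes = de, lincRNAs = lincs,
                correlation_strength = 0.6, factor_genes = fact)
}

#' Null truth: no planted effects, no latent factor
#' @return A [planted_truth()] object with empty effect maps.
#' @export
null_truth <- function() planted_truth()

# genes on which the latent factor loads (all with the same sign: the factor
# raises the lincRNAs together with the down-regulated clock genes, which
# reflects into a negative lincRNA-vs-risk-score correlation)
factor_loaded_genes <- function(truth) {
  down_clock <- names(truth$clock_effect_directions)[
    truth$clock_effect_directions == "down"]
  unique(c(truth$planted_circadian_lincRNAs, down_clock, truth$factor_genes))
}

#' Generate one synthetic cohort of negative-binomial counts
#'
#' Baseline abundances are log-normal; planted genes are re-drawn from the
#' 40th-90th baseline percentile band so that they survive the CPM filter.
#' Case-group means are multiplied by `2^lfc` for planted genes; the latent
#' factor adds `correlation_strength * f_j` to the log2 mean of each loaded
#' gene, with `f_j ~ N(0, 1)` per sample. Per-sample abundances are
#' renormalized to proportions and scaled to log-normal library sizes before
#' negative-binomial sampling, so column sums track the target depths.
#'
#' @param spec A [cohort_spec()].
#' @param truth A [planted_truth()]; all referenced genes must exist in
#'   [gene_universe()] of `spec`.
#' @return A list of class `synthetic_cohort` with elements `counts` (a
#'   [cohort_counts()] with term samples first), `truth`, and
#'   `lib_size_target` (the sampled target depths).
#' @export
#' @examples
#' sc <- generate_cohort(cohort_spec(4, 4, n_genes = 300, n_lincRNAs = 20),
#'                       null_truth())
#' dim(sc$counts)
generate_cohort <- function(spec, truth) {
  if (!inherits(spec, "cohort_spec")) cl_stop("'spec' must be a cohort_spec",
                                              "circlinc_spec_error")
  if (!inherits(truth, "planted_truth")) cl_stop("'truth' must be a planted_truth",
                                                 "circlinc_spec_error")
  genes <- gene_universe(spec)
  referenced <- unique(c(names(truth$de_genes),
                         truth$planted_circadian_lincRNAs, truth$factor_genes))
  unknown <- setdiff(referenced, genes)
  if (length(unknown))
    cl_stop(sprintf("truth references genes outside the universe: %s",
                    paste(utils::head(unknown, 5), collapse = ", ")),
            "circlinc_spec_error")

  set.seed(spec$seed)
  n <- spec$n_control + spec$n_case
  group <- c(rep("term", spec$n_control), rep("sPTB", spec$n_case))
  samples <- sprintf("S%03d", seq_len(n))

  # baseline abundances; planted and clock genes are kept comfortably
  # expressed so the planted structure is not erased by the CPM filter
  m <- stats::rlnorm(spec$n_genes, spec$baseline_meanlog, spec$baseline_sdlog)
  names(m) <- genes
  anchored <- unique(c(referenced, intersect(spec$clock_symbols, genes)))
  m[anchored] <- stats::qlnorm(stats::runif(length(anchored), 0.40, 0.90),
                               spec$baseline_meanlog, spec$baseline_sdlog)

  if (spec$lib_size_cv == 0) {
    lib <- rep(spec$lib_size_mean, n)
  } else {
    s2 <- log(1 + spec$lib_size_cv^2)
    lib <- stats::rlnorm(n, log(spec$lib_size_mean) - s2 / 2, sqrt(s2))
  }

  f <- stats::rnorm(n)

  log2mu <- matrix(log2(m), spec$n_genes, n, dimnames = list(genes, samples))
  is_case <- group == "sPTB"
  if (length(truth$de_genes))
    log2mu[names(truth$de_genes), is_case] <-
      log2mu[names(truth$de_genes), is_case] + truth$de_genes
  loaded <- factor_loaded_genes(truth)
  if (length(loaded) && truth$correlation_strength > 0)
    log2mu[loaded, ] <- log2mu[loaded, ] +
      truth$correlation_strength * rep(f, each = length(loaded))

  mu <- 2^log2mu
  mu <- sweep(mu, 2, colSums(mu), "/")
  mu <- sweep(mu, 2, lib, "*")
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion),
                   nrow = spec$n_genes, dimnames = dimnames(mu))

  structure(list(counts = cohort_counts(counts, group), truth = truth,
                 lib_size_target = stats::setNames(lib, samples)),
            class = "synthetic_cohort")
}

#' Generate a synthetic gene-set collection with planted enrichment
#'
#' `n_enriched` sets draw a fixed fraction of their members from the genes
#' that carry the planted latent factor, so their per-sample enrichment
#' scores co-vary with the lincRNA-based risk score; the remaining sets are
#' uniform draws from the universe.
#'
#' @param universe Character vector of gene symbols available to the sets.
#' @param truth A [planted_truth()]; its `factor_genes` form the enrichment
#'   pool.
#' @param n_sets Number of sets to generate.
#' @param set_size_range Integer vector `c(min, max)` of set sizes.
#' @param n_enriched Number of factor-seeded sets (must not exceed `n_sets`).
#' @param seed Integer seed.
#' @param factor_member_fraction Fraction of an enriched set drawn from the
#'   factor pool (capped by the pool size).
#' @return A [gene_set_collection()] whose first `n_enriched` sets are the
#'   planted ones; their names are recorded in the `enriched` attribute.
#' @export
generate_gene_sets <- function(universe, truth, n_sets = 60L,
                               set_size_range = c(15L, 25L), n_enriched = 6L,
                               seed = 1L, factor_member_fraction = 0.85) {
  if (!is_count(n_sets) || n_sets < 1)
    cl_stop("'n_sets' must be a positive integer", "circlinc_spec_error")
  if (!is_count(n_enriched) || n_enriched > n_sets)
    cl_stop("'n_enriched' must be an integer <= 'n_sets'", "circlinc_spec_error")
  lo <- as.integer(min(set_size_range)); hi <- as.integer(max(set_size_range))
  if (lo < 1 || hi > length(universe))
    cl_stop("set sizes must lie in [1, |universe|]", "circlinc_spec_error")
  pool <- intersect(truth$factor_genes, universe)
  if (n_enriched > 0 && length(pool) == 0)
    cl_stop("cannot plant enriched sets: truth has no factor genes in the universe",
            "circlinc_spec_error")

  set.seed(seed)
  sizes <- lo + sample.int(hi - lo + 1L, n_sets, replace = TRUE) - 1L
  rest <- setdiff(universe, pool)
  sets <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    if (i <= n_enriched) {
      k <- min(length(pool), max(1L, round(factor_member_fraction * sizes[i])))
      sets[[i]] <- c(sample(pool, k),
                     if (sizes[i] > k) sample(rest, sizes[i] - k))
    } else {
      sets[[i]] <- sample(universe, sizes[i])
    }
  }
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  out <- gene_set_collection(sets, descriptions = ifelse(
    seq_len(n_sets) <= n_enriched, "planted factor set", "random set"))
  attr(out, "enriched") <- names(sets)[seq_len(n_enriched)]
  out
}

#' Generate a matched two-cohort synthetic study
#'
#' Both cohorts share one planted truth (the replication scenario) but are
#' otherwise independent draws. Cohort shapes default to the two study
#' designs the pipeline targets: 10 term vs 20 sPTB, and 16 vs 16.
#'
#' @param truth A [planted_truth()] shared by both cohorts.
#' @param seed Integer master seed; the two cohorts and the gene sets use
#'   offset sub-seeds.
#' @param spec1,spec2 Optional [cohort_spec()] overrides (their `seed`
#'   fields are replaced by offsets of `seed`).
#' @param gene_sets Logical; also generate a gene-set collection?
#' @param ... Passed on to [generate_gene_sets()].
#' @return List of class `synthetic_study` with `cohort1`, `cohort2`,
#'   `truth`, and optionally `gene_sets`.
#' @export
generate_study <- function(truth = default_truth(), seed = 1L,
                           spec1 = NULL, spec2 = NULL, gene_sets = TRUE, ...) {
  spec1 <- spec1 %||% cohort_spec(n_case = 20, n_control = 10)
  spec2 <- spec2 %||% cohort_spec(n_case = 16, n_control = 16)
  spec1$seed <- as.integer(seed)
  spec2$seed <- as.integer(seed + 500000L)
  c1 <- generate_cohort(spec1, truth)
  c2 <- generate_cohort(spec2, truth)
  gs <- NULL
  if (gene_sets)
    gs <- generate_gene_sets(union(gene_universe(spec1), gene_universe(spec2)),
                             truth, seed = as.integer(seed + 1000000L), ...)
  structure(list(cohort1 = c1, cohort2 = c2, truth = truth, gene_sets = gs),
            class = "synthetic_study")
}
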