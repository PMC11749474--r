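# Shared fixtures, all built in code at test time.

suppressPackageStartupMessages({
  library(Matrix)
  library(SingleCellExperiment)
})

# Small SCE from a dense matrix; metadata defaults to one sample.
toy_sce <- function(counts, sample = "s1", region = "SVZ", age_months = 2,
                    sex = "F", normalize = TRUE, scale = 1e6) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  n <- ncol(counts)
  meta <- data.frame(cell_id = colnames(counts),
                     sample = rep_len(sample, n),
                     region = rep_len(region, n),
                     age_months = rep_len(age_months, n),
                     sex = rep_len(sex, n), stringsAsFactors = FALSE)
  sce <- as_niche_sce(Matrix(counts, sparse = TRUE), meta)
  if (normalize) sce <- normalize_counts(sce, scale)
  sce
}

# Default-condition simulation shared across test files (computed once).
.fixture_env <- new.env(parent = emptyenv())
cached_default_sim <- function() {
  if (is.null(.fixture_env$default_sim)) {
    res <- simulate_niche(niche_sim_config(seed = 1L))
    sce <- normalize_counts(
      qc_filter(res$sce, qc_thresholds(min_genes = 300))$sce)
    meta <- as.data.frame(SummarizedExperiment::colData(sce))
    truth_type <- res$truth$cells$type[match(colnames(sce),
                                             res$truth$cells$cell_id)]
    names(truth_type) <- colnames(sce)
    .fixture_env$default_sim <- list(sim = res, sce = sce, meta = meta,
                                     truth_type = truth_type)
  }
  .fixture_env$default_sim
}

# Adjusted Rand index (used where mclust is unavailable).
rand_index_adj <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
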