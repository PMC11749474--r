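#' Dispersion-based highly variable genes
#'
#' Ranks genes by mean-binned standardized dispersion (variance/mean) of
#' the log-normalized layer, the classic single-cell variable-gene
#' statistic, and returns the top `n` gene names.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param n number of genes to keep.
#' @param n_bins mean-expression bins used to standardize dispersion.
#' @return character vector of gene names.
#' @export
variable_genes <- function(sce, n = 2000, n_bins = 20) {
  logc <- .logcounts(sce)
  mu <- Matrix::rowMeans(logc)
  v <- .row_vars_sparse(logc, mu)
  disp <- ifelse(mu > 0, v / mu, 0)
  bin <- cut(rank(mu, ties.method = "first"), breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bin)) {
    i <- bin == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  names(sort(z, decreasing = TRUE))[seq_len(min(n, length(z)))]
}

.row_vars_sparse <- function(m, mu = Matrix::rowMeans(m)) {
  n <- ncol(m)
  sq <- Matrix::rowSums(m^2)
  (sq - n * mu^2) / (n - 1)
}

#' Graph-based clustering of cells
#'
#' Standard single-cell clustering pipeline: dispersion-based variable-gene
#' selection, per-gene standardization, principal-component reduction,
#' shared-nearest-neighbor graph, and Louvain modularity optimization at a
#' given resolution. Fixed seeds give identical labels.
#'
#' @param sce normalized `SingleCellExperiment` (log layer required).
#' @param n_top_genes number of variable genes.
#' @param n_components number of principal components.
#' @param k_neighbors neighbors for the SNN graph (must be < number of
#'   cells).
#' @param resolution Louvain resolution; lower values merge communities.
#' @param seed integer seed controlling PCA initialization and Louvain.
#' @return factor of cluster labels, named by cell id.
#' @export
cluster_cells <- function(sce, n_top_genes = 2000, n_components = 30,
                          k_neighbors = 15, resolution = 1, seed = 0) {
  if (k_neighbors >= ncol(sce))
    stop("k_neighbors must be smaller than the number of cells")
  hvg <- variable_genes(sce, n = n_top_genes)
  n_components <- min(n_components, length(hvg) - 1, ncol(sce) - 1)
  set.seed(seed)
  pcs <- scater::calculatePCA(sce, ncomponents = n_components,
                              subset_row = hvg, scale = TRUE,
                              exprs_values = "logcounts")
  g <- scran::buildSNNGraph(t(pcs), k = k_neighbors, transposed = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- factor(igraph::membership(cl))
  names(labels) <- colnames(sce)
  labels
}
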