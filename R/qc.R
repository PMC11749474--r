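#' QC thresholds
#'
#' Container for quality-control thresholds. Defaults are this package's
#' choices for 10x-style mouse brain data and are fully overridable.
#'
#' @param min_genes,max_genes admissible range of detected genes per cell.
#' @param max_mito maximum mitochondrial UMI fraction per cell.
#' @param min_cells minimum number of cells a gene must be detected in.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 500, max_genes = 6000,
                          max_mito = 0.10, min_cells = 3) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  if (max_mito < 0 || max_mito > 1) stop("max_mito must be in [0, 1]")
  if (min_genes < 0 || min_cells < 0) stop("thresholds must be >= 0")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito, min_cells = min_cells),
            class = "qc_thresholds")
}

#' Quality-control filtering of cells and genes
#'
#' Removes cells whose detected-gene count falls outside
#' `[min_genes, max_genes]` or whose mitochondrial UMI fraction exceeds
#' `max_mito`, then removes genes detected in fewer than `min_cells` of the
#' surviving cells. The order (cells first, then genes) is fixed, so the
#' result is deterministic.
#'
#' @param sce `SingleCellExperiment` with a counts layer.
#' @param thresholds a [qc_thresholds()].
#' @param mito_prefix feature-name prefix identifying mitochondrial genes
#'   (mouse default `"mt-"`).
#' @return list with `sce` (filtered) and `report` (per-criterion removal
#'   counts and threshold echo).
#' @export
qc_filter <- function(sce, thresholds = qc_thresholds(),
                      mito_prefix = "mt-") {
  counts <- .counts(sce)
  detected <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  is_mito <- startsWith(rownames(counts), mito_prefix)
  mito_frac <- if (any(is_mito)) {
    mf <- Matrix::colSums(counts[is_mito, , drop = FALSE]) / pmax(total, 1)
    mf[total == 0] <- 0
    mf
  } else rep(0, ncol(counts))

  low <- detected < thresholds$min_genes
  high <- detected > thresholds$max_genes
  mito_fail <- mito_frac > thresholds$max_mito
  keep_cells <- !(low | high | mito_fail)
  if (!any(keep_cells)) stop("no cells survive QC")
  sub <- counts[, keep_cells, drop = FALSE]
  gene_detected <- Matrix::rowSums(sub > 0)
  keep_genes <- gene_detected >= thresholds$min_cells

  out <- sce[keep_genes, keep_cells]
  report <- list(
    n_cells_in = ncol(counts), n_genes_in = nrow(counts),
    cells_low_genes = sum(low), cells_high_genes = sum(high),
    cells_high_mito = sum(mito_fail),
    cells_removed = sum(!keep_cells), genes_removed = sum(!keep_genes),
    n_cells_out = ncol(out), n_genes_out = nrow(out),
    thresholds = unclass(thresholds), mito_prefix = mito_prefix)
  list(sce = out, report = report)
}

#' Per-cell normalization and log transform
#'
#' Scales each cell's counts to sum to `scale` (counts-per-million for the
#' default `1e6`; for 3'-tag UMI data this carries no gene-length term) and
#' adds a natural-log `log1p` layer. Cells with zero total counts are
#' flagged in `colData(sce)$zero_total` and left all-zero.
#'
#' @param sce `SingleCellExperiment` with a counts layer.
#' @param scale target per-cell sum (must be positive).
#' @return the object with `cpm` and `logcounts` assays added.
#' @export
normalize_counts <- function(sce, scale = 1e6) {
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0)
    stop("scale must be a positive number")
  counts <- .counts(sce)
  total <- Matrix::colSums(counts)
  fac <- ifelse(total > 0, scale / total, 0)
  cpm <- counts %*% Matrix::Diagonal(x = fac)
  dimnames(cpm) <- dimnames(counts)
  logc <- cpm
  logc@x <- log1p(logc@x)
  SummarizedExperiment::assay(sce, "cpm") <- cpm
  SummarizedExperiment::assay(sce, "logcounts") <- logc
  SummarizedExperiment::colData(sce)$zero_total <- total == 0
  S4Vectors::metadata(sce)$layers <- c("counts", "cpm", "logcounts")
  S4Vectors::metadata(sce)$normalization_scale <- scale
  sce
}
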