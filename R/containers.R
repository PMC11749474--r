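#' Build a niche SingleCellExperiment from counts and cell metadata
#'
#' Wraps a sparse UMI count matrix and per-cell metadata into a
#' [SingleCellExperiment::SingleCellExperiment] with the column annotations
#' the rest of the pipeline expects (`sample`, `region`, `age_months`,
#' `sex`).
#'
#' @param counts sparse (or dense) gene x cell matrix of non-negative
#'   integer UMI counts with unique row and column names.
#' @param cell_meta `data.frame` with one row per cell. Must contain a
#'   `cell_id` column matching `colnames(counts)` (any order) plus
#'   `sample`, `region`, `age_months` and `sex`.
#' @return A `SingleCellExperiment` with a `counts` assay.
#' @export
as_niche_sce <- function(counts, cell_meta) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids in counts")
  if (anyDuplicated(colnames(counts)))
    stop("duplicate cell ids in counts")
  if (any(counts@x < 0))
    stop("counts must be non-negative")
  if (any(counts@x != round(counts@x)))
    stop("counts layer must hold integers")
  required <- c("cell_id", "sample", "region", "age_months", "sex")
  missing_cols <- setdiff(required, colnames(cell_meta))
  if (length(missing_cols))
    stop("cell_meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (!setequal(cell_meta$cell_id, colnames(counts)))
    stop("cell_meta does not cover exactly the cells in counts")
  cell_meta <- cell_meta[match(colnames(counts), cell_meta$cell_id), ,
                         drop = FALSE]
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(cell_meta, row.names = cell_meta$cell_id))
  S4Vectors::metadata(sce)$layers <- "counts"
  sce
}

#' @keywords internal
.counts <- function(sce) {
  if (!"counts" %in% SummarizedExperiment::assayNames(sce))
    stop("object has no counts layer")
  SummarizedExperiment::assay(sce, "counts")
}

#' @keywords internal
.logcounts <- function(sce) {
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce))
    stop("object has no normalized log layer; run normalize_counts() first")
  SummarizedExperiment::assay(sce, "logcounts")
}

#' @keywords internal
.cpm <- function(sce) {
  if (!"cpm" %in% SummarizedExperiment::assayNames(sce))
    stop("object has no normalized layer; run normalize_counts() first")
  SummarizedExperiment::assay(sce, "cpm")
}

#' @keywords internal
.cell_meta <- function(sce) {
  as.data.frame(SummarizedExperiment::colData(sce))
}
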