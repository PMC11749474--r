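#' Default cell-cycle phase gene sets
#'
#' Compact mouse S-phase and G2/M gene lists covering the canonical
#' proliferation markers (Mcm2, Pcna for S; Ube2c, Hmgb2, Mki67, Top2a for
#' G2/M). Users can substitute full lists via plain-text or YAML files.
#'
#' @return list with `s` and `g2m` character vectors.
#' @export
default_cycle_genes <- function() {
  list(
    s = c("Mcm2", "Mcm6", "Pcna", "Rrm2", "Uhrf1", "Gins2", "Slbp", "Cdc6"),
    g2m = c("Ube2c", "Hmgb2", "Mki67", "Top2a", "Ccnb1", "Cdk1", "Cenpa",
            "Birc5", "Aurka", "Plk1"))
}

#' Read a gene set from a one-gene-per-line text file
#' @param path text file, one gene symbol per line; blank lines and lines
#'   starting with `#` are skipped.
#' @return character vector.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Binned-control module score
#'
#' Scores each cell for a gene program as the mean log-normalized
#' expression of the set minus the mean over control genes drawn (seeded,
#' without replacement) from expression-magnitude bins matched to the set's
#' genes. This background subtraction makes scores comparable across cells
#' with different depths and across programs of different baseline
#' expression.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param genes gene set to score.
#' @param n_bins number of mean-expression bins (>= 2).
#' @param n_ctrl control genes sampled per set gene.
#' @param seed integer seed for control sampling.
#' @return named numeric vector of per-cell scores.
#' @export
module_score <- function(sce, genes, n_bins = 25, n_ctrl = 50, seed = 0) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  logc <- .logcounts(sce)
  present <- intersect(genes, rownames(logc))
  absent <- setdiff(genes, rownames(logc))
  if (length(absent))
    warning("gene(s) absent from matrix: ", paste(absent, collapse = ", "))
  if (!length(present)) stop("no usable genes in the set")

  avg <- Matrix::rowMeans(logc)
  bin <- cut(rank(avg, ties.method = "first"),
             breaks = min(n_bins, nrow(logc)), labels = FALSE)
  names(bin) <- rownames(logc)

  set.seed(seed)
  ctrl <- character()
  for (g in present) {
    pool <- setdiff(names(bin)[bin == bin[g]], present)
    if (!length(pool)) next
    ctrl <- c(ctrl, sample(pool, min(n_ctrl, length(pool))))
  }
  ctrl <- unique(ctrl)
  if (!length(ctrl))
    stop("no control genes available; matrix too small for binned controls")
  set_mean <- Matrix::colMeans(logc[present, , drop = FALSE])
  ctrl_mean <- Matrix::colMeans(logc[ctrl, , drop = FALSE])
  score <- set_mean - ctrl_mean
  names(score) <- colnames(logc)
  score
}

#' Assign cell-cycle phase from S and G2/M scores
#'
#' A cell with both scores at or below `threshold` is called G1; otherwise
#' the phase of the larger score wins. An exact tie above the threshold is
#' called S with a warning.
#'
#' @param s_score,g2m_score per-cell module scores (finite).
#' @param threshold score floor below which a cell is non-cycling.
#' @return character vector of phases in `{"G1", "S", "G2M"}`.
#' @export
assign_phase <- function(s_score, g2m_score, threshold = 0) {
  stopifnot(length(s_score) == length(g2m_score),
            all(is.finite(s_score)), all(is.finite(g2m_score)))
  phase <- rep("G1", length(s_score))
  cycling <- s_score > threshold | g2m_score > threshold
  tie <- cycling & s_score == g2m_score
  if (any(tie))
    warning(sum(tie), " cell(s) with exactly tied scores assigned to S")
  phase[cycling] <- ifelse(s_score[cycling] >= g2m_score[cycling], "S", "G2M")
  phase
}

#' Score cells for cell-cycle phase
#'
#' Computes binned-control module scores for the S and G2/M programs and
#' assigns each cell a phase via [assign_phase()].
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param s_genes,g2m_genes disjoint, nonempty phase gene sets.
#' @param n_bins,n_ctrl,seed passed to [module_score()].
#' @param threshold passed to [assign_phase()].
#' @return data.frame with `cell_id`, `s_score`, `g2m_score`, `phase`.
#' @export
score_cell_cycle <- function(sce, s_genes = default_cycle_genes()$s,
                             g2m_genes = default_cycle_genes()$g2m,
                             n_bins = 25, n_ctrl = 50, seed = 0,
                             threshold = 0) {
  if (length(intersect(s_genes, g2m_genes)))
    stop("s_genes and g2m_genes must be disjoint")
  s <- module_score(sce, s_genes, n_bins, n_ctrl, seed)
  g2m <- module_score(sce, g2m_genes, n_bins, n_ctrl, seed)
  data.frame(cell_id = colnames(sce), s_score = unname(s),
             g2m_score = unname(g2m),
             phase = assign_phase(s, g2m, threshold),
             stringsAsFactors = FALSE)
}
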