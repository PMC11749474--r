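#' Marker panels for niche cell types
#'
#' A marker panel maps each cell type to a positive marker gene set and an
#' optional negative set (genes the type must lack). The shipped SVZ panel
#' identifies NSCs by the stem-cell markers Nr2e1, Thbs4, Igfbp5 and Notum
#' while requiring the absence of the mature astrocyte genes Aqp4, Tril and
#' Grin2c; the DG panel uses Thrsp, Fabp7, Hopx and Nr2e1 with the same
#' astrocyte exclusions.
#'
#' @param region `"SVZ"` or `"DG"`.
#' @return list of class `marker_panel`: type -> list(positive, negative),
#'   with a `region` attribute.
#' @export
default_marker_panel <- function(region = c("SVZ", "DG")) {
  region <- match.arg(region)
  astro_neg <- c("Aqp4", "Tril", "Grin2c")
  nsc_pos <- if (region == "SVZ")
    c("Nr2e1", "Thbs4", "Igfbp5", "Notum") else
      c("Thrsp", "Fabp7", "Hopx", "Nr2e1")
  panel <- list(
    NSC = list(positive = nsc_pos, negative = astro_neg),
    Astrocyte = list(positive = c("Aqp4", "Tril", "Grin2c", "Slc1a3"),
                     negative = c("Thbs4", "Notum")),
    TAP = list(positive = c("Ascl1", "Egfr", "Hmgb2", "Mki67"),
               negative = character()),
    NB = list(positive = c("Dcx", "Stmn2", "Sox11"), negative = character()),
    OPC = list(positive = c("Pdgfra", "Cspg4", "Olig1"),
               negative = character()),
    Oligodendrocyte = list(positive = c("Plp1", "Mbp", "Mog"),
                           negative = character()),
    Microglia = list(positive = c("Cx3cr1", "C1qa", "Tmem119"),
                     negative = character()),
    Endothelial = list(positive = c("Cldn5", "Pecam1", "Flt1"),
                       negative = character()))
  .validate_marker_panel(panel)
  structure(panel, class = "marker_panel", region = region)
}

.validate_marker_panel <- function(panel) {
  for (tp in names(panel)) {
    pos <- panel[[tp]]$positive
    neg <- panel[[tp]]$negative
    if (!length(pos)) stop("marker panel: empty positive set for ", tp)
    if (length(intersect(pos, neg)))
      stop("marker panel: positive and negative sets overlap for ", tp)
  }
  invisible(TRUE)
}

#' Read a marker panel from YAML
#'
#' Expected layout: `type: {positive: [...], negative: [...]}` with an
#' optional top-level `region`.
#'
#' @param path YAML file.
#' @return `marker_panel`.
#' @export
read_marker_panel <- function(path) {
  y <- yaml::read_yaml(path)
  region <- y$region
  y$region <- NULL
  panel <- lapply(y, function(e)
    list(positive = as.character(e$positive %||% character()),
         negative = as.character(e$negative %||% character())))
  .validate_marker_panel(panel)
  structure(panel, class = "marker_panel", region = region %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign cell types to clusters from a marker panel
#'
#' For each cluster and candidate type, the score is the mean standardized
#' log expression of the positive markers minus `negative_weight` times the
#' mean for the negative markers; the cluster takes the arg-max type, or
#' `"unassigned"` when its best score falls below `floor`. Ties are broken
#' by lexicographic type name with a warning. Cells inherit their cluster's
#' label.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param labels cluster labels covering every cell (named or in column
#'   order).
#' @param panel a `marker_panel`.
#' @param floor minimum best score for assignment.
#' @param negative_weight weight of the negative-marker term.
#' @return list with `assignment` (data.frame cluster/type/score), `scores`
#'   (cluster x type matrix), and `cell_types` (per-cell character vector,
#'   named by cell id).
#' @export
assign_types <- function(sce, labels, panel, floor = 0.05,
                         negative_weight = 1) {
  logc <- .logcounts(sce)
  if (length(labels) != ncol(sce))
    stop("labels must cover every cell")
  labels <- as.character(labels)
  ## standardize genes across cells (zero-variance genes score 0)
  all_markers <- unique(unlist(lapply(panel, unlist)))
  present <- intersect(all_markers, rownames(logc))
  absent <- setdiff(all_markers, rownames(logc))
  if (length(absent))
    warning("marker gene(s) absent from matrix: ",
            paste(absent, collapse = ", "))
  sub <- as.matrix(logc[present, , drop = FALSE])
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1, stats::sd)
  z <- (sub - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0

  cl_levels <- sort(unique(labels))
  types <- names(panel)
  cluster_mean_z <- sapply(cl_levels, function(cl)
    rowMeans(z[, labels == cl, drop = FALSE]))
  if (is.null(dim(cluster_mean_z)))
    cluster_mean_z <- matrix(cluster_mean_z, nrow = length(present),
                             dimnames = list(present, cl_levels))

  scores <- matrix(NA_real_, length(cl_levels), length(types),
                   dimnames = list(cl_levels, types))
  for (tp in types) {
    pos <- intersect(panel[[tp]]$positive, present)
    neg <- intersect(panel[[tp]]$negative, present)
    if (!length(pos))
      stop("all positive markers for type ", tp, " are absent from matrix")
    pos_score <- colMeans(cluster_mean_z[pos, , drop = FALSE])
    neg_score <- if (length(neg))
      colMeans(cluster_mean_z[neg, , drop = FALSE]) else 0
    scores[, tp] <- pos_score - negative_weight * neg_score
  }
  ## a cluster with no marker expression at all carries no evidence for any
  ## type (its scores are artifacts of standardization): leave it unassigned
  marker_signal <- sapply(cl_levels, function(cl)
    sum(sub[, labels == cl, drop = FALSE]))
  assigned <- apply(scores, 1, function(s) {
    best <- max(s)
    if (best < floor) return("unassigned")
    hits <- sort(names(s)[s == best])
    if (length(hits) > 1)
      warning("tied marker scores; assigning lexicographically first type")
    hits[1]
  })
  assigned[marker_signal == 0] <- "unassigned"
  assignment <- data.frame(cluster = cl_levels, type = unname(assigned),
                           score = apply(scores, 1, max),
                           stringsAsFactors = FALSE)
  cell_types <- unname(assigned[labels])
  names(cell_types) <- colnames(sce)
  list(assignment = assignment, scores = scores, cell_types = cell_types)
}

#' Subcluster TAPs into cycle-active and cycle-inactive states
#'
#' Two-way k-means partition of TAP cells on the standardized log
#' expression of a cell-cycle gene set; the subcluster with the higher mean
#' cycle-gene score is labeled `cycle_active`.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param tap_cells cell ids of the TAP population (>= `min_cells`).
#' @param cycle_genes cell-cycle gene set.
#' @param seed integer seed for k-means.
#' @param min_cells minimum TAP count.
#' @return list with `labels` (per TAP cell), `fractions_by_age`
#'   (data.frame), `degenerate` flag.
#' @export
subcluster_tap <- function(sce, tap_cells, cycle_genes, seed = 0,
                           min_cells = 20) {
  sub <- .subcluster_matrix(sce, tap_cells, cycle_genes, min_cells)
  if (sub$degenerate)
    return(list(labels = NULL, fractions_by_age = NULL, degenerate = TRUE))
  set.seed(seed)
  km <- stats::kmeans(t(sub$z), centers = 2, nstart = 10)
  grp <- km$cluster
  mean_score <- tapply(colMeans(sub$z), grp, mean)
  active_grp <- names(which.max(mean_score))
  labels <- ifelse(grp == active_grp, "cycle_active", "cycle_inactive")
  names(labels) <- tap_cells
  meta <- .cell_meta(sce)[tap_cells, ]
  frac <- stats::aggregate(labels == "cycle_active",
                           by = list(age_months = meta$age_months), FUN = mean)
  names(frac)[2] <- "active_fraction"
  list(labels = labels, fractions_by_age = frac, degenerate = FALSE)
}

#' Subcluster NSCs into receptor-high and receptor-low states
#'
#' Agglomerative (Ward) clustering of NSCs on standardized log expression
#' of the curated receptor genes, cut at k = 2, followed by a k-means
#' boundary refinement initialized at the two Ward centroids (the Ward cut
#' fixes the partition structure; the refinement corrects greedy merge
#' errors near the boundary, which a single agglomerative pass cannot
#' revisit). The subcluster with higher mean receptor expression is `R_H`.
#' A per-receptor rank-sum differential test between the two subclusters is
#' returned.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param nsc_cells NSC cell ids (>= `min_cells`).
#' @param receptor_genes receptors from the curated ligand-receptor table
#'   that are present in the matrix.
#' @param min_cells minimum NSC count.
#' @return list with `labels`, `receptor_table` (differential test),
#'   `degenerate` flag.
#' @export
subcluster_receptor <- function(sce, nsc_cells, receptor_genes,
                                min_cells = 20) {
  sub <- .subcluster_matrix(sce, nsc_cells, receptor_genes, min_cells)
  if (sub$degenerate)
    return(list(labels = NULL, receptor_table = NULL, degenerate = TRUE))
  hc <- stats::hclust(stats::dist(t(sub$z)), method = "ward.D2")
  grp0 <- stats::cutree(hc, k = 2)
  if (min(table(grp0)) > 0 && length(unique(grp0)) == 2) {
    centers <- rbind(colMeans(t(sub$z)[grp0 == 1, , drop = FALSE]),
                     colMeans(t(sub$z)[grp0 == 2, , drop = FALSE]))
    grp <- tryCatch(stats::kmeans(t(sub$z), centers = centers)$cluster,
                    error = function(e) grp0)
  } else grp <- grp0
  logc <- .logcounts(sce)[sub$genes, nsc_cells, drop = FALSE]
  mean_expr <- tapply(Matrix::colMeans(logc), grp, mean)
  high_grp <- names(which.max(mean_expr))
  labels <- ifelse(grp == high_grp, "R_H", "R_L")
  names(labels) <- nsc_cells
  tbl <- wilcoxon_deg(sce, nsc_cells[labels == "R_H"],
                      nsc_cells[labels == "R_L"],
                      genes = sub$genes, min_fraction = 0,
                      min_abs_log2fc = 0)
  list(labels = labels, receptor_table = tbl, degenerate = FALSE)
}

.subcluster_matrix <- function(sce, cells, genes, min_cells) {
  if (length(cells) < min_cells)
    stop("need at least ", min_cells, " cells to subcluster (got ",
         length(cells), ")")
  logc <- .logcounts(sce)
  present <- intersect(genes, rownames(logc))
  absent <- setdiff(genes, rownames(logc))
  if (length(absent))
    warning("gene(s) absent from matrix: ", paste(absent, collapse = ", "))
  if (!length(present)) stop("no usable genes for subclustering")
  m <- as.matrix(logc[present, cells, drop = FALSE])
  sdv <- apply(m, 1, stats::sd)
  if (all(sdv == 0))
    return(list(degenerate = TRUE))
  z <- (m - rowMeans(m)) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  list(z = z, genes = present, degenerate = FALSE)
}

#' Per-sample cell-type composition
#'
#' Fraction of each sample's cells assigned to each type (including
#' `"unassigned"`); fractions sum to one per sample. Sample-level age, sex
#' and region are carried along from the cell metadata.
#'
#' @param cell_types per-cell type labels named by cell id.
#' @param cell_meta per-cell metadata (`cell_id`, `sample`, `region`,
#'   `age_months`, `sex`), e.g. `as.data.frame(colData(sce))`.
#' @return data.frame with one row per (sample, type).
#' @export
composition_by_sample <- function(cell_types, cell_meta) {
  cell_meta <- as.data.frame(cell_meta)
  stopifnot(all(names(cell_types) %in% cell_meta$cell_id))
  meta <- cell_meta[match(names(cell_types), cell_meta$cell_id), ]
  samples <- unique(meta$sample)
  types <- sort(unique(cell_types))
  rows <- list()
  for (s in samples) {
    i <- meta$sample == s
    n <- sum(i)
    if (n == 0) { warning("empty sample: ", s); next }
    tab <- table(factor(cell_types[i], levels = types))
    rows[[s]] <- data.frame(
      sample = s, cell_type = types,
      fraction = as.numeric(tab) / n, n_cells = as.numeric(tab),
      region = meta$region[i][1], age_months = meta$age_months[i][1],
      sex = meta$sex[i][1], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
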