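#' Read a curated ligand-receptor table
#'
#' Tab-separated table with columns `ligand`, `receptor` and optionally
#' `source`; (ligand, receptor) pairs must be unique and nonempty.
#'
#' @param path TSV file.
#' @return data.frame of class `lr_table`.
#' @export
read_lr_table <- function(path) {
  lr <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (!all(c("ligand", "receptor") %in% colnames(lr)))
    stop("ligand-receptor table needs 'ligand' and 'receptor' columns: ", path)
  if (!"source" %in% colnames(lr)) lr$source <- NA_character_
  if (any(!nzchar(lr$ligand)) || any(!nzchar(lr$receptor)))
    stop("empty gene symbol in ligand-receptor table")
  if (anyDuplicated(lr[, c("ligand", "receptor")]))
    stop("duplicate (ligand, receptor) pair in table")
  class(lr) <- c("lr_table", "data.frame")
  lr
}

#' The shipped curated ligand-receptor table
#'
#' Editable niche-signaling pairs covering the neurotrophin (Bdnf-Ntrk2),
#' midkine/pleiotrophin (Mdk/Ptn-Ptprz1), Notch, growth-factor and guidance
#' axes relevant to the adult neurogenic niches.
#'
#' @return data.frame of class `lr_table`.
#' @export
default_lr_table <- function() {
  read_lr_table(system.file("extdata", "lr_pairs.tsv", package = "nichecomm",
                            mustWork = TRUE))
}

#' Single ligand-receptor pair contribution
#'
#' The contribution of one curated pair to a focal cell's communication
#' score: the focal cell's normalized expression of its side's gene times
#' the partner population's mean normalized expression of the other side's
#' gene. Definitional arithmetic, exposed for oracle checks.
#'
#' @param focal_expr focal-side normalized expression (scalar or vector).
#' @param partner_mean partner-side population mean (scalar or conforming
#'   vector).
#' @return nonnegative contribution(s).
#' @export
pair_contribution <- function(focal_expr, partner_mean) {
  if (any(focal_expr < 0) || any(partner_mean < 0))
    stop("expression values must be nonnegative")
  focal_expr * partner_mean
}

## Partner-side population mean per gene and age: mean within each sample,
## then averaged across samples of the same age, so unequal sample sizes do
## not bias age contrasts.
.partner_means_by_age <- function(cpm, partner_cells, meta, genes) {
  pm <- meta[match(partner_cells, meta$cell_id), ]
  ages <- sort(unique(pm$age_months))
  out <- matrix(0, length(genes), length(ages),
                dimnames = list(genes, as.character(ages)))
  for (a in ages) {
    cells_a <- partner_cells[pm$age_months == a]
    samp <- pm$sample[pm$age_months == a]
    per_sample <- sapply(unique(samp), function(s) {
      Matrix::rowMeans(cpm[genes, cells_a[samp == s], drop = FALSE])
    })
    if (is.null(dim(per_sample)))
      per_sample <- matrix(per_sample, nrow = length(genes))
    out[, as.character(a)] <- rowMeans(per_sample)
  }
  out
}

#' Per-cell global communication scores
#'
#' For every focal cell, the global score is the sum over curated
#' ligand-receptor pairs of [pair_contribution()]: the focal cell's
#' normalized expression of the focal-side gene (receptor for
#' `"receptor_side"`, ligand for `"ligand_side"`) times the partner
#' population's mean normalized expression of the opposite-side gene.
#' Partner means are computed within each sample and averaged across
#' samples of the focal cell's age group. A cell whose score is exactly
#' zero communicates through none of the curated pairs ("silent").
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param lr ligand-receptor table ([read_lr_table()]).
#' @param focal_cells,partner_cells nonempty cell id sets.
#' @param focal_role `"receptor_side"` (focal cells receive) or
#'   `"ligand_side"` (focal cells send).
#' @return list of class `comm_scores`: `scores` (named per-cell global
#'   scores), `contributions` (cells x pairs matrix), `pairs`, `config`.
#' @export
global_score <- function(sce, lr, focal_cells, partner_cells,
                         focal_role = c("receptor_side", "ligand_side")) {
  focal_role <- match.arg(focal_role)
  if (!length(focal_cells) || !length(partner_cells))
    stop("focal and partner populations must be nonempty")
  cpm <- .cpm(sce)
  meta <- .cell_meta(sce)
  focal_gene <- if (focal_role == "receptor_side") lr$receptor else lr$ligand
  partner_gene <- if (focal_role == "receptor_side") lr$ligand else lr$receptor
  present_f <- focal_gene %in% rownames(cpm)
  present_p <- partner_gene %in% rownames(cpm)
  missing <- unique(c(focal_gene[!present_f], partner_gene[!present_p]))
  if (length(missing) == length(unique(c(focal_gene, partner_gene))))
    stop("no ligand-receptor gene present in the matrix")
  if (length(missing))
    warning("ligand-receptor gene(s) absent from matrix (contribution 0): ",
            paste(missing, collapse = ", "))
  usable <- present_f & present_p

  pair_id <- paste(lr$ligand, lr$receptor, sep = "->")
  contrib <- matrix(0, length(focal_cells), nrow(lr),
                    dimnames = list(focal_cells, pair_id))
  focal_age <- as.character(meta$age_months[match(focal_cells, meta$cell_id)])
  pmeans <- .partner_means_by_age(cpm, partner_cells, meta,
                                  unique(partner_gene[usable]))
  missing_age <- setdiff(unique(focal_age), colnames(pmeans))
  if (length(missing_age))
    stop("no partner cells at age(s): ", paste(missing_age, collapse = ", "))
  focal_expr <- Matrix::t(cpm[unique(focal_gene[usable]), focal_cells,
                              drop = FALSE])
  for (j in which(usable)) {
    contrib[, j] <- pair_contribution(
      as.numeric(focal_expr[, focal_gene[j]]),
      pmeans[partner_gene[j], focal_age])
  }
  scores <- rowSums(contrib)
  structure(list(scores = scores, contributions = contrib,
                 pairs = lr[, c("ligand", "receptor")],
                 config = list(focal_role = focal_role,
                               n_focal = length(focal_cells),
                               n_partner = length(partner_cells))),
            class = "comm_scores")
}

#' Empirical cumulative fraction of communication scores
#'
#' Right-continuous ECDF point set over the scores; the last point is
#' `(max(scores), 1)`.
#'
#' @param scores numeric scores (>= 1 value); a `comm_scores` object is
#'   also accepted.
#' @return data.frame with `score` (sorted unique values) and `fraction`.
#' @export
cumulative_fraction <- function(scores) {
  scores <- .as_scores(scores)
  x <- sort(unique(scores))
  data.frame(score = x,
             fraction = vapply(x, function(v) mean(scores <= v), numeric(1)))
}

#' Fraction of silent focal cells
#'
#' Fraction of focal cells whose global communication score is exactly
#' zero, i.e. that neither express any curated focal-side gene nor face a
#' nonzero partner mean on any pair.
#'
#' @param scores numeric scores or a `comm_scores` object.
#' @return fraction in \[0, 1\].
#' @export
fraction_silent <- function(scores) {
  scores <- .as_scores(scores)
  mean(scores == 0)
}

.as_scores <- function(scores) {
  if (inherits(scores, "comm_scores")) scores <- scores$scores
  if (!length(scores)) stop("need at least one score")
  scores
}

#' Normalized mutual information between two expression vectors
#'
#' Discretizes the two per-cell expression vectors (default: binary
#' detected/undetected; `"quantile3"` cuts at tertiles), computes plug-in
#' mutual information from the joint frequency table, and normalizes by the
#' mean of the two marginal entropies. A degenerate marginal (zero entropy)
#' yields nMI 0 with `degenerate = TRUE`. The measure is symmetric and lies
#' in \[0, 1\].
#'
#' @param x,y per-cell expression vectors of equal length (>= 10).
#' @param discretize `"binary"` or `"quantile3"`.
#' @return one-row data.frame: `nmi`, `n`, `discretization`, `degenerate`.
#' @export
nmi <- function(x, y, discretize = c("binary", "quantile3")) {
  discretize <- match.arg(discretize)
  if (length(x) != length(y))
    stop("expression vectors must have equal length")
  if (length(x) < 10) stop("need at least 10 cells")
  dx <- .discretize_expr(x, discretize)
  dy <- .discretize_expr(y, discretize)
  tab <- table(dx, dy)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  hx <- .entropy(px); hy <- .entropy(py)
  if (hx == 0 || hy == 0)
    return(data.frame(nmi = 0, n = length(x), discretization = discretize,
                      degenerate = TRUE))
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  }
  data.frame(nmi = max(0, mi) / mean(c(hx, hy)), n = length(x),
             discretization = discretize, degenerate = FALSE)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.discretize_expr <- function(v, how) {
  if (how == "binary") return(as.integer(v > 0))
  br <- unique(stats::quantile(v, c(0, 1 / 3, 2 / 3, 1)))
  ## zero inflation can collapse the tertiles; fall back to
  ## detected/undetected rather than a single uninformative bin
  if (length(br) <= 2) return(as.integer(v > min(v)))
  cut(v, breaks = br, include.lowest = TRUE, labels = FALSE)
}

#' Differential ligand-receptor network between two ages
#'
#' For every curated pair whose ligand or receptor is differentially
#' expressed in the focal cell type between the two ages (rank-sum test,
#' `q <= q_max`), records the gene-wise log2 fold-change (old over young)
#' and direction, the nMI edge weight computed over the pooled focal and
#' partner cells, and the partner cell types whose mean partner-side
#' expression exceeds `partner_floor`.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param lr ligand-receptor table.
#' @param cell_types per-cell type labels named by cell id.
#' @param young_age,old_age ages (months) to contrast; both must have at
#'   least `min_cells` focal cells.
#' @param focal_type the focal cell type (default `"NSC"`).
#' @param q_max FDR ceiling for calling a gene differential.
#' @param partner_floor minimum partner mean (normalized units) for listing
#'   a partner type.
#' @param min_cells minimum focal cells per age.
#' @param discretize nMI discretizer.
#' @return data.frame, one row per (pair, differential gene): `ligand`,
#'   `receptor`, `gene`, `side`, `log2fc_old_vs_young`, `direction`, `q`,
#'   `nmi`, `partner_types`; sorted by significance.
#' @export
differential_lr_network <- function(sce, lr, cell_types, young_age, old_age,
                                    focal_type = "NSC", q_max = 0.05,
                                    partner_floor = 1, min_cells = 20,
                                    discretize = "quantile3") {
  meta <- .cell_meta(sce)
  cpm <- .cpm(sce)
  types <- cell_types[colnames(sce)]
  focal <- colnames(sce)[types == focal_type & !is.na(types)]
  f_age <- meta$age_months[match(focal, meta$cell_id)]
  for (a in c(young_age, old_age)) {
    if (!a %in% f_age) stop("age level absent among focal cells: ", a)
    if (sum(f_age == a) < min_cells)
      stop("fewer than ", min_cells, " focal cells at age ", a)
  }
  lr_genes <- unique(c(lr$ligand, lr$receptor))
  deg <- wilcoxon_deg(sce, focal[f_age == old_age], focal[f_age == young_age],
                      genes = intersect(lr_genes, rownames(cpm)))
  hits <- deg[deg$q <= q_max, , drop = FALSE]
  empty <- data.frame(ligand = character(), receptor = character(),
                      gene = character(), side = character(),
                      log2fc_old_vs_young = numeric(), direction = numeric(),
                      q = numeric(), nmi = numeric(),
                      partner_types = character(), stringsAsFactors = FALSE)
  if (!nrow(hits)) return(empty)

  partner <- colnames(sce)[types != focal_type & !is.na(types)]
  pooled <- c(focal, partner)
  rows <- list()
  for (r in seq_len(nrow(lr))) {
    lg <- lr$ligand[r]; rc <- lr$receptor[r]
    for (side in c("ligand", "receptor")) {
      g <- if (side == "ligand") lg else rc
      h <- hits[hits$gene == g, , drop = FALSE]
      if (!nrow(h)) next
      counterpart <- if (side == "ligand") rc else lg
      edge_nmi <- if (lg %in% rownames(cpm) && rc %in% rownames(cpm))
        nmi(as.numeric(cpm[lg, pooled]), as.numeric(cpm[rc, pooled]),
            discretize = discretize)$nmi else NA_real_
      ptypes <- if (counterpart %in% rownames(cpm)) {
        pm <- tapply(as.numeric(cpm[counterpart, partner]),
                     types[partner], mean)
        paste(sort(names(pm)[!is.na(pm) & pm > partner_floor]),
              collapse = ",")
      } else ""
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = lg, receptor = rc, gene = g, side = side,
        log2fc_old_vs_young = h$log2fc[1], direction = h$direction[1],
        q = h$q[1], nmi = edge_nmi, partner_types = ptypes,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$q), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-age expression trend of one gene
#'
#' Per-age summaries (mean, median, quartiles, n) of a gene's normalized
#' expression in a cell set, over all cells or only cells that express the
#' gene (`expressing_only`), plus a one-way ANOVA across ages on the
#' per-cell values.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param gene gene symbol (must be present).
#' @param cells cell ids to summarize.
#' @param expressing_only restrict to cells with nonzero normalized value.
#' @return list with `summary` (data.frame per age; ages with no expressing
#'   cells flagged `empty`) and `anova_p`.
#' @export
age_trend <- function(sce, gene, cells, expressing_only = FALSE) {
  cpm <- .cpm(sce)
  if (!gene %in% rownames(cpm)) stop("gene not present: ", gene)
  meta <- .cell_meta(sce)
  age <- meta$age_months[match(cells, meta$cell_id)]
  v <- as.numeric(cpm[gene, cells])
  rows <- list(); vals <- list()
  for (a in sort(unique(age))) {
    x <- v[age == a]
    if (expressing_only) x <- x[x > 0]
    if (!length(x)) {
      rows[[as.character(a)]] <- data.frame(
        age_months = a, n = 0, mean = NA_real_, median = NA_real_,
        q25 = NA_real_, q75 = NA_real_, empty = TRUE)
      next
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75))
    rows[[as.character(a)]] <- data.frame(
      age_months = a, n = length(x), mean = mean(x), median = q[2],
      q25 = q[1], q75 = q[3], empty = FALSE)
    vals[[as.character(a)]] <- x
  }
  summary_df <- do.call(rbind, rows)
  rownames(summary_df) <- NULL
  anova_p <- NA_real_
  if (length(vals) >= 2) {
    y <- unlist(vals, use.names = FALSE)
    g <- factor(rep(names(vals), lengths(vals)))
    if (stats::var(y) > 0) {
      fit <- stats::aov(y ~ g)
      anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    } else anova_p <- 1
  }
  list(summary = summary_df, anova_p = anova_p)
}
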