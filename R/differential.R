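#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' monotone in sorted order and capped at 1.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values of the same length.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## Exact two-sided rank-sum p by enumeration of all group assignments of
## the observed values (ties handled through midranks). Used when both
## groups have at most `exact_limit` observations.
.wilcox_exact_p <- function(a, b) {
  values <- c(a, b)
  r <- rank(values)
  n_a <- length(a)
  mu <- n_a * (length(values) + 1) / 2
  obs <- abs(sum(r[seq_len(n_a)]) - mu)
  splits <- utils::combn(length(values), n_a)
  w <- colSums(matrix(r[splits], nrow = n_a))
  mean(abs(w - mu) >= obs - 1e-12)
}

## Normal approximation with tie and continuity corrections.
.wilcox_approx_p <- function(a, b) {
  values <- c(a, b)
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  r <- rank(values)
  w <- sum(r[seq_len(n_a)])
  mu <- n_a * (n + 1) / 2
  ties <- table(values)
  sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  d <- max(0, abs(w - mu) - 0.5)
  min(1, 2 * stats::pnorm(-d / sqrt(sigma2)))
}

#' Rank-sum p-value (exact for small groups)
#'
#' Two-sided Wilcoxon rank-sum p-value: exact enumeration of all group
#' assignments when both groups have at most `exact_limit` observations,
#' normal approximation with tie correction otherwise.
#'
#' @param a,b numeric vectors.
#' @param exact_limit group-size ceiling for the exact path.
#' @return p-value.
#' @export
wilcoxon_p <- function(a, b, exact_limit = 8) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  if (length(a) <= exact_limit && length(b) <= exact_limit)
    .wilcox_exact_p(a, b)
  else
    .wilcox_approx_p(a, b)
}

#' Wilcoxon differential expression between two cell groups
#'
#' Genes are pre-filtered by expressing-cell fraction (in either group);
#' each surviving gene gets a two-sided rank-sum p-value on the normalized
#' values and Benjamini-Hochberg adjustment across all tested genes. The
#' absolute log2 fold-change filter (with pseudocount) is applied to the
#' reported table only, after adjustment: filtering on the observed effect
#' before adjustment selects null genes with extreme statistics into a
#' smaller BH family and inflates the false-discovery rate.
#'
#' @param sce normalized `SingleCellExperiment`.
#' @param cells_a,cells_b cell ids of the two groups (each >= 3 cells).
#' @param genes optional gene subset to test (default: all genes).
#' @param min_fraction minimum expressing fraction in at least one group.
#' @param min_abs_log2fc minimum |log2 fold-change| to test.
#' @param pseudocount added to normalized group means before the ratio.
#' @return data.frame with one row per tested gene: `gene`, `mean_a`,
#'   `mean_b`, `frac_a`, `frac_b`, `log2fc` (A over B), `p`, `q`,
#'   `direction` (sign of log2fc). Zero tested genes give an empty table
#'   with a `note` attribute.
#' @export
wilcoxon_deg <- function(sce, cells_a, cells_b, genes = NULL,
                         min_fraction = 0.1, min_abs_log2fc = 0.25,
                         pseudocount = 1) {
  if (!length(cells_a) || !length(cells_b))
    stop("both cell groups must be nonempty")
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop("both groups need at least 3 cells")
  cpm <- .cpm(sce)
  if (!is.null(genes)) cpm <- cpm[intersect(genes, rownames(cpm)), ,
                                  drop = FALSE]
  a <- cpm[, cells_a, drop = FALSE]
  b <- cpm[, cells_b, drop = FALSE]
  mean_a <- Matrix::rowMeans(a)
  mean_b <- Matrix::rowMeans(b)
  frac_a <- Matrix::rowMeans(a > 0)
  frac_b <- Matrix::rowMeans(b > 0)
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  keep <- pmax(frac_a, frac_b) >= min_fraction
  reported <- keep & abs(log2fc) >= min_abs_log2fc
  empty <- data.frame(gene = character(), mean_a = numeric(),
                      mean_b = numeric(), frac_a = numeric(),
                      frac_b = numeric(), log2fc = numeric(), p = numeric(),
                      q = numeric(), direction = numeric())
  if (!any(reported)) {
    attr(empty, "note") <- "no genes passed the pre-filters"
    return(empty)
  }
  idx <- which(keep)
  am <- as.matrix(a[idx, , drop = FALSE])
  bm <- as.matrix(b[idx, , drop = FALSE])
  p <- vapply(seq_along(idx), function(i) wilcoxon_p(am[i, ], bm[i, ]),
              numeric(1))
  out <- data.frame(
    gene = rownames(cpm)[idx], mean_a = mean_a[idx], mean_b = mean_b[idx],
    frac_a = frac_a[idx], frac_b = frac_b[idx], log2fc = log2fc[idx],
    p = p, q = bh_adjust(p), direction = sign(log2fc[idx]),
    stringsAsFactors = FALSE)
  out <- out[reported[idx], , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$p), , drop = FALSE]
}

#' Genes with opposite aging direction in the two sexes
#'
#' Intersects two differential tables from the same contrast (old vs young
#' within a cell type, one per sex) and keeps genes significant in both
#' sexes (`q <= q_max`) with opposite fold-change signs, sorted by combined
#' significance (product of the two p-values).
#'
#' @param deg_female,deg_male data.frames from [wilcoxon_deg()].
#' @param q_max FDR ceiling applied in both sexes.
#' @return data.frame with per-sex log2 fold-changes and q-values.
#' @export
opposite_sex_pattern <- function(deg_female, deg_male, q_max = 0.05) {
  m <- merge(deg_female[, c("gene", "log2fc", "p", "q")],
             deg_male[, c("gene", "log2fc", "p", "q")],
             by = "gene", suffixes = c("_female", "_male"))
  hit <- m$q_female <= q_max & m$q_male <= q_max &
    sign(m$log2fc_female) * sign(m$log2fc_male) < 0
  out <- m[hit, , drop = FALSE]
  out <- out[order(out$p_female * out$p_male), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Dunnett many-to-one comparisons on composition
#'
#' Tests whether a cell type's per-sample fraction changes across age
#' groups: one-way fixed-effects ANOVA on the per-sample fractions followed
#' by Dunnett's multiple comparisons of each age against the baseline age
#' (adjusted p-values from the equicorrelated multivariate-t distribution).
#'
#' @param composition data.frame from [composition_by_sample()].
#' @param cell_type cell type to test.
#' @param baseline_age reference age (months).
#' @return list with `F`, `df` (length 2), `p`, and `dunnett` (data.frame
#'   `age`, `estimate`, `p_adj`).
#' @export
proportion_anova_dunnett <- function(composition, cell_type, baseline_age) {
  d <- composition[composition$cell_type == cell_type, , drop = FALSE]
  if (!nrow(d)) stop("cell type not present in composition table: ", cell_type)
  counts <- table(d$age_months)
  small <- names(counts)[counts < 2]
  if (length(small))
    stop("age group(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  if (length(counts) < 2) stop("need at least 2 age groups")
  if (!as.character(baseline_age) %in% names(counts))
    stop("baseline age ", baseline_age, " absent from composition table")
  d$age_f <- stats::relevel(factor(d$age_months), ref = as.character(baseline_age))
  if (stats::var(d$fraction) == 0) {
    ## no variance at all: no between-group signal, nothing to test
    lv <- setdiff(levels(d$age_f), as.character(baseline_age))
    return(list(F = 0, df = c(nlevels(d$age_f) - 1,
                              nrow(d) - nlevels(d$age_f)), p = 1,
                dunnett = data.frame(age = lv, estimate = 0, p_adj = 1,
                                     stringsAsFactors = FALSE)))
  }
  fit <- stats::aov(fraction ~ age_f, data = d)
  s <- summary(fit)[[1]]
  res <- .with_local_seed(20201101L, {
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(age_f = "Dunnett"))
    summary(gl)
  })
  cmp <- res$test
  dunnett <- data.frame(
    age = sub(" - .*$", "", names(cmp$coefficients)),
    estimate = as.numeric(cmp$coefficients),
    p_adj = as.numeric(cmp$pvalues), stringsAsFactors = FALSE)
  list(F = s[["F value"]][1], df = c(s[["Df"]][1], s[["Df"]][2]),
       p = s[["Pr(>F)"]][1], dunnett = dunnett)
}

## Run code under a fixed RNG state without disturbing the caller's stream
## (the multivariate-t evaluation inside multcomp is quasi-random).
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
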