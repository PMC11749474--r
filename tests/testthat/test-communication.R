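# Toy with planted ligand/receptor structure in a single sample: cells
# 1..10 are the focal population, 11..20 the partner population.
comm_toy <- function(seed = 1) {
  set.seed(seed)
  genes <- c("Bdnf", "Mdk", "Ntrk2", "Ptprz1", sprintf("f%02d", 1:40))
  counts <- matrix(rpois(length(genes) * 20, 2), nrow = length(genes),
                   dimnames = list(genes, NULL))
  sce <- toy_sce(counts)
  lr <- data.frame(ligand = c("Bdnf", "Mdk"),
                   receptor = c("Ntrk2", "Ptprz1"),
                   source = "toy", stringsAsFactors = FALSE)
  class(lr) <- c("lr_table", "data.frame")
  list(sce = sce, lr = lr, focal = colnames(sce)[1:10],
       partner = colnames(sce)[11:20])
}

test_that("pair contributions are definitional arithmetic", {
  expect_equal(pair_contribution(5, 10), 50)
  expect_equal(pair_contribution(0, 10), 0)
  expect_equal(pair_contribution(c(1, 2), 3), c(3, 6))
  expect_error(pair_contribution(-1, 2), "nonnegative")
})

test_that("global scores equal a brute-force double loop over cells and pairs", {
  toy <- comm_toy()
  cpm <- as.matrix(SummarizedExperiment::assay(toy$sce, "cpm"))
  res <- global_score(toy$sce, toy$lr, toy$focal, toy$partner,
                      "receptor_side")
  brute <- sapply(toy$focal, function(cell) {
    s <- 0
    for (k in seq_len(nrow(toy$lr))) {
      partner_mean <- mean(cpm[toy$lr$ligand[k], toy$partner])
      s <- s + cpm[toy$lr$receptor[k], cell] * partner_mean
    }
    s
  })
  expect_lt(max(abs(res$scores - brute)), 1e-9)
  # table invariant: global score is the sum of pair contributions
  expect_lt(max(abs(rowSums(res$contributions) - res$scores)), 1e-9)
  expect_true(all(res$contributions >= 0))

  # annihilation: zero all partner-side ligands
  zeroed <- toy$sce
  cpm0 <- SummarizedExperiment::assay(zeroed, "cpm")
  cpm0[c("Bdnf", "Mdk"), toy$partner] <- 0
  SummarizedExperiment::assay(zeroed, "cpm") <- cpm0
  res0 <- global_score(zeroed, toy$lr, toy$focal, toy$partner,
                       "receptor_side")
  expect_true(all(res0$scores == 0))
})

test_that("scaling partner ligand expression by lambda scales receptor-side scores by lambda", {
  toy <- comm_toy(seed = 2)
  base <- global_score(toy$sce, toy$lr, toy$focal, toy$partner,
                       "receptor_side")
  lambda <- 2.5
  scaled <- toy$sce
  cpm <- SummarizedExperiment::assay(scaled, "cpm")
  cpm[c("Bdnf", "Mdk"), toy$partner] <- lambda * cpm[c("Bdnf", "Mdk"),
                                                     toy$partner]
  SummarizedExperiment::assay(scaled, "cpm") <- cpm
  res <- global_score(scaled, toy$lr, toy$focal, toy$partner,
                      "receptor_side")
  expect_equal(res$scores, lambda * base$scores, tolerance = 1e-12)
})

test_that("ECDF points match brute-force counting and end at (max, 1)", {
  expect_equal(cumulative_fraction(c(1, 2, 3, 4))$fraction[2], 0.5)
  one <- cumulative_fraction(rep(3, 7))
  expect_equal(nrow(one), 1)
  expect_equal(one$fraction, 1)
  set.seed(5)
  x <- rexp(100)
  ecdf_pts <- cumulative_fraction(x)
  for (i in sample(nrow(ecdf_pts), 10))
    expect_equal(ecdf_pts$fraction[i], mean(x <= ecdf_pts$score[i]))
  expect_equal(ecdf_pts$score[nrow(ecdf_pts)], max(x))
  expect_equal(ecdf_pts$fraction[nrow(ecdf_pts)], 1)
})

test_that("silent fraction counts exact zeros", {
  expect_equal(fraction_silent(c(0, 0, 1, 2)), 0.5)
  expect_equal(fraction_silent(c(1, 2, 3)), 0)
  expect_error(fraction_silent(numeric()), "at least one")
})

test_that("nMI matches plug-in values on constructed tables", {
  # identical binary vectors with both states present
  v <- rep(c(0, 5), each = 10)
  expect_equal(nmi(v, v)$nmi, 1)
  # independence: joint [[25,25],[25,25]]
  x <- rep(c(0, 0, 1, 1), 25); y <- rep(c(0, 1, 0, 1), 25)
  expect_equal(nmi(x, y)$nmi, 0)
  # diagonal [[5,0],[0,5]]: MI = 1 bit = both marginal entropies
  x2 <- rep(c(0, 1), each = 5); y2 <- rep(c(0, 1), each = 5)
  expect_equal(nmi(x2, y2)$nmi, 1)
  # symmetry and range on random vectors
  set.seed(6)
  a <- rpois(200, 1); b <- rpois(200, 1)
  expect_equal(nmi(a, b)$nmi, nmi(b, a)$nmi)
  expect_gte(nmi(a, b)$nmi, 0)
  expect_lte(nmi(a, b)$nmi, 1)
  # independent Bernoulli null at n = 1e4
  x3 <- rbinom(1e4, 1, 0.5); y3 <- rbinom(1e4, 1, 0.5)
  expect_lt(nmi(x3, y3)$nmi, 0.01)
  # degenerate marginal
  expect_true(nmi(rep(0, 20), rbinom(20, 1, 0.5))$degenerate)
  expect_error(nmi(1:10, 1:11), "equal length")
})

test_that("nMI equals a brute-force joint-table computation on all small 2x2 tables", {
  brute_nmi <- function(tab) {
    p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
    if (ent(px) == 0 || ent(py) == 0) return(0)
    mi <- 0
    for (i in 1:2) for (j in 1:2)
      if (p[i, j] > 0) mi <- mi + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    max(0, mi) / mean(c(ent(px), ent(py)))
  }
  for (a in 0:6) for (b in 0:6) for (cc in 0:6) for (d in 0:6) {
    n <- a + b + cc + d
    if (n < 10) next
    x <- rep(c(0, 0, 1, 1), times = c(a, b, cc, d))
    y <- rep(c(0, 1, 0, 1), times = c(a, b, cc, d))
    expect_equal(nmi(x, y)$nmi, brute_nmi(matrix(c(a, cc, b, d), 2)),
                 tolerance = 1e-12)
  }
})

test_that("the differential network reports planted receptor loss as down in old", {
  fx <- cached_default_sim()
  net <- differential_lr_network(fx$sce, default_lr_table(), fx$truth_type,
                                 young_age = 2, old_age = 19)
  expect_gt(nrow(net), 0)
  ntrk2 <- net[net$gene == "Ntrk2", ]
  expect_gt(nrow(ntrk2), 0)
  expect_true(all(ntrk2$direction == -1))
  expect_true(all(net$nmi >= 0 & net$nmi <= 1, na.rm = TRUE))
  expect_error(
    differential_lr_network(fx$sce, default_lr_table(), fx$truth_type,
                            young_age = 3, old_age = 19), "age")
})

test_that("no differential genes gives an empty network", {
  toy <- comm_toy(seed = 3)
  # two age groups drawn from the same law: nothing should pass q <= 0.05
  meta <- as.data.frame(SummarizedExperiment::colData(toy$sce))
  meta$age_months <- rep(c(2, 19), 10)
  sce <- as_niche_sce(SingleCellExperiment::counts(toy$sce), meta)
  sce <- normalize_counts(sce)
  types <- setNames(rep(c("NSC", "Other"), each = 10), colnames(sce))
  net <- differential_lr_network(sce, toy$lr, types, 2, 19,
                                 min_cells = 5)
  expect_equal(nrow(net), 0)
})

test_that("age trends honor the expressing-only flag and detect planted decline", {
  counts <- matrix(0L, 3, 4, dimnames = list(c("g1", "g2", "g3"), NULL))
  counts["g1", ] <- c(0L, 0L, 4L, 4L)
  counts["g2", ] <- 1L
  counts["g3", ] <- 3L
  sce <- toy_sce(counts, normalize = FALSE)
  vals <- counts + 0
  colnames(vals) <- colnames(sce)
  SummarizedExperiment::assay(sce, "cpm") <- Matrix::Matrix(vals, sparse = TRUE)
  SummarizedExperiment::assay(sce, "logcounts") <-
    Matrix::Matrix(log1p(vals), sparse = TRUE)
  t_all <- age_trend(sce, "g1", colnames(sce), expressing_only = FALSE)
  t_expr <- age_trend(sce, "g1", colnames(sce), expressing_only = TRUE)
  expect_equal(t_all$summary$mean, 2)
  expect_equal(t_expr$summary$mean, 4)

  fx <- cached_default_sim()
  nscs <- names(fx$truth_type)[fx$truth_type == "NSC"]
  tr <- age_trend(fx$sce, "Ptprz1", nscs)
  ord <- order(tr$summary$age_months)
  # per-cell expression is heavy-tailed, so the planted decline is read
  # from the median (the mean can flip once from a few extreme cells)
  expect_true(all(diff(tr$summary$median[ord]) < 0))
  expect_lt(tr$anova_p, 0.01)
})

test_that("the age-trend ANOVA is calibrated under the null", {
  set.seed(9)
  rejected <- replicate(100, {
    y <- rnorm(80)
    g <- factor(rep(1:4, each = 20))
    summary(stats::aov(y ~ g))[[1]][["Pr(>F)"]][1] < 0.05
  })
  # direct null calibration of the same test age_trend applies
  expect_lte(mean(rejected), 0.10)

  counts <- matrix(rpois(50 * 80, 2), nrow = 50,
                   dimnames = list(sprintf("g%02d", 1:50), NULL))
  sce <- toy_sce(counts, age_months = rep(c(2, 7, 12, 19), each = 20))
  tr <- age_trend(sce, "g01", colnames(sce))
  expect_true(is.finite(tr$anova_p))
})
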