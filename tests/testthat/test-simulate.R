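# Small two-type configuration used by several generator checks.
two_type_config <- function(seed = 5L, n_per_type = 500, marker_l2fc = 2,
                            ...) {
  niche_sim_config(
    cell_types = c(TypeA = n_per_type, TypeB = n_per_type),
    age_groups = 2, sexes = "F", n_replicates = 1,
    proportion_trajectory = c(TypeA = 1),
    marker_spec = list(TypeA = c(Thbs4 = marker_l2fc)),
    program_size = 0,
    lr_coupling = data.frame(ligand = character(), receptor = character(),
                             sender = character(), receiver = character(),
                             rho = numeric()),
    silent_fraction = 0,
    seed = seed, ...)
}

test_that("identical config and seed give bit-identical output", {
  cfg <- two_type_config(seed = 9L, n_per_type = 80)
  a <- simulate_niche(cfg)
  b <- simulate_niche(cfg)
  expect_identical(as.matrix(SingleCellExperiment::counts(a$sce)),
                   as.matrix(SingleCellExperiment::counts(b$sce)))
  expect_identical(a$truth$cells, b$truth$cells)
  c <- simulate_niche(two_type_config(seed = 10L, n_per_type = 80))
  expect_false(identical(as.matrix(SingleCellExperiment::counts(a$sce)),
                         as.matrix(SingleCellExperiment::counts(c$sce))))
})

test_that("a planted marker log2FC of 2 yields a fourfold mean, within 3 SE", {
  # oracle: NB mean formula; dropout off so E[count] = mu exactly
  cfg <- two_type_config(seed = 5L, n_per_type = 500,
                         dropout_midpoint = -Inf)
  res <- simulate_niche(cfg)
  counts <- SingleCellExperiment::counts(res$sce)
  type <- res$truth$cells$type[match(colnames(counts),
                                     res$truth$cells$cell_id)]
  g <- as.numeric(counts["Thbs4", ])
  xa <- g[type == "TypeA"]; xb <- g[type == "TypeB"]
  diff_se <- sqrt(var(xa) / length(xa) + 16 * var(xb) / length(xb))
  expect_lt(abs(mean(xa) - 4 * mean(xb)), 3 * diff_se)
})

test_that("the realized TAP active fraction sits in the exact binomial 99% interval", {
  cfg <- niche_sim_config(
    cell_types = c(NSC = 50, TAP = 400), age_groups = 2, sexes = "F",
    proportion_trajectory = c(TAP = 1), program_size = 0, seed = 4L)
  res <- simulate_niche(cfg)
  taps <- res$truth$cells[res$truth$cells$type == "TAP", ]
  n <- nrow(taps)
  k <- sum(taps$tap_subtype == "cycle_active")
  lo <- qbinom(0.005, n, 0.6)
  hi <- qbinom(0.995, n, 0.6)
  expect_gte(k, lo)
  expect_lte(k, hi)
})

test_that("realized per-type counts fall in exact multinomial 99% marginal regions", {
  cfg <- niche_sim_config(seed = 12L)
  res <- simulate_niche(cfg)
  comp <- res$truth$composition
  cells <- res$truth$cells
  for (s in unique(comp$sample)) {
    sub <- comp[comp$sample == s, ]
    n <- sum(cells$sample == s)
    for (i in seq_len(nrow(sub))) {
      k <- sum(cells$sample == s & cells$type == sub$type[i])
      expect_gte(k, qbinom(0.005, n, sub$expected_fraction[i]))
      expect_lte(k, qbinom(0.995, n, sub$expected_fraction[i]))
    }
  }
})

test_that("without dropout and with Poisson counts, sample means match configured means", {
  cfg <- two_type_config(seed = 3L, n_per_type = 1000,
                         dropout_midpoint = -Inf, nb_dispersion = Inf,
                         libsize_sigma = 0)
  res <- simulate_niche(cfg)
  counts <- SingleCellExperiment::counts(res$sce)
  type <- res$truth$cells$type[match(colnames(counts),
                                     res$truth$cells$cell_id)]
  # in TypeB cells no spec applies, so means are the configured baselines;
  # restrict to well-expressed genes where a 5% relative error is testable
  mb <- Matrix::rowMeans(counts[, type == "TypeB"])
  set.seed(cfg$seed)
  base <- rlnorm(2000, cfg$base_meanlog, cfg$base_sdlog)
  names(base) <- rownames(counts)[seq_along(base)]
  touched <- unique(c(res$truth$de$gene, default_lr_program()$gene,
                      cfg$sex_spec$genes, cfg$receptor_spec$genes,
                      "Thbs4"))
  hi <- names(base)[base >= 2 & !startsWith(names(base), "mt-") &
                      !names(base) %in% touched]
  hi <- intersect(hi, rownames(counts))
  skip_if(length(hi) < 20)
  rel_err <- abs(mb[hi] - base[hi]) / base[hi]
  expect_lt(median(rel_err), 0.05)
  expect_lt(mean(rel_err > 0.15), 0.01)
})

test_that("couple_lr honors the coupling strength", {
  set.seed(42)
  n <- 1000
  latent <- rbinom(n, 1, 0.5)
  lig <- rep(4, n); rec <- rep(3, n)
  # rho = 0: means unchanged, simulated expression uncorrelated
  out0 <- couple_lr(latent, lig, rec, rho = 0, log2_effect = 2)
  expect_identical(out0$ligand_mean, lig)
  expect_identical(out0$receptor_mean, rec)
  x <- rpois(n, out0$ligand_mean); y <- rpois(n, out0$receptor_mean)
  expect_lt(abs(cor(x, y)), 3 / sqrt(n))
  # rho = 1, no noise: binarized adjusted means coincide across cells
  out1 <- couple_lr(latent, lig, rec, rho = 1, log2_effect = 2)
  expect_identical(as.integer(out1$ligand_mean > 4),
                   as.integer(out1$receptor_mean > 3))
  expect_identical(as.integer(out1$ligand_mean > 4), latent)
  expect_error(couple_lr(latent, lig, rec, rho = 1.2), "rho")
})

test_that("stronger coupling yields larger nMI (Monte-Carlo ordering)", {
  set.seed(77)
  wins <- 0L
  for (r in 1:20) {
    n <- 1000
    latent <- rbinom(n, 1, 0.5)
    hi <- couple_lr(latent, rep(3, n), rep(3, n), rho = 0.8, log2_effect = 2)
    latent2 <- rbinom(n, 1, 0.5)
    lo <- couple_lr(latent2, rep(3, n), rep(3, n), rho = 0.2, log2_effect = 2)
    n_hi <- nmi(rnbinom(n, mu = hi$ligand_mean, size = 2),
                rnbinom(n, mu = hi$receptor_mean, size = 2),
                discretize = "quantile3")$nmi
    n_lo <- nmi(rnbinom(n, mu = lo$ligand_mean, size = 2),
                rnbinom(n, mu = lo$receptor_mean, size = 2),
                discretize = "quantile3")$nmi
    if (n_hi > n_lo) wins <- wins + 1L
  }
  expect_gte(wins, 19L)
})

test_that("invalid configurations are rejected with all violations named", {
  cfg <- niche_sim_config(silent_fraction = 1.4)
  cfg$receptor_spec$high_fraction <- -0.1
  v <- validate_sim_config(cfg)
  expect_true(any(grepl("silent_fraction", v)))
  expect_true(any(grepl("high_fraction", v)))
  expect_error(simulate_niche(cfg), "invalid simulation config")

  cfg2 <- niche_sim_config(
    gene_names = sprintf("g%04d", 1:2000))
  v2 <- validate_sim_config(cfg2)
  expect_true(any(grepl("Thbs4|configuration error", v2)))
})

test_that("truth record is complete and composition rows sum to one", {
  res <- cached_default_sim()$sim
  tr <- res$truth
  expect_setequal(tr$cells$cell_id, colnames(res$sce))
  expect_true(all(!is.na(tr$cells$type)))
  sums <- tapply(tr$composition$realized_fraction, tr$composition$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(c("contrast", "gene", "log2fc") %in% colnames(tr$de)))
  expect_true(all(tr$cells$tap_subtype[tr$cells$type == "TAP"] %in%
                    c("cycle_active", "cycle_inactive")))
})
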