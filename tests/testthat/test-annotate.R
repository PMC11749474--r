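# Toy data with marker structure: cluster 1 = stem-like (Thbs4/Nr2e1/
# Igfbp5/Notum high, astrocyte genes zero), cluster 2 = astrocyte-like,
# cluster 3 = all-zero background.
marker_toy <- function(seed = 1) {
  set.seed(seed)
  genes <- c("Nr2e1", "Thbs4", "Igfbp5", "Notum", "Aqp4", "Tril", "Grin2c",
             "Slc1a3", sprintf("f%02d", 1:30))
  n_per <- 30
  counts <- matrix(rpois(length(genes) * 3 * n_per, 1),
                   nrow = length(genes), dimnames = list(genes, NULL))
  cl <- rep(c("1", "2", "3"), each = n_per)
  counts[c("Nr2e1", "Thbs4", "Igfbp5", "Notum"), cl == "1"] <-
    rpois(4 * n_per, 20)
  counts[c("Aqp4", "Tril", "Grin2c"), cl == "1"] <- 0
  counts[c("Aqp4", "Tril", "Grin2c", "Slc1a3"), cl == "2"] <-
    rpois(4 * n_per, 20)
  counts[, cl == "3"] <- 0
  list(sce = toy_sce(counts), labels = cl)
}

# Panel restricted to the two types present in the toy data.
toy_panel <- function() {
  full <- default_marker_panel("SVZ")
  structure(full[c("NSC", "Astrocyte")], class = "marker_panel",
            region = "SVZ")
}

test_that("stem-cell markers without astrocyte genes give NSC; astrocyte genes give Astrocyte", {
  toy <- marker_toy()
  panel <- toy_panel()
  res <- suppressWarnings(assign_types(toy$sce, toy$labels, panel))
  types <- setNames(res$assignment$type, res$assignment$cluster)
  expect_equal(unname(types["1"]), "NSC")
  expect_equal(unname(types["2"]), "Astrocyte")
  expect_equal(unname(types["3"]), "unassigned")
})

test_that("type assignment is invariant to cluster relabeling and gene order", {
  toy <- marker_toy(seed = 2)
  panel <- toy_panel()
  base <- suppressWarnings(assign_types(toy$sce, toy$labels, panel))
  relab <- c("1" = "x", "2" = "y", "3" = "z")[toy$labels]
  shuffled <- toy$sce[sample(nrow(toy$sce)), ]
  res2 <- suppressWarnings(assign_types(shuffled, relab, panel))
  expect_identical(unname(base$cell_types), unname(res2$cell_types))
})

test_that("planted 60/40 TAP cycle split is recovered within 5 points, with Ube2c high in active cells", {
  fx <- cached_default_sim()
  taps <- names(fx$truth_type)[fx$truth_type == "TAP"]
  cyc <- unique(unlist(default_cycle_genes()))
  sub <- subcluster_tap(fx$sce, taps, cyc, seed = 1)
  expect_false(sub$degenerate)
  planted <- fx$sim$truth$params$tap_active_fraction[["2"]]
  expect_lt(abs(mean(sub$labels == "cycle_active") - planted), 0.05)
  logc <- SummarizedExperiment::assay(fx$sce, "logcounts")
  ube2c <- as.numeric(logc["Ube2c", taps])
  expect_gt(mean(ube2c[sub$labels == "cycle_active"]),
            mean(ube2c[sub$labels == "cycle_inactive"]))
})

test_that("identical TAP expression is reported as degenerate, and tiny inputs error", {
  counts <- matrix(2L, nrow = 40, ncol = 30,
                   dimnames = list(c(default_cycle_genes()$g2m,
                                     sprintf("f%02d", 1:30)), NULL))
  sce <- toy_sce(counts)
  expect_true(suppressWarnings(
    subcluster_tap(sce, colnames(sce), default_cycle_genes()$g2m))$degenerate)
  expect_error(subcluster_tap(sce, colnames(sce)[1:5],
                              default_cycle_genes()$g2m), "at least")
})

test_that("receptor-high NSC fraction is recovered within 5 points and R_H has higher receptor expression", {
  cfg <- niche_sim_config(seed = 2L)
  cfg$receptor_spec$age_log2fc <- 0   # isolate the bimodal receptor program
  res <- simulate_niche(cfg)
  sce <- normalize_counts(qc_filter(res$sce, qc_thresholds(min_genes = 300))$sce)
  tt <- res$truth$cells$type[match(colnames(sce), res$truth$cells$cell_id)]
  nscs <- colnames(sce)[tt == "NSC"]
  receptors <- intersect(unique(default_lr_table()$receptor), rownames(sce))
  sub <- subcluster_receptor(sce, nscs, receptors)
  expect_false(sub$degenerate)
  expect_lt(abs(mean(sub$labels == "R_H") -
                  res$truth$params$nsc_high_fraction), 0.05)
  logc <- SummarizedExperiment::assay(sce, "logcounts")
  rmean <- Matrix::colMeans(logc[receptors, nscs])
  expect_gt(mean(rmean[sub$labels == "R_H"]),
            mean(rmean[sub$labels == "R_L"]))
  expect_true(is.data.frame(sub$receptor_table))
})

test_that("composition fractions are exact and sum to one per sample", {
  types <- c(rep("TAP", 3), rep("NSC", 7))
  names(types) <- sprintf("c%03d", 1:10)
  meta <- data.frame(cell_id = names(types), sample = "s1", region = "SVZ",
                     age_months = 2, sex = "F")
  comp <- composition_by_sample(types, meta)
  expect_equal(comp$fraction[comp$cell_type == "TAP"], 0.3)
  expect_equal(sum(comp$fraction), 1)

  fx <- cached_default_sim()
  comp2 <- composition_by_sample(fx$truth_type, fx$meta)
  sums <- tapply(comp2$fraction, comp2$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a declining TAP trajectory produces monotone decreasing mean fractions", {
  fx <- cached_default_sim()
  comp <- composition_by_sample(fx$truth_type, fx$meta)
  taps <- comp[comp$cell_type == "TAP", ]
  by_age <- tapply(taps$fraction, taps$age_months, mean)
  by_age <- by_age[order(as.numeric(names(by_age)))]
  expect_true(all(diff(by_age) < 0))
})
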