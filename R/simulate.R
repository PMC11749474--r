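#' Configuration for the synthetic neurogenic-niche generator
#'
#' Builds the full parameter set for [simulate_niche()]. Defaults emulate a
#' subventricular-zone (SVZ) niche profiled at four ages in both sexes:
#' discrete cell types with marker programs, an age-dependent decline of
#' transient amplifying progenitors (TAPs) and neuroblasts (NBs), a
#' cell-cycle program splitting TAPs roughly 60/40 into cycle-active and
#' cycle-inactive states, receptor-high vs receptor-low neural stem cell
#' (NSC) subpopulations whose receptor program declines with age,
#' sex-opposite aging genes, a silent fraction of niche sender cells that
#' express no curated ligand, and latent coupling between ligand expression
#' in senders and receptor expression in receivers.
#'
#' Counts are negative-binomial draws (mean/inverse-dispersion
#' parameterization) thinned by a logistic dropout in the log-mean, with a
#' log-normal per-cell library-size factor.
#'
#' @param cell_types named numeric vector: expected cells per sample per
#'   type at the youngest age.
#' @param age_groups strictly increasing ages in months.
#' @param sexes sample sexes; one sample per (age, sex, replicate).
#' @param n_replicates samples per (age, sex) combination.
#' @param region region tag written into cell metadata.
#' @param proportion_trajectory named multiplicative change in expected
#'   count per age step (types absent default to 1).
#' @param n_genes total gene universe size (named program genes plus
#'   anonymous filler genes).
#' @param marker_spec list: type -> named numeric of marker log2 fold-changes.
#' @param program_size,program_log2fc each cell type additionally receives
#'   a broad identity program: `program_size` filler genes (disjoint across
#'   types, chosen under the seed) up-regulated by `program_log2fc` log2
#'   units, emulating the hundreds of genes that separate real cell types.
#' @param cycle_spec list with `s_genes`, `g2m_genes`, `active_fraction`
#'   (named by age, fraction of TAPs in the cycle-active state),
#'   `log2_effect`.
#' @param receptor_spec list with `genes` (NSC receptor program),
#'   `high_fraction` (fraction of NSCs in the receptor-high state),
#'   `log2_effect`, and `age_log2fc` (log2 change per age step applied to
#'   every NSC ligand/receptor program gene).
#' @param sex_spec list with `genes`, `log2_effect` and `base_mean`: genes
#'   whose aging response in NSCs has equal magnitude and opposite sign in
#'   the two sexes (positive in females); `base_mean` pins their baseline
#'   so the planted fold-change acts on a measurable level.
#' @param lr_program data.frame (`type`, `gene`, `mean`): per-type baseline
#'   means of ligand/receptor genes; these genes are zero elsewhere.
#' @param silent_fraction fraction of niche (non-NSC) cells whose entire
#'   ligand program is switched off.
#' @param lr_coupling data.frame (`ligand`, `receptor`, `sender`,
#'   `receiver`, `rho`): latent sender-receiver couplings, rho in \[0, 1\].
#' @param coupling_log2_effect amplitude (log2) of the shared latent factor
#'   at rho = 1.
#' @param nb_dispersion inverse-dispersion (NB `size`); scalar or per-gene
#'   vector; `Inf` gives Poisson counts.
#' @param dropout_midpoint,dropout_slope logistic dropout:
#'   `P(drop) = plogis(slope * (midpoint - log(mean)))`; `midpoint = -Inf`
#'   disables dropout.
#' @param libsize_sigma sd of the log-normal per-cell library factor.
#' @param base_meanlog,base_sdlog log-normal law of baseline gene means.
#' @param n_mito_genes,mito_mean mitochondrial (`mt-`) genes and their mean.
#' @param gene_names optional explicit gene universe; every gene named in
#'   any spec must appear in it.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list of class `niche_sim_config`.
#' @export
niche_sim_config <- function(
    cell_types = c(NSC = 80, TAP = 70, NB = 70, Astrocyte = 90, OPC = 40,
                   Oligodendrocyte = 50, Microglia = 50, Endothelial = 50),
    age_groups = c(2, 7, 12, 19),
    sexes = c("F", "M"),
    n_replicates = 1,
    region = "SVZ",
    proportion_trajectory = c(TAP = 0.65, NB = 0.7),
    n_genes = 2000,
    marker_spec = default_marker_spec(),
    program_size = 50,
    program_log2fc = 1.5,
    cycle_spec = list(
      s_genes = default_cycle_genes()$s,
      g2m_genes = default_cycle_genes()$g2m,
      active_fraction = stats::setNames(rep(0.6, length(age_groups)),
                                        as.character(age_groups)),
      log2_effect = 2),
    receptor_spec = list(
      genes = c("Ntrk2", "Ptprz1", "Notch1", "Igf1r", "Fgfr1", "Fgfr3",
                "Lrp1", "Cxcr4"),
      high_fraction = 0.4,
      log2_effect = 3,
      age_log2fc = -0.5),
    sex_spec = list(
      genes = c("Prdx1", "Sod1", "Cat", "Gpx1", "Hspa5", "Fos", "Jun",
                "Egr1", "Klf6", "Socs3", "Atf3", "Ier2", "Btg2", "Dusp1"),
      log2_effect = 2,
      base_mean = 2),
    lr_program = default_lr_program(),
    silent_fraction = 0.35,
    lr_coupling = data.frame(
      ligand = c("Bdnf", "Mdk"), receptor = c("Ntrk2", "Ptprz1"),
      sender = "NSC", receiver = "NSC", rho = 0.8,
      stringsAsFactors = FALSE),
    coupling_log2_effect = 2,
    nb_dispersion = 2,
    dropout_midpoint = log(0.1),
    dropout_slope = 1,
    libsize_sigma = 0.3,
    base_meanlog = log(0.6),
    base_sdlog = 1,
    n_mito_genes = 10,
    mito_mean = 3,
    gene_names = NULL,
    seed = 1L) {
  cfg <- list(
    cell_types = cell_types, age_groups = age_groups, sexes = sexes,
    n_replicates = n_replicates, region = region,
    proportion_trajectory = proportion_trajectory, n_genes = n_genes,
    marker_spec = marker_spec, program_size = program_size,
    program_log2fc = program_log2fc, cycle_spec = cycle_spec,
    receptor_spec = receptor_spec, sex_spec = sex_spec,
    lr_program = lr_program, silent_fraction = silent_fraction,
    lr_coupling = lr_coupling, coupling_log2_effect = coupling_log2_effect,
    nb_dispersion = nb_dispersion, dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope, libsize_sigma = libsize_sigma,
    base_meanlog = base_meanlog, base_sdlog = base_sdlog,
    n_mito_genes = n_mito_genes, mito_mean = mito_mean,
    gene_names = gene_names, seed = as.integer(seed))
  class(cfg) <- "niche_sim_config"
  cfg
}

#' Default marker log2 fold-change specification
#'
#' Mouse SVZ marker programs. NSCs carry the stem-cell markers used to
#' separate them from astrocytes (Nr2e1, Thbs4, Igfbp5, Notum) while
#' astrocytes carry the mature astrocyte genes NSCs lack (Aqp4, Tril,
#' Grin2c); Fabp7 and Aldoc are shared between the two, reproducing their
#' overlapping expression profiles.
#'
#' @return named list: cell type -> named numeric of log2 effects.
#' @export
default_marker_spec <- function() {
  list(
    NSC = c(Nr2e1 = 2, Thbs4 = 2.5, Igfbp5 = 2, Notum = 2, Hopx = 1.5,
            Thrsp = 1.5, Fabp7 = 1.5, Aldoc = 1),
    Astrocyte = c(Aqp4 = 2.5, Tril = 2, Grin2c = 2, Aldoc = 1.5,
                  Slc1a3 = 1.5, Fabp7 = 1),
    TAP = c(Ascl1 = 2, Egfr = 2, Hmgb2 = 2, Mki67 = 1.5),
    NB = c(Dcx = 2.5, Stmn2 = 2, Sox11 = 2),
    OPC = c(Pdgfra = 2.5, Cspg4 = 2, Olig1 = 2),
    Oligodendrocyte = c(Plp1 = 2.5, Mbp = 2.5, Mog = 2),
    Microglia = c(Cx3cr1 = 2.5, C1qa = 2.5, Tmem119 = 2),
    Endothelial = c(Cldn5 = 2.5, Pecam1 = 2, Flt1 = 2))
}

#' Default per-type ligand/receptor expression program
#'
#' Baseline means of curated ligand and receptor genes by cell type. NSCs
#' express the receptor program (Ntrk2, Ptprz1, ...) plus autocrine ligands
#' (Bdnf, Mdk, Ptn); each niche type expresses at least three ligands whose
#' receptors sit in the NSC program, so that a non-silent sender reliably
#' reaches NSCs through several channels and observed silence reflects the
#' planted silent fraction rather than dropout of a lone channel. Some
#' types additionally express receptors so the reverse direction is
#' defined.
#'
#' @return data.frame with columns `type`, `gene`, `mean`.
#' @export
default_lr_program <- function() {
  rb <- function(type, genes, means)
    data.frame(type = type, gene = genes, mean = means,
               stringsAsFactors = FALSE)
  rbind(
    ## receptor-low baseline is scant (dormant NSCs barely express the
    ## receptor program); the receptor-high state sits 2^3 above it
    rb("NSC", c("Ntrk2", "Ptprz1", "Notch1", "Igf1r", "Fgfr1", "Fgfr3",
                "Lrp1", "Cxcr4"), rep(1.5, 8)),
    rb("NSC", c("Bdnf", "Mdk", "Ptn"), c(4, 4, 3)),
    rb("Astrocyte", c("Apoe", "Cxcl12", "Jag1"), c(5, 4, 3)),
    rb("Astrocyte", c("Ntrk2", "Notch1"), c(2, 2)),
    rb("TAP", c("Dll1", "Fgf2", "Ptn", "Efnb2"), c(4, 3, 3, 3)),
    rb("TAP", c("Notch1", "Ptprz1"), c(3, 2)),
    rb("NB", c("Dll1", "Bdnf", "Mdk"), c(4, 3, 3)),
    rb("NB", c("Ntrk2", "Notch1"), c(3, 2)),
    rb("OPC", c("Ptn", "Fgf2", "Jag1"), c(4, 3, 3)),
    rb("OPC", c("Ptprz1", "Pdgfra"), c(3, 3)),
    rb("Oligodendrocyte", c("Ptn", "Apoe", "Jag1", "Tgfb1"), c(3, 3, 3, 3)),
    rb("Oligodendrocyte", c("Ephb4"), 2),
    rb("Microglia", c("Igf1", "Apoe", "Cxcl12", "Tgfb1"), c(4, 3, 3, 4)),
    rb("Microglia", c("Tgfbr1"), 4),
    rb("Endothelial", c("Igf1", "Cxcl12", "Fgf2", "Vegfa", "Pdgfa"),
       c(3, 4, 3, 4, 3)),
    rb("Endothelial", c("Flt1", "Ephb4"), c(4, 3)))
}

#' Validate a simulation configuration
#'
#' Collects all invariant violations (fractions outside \[0, 1\], negative
#' expected counts, non-increasing ages, rho outside \[0, 1\], genes named
#' in a spec but absent from an explicit gene universe) rather than
#' stopping at the first.
#'
#' @param config a `niche_sim_config`.
#' @return character vector of violations; empty when valid.
#' @export
validate_sim_config <- function(config) {
  v <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  chk(all(config$cell_types >= 0), "cell_types: expected counts must be >= 0")
  chk(all(diff(config$age_groups) > 0),
      "age_groups must be strictly increasing")
  af <- config$cycle_spec$active_fraction
  chk(all(af >= 0 & af <= 1), "cycle_spec$active_fraction outside [0, 1]")
  chk(config$receptor_spec$high_fraction >= 0 &&
        config$receptor_spec$high_fraction <= 1,
      "receptor_spec$high_fraction outside [0, 1]")
  chk(config$silent_fraction >= 0 && config$silent_fraction <= 1,
      "silent_fraction outside [0, 1]")
  if (nrow(config$lr_coupling))
    chk(all(config$lr_coupling$rho >= 0 & config$lr_coupling$rho <= 1),
        "lr_coupling$rho outside [0, 1]")
  chk(all(config$nb_dispersion > 0), "nb_dispersion must be positive")
  chk(config$libsize_sigma >= 0, "libsize_sigma must be >= 0")
  named <- .sim_named_genes(config)
  if (!is.null(config$gene_names)) {
    unknown <- setdiff(named, config$gene_names)
    if (length(unknown))
      v <- c(v, paste0("configuration error: gene(s) named in a spec but ",
                       "absent from gene_names: ",
                       paste(unknown, collapse = ", ")))
    chk(length(config$gene_names) == config$n_genes,
        "gene_names length must equal n_genes")
  } else {
    chk(config$n_genes >= length(named) + config$n_mito_genes,
        "n_genes too small for the named program genes")
  }
  v
}

.sim_named_genes <- function(config) {
  unique(c(unlist(lapply(config$marker_spec, names)),
           config$cycle_spec$s_genes, config$cycle_spec$g2m_genes,
           config$receptor_spec$genes, config$sex_spec$genes,
           config$lr_program$gene,
           config$lr_coupling$ligand, config$lr_coupling$receptor))
}

.sim_mito_names <- function(n) {
  pool <- c("mt-Nd1", "mt-Nd2", "mt-Nd3", "mt-Nd4", "mt-Nd5", "mt-Co1",
            "mt-Co2", "mt-Co3", "mt-Cytb", "mt-Atp6", "mt-Atp8", "mt-Nd6")
  if (n <= length(pool)) pool[seq_len(n)]
  else c(pool, sprintf("mt-x%02d", seq_len(n - length(pool))))
}

#' Couple ligand and receptor means through a shared latent factor
#'
#' Multiplies per-cell ligand and receptor means by `2^(log2_effect * rho *
#' latent)`, a shared binary latent activity. At `rho = 0` the means are
#' returned unchanged; at `rho = 1` both genes carry the full latent
#' amplitude, so their binarized states coincide across cells.
#'
#' @param latent per-cell 0/1 latent activity draw.
#' @param ligand_mean,receptor_mean per-cell means (same length as
#'   `latent`).
#' @param rho coupling strength in \[0, 1\].
#' @param log2_effect latent amplitude in log2 units at `rho = 1`.
#' @return list with adjusted `ligand_mean`, `receptor_mean`, and the
#'   `latent` used.
#' @export
couple_lr <- function(latent, ligand_mean, receptor_mean, rho,
                      log2_effect = 1) {
  if (!is.numeric(rho) || length(rho) != 1 || is.na(rho) || rho < 0 || rho > 1)
    stop("rho must be a single value in [0, 1]")
  stopifnot(length(latent) == length(ligand_mean),
            length(latent) == length(receptor_mean))
  f <- 2^(log2_effect * rho * latent)
  list(ligand_mean = ligand_mean * f,
       receptor_mean = receptor_mean * f,
       latent = latent)
}

#' Simulate a synthetic neurogenic niche
#'
#' Draws a sparse gene x cell UMI count matrix under the configured
#' generative model together with a complete machine-readable truth record
#' (per-cell labels, planted differential effects, per-sample composition,
#' realized couplings). Identical configurations and seeds give
#' bit-identical output.
#'
#' @param config a valid [niche_sim_config()].
#' @return list with `sce` (a `SingleCellExperiment`, counts layer) and
#'   `truth` (list of data.frames: `cells`, `de`, `composition`,
#'   `couplings`, plus `params` echoing planted quantities).
#' @export
simulate_niche <- function(config) {
  viol <- validate_sim_config(config)
  if (length(viol)) stop("invalid simulation config:\n  ",
                         paste(viol, collapse = "\n  "))
  set.seed(config$seed)

  ## ---- gene universe and baseline means ----
  named <- .sim_named_genes(config)
  mito <- .sim_mito_names(config$n_mito_genes)
  if (!is.null(config$gene_names)) {
    genes <- config$gene_names
  } else {
    n_fill <- config$n_genes - length(named) - length(mito)
    genes <- c(named, mito, sprintf("gene%04d", seq_len(n_fill)))
  }
  n_genes <- length(genes)
  base_mean <- stats::rlnorm(n_genes, config$base_meanlog, config$base_sdlog)
  names(base_mean) <- genes
  lr_genes <- unique(c(config$lr_program$gene,
                       config$lr_coupling$ligand, config$lr_coupling$receptor))
  base_mean[intersect(lr_genes, genes)] <- 0   # program genes only where planted
  base_mean[intersect(mito, genes)] <- config$mito_mean
  ## planted sex-opposite genes get a defined, well-expressed baseline so
  ## their fold-changes act on a measurable level
  if (!is.null(config$sex_spec$base_mean))
    base_mean[intersect(config$sex_spec$genes, genes)] <-
      config$sex_spec$base_mean
  size <- rep_len(config$nb_dispersion, n_genes)

  ## ---- samples and cell labels ----
  ages <- config$age_groups
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      sex = config$sexes, age = ages,
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_%gmo_%s_r%d", config$region, grid$age,
                         grid$sex, grid$replicate)
  traj <- config$proportion_trajectory
  types <- names(config$cell_types)
  step_mult <- stats::setNames(rep(1, length(types)), types)
  shared <- intersect(names(traj), types)
  step_mult[shared] <- traj[shared]

  cells_list <- list()
  comp_list <- list()
  for (k in seq_len(nrow(grid))) {
    age_idx <- match(grid$age[k], ages)
    expected <- config$cell_types * step_mult^(age_idx - 1)
    n_tot <- round(sum(expected))
    probs <- expected / sum(expected)
    lab <- sample(types, n_tot, replace = TRUE, prob = probs)
    cells_list[[k]] <- data.frame(
      sample = grid$sample[k], region = config$region,
      age_months = grid$age[k], sex = grid$sex[k], type = lab,
      stringsAsFactors = FALSE)
    comp_list[[k]] <- data.frame(
      sample = grid$sample[k], type = types,
      expected_fraction = as.numeric(probs),
      realized_fraction = as.numeric(table(factor(lab, types))) / n_tot,
      stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells_list)
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("cell_%05d", seq_len(n_cells))
  age_idx <- match(cells$age_months, ages)

  ## ---- planted subtypes, phases, silence ----
  af <- config$cycle_spec$active_fraction[as.character(cells$age_months)]
  is_tap <- cells$type == "TAP"
  cells$tap_subtype <- NA_character_
  cells$tap_subtype[is_tap] <- ifelse(
    stats::runif(sum(is_tap)) < af[is_tap], "cycle_active", "cycle_inactive")
  cells$phase <- "G1"
  act <- which(!is.na(cells$tap_subtype) & cells$tap_subtype == "cycle_active")
  cells$phase[act] <- sample(c("S", "G2M"), length(act), replace = TRUE)

  is_nsc <- cells$type == "NSC"
  cells$nsc_subtype <- NA_character_
  cells$nsc_subtype[is_nsc] <- ifelse(
    stats::runif(sum(is_nsc)) < config$receptor_spec$high_fraction,
    "R_H", "R_L")

  cells$silent <- !is_nsc & stats::runif(n_cells) < config$silent_fraction

  ## ---- per-cell mean matrix ----
  mu <- matrix(base_mean, nrow = n_genes, ncol = n_cells,
               dimnames = list(genes, cells$cell_id))
  boost <- function(gene_set, cell_idx, l2fc) {
    g <- intersect(gene_set, genes)
    if (length(g) && length(cell_idx))
      mu[g, cell_idx] <<- mu[g, cell_idx] * 2^l2fc
  }
  for (tp in names(config$marker_spec)) {
    idx <- which(cells$type == tp)
    ms <- config$marker_spec[[tp]]
    for (g in names(ms)) boost(g, idx, ms[[g]])
  }
  ## broad identity programs: disjoint filler-gene sets per type
  programs <- list()
  if (config$program_size > 0) {
    special <- unique(c(named, mito, lr_genes))
    pool <- setdiff(genes, special)
    need <- config$program_size * length(types)
    if (length(pool) < need)
      stop("n_genes too small for per-type identity programs")
    picked <- sample(pool, need)
    for (k in seq_along(types)) {
      tp <- types[k]
      pg <- picked[((k - 1) * config$program_size + 1):(k * config$program_size)]
      programs[[tp]] <- pg
      boost(pg, which(cells$type == tp), config$program_log2fc)
    }
  }
  for (r in seq_len(nrow(config$lr_program))) {
    g <- config$lr_program$gene[r]
    idx <- which(cells$type == config$lr_program$type[r])
    if (g %in% genes && length(idx)) mu[g, idx] <- config$lr_program$mean[r]
  }
  ## NSC receptor-high boost, and age decline of the whole NSC LR program
  rg <- intersect(config$receptor_spec$genes, genes)
  hi <- which(!is.na(cells$nsc_subtype) & cells$nsc_subtype == "R_H")
  boost(rg, hi, config$receptor_spec$log2_effect)
  nsc_prog <- unique(config$lr_program$gene[config$lr_program$type == "NSC"])
  nsc_idx <- which(is_nsc)
  if (length(nsc_prog) && length(nsc_idx)) {
    decline <- 2^(config$receptor_spec$age_log2fc * (age_idx[nsc_idx] - 1))
    mu[intersect(nsc_prog, genes), nsc_idx] <-
      sweep(mu[intersect(nsc_prog, genes), nsc_idx, drop = FALSE], 2,
            decline, `*`)
  }
  ## cycle programs: cycle-active TAPs share a broad proliferation boost
  ## over the whole cycle set, with a phase-specific extra on their own set
  cyc_all <- unique(c(config$cycle_spec$s_genes, config$cycle_spec$g2m_genes))
  boost(cyc_all, which(cells$phase != "G1"), config$cycle_spec$log2_effect)
  phase_extra <- config$cycle_spec$phase_log2fc %||% 1
  boost(config$cycle_spec$s_genes, which(cells$phase == "S"), phase_extra)
  boost(config$cycle_spec$g2m_genes, which(cells$phase == "G2M"), phase_extra)
  ## sex-opposite aging genes in NSCs (equal magnitude, opposite sign)
  sx <- intersect(config$sex_spec$genes, genes)
  if (length(sx) && length(nsc_idx)) {
    sgn <- ifelse(cells$sex[nsc_idx] == config$sexes[1], 1, -1)
    amp <- config$sex_spec$log2_effect *
      (age_idx[nsc_idx] - 1) / max(1, length(ages) - 1)
    mu[sx, nsc_idx] <- sweep(mu[sx, nsc_idx, drop = FALSE], 2,
                             2^(sgn * amp), `*`)
  }
  ## silence the ligand program of silent niche cells
  lig_all <- intersect(unique(config$lr_coupling$ligand), genes)
  prog_lig <- unique(config$lr_program$gene)
  silent_idx <- which(cells$silent)
  if (length(silent_idx)) {
    lig_genes <- intersect(unique(c(lig_all, prog_lig)), genes)
    lig_genes <- intersect(lig_genes, .lr_ligand_universe(config))
    if (length(lig_genes)) mu[lig_genes, silent_idx] <- 0
  }
  ## latent ligand-receptor coupling
  coup_rows <- list()
  if (nrow(config$lr_coupling)) {
    for (r in seq_len(nrow(config$lr_coupling))) {
      cp <- config$lr_coupling[r, ]
      latent <- stats::rbinom(n_cells, 1, 0.5)
      adj <- couple_lr(latent, mu[cp$ligand, ], mu[cp$receptor, ], cp$rho,
                       config$coupling_log2_effect)
      snd <- which(cells$type == cp$sender)
      rcv <- which(cells$type == cp$receiver)
      mu[cp$ligand, snd] <- adj$ligand_mean[snd]
      mu[cp$receptor, rcv] <- adj$receptor_mean[rcv]
      coup_rows[[r]] <- data.frame(cp, n_sender = length(snd),
                                   n_receiver = length(rcv))
    }
  }
  ## per-cell library-size factor
  lib <- stats::rlnorm(n_cells, 0, config$libsize_sigma)
  mu <- sweep(mu, 2, lib, `*`)

  ## ---- counts: NB draws thinned by logistic dropout ----
  if (all(is.infinite(size))) {
    counts <- stats::rpois(length(mu), lambda = as.vector(mu))
  } else {
    counts <- stats::rnbinom(length(mu), size = size, mu = as.vector(mu))
  }
  if (is.finite(config$dropout_midpoint)) {
    nz <- which(counts > 0)
    p_drop <- stats::plogis(config$dropout_slope *
                              (config$dropout_midpoint - log(mu[nz])))
    counts[nz][stats::runif(length(nz)) < p_drop] <- 0
  }
  counts <- matrix(counts, nrow = n_genes, ncol = n_cells,
                   dimnames = dimnames(mu))
  perm <- sample(n_cells)
  counts <- counts[, perm, drop = FALSE]
  cells <- cells[perm, , drop = FALSE]
  rownames(cells) <- NULL

  sce <- as_niche_sce(Matrix::Matrix(counts, sparse = TRUE),
                      cells[, c("cell_id", "sample", "region", "age_months",
                                "sex")])

  ## ---- truth record ----
  de <- .sim_truth_de(config, genes)
  if (length(programs))
    de <- rbind(de, do.call(rbind, lapply(names(programs), function(tp)
      data.frame(contrast = paste0("program:", tp), gene = programs[[tp]],
                 log2fc = config$program_log2fc, stringsAsFactors = FALSE))))
  composition <- do.call(rbind, comp_list)
  truth <- list(
    cells = cells,
    de = de,
    composition = composition,
    couplings = if (length(coup_rows)) do.call(rbind, coup_rows) else
      config$lr_coupling,
    params = list(
      tap_active_fraction = config$cycle_spec$active_fraction,
      nsc_high_fraction = config$receptor_spec$high_fraction,
      silent_fraction = config$silent_fraction,
      sex_opposite_genes = intersect(config$sex_spec$genes, genes),
      receptor_age_log2fc = config$receptor_spec$age_log2fc,
      seed = config$seed))
  list(sce = sce, truth = truth)
}

## ligand-side gene universe used for silencing: genes that appear as a
## ligand in the default curated table orientation (column position in
## lr_program is type-agnostic, so restrict to known ligand symbols).
.lr_ligand_universe <- function(config) {
  unique(c(config$lr_coupling$ligand,
           c("Bdnf", "Mdk", "Ptn", "Dll1", "Jag1", "Igf1", "Fgf2", "Apoe",
             "Cxcl12", "Shh", "Vegfa", "Efnb2", "Egf", "Pdgfa", "Tgfb1")))
}

.sim_truth_de <- function(config, genes) {
  rows <- list()
  for (tp in names(config$marker_spec)) {
    ms <- config$marker_spec[[tp]]
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste0("marker:", tp), gene = names(ms),
      log2fc = as.numeric(ms), stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- data.frame(
    contrast = "tap_cycle_active_vs_inactive",
    gene = unique(c(config$cycle_spec$s_genes, config$cycle_spec$g2m_genes)),
    log2fc = config$cycle_spec$log2_effect, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    contrast = "nsc_RH_vs_RL", gene = config$receptor_spec$genes,
    log2fc = config$receptor_spec$log2_effect, stringsAsFactors = FALSE)
  n_steps <- length(config$age_groups) - 1
  rows[[length(rows) + 1L]] <- data.frame(
    contrast = "nsc_old_vs_young_lr_program",
    gene = unique(config$lr_program$gene[config$lr_program$type == "NSC"]),
    log2fc = config$receptor_spec$age_log2fc * n_steps,
    stringsAsFactors = FALSE)
  sx <- config$sex_spec$genes
  rows[[length(rows) + 1L]] <- data.frame(
    contrast = paste0("nsc_old_vs_young_", config$sexes[1]),
    gene = sx, log2fc = config$sex_spec$log2_effect, stringsAsFactors = FALSE)
  rows[[length(rows) + 1L]] <- data.frame(
    contrast = paste0("nsc_old_vs_young_", config$sexes[2]),
    gene = sx, log2fc = -config$sex_spec$log2_effect,
    stringsAsFactors = FALSE)
  de <- do.call(rbind, rows)
  de[de$gene %in% genes, , drop = FALSE]
}

#' Write a truth record to tab-separated files
#'
#' @param truth truth record from [simulate_niche()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("cells", "de", "composition", "couplings"))
    .write_tsv_plain(truth[[nm]], file.path(dir, paste0("truth_", nm, ".tsv")))
  yaml::write_yaml(truth$params, file.path(dir, "truth_params.yaml"))
  invisible(dir)
}

#' Write a simulation configuration as YAML
#' @param config a `niche_sim_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$lr_program <- as.list(cfg$lr_program)
  cfg$lr_coupling <- as.list(cfg$lr_coupling)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read a simulation configuration from YAML
#' @param path YAML file written by [write_sim_config()].
#' @return a `niche_sim_config`.
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$cell_types <- unlist(cfg$cell_types)
  cfg$proportion_trajectory <- unlist(cfg$proportion_trajectory)
  cfg$marker_spec <- lapply(cfg$marker_spec, unlist)
  cfg$cycle_spec$active_fraction <- unlist(cfg$cycle_spec$active_fraction)
  cfg$lr_program <- as.data.frame(cfg$lr_program, stringsAsFactors = FALSE)
  cfg$lr_coupling <- as.data.frame(cfg$lr_coupling, stringsAsFactors = FALSE)
  cfg$sexes <- as.character(cfg$sexes)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "niche_sim_config"
  cfg
}
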