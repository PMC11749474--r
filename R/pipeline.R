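#' Derive a stage seed from the global seed
#'
#' Stable hash of the stage name folded into the global seed, so adding a
#' stage never perturbs the randomness of earlier stages.
#'
#' @param global_seed integer global seed.
#' @param stage stage name.
#' @return integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 104729
  as.integer((as.numeric(global_seed) * 7919 + h) %% (2^31 - 1))
}

#' Validate a pipeline run configuration
#'
#' Reports every invariant violation at once rather than stopping at the
#' first: exactly one input source, sane QC thresholds, positive
#' normalization scale, positive clustering parameters.
#'
#' @param config a run-configuration list or path to a YAML file.
#' @return character vector of violations; empty when the config is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  v <- character()
  src <- config$input
  n_src <- sum(!is.null(src$simulate) && isTRUE(src$simulate),
               !is.null(src$triplet_dir))
  if (n_src != 1)
    v <- c(v, "input: exactly one of 'simulate: true' or 'triplet_dir' required")
  qc <- config$qc
  if (!is.null(qc)) {
    if (!is.null(qc$min_genes) && qc$min_genes < 0)
      v <- c(v, "qc$min_genes must be >= 0")
    if (!is.null(qc$max_mito) && (qc$max_mito < 0 || qc$max_mito > 1))
      v <- c(v, "qc$max_mito must be in [0, 1]")
    if (!is.null(qc$min_genes) && !is.null(qc$max_genes) &&
        qc$min_genes >= qc$max_genes)
      v <- c(v, "qc$min_genes must be < qc$max_genes")
    if (!is.null(qc$min_cells) && qc$min_cells < 0)
      v <- c(v, "qc$min_cells must be >= 0")
  }
  if (!is.null(config$normalize$scale) && config$normalize$scale <= 0)
    v <- c(v, "normalize$scale must be positive")
  cl <- config$cluster
  if (!is.null(cl)) {
    for (f in c("n_top_genes", "n_components", "k_neighbors", "resolution"))
      if (!is.null(cl[[f]]) && cl[[f]] <= 0)
        v <- c(v, paste0("cluster$", f, " must be positive"))
  }
  if (is.null(config$seed))
    v <- c(v, "seed is required")
  v
}

#' Run the full niche analysis pipeline
#'
#' Executes the stages input (simulate or read) -> qc -> normalize ->
#' cluster -> annotate -> cellcycle -> differential -> communication,
#' writing each stage's tables before the next stage starts and returning a
#' machine-readable run report (per-stage dimensions, parameter echoes,
#' output checksums). Identical config and seed give byte-identical output
#' files.
#'
#' @param config run-configuration list or path to YAML (see
#'   [validate_config()]); recognized fields: `input` (`simulate: true` or
#'   `triplet_dir`), `sim` (overrides for [niche_sim_config()]), `qc`,
#'   `normalize$scale`, `cluster`, `marker_panel` (YAML path; default SVZ
#'   panel), `lr_table` (TSV path; default shipped table), `contrast`
#'   (`young_age`, `old_age`, `focal_type`), `seed`.
#' @param out_dir output directory.
#' @return run report (list), invisibly written to `report.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  viol <- validate_config(config)
  if (length(viol)) stop("invalid config:\n  ", paste(viol, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  report <- list(seed = seed, stages = list(),
                 versions = list(nichecomm = as.character(
                   utils::packageVersion("nichecomm")),
                   R = paste(R.version$major, R.version$minor, sep = ".")))
  outputs <- character()
  env <- new.env()

  run_stage <- function(name, fn) {
    message("[nichecomm] stage: ", name)
    info <- tryCatch(fn(stage_seed(seed, name)), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$stages[[name]] <<- info
  }
  save_tsv <- function(df, file) {
    path <- file.path(out_dir, file)
    .write_tsv_plain(df, path)
    outputs <<- c(outputs, path)
    path
  }

  run_stage("input", function(s) {
    if (isTRUE(config$input$simulate)) {
      sim_args <- config$sim %||% list()
      if (is.null(sim_args$seed)) sim_args$seed <- s
      sim <- do.call(niche_sim_config, sim_args)
      res <- simulate_niche(sim)
      env$sce <- res$sce
      env$truth <- res$truth
      write_truth(res$truth, file.path(out_dir, "truth"))
    } else {
      env$sce <- read_10x_triplet(config$input$triplet_dir)
    }
    list(n_genes = nrow(env$sce), n_cells = ncol(env$sce),
         source = if (isTRUE(config$input$simulate)) "simulate" else
           config$input$triplet_dir)
  })

  run_stage("qc", function(s) {
    th <- do.call(qc_thresholds, config$qc %||% list())
    res <- qc_filter(env$sce, th)
    env$sce <- res$sce
    jsonlite::write_json(res$report, file.path(out_dir, "qc_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    res$report
  })

  run_stage("normalize", function(s) {
    scale <- config$normalize$scale %||% 1e6
    env$sce <- normalize_counts(env$sce, scale)
    list(scale = scale, zero_total_cells =
           sum(SummarizedExperiment::colData(env$sce)$zero_total))
  })

  run_stage("cluster", function(s) {
    cl <- config$cluster %||% list()
    env$labels <- cluster_cells(
      env$sce, n_top_genes = cl$n_top_genes %||% 2000,
      n_components = cl$n_components %||% 30,
      k_neighbors = cl$k_neighbors %||% 15,
      resolution = cl$resolution %||% 1, seed = s)
    save_tsv(data.frame(cell_id = names(env$labels),
                        cluster = as.character(env$labels)),
             "cluster_labels.tsv")
    list(n_clusters = nlevels(env$labels), params = cl)
  })

  run_stage("annotate", function(s) {
    panel <- if (!is.null(config$marker_panel))
      read_marker_panel(config$marker_panel) else default_marker_panel("SVZ")
    ann <- assign_types(env$sce, env$labels, panel)
    env$cell_types <- ann$cell_types
    save_tsv(data.frame(cell_id = names(ann$cell_types),
                        cell_type = unname(ann$cell_types)),
             "cell_types.tsv")
    save_tsv(ann$assignment, "cluster_assignment.tsv")
    comp <- composition_by_sample(ann$cell_types, .cell_meta(env$sce))
    env$composition <- comp
    save_tsv(comp, "composition.tsv")
    list(types = table(ann$cell_types))
  })

  run_stage("cellcycle", function(s) {
    cc <- score_cell_cycle(env$sce, seed = s)
    env$cellcycle <- cc
    save_tsv(cc, "cellcycle.tsv")
    taps <- names(env$cell_types)[env$cell_types == "TAP"]
    if (length(taps) >= 20) {
      cyc <- unique(unlist(default_cycle_genes()))
      sub <- subcluster_tap(env$sce, taps, cyc, seed = s)
      if (!sub$degenerate) {
        save_tsv(data.frame(cell_id = names(sub$labels),
                            tap_subtype = unname(sub$labels)),
                 "tap_subtypes.tsv")
        save_tsv(sub$fractions_by_age, "tap_active_fraction_by_age.tsv")
        env$tap_sub <- sub
      }
    }
    list(phases = table(cc$phase))
  })

  run_stage("differential", function(s) {
    ct <- config$contrast %||% list()
    young <- ct$young_age %||% 2
    old <- ct$old_age %||% 19
    focal <- ct$focal_type %||% "NSC"
    meta <- .cell_meta(env$sce)
    fc <- names(env$cell_types)[env$cell_types == focal]
    age <- meta$age_months[match(fc, meta$cell_id)]
    sex <- meta$sex[match(fc, meta$cell_id)]
    deg <- wilcoxon_deg(env$sce, fc[age == old], fc[age == young])
    save_tsv(deg, paste0("deg_", focal, "_", old, "_vs_", young, "mo.tsv"))
    degs <- list()
    for (sx in unique(sex)) {
      ga <- fc[age == old & sex == sx]; gb <- fc[age == young & sex == sx]
      if (length(ga) >= 3 && length(gb) >= 3)
        degs[[sx]] <- wilcoxon_deg(env$sce, ga, gb)
    }
    if (length(degs) == 2) {
      opp <- opposite_sex_pattern(degs[[1]], degs[[2]])
      names(opp) <- sub("female", names(degs)[1], names(opp))
      names(opp) <- sub("male", names(degs)[2], names(opp))
      save_tsv(opp, "sex_opposite_genes.tsv")
      env$sex_opposite <- opp
    }
    anova_res <- NULL
    if ("TAP" %in% env$composition$cell_type) {
      anova_res <- tryCatch(
        proportion_anova_dunnett(env$composition, "TAP", young),
        error = function(e) NULL)
      if (!is.null(anova_res)) save_tsv(anova_res$dunnett, "tap_dunnett.tsv")
    }
    env$deg <- deg
    list(n_deg_tested = nrow(deg),
         n_deg_significant = sum(deg$q <= 0.05),
         tap_anova_p = if (!is.null(anova_res)) anova_res$p else NA)
  })

  run_stage("communication", function(s) {
    lr <- if (!is.null(config$lr_table)) {
      if (!file.exists(config$lr_table))
        stop("ligand-receptor table not found: ", config$lr_table)
      read_lr_table(config$lr_table)
    } else default_lr_table()
    ct <- config$contrast %||% list()
    focal <- ct$focal_type %||% "NSC"
    nsc <- names(env$cell_types)[env$cell_types == focal]
    niche <- names(env$cell_types)[!env$cell_types %in%
                                     c(focal, "unassigned")]
    auto <- global_score(env$sce, lr, nsc, nsc, "receptor_side")
    save_tsv(data.frame(cell_id = names(auto$scores),
                        global_score = unname(auto$scores)),
             "comm_scores_nsc_nsc.tsv")
    niche_s <- global_score(env$sce, lr, niche, nsc, "ligand_side")
    save_tsv(data.frame(cell_id = names(niche_s$scores),
                        global_score = unname(niche_s$scores)),
             "comm_scores_niche_to_nsc.tsv")
    net <- differential_lr_network(
      env$sce, lr, env$cell_types, ct$young_age %||% 2, ct$old_age %||% 19,
      focal_type = focal)
    save_tsv(net, "lr_network.tsv")
    env$comm <- list(auto = auto, niche = niche_s, network = net)
    list(silent_niche_fraction = fraction_silent(niche_s),
         n_network_edges = nrow(net))
  })

  report$stages <- report$stages
  report$outputs <- as.list(tools::md5sum(outputs))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(report)
}
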