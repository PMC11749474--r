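# nichecomm

Single-cell analysis of the aging neurogenic niches — the subventricular
zone (SVZ) and dentate gyrus (DG) of the adult mouse brain — with a
per-cell ligand–receptor intercellular-communication score.

Adult neurogenesis declines with age, both because neural stem cells
(NSCs) become less functional and because the surrounding niche signals
them less effectively. `nichecomm` is for researchers who profile these
niches with droplet scRNA-seq across ages and sexes and want a tested,
reusable pipeline for the downstream questions: which cell types are
present and how their proportions shift with age, which transient
amplifying progenitors (TAPs) are cycling, which NSCs are primed
(receptor-high) versus dormant, which genes age differently in females and
males, and — centrally — how much each cell communicates with the NSC
compartment through curated ligand–receptor (LR) pairs.

## The model

For a focal cell *c* and a curated pair *(l, r)*, with cells normalized to
counts-per-million (3'-tag UMI data carries no gene-length term), the pair
contribution on the receptor side is

```
s_p(c) = x_r(c) · mean_partner(x_l)
```

the focal cell's normalized receptor expression times the partner
population's mean normalized ligand expression (partner means are taken
within each sample, then averaged across samples of the same age group).
The **global communication score** is `S(c) = Σ_p s_p(c)`, summed over the
curated table; a cell with `S(c) = 0` communicates through none of the
pairs and is called **silent** — the only scale-free definition of "no
communication". Scores are summarized as per-cell cumulative-fraction
(ECDF) curves and silent fractions, and LR pairs that change with age are
assembled into a differential network whose edges are weighted by the
**normalized mutual information** between the discretized ligand and
receptor expression, nMI = MI / mean(H_ligand, H_receptor) ∈ [0, 1].

Around this core the package provides 10x-style MatrixMarket IO, QC
filtering, graph-based clustering (PCA → SNN graph → Louvain), marker-panel
cell-type annotation with negative markers (NSCs are called by Nr2e1,
Thbs4, Igfbp5, Notum and the *absence* of Aqp4, Tril, Grin2c),
binned-control cell-cycle phase scoring, Wilcoxon rank-sum differential
expression with Benjamini–Hochberg control, one-way ANOVA with Dunnett
many-to-one comparisons for composition trends, and a negative-binomial
synthetic niche generator with planted ground truth that every stage is
validated against.

## Worked example

```r
library(nichecomm)

sim <- simulate_niche(niche_sim_config(seed = 1))   # 8 samples, 4 ages, 2 sexes
sce <- qc_filter(sim$sce, qc_thresholds(min_genes = 300))$sce
sce <- normalize_counts(sce)                        # CPM + log1p layers

labels <- cluster_cells(sce, seed = 1)
ann    <- assign_types(sce, labels, default_marker_panel("SVZ"))
table(ann$cell_types)
#>  Astrocyte Endothelial  Microglia   NB  NSC Oligodendrocyte  OPC  TAP
#>        675         420        408  368  636             383  333  339

lr   <- default_lr_table()
nsc  <- names(ann$cell_types)[ann$cell_types == "NSC"]
auto <- global_score(sce, lr, nsc, nsc, "receptor_side")
tapply(auto$scores, sce[, nsc]$age_months, mean)
#>        2        7       12       19
#> 51624863 24905414 17571902  5960234
```

The autocrine NSC scores fall roughly ninefold from 2 to 19 months: the
simulated niche plants an age-declining NSC receptor program, and the
score recovers it as a monotone loss of communication. The acceptance run
below (`--seed 1`) continues from the same machinery: `subcluster_tap()`
recovers the planted 60/40 cycle-active/inactive TAP split (55.3% active),
`opposite_sex_pattern()` returns exactly the 14 planted sex-opposite aging
genes, and `fraction_silent()` reports 34.6% of niche cells sending no
curated ligand (planted: 35%).

`run_pipeline(config, out_dir)` chains all stages from one YAML config
(see `inst/extdata/example_run_config.yaml`) and writes every table plus a
JSON run report with parameter echoes and output checksums.

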