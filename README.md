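# srtnorm

Benchmarking gene count normalization for imaging-based spatially resolved
transcriptomics (im-SRT) under skewed gene panels.

## The problem

im-SRT technologies (MERFISH, STARmap, seqFISH, CosMx, Xenium, ...) probe a
pre-selected **gene panel** of a few hundred species per cell, with spatial
coordinates. Panels designed around a region or cell type of interest
overrepresent that subpopulation's transcripts, so its cells detect more
total counts for technical reasons. Any normalization whose per-cell scaling
factor is derived from detected counts — library size (factor
$s_i = \sum_g c_{gi}$), median-of-ratios / poscounts, TMM, NB Pearson
residuals — then deflates that subpopulation's normalized expression
$x_{gi} = c_{gi}/s_i$ in a region-specific way, while count-independent
factors (cell **volume** or area) are immune by construction. `srtnorm`
simulates im-SRT-like data with controllable panel skew and quantifies the
downstream damage:

* **panel skew** (KL divergence, nats):
  $\mathrm{Skew} = \sum_i P_i \ln(P_i/Q_i)$, with $P_i$ a subpopulation's
  share of detected counts and $Q_i$ its share of cells;
* **differential expression**: one-sided Wilcoxon region-vs-rest with BH
  adjustment; log2 fold change
  $\mathrm{LFC}_{A,g} = \log_2(\bar{x}^A_g / \bar{x}^{A'}_g)$ (no
  pseudocount);
* **concordance vs the full panel as ground truth**:
  $\mathrm{FPR} = FP/(FP{+}TN)$, $\mathrm{FNR} = FN/(FN{+}TP)$ on
  significance; switched-positive/negative fold-change rates
  $\mathrm{SPR} = SP/(SP{+}TN)$, $\mathrm{SNR} = SN/(SN{+}TP)$; scaling
  factor RMSE on unit-mean factors; per-gene Pearson correlation;
* **spatially variable genes**: 50 µm rasterization, log10(x+1), permutation
  Moran's I with k-nearest-neighbour bin weights, SVG false-negative rates;
* **partial-volume capture**: spherical cells cut by a finite Z stack
  (spherical-cap fraction $h^2(3r-h)/(4r^3)$), count thinning, and a PCA /
  silhouette separability comparison across normalizations.

## Worked example

Simulate a MERFISH-like dataset (500 genes x 2000 cells, two spatial
subpopulations, 30% of genes enriched per subpopulation at ~2.7x), draw a
100-gene panel skewed to subpopulation A, and compare library-size against
volume normalization, taking the full panel as ground truth:

```r
library(srtnorm)

cfg <- list(
  sim = sim_config(n_genes = 500, n_cells = 2000, de_prob = 0.3, seed = 101),
  panels = list(list(type = "skewed", subpop = "A", size = 100, seed = 101)),
  methods = c("library_size", "volume"),
  seed = 101
)
res <- run_evaluation(cfg)
print(res$report, digits = 3)
#>       panel       method        metric value
#> 1  skewed:A library_size       sf_rmse 0.509
#> 2  skewed:A library_size median_gene_r 0.843
#> 3  skewed:A library_size           fpr 0.060
#> 4  skewed:A library_size           fnr 0.180
#> 5  skewed:A library_size           spr 0.470
#> 6  skewed:A library_size           snr 0.470
#> 7  skewed:A       volume       sf_rmse 0.000
#> 8  skewed:A       volume median_gene_r 1.000
#> 9  skewed:A       volume           fpr 0.000
#> 10 skewed:A       volume           fnr 0.000
#> 11 skewed:A       volume           spr 0.000
#> 12 skewed:A       volume           snr 0.000
```

Reading the numbers: under **library size** normalization the A-skewed panel
inflates A cells' scaling factors (unit-mean factor RMSE 0.51 against the
full panel), drags per-gene expression correlation down to a median of 0.84,
and — against the full-panel ground truth — loses 18% of significant DE
calls (FNR 0.18) and flips the sign of 47% of evaluable fold changes (SPR =
SNR 0.47; with two subpopulations the A-vs-rest and B-vs-rest switches
mirror each other). Under **volume** normalization the scaling factor does
not depend on which genes were probed, so every metric is exactly at its
no-distortion value (RMSE 0, correlation 1, all rates 0).

The panel skew score confirms the design:

```r
panel_counts <- subset_panel(res$data$counts, res$panels[["skewed:A"]])
compute_skew(panel_counts, res$data$cells)   # 0.1017 nats
compute_skew(res$data$counts, res$data$cells) # 0.0003 nats (full panel)
```

Other entry points: `run_panel_size_sweep()` (skew and factor separation as
top-k panels grow, emulating the scRNA-seq panel-design experiment),
`run_capture_study()` (partial cell capture by a 7-plane Z stack and
separability after normalization), and a CLI
(`inst/cli/srtnorm <simulate|capture|evaluate|sweep> --config cfg.json --out dir`).

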