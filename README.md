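# flipper

Differential RNA-binding-protein (RBP) binding analysis from eCLIP
window-level count data, with explicit control for RNA expression.

## The problem

CLIP-family assays measure where an RBP binds by sequencing the RNA
fragments it is crosslinked to. The read count at a binding site reflects
*both* the strength of the protein–RNA interaction and the abundance of the
RNA substrate. When a drug or mutation changes gene expression, an
IP-only differential analysis cannot tell increased binding from increased
substrate. eCLIP uniquely ships a size-matched input (IN) library alongside
the immunoprecipitate (IP); this package uses it as an expression covariate
rather than only as background.

## The model

Analysis operates on ~100 bp transcriptomic windows with per-sample integer
counts (as emitted by a window-based peak caller). For every window showing
significant IP enrichment in at least one condition, the package builds a
unified count table pairing window-level IP counts with gene-level input
counts (INg — IN reads summed over all windows of the window's gene, since
size-matched input is too sparse at single-window resolution). Each window
is then fit with a negative-binomial GLM (log link, dispersion shrinkage
via DESeq2) under the design

```
~ assay + treatment + assay:treatment
```

where `assay` ∈ {IN, IP} and `treatment` ∈ {control, treatment}. The
`assay:treatment` interaction coefficient is the log2 change of the IP/INg
ratio between conditions: a change in pulldown that is mirrored by a change
in expression cancels out of it. Windows with BH-adjusted p < 0.05 and
|log2FC| > 1 are called differentially bound.

Normalization is hierarchical for IP libraries: within-condition factors
are estimated by median-of-ratios (MOR) on binding windows only, and
between-condition depth by MOR on background regions, multiplied together —
so a genuine global binding shift is not normalized away and
signal-to-noise differences between replicates are corrected. IN libraries
are normalized jointly with conventional MOR on the INg matrix.

The package also provides:

* a simplified beta-binomial enrichment caller (used to select tested
  windows and to realize two comparator methods: the ad-hoc per-condition
  set-difference method and a repurposed IP-vs-IP "peak caller" method);
* a synthetic eCLIP experiment generator with known per-gene binding
  strength κ, treatment binding effect ζ, and expression effect β;
* a sensitivity/precision benchmark harness over the ζ × β grid.

## Worked example

Simulate a small experiment with a 4-fold binding effect on half of 200
bound genes plus strong expression confounding (β ~ N(0, 2)), and run the
full pipeline:

```r
library(flipper)

cfg <- simulation_config(n_genes = 1000, n_bound = 200,
                         zeta = 4, beta_sd = 2, seed = 42)
sim <- simulate_experiment(cfg)
fit <- flipper_pipeline(sim$table, sim$samples)

head(fit$results[order(fit$results$padj), ], 5)
#>     window_id gene_id feature_type baseMean log2FC lfcSE   pvalue     padj direction
#>   G000024_w58 G000024         UTR3     2142   2.86 0.480 2.37e-09 2.85e-07        up
#>  G000502_w494 G000502         UTR3      303   2.81 0.475 3.58e-09 2.85e-07        up
#>    G000882_w3 G000882          CDS      956   2.68 0.459 4.81e-09 2.85e-07        up
#>  G000905_w142 G000905          CDS      867   2.56 0.475 6.84e-08 3.04e-06        up
#>   G000813_w46 G000813         UTR5      977   2.43 0.456 9.97e-08 3.55e-06        up

evaluate_calls(fit$results$window_id[fit$results$significant], sim$truth)
#>  TP FP FN sensitivity precision
#>  49  1 51        0.49      0.98
```

Of 179,615 simulated windows, 178 pass enrichment filtering and 50 are
called significant; 49 of the 50 are truly differential (precision 0.98)
and the recovered log2 fold changes cluster near log2(4) = 2 plus the
per-gene κ variation. `fit$gene_summaries` ranks genes by Fisher-combined
p-values over their significant windows, and `fit$factors` exposes the
hierarchical IP / joint IN size factors.

On real data, replace the simulated inputs with files:

```r
samples <- load_sample_sheet("samples.tsv")   # sample_id, assay, condition, replicate[, reference]
table   <- load_window_counts("windows.tsv", samples)
fit     <- flipper_pipeline(table, samples)
write_outputs(fit$results, fit$gene_summaries, "out/")
```

A command-line wrapper with `run`, `simulate`, `benchmark`, and
`summarize` subcommands is installed at
`system.file("cli/flipper.R", package = "flipper")`.

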