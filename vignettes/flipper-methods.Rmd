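---
title: "Expression-controlled differential RBP binding: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-controlled differential RBP binding: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models implemented in `flipper`,
the assumptions behind them, and the design decisions taken where more than
one reasonable implementation existed. It is the authoritative description
of *why* the package works the way it does; the function reference
documents *how* to call it.

## 1. The measurement model

An eCLIP experiment yields two library types per condition: the
immunoprecipitate (IP), enriched for fragments bound by the targeted RBP,
and a size-matched input (IN) that passed the same size selection but no
immunoprecipitation. The expected read count of an IP library at a bound
window is, to first order,

> (binding strength) × (RNA substrate abundance) × (technical scale),

while the IN library sees only abundance × scale. A treatment that changes
transcription therefore changes IP counts without any change in binding.
Differential *binding* must be defined as a change in the IP signal that is
**not** explained by the matching change in expression.

### Window counts and gene-level input

The unit of analysis is a ~100 bp transcriptomic window that does not cross
feature boundaries, with one integer count per sample (the output format of
window-based peak callers). Coordinates are 0-based half-open (BED
convention) end to end, so emitted BED files are bit-compatible with the
input windows.

Size-matched input is much sparser than total-RNA input: window-level IN
counts are mostly 0–2 and cannot estimate an expression ratio. IN counts
are therefore aggregated over **all** windows of a gene — not only enriched
ones; the sum is an expression measurement, and restricting it to enriched
windows would couple it to binding — giving the gene-level input INg used
as the expression covariate. All rows of a gene consequently carry
identical INg columns; this duplication is deliberate and is asserted as an
invariant. Genes whose INg is zero in every IN sample are dropped with a
warning, because their IP/INg ratio is undefined.

### The interaction GLM

For each tested window the counts across all samples are modeled as
negative binomial with log link under

```
~ assay + treatment + assay:treatment
```

with `assay` (IN reference, IP) and `treatment` (control reference,
treatment). Per-sample size factors enter as multiplicative offsets.
Fitting, the mean–dispersion trend, dispersion shrinkage, and the Wald test
are delegated to DESeq2 — this is a standard NB-GLM contract, and
re-implementing it would add risk without adding science. The reported
log2 fold change is the **unshrunken maximum-likelihood** interaction
coefficient: the significance thresholds (adjusted p < 0.05 and
|log2FC| > 1, both strict inequalities) are defined on that scale, and
posterior LFC shrinkage would silently change what the threshold means.
DESeq2's independent filtering and outlier handling are left at defaults;
windows it refuses to test carry `padj = NA` and are never called
significant (on simulated data about 2 % of tested windows, all at very low
base mean).

The interaction coefficient equals the log2 ratio-of-ratios
`(IP_trt/INg_trt) / (IP_ctrl/INg_ctrl)`. Two consequences are asserted as
tests: a constructed window whose IP ratio doubles against matched INg
recovers log2FC ≈ 1, and a window whose IP and INg both double recovers
log2FC ≈ 0 (expression absorbed).

### Gene summaries

Genes with at least one significant window are summarized by Fisher's
combined probability over the **raw** p-values of their significant
windows (Fisher's method is defined on untransformed p-values), the signed
sum of log2 fold changes, and the minimum p-value with its fold change.
Because a gene's rows share INg columns, these window tests are not
independent; the summaries are descriptive rankings, not calibrated
gene-level inference, and are documented as such.

## 2. Hierarchical normalization

Global scaling normalization assumes most features are unchanged. eCLIP
violates it twice: treatments can shift binding globally, and IP libraries
have an extra technical axis — pulldown/washing efficiency — that moves
binding-region signal and background in *opposite* directions, so a single
factor per IP sample confounds depth with signal-to-noise ratio.

IP factors are therefore estimated in two stages:

1. **Within-condition** median-of-ratios on binding windows only.
   Assumption: replicates of one condition have comparable overall binding.
   These factors are rescaled to geometric mean 1 within each condition so
   they carry no depth information (the renormalization prevents stage 1
   and stage 2 from double-counting depth).
2. **Between-condition** depth from background regions across all IP
   samples, collapsed to one factor per condition by a geometric mean
   (factors are multiplicative; an arithmetic mean would overweight
   high-depth replicates — an arithmetic switch is exposed for comparison).

The final factor is the product of the two components (the stages address
orthogonal multiplicative effects), rescaled to overall geometric mean 1.
The overall rescaling is cosmetic: because the model contains an assay main
effect, multiplying all IP factors (or all IN factors) by any constant
leaves the interaction coefficient unchanged, which the suite asserts
numerically to 1e-4 (the tolerance is set by the GLM fitter's convergence
criteria, not by the algebra).

IN libraries have no pulldown step, so all IN samples are normalized
jointly by one median-of-ratios pass over the INg matrix.

### Stage 2 operates on gene-aggregated background counts

Median-of-ratios excludes rows containing any zero. At window resolution
eCLIP background is so sparse that this filter selects a non-random subset
of windows: a gene whose expression rises under treatment has fewer zeros
in treatment samples, so the usable rows over-represent up-shifted genes
and the between-condition depth factor absorbs part of the expression
distribution. The INg factors suffer a much smaller version of the same
selection. The mismatch between the two biases shifts *every* interaction
estimate by a constant (about −0.5 log2 units under strong expression
effects in simulation). Stage 2 therefore sums background windows to the
gene level before median-of-ratios: aggregation removes most sparsity, and
because it mirrors the INg construction, any residual filter bias appears
identically in the IP and IN factor blocks and cancels out of the
interaction. With this choice, simulated bound-but-non-differential
windows recover mean log2FC ≈ 0 even with expression effects of SD 2.

### Zero handling

`mor_size_factors` follows the strict all-positive row filter and errors
when nothing survives; callers fall back to a logged variant that takes
per-row geometric means over positive entries only. The strict rule is the
default because the fallback's positivity conditioning is exactly the bias
described above; the fallback exists because eCLIP sparsity otherwise makes
small analyses brittle.

## 3. The enrichment caller and the comparators

Selecting tested windows (and the binding/background partition of the
normalization) requires an IP-over-IN enrichment test. The package ships a
deliberately **simplified** beta-binomial caller — replicates pooled by
summation, one global null fraction `p0` and one intra-class correlation
`rho`, upper-tail p-values, BH per run — and does not attempt GC-stratified
nulls or window re-testing. It exists to provide a consistent engine for
window selection and for the comparator methods, not to reproduce any
specific peak caller's calls.

Numerics: the tail `P(X ≥ x)` is accumulated from whichever side of `x`
has fewer terms (cost `min(x, n−x+1)` log-pmf evaluations per window, which
is small on sparse data); at `rho = 0` the exact binomial tail is used, and
the suite asserts equality to 1e-12 against `pbinom` and agreement with
numerical integration over the Beta mixing density for `rho > 0`. P-values
are clamped to `(1e-300, 1]`.

### Robust null estimation

The textbook estimates — pooled `p0 = Σx/Σn` and the method-of-moments
`rho` from `Var(x) = n p0 (1−p0)(1 + (n−1) rho)` — are both wrecked by the
minority of windows the test is supposed to find: enriched windows
contribute disproportionate read mass (dragging `p0` up, which makes every
null window look overdispersed) and enormous squared residuals with
`n(n−1)` weights (dragging `rho` toward the signal). The default estimator
(`estimate_null`) therefore:

1. initializes `p0` at the median per-window fraction;
2. iteratively trims windows whose per-window moment ratio exceeds
   Q3 + 3·IQR and re-pools `p0` over the kept windows;
3. solves the weighted moment equation on the kept set with
   variance-saturating weights `((n−1)/(1+(n−1)rho))²` — under
   overdispersion the information per window stops growing with `n`, so
   raw `n²` weights would let a few ultra-deep windows dominate.

On clean beta-binomial data the estimator recovers `rho = 0.1` as ≈ 0.085
at 10⁴ windows (the trim costs a small downward bias, growing at high
`rho`); under 3 % contamination by strongly enriched windows it stays at
the technical value where the plain estimator inflates by an order of
magnitude. The plain pooled path is retained as `null_method = "pooled"`
and as the exported `estimate_overdispersion`.

### Comparator methods

*Ad-hoc*: windows enriched exclusively in treatment are "up", exclusively
in control "down" — the classical qualitative approach, implemented as set
differences of the per-condition calls.

*IP-vs-IP repurposing* (a "Diff-Skipper"-style comparator): the enrichment
test is run twice genome-wide — treatment IP as foreground over control IP,
and the reverse — and the calls are then restricted to the tested-window
set. Two design points matter:

* The runs are genome-wide because a repurposed peak caller estimates its
  null on the whole dataset; estimating the null on the signal-dominated
  tested subset destroys the method outright.
* The null `rho` for these runs is calibrated on **within-condition
  replicate splits** (half of a condition's replicates as "foreground" of
  the condition total), i.e. technical variation only. A peak caller's
  null does not include cross-condition expression changes — which is
  precisely the documented failure mode of IP-only differential analysis:
  expression-driven IP shifts are indistinguishable from binding shifts to
  such a test. Calibrating instead on the marginal cross-condition
  dispersion would absorb the expression distribution into the null and
  make the comparator refuse to call anything under expression effects,
  which contradicts how repurposed peak callers behave in practice.

A window significant in both directions is impossible for one-sided tails
around a common null; if the two runs' differing null estimates ever
produce one, it is dropped from both sets with a warning.

## 4. The synthetic experiment generator

The generator emulates the count structure of a two-condition eCLIP
experiment with known truth, in five stages: gene-level NB counts →
binomial thinning → length assignment → window distribution → IP-only
binding injection. Defaults describe the full-size design (30,000 genes, 8
replicates split 4 IN / 4 IP and evenly between conditions, 6,000 bound
genes of which half are differential).

Per gene, intercept `a ~ N(intercept_mean, intercept_sd)` on log2 scale
gives baseline abundance `q = 2^a`; an expression treatment effect
`β ~ N(0, beta_sd)` multiplies treatment-condition means by `2^β`
(log2-linear, consistent with the intercept scale); counts are independent
NB draws with variance `m + α m²`, the dispersion `α(q) = a0 + a1/q` held
constant across replicates. Gene lengths are drawn from a heavy-tailed
log-normal emulating genomic (intron-inclusive) gene spans and matched to
expression by rank with Gaussian rank noise of SD
`coupling_strength · n_genes` (at the default 0.3 this yields a Spearman
correlation of roughly 0.7 — strong but imperfect, as in real data; the
noise scale convention is a package choice). Counts are split between a
random 20 % of "active" (exon-like) windows receiving 80 % of reads and the
inactive remainder, then distributed within each region by a single
multinomial draw per replicate with gamma window weights drawn **once per
gene** (shared across replicates, so a gene's profile is reproducible);
conservation of the gene count is exact and asserted window-by-window.
Binding is injected only into IP replicates: per bound gene a strength
`κ = 0.5 + Gamma(2, 0.5)` (strictly positive, mean 1.5), and per IP
replicate `round(gene count · κ · ζ_eff)` reads added to one fixed active
window, with `ζ_eff = ζ` only in treatment replicates of differential
genes. IN replicates are never touched (asserted bit-for-bit).

Parameter defaults with units and rationale:

| parameter | default | why |
|---|---|---|
| `intercept_mean`, `intercept_sd` | 7, 3 (log2) | median gene ≈ 128 generative reads, ~13 after thinning; dynamic range ~2^(7±3) matches deduplicated eCLIP gene-count spread |
| `beta_sd` | 0 (scenario parameter: 0 or 2) | expression constant vs. strongly confounded scenarios |
| `dispersion_a0`, `a1` | 0.05, 3 | asymptotic CV² 0.05 with Poisson-dominated low counts, the standard RNA-seq-like 1/q trend |
| `downsample_rate` | 0.1 | binomial thinning to eCLIP sparsity; thinning is the simplest mechanism consistent with "down-sampling" |
| `length_meanlog`, `length_sdlog` | log 5000, 1.5 (bp) | synthetic log-normal stand-in for genomic gene spans (median 5 kb, mean ~15 kb, clamped to [100, 10⁶] bp); a real annotation-derived sample would require a genome download and is deliberately not fabricated |
| `window_size` | 100 bp | the window convention of the upstream caller |
| `active_window_fraction`, `active_read_fraction` | 0.2, 0.8 | exon/intron read-depth contrast |
| `peakiness_active`, `peakiness_inactive` | 0.5, 2.0 | gamma shapes; smaller = peakier; active regions carry sharper peaks |
| `kappa_shift`, `shape`, `scale` | 0.5, 2, 0.5 | strictly positive binding with mean pulldown ≈ 1.5× the gene's read count at its peak — strong enough for an enrichment caller to see, as intended |
| `min_expression_for_binding` | q ≥ 20 | bound genes must be expressed; pre-thinning scale |
| `zeta` | 2 (scenarios use 2, 3, 4) | treatment binding fold change |

These defaults were fixed once as field-realistic values and are exposed in
the configuration; the benchmark's absolute sensitivity figures move with
the depth/dispersion choices (power), while the orderings between methods
and the expression-robustness of the interaction design do not.

What the generator does **not** emulate: crosslink-site read pileups, PCR
duplication, mappability and GC bias, overlapping windows, multi-RBP
competition, or any correlation between binding and expression *changes*.
Passing benchmarks here therefore demonstrate correct statistical behavior
under the stated generative model, not performance guarantees on any
particular real dataset.

## 5. Benchmarking

`run_benchmark` crosses ζ ∈ {2, 3, 4} with β-SD ∈ {0, 2}, simulates
`n_sim_reps` experiments per cell with seeds derived from a master seed by
a stable arithmetic hash (cells are independent and reorderable), runs the
interaction pipeline and both comparators on identical inputs, and scores
calls against truth. Sensitivity is TP/(TP+FN) over true differential
genes; precision is TP/(TP+FP) over calls, reported NA when nothing is
called. Default matching is per **window** (each bound gene has exactly one
injected window, so window- and gene-level matching agree except for
neighbor-window calls); a gene-level mode collapses duplicate calls per
gene for robustness analysis.

Problem sizes: the acceptance script runs the full grid at 6,000 genes /
1,200 bound with 5 simulation replicates per cell; the test suite runs the
heavy property checks at 3,000 genes / 600 bound with 3 replicates and the
expression-confound check at 6,000 genes. These sizes were chosen as the
smallest at which the benchmark's rate metrics are stable (they are
scale-free in the gene count, since all proportions are preserved).

## 6. Known limitations

* Pairwise designs only (two conditions, one RBP); no multi-factor models.
* The hierarchical scheme assumes pulldown efficiency does not differ
  *systematically* between conditions — that assumption is what lets a
  global binding shift survive normalization, and it is unverifiable
  without spike-ins.
* Gene summaries are descriptive (dependent window tests).
* The enrichment caller is a simplified stand-in; its calls should not be
  expected to match any specific peak caller on real data.
* The generator's absolute power figures depend on its depth and
  dispersion defaults; comparisons *between* methods on the same
  simulation are the robust quantity.
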