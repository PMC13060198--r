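# Negative-binomial interaction test on the unified IP/INg table.
#
# The model for each window is a NB GLM with log link and design
#   ~ assay + treatment + assay:treatment
# where assay is IN (reference) vs IP and treatment is control (reference)
# vs treatment. The assay:treatment coefficient is the log2 change of the
# IP/INg ratio between conditions: changes in pulldown that are mirrored by
# expression (INg) cancel out of it. Fitting, dispersion shrinkage toward a
# mean-dispersion trend, and Wald testing are delegated to DESeq2; per-sample
# size factors enter as multiplicative offsets.

#' Fit the assay-by-treatment interaction model
#'
#' Fits, per enriched window, a negative-binomial GLM on the unified table
#' (window-level IP counts next to gene-level INg counts) with design
#' `~ assay + treatment + assay:treatment` and reports the Wald test of the
#' interaction coefficient. The reported `log2FC` is the maximum-likelihood
#' interaction estimate (no posterior shrinkage is applied: the downstream
#' significance thresholds refer to the unshrunken coefficient). Windows
#' removed by the engine's independent filtering or outlier handling carry
#' `padj = NA` and are never called significant; all-zero windows are kept in
#' the output with NA statistics and flagged in the `all_zero` column.
#'
#' @param unified A `unified_table` from [build_unified_table()].
#' @param samples Validated sample sheet (defaults to the one embedded in
#'   `unified`).
#' @param factors data.frame with `sample_id` and `factor` columns (see
#'   [normalization_factors()]), covering every sample of the unified table.
#' @return data.frame with the window annotation plus `baseMean`, `log2FC`,
#'   `lfcSE`, `stat`, `pvalue`, `padj`, `all_zero`.
#' @export
fit_interaction_model <- function(unified, samples = unified$samples,
                                  factors) {
  if (nrow(unified$meta) < 2L)
    stop("at least two windows are required to fit the interaction model")
  idx <- match(colnames(unified$counts), factors$sample_id)
  if (any(is.na(idx)))
    stop("normalization factors missing for sample(s): ",
         paste(setdiff(colnames(unified$counts), factors$sample_id),
               collapse = ", "))
  sf <- factors$factor[idx]
  if (any(!is.finite(sf)) || any(sf <= 0))
    stop("normalization factors must be positive and finite")

  samp <- samples[match(colnames(unified$counts), samples$sample_id), ]
  col_data <- data.frame(
    assay = factor(samp$assay, levels = c("IN", "IP")),
    treatment = factor(samp$condition, levels = c("control", "treatment")),
    row.names = colnames(unified$counts))
  cells <- table(col_data$assay, col_data$treatment)
  if (any(cells == 0L))
    stop("design not full rank: an assay x treatment cell has no samples")

  counts <- unified$counts
  storage.mode(counts) <- "integer"
  dds <- DESeq2::DESeqDataSetFromMatrix(countData = counts,
                                        colData = col_data,
                                        design = ~ assay + treatment +
                                          assay:treatment)
  DESeq2::sizeFactors(dds) <- sf
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, name = "assayIP.treatmenttreatment")

  out <- cbind(unified$meta,
               data.frame(baseMean = res$baseMean,
                          log2FC = res$log2FoldChange,
                          lfcSE = res$lfcSE,
                          stat = res$stat,
                          pvalue = res$pvalue,
                          padj = res$padj,
                          all_zero = res$baseMean == 0,
                          row.names = NULL))
  rownames(out) <- NULL
  out
}

#' Flag significantly differentially bound windows
#'
#' A window is called significant when `padj < padj_threshold` (strict) and
#' `|log2FC| > lfc_threshold` (strict). Windows with `padj = NA` (filtered or
#' all-zero) are not significant. `direction` is `up` for positive and `down`
#' for negative interaction log2 fold changes.
#'
#' @param results data.frame from [fit_interaction_model()].
#' @param padj_threshold Adjusted p-value cutoff (default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 1).
#' @return `results` with `significant` (logical) and `direction`
#'   (`"up"`/`"down"`, NA when log2FC is NA) columns added.
#' @export
call_significant <- function(results, padj_threshold = 0.05,
                             lfc_threshold = 1) {
  stopifnot("padj" %in% names(results))
  results$significant <- !is.na(results$padj) & !is.na(results$log2FC) &
    results$padj < padj_threshold & abs(results$log2FC) > lfc_threshold
  results$direction <- ifelse(is.na(results$log2FC), NA_character_,
                              ifelse(results$log2FC > 0, "up", "down"))
  results
}

#' Per-gene summaries of significant windows
#'
#' For each gene with at least one significant window: Fisher's combined
#' probability over the raw p-values of the gene's significant windows
#' (X^2 = -2 * sum(log p) against chi-square with 2k df), the signed sum of
#' their log2 fold changes, and the minimum p-value with its fold change.
#' Because all windows of a gene share the same INg columns, the combined
#' p-values are not independent tests; the summaries are descriptive
#' rankings, not calibrated gene-level inference.
#'
#' @param results data.frame from [call_significant()].
#' @return data.frame with columns `gene_id`, `n_sig_windows`, `fisher_p`,
#'   `summed_lfc`, `min_p`, `lfc_at_min_p`, one row per gene with at least
#'   one significant window (empty if none).
#' @export
summarize_genes <- function(results) {
  sig <- results[!is.na(results$significant) & results$significant, ,
                 drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(gene_id = character(0), n_sig_windows = integer(0),
                      fisher_p = numeric(0), summed_lfc = numeric(0),
                      min_p = numeric(0), lfc_at_min_p = numeric(0)))
  }
  parts <- split(sig, sig$gene_id)
  out <- do.call(rbind, lapply(parts, function(g) {
    k <- nrow(g)
    x2 <- -2 * sum(log(pmax(g$pvalue, 1e-300)))
    i <- which.min(g$pvalue)
    data.frame(gene_id = g$gene_id[1L],
               n_sig_windows = k,
               fisher_p = stats::pchisq(x2, df = 2 * k, lower.tail = FALSE),
               summed_lfc = sum(g$log2FC),
               min_p = g$pvalue[i],
               lfc_at_min_p = g$log2FC[i])
  }))
  rownames(out) <- NULL
  out[order(out$fisher_p), , drop = FALSE]
}

#' Count significant windows by genomic feature and direction
#'
#' @param results data.frame from [call_significant()].
#' @return data.frame with columns `feature_type`, `up`, `down` (counts of
#'   significant windows); empty if nothing is significant.
#' @export
feature_direction_counts <- function(results) {
  sig <- results[!is.na(results$significant) & results$significant, ,
                 drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(feature_type = character(0), up = integer(0),
                      down = integer(0)))
  }
  tab <- table(factor(sig$feature_type),
               factor(sig$direction, levels = c("up", "down")))
  data.frame(feature_type = rownames(tab),
             up = as.integer(tab[, "up"]),
             down = as.integer(tab[, "down"]),
             row.names = NULL)
}

#' Volcano-plot table
#'
#' Returns a plotting-ready table of `log2FC` against `-log10(padj)`;
#' `neg_log10_padj` is capped at `cap` (default 300) so that underflowed
#' adjusted p-values remain finite.
#'
#' @param results data.frame from [call_significant()].
#' @param cap Ceiling for `-log10(padj)`.
#' @return data.frame with `window_id`, `gene_id`, `log2FC`,
#'   `neg_log10_padj`, `significant`, `direction`.
#' @export
volcano_table <- function(results, cap = 300) {
  keep <- !is.na(results$padj)
  r <- results[keep, , drop = FALSE]
  data.frame(window_id = r$window_id,
             gene_id = r$gene_id,
             log2FC = r$log2FC,
             neg_log10_padj = pmin(-log10(pmax(r$padj, 10^(-cap))), cap),
             significant = r$significant,
             direction = r$direction,
             row.names = NULL)
}
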