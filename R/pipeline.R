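# End-to-end differential binding pipeline on a window table.

#' Run the full differential binding pipeline
#'
#' Chains the analysis stages: per-condition enrichment calling (unless a
#' precomputed enriched set is supplied), gene-level input aggregation,
#' hierarchical IP / joint IN normalization, the assay-by-treatment
#' interaction model, significance calling, and gene summaries.
#'
#' @param table A [window_table()].
#' @param samples Validated sample sheet.
#' @param enriched Optional precomputed enriched windows (character vector
#'   of window ids or data.frame with `window_id`); when `NULL` the built-in
#'   beta-binomial caller defines the tested set.
#' @param q_threshold Enrichment q-value cutoff for the caller.
#' @param padj_threshold,lfc_threshold Significance thresholds for
#'   [call_significant()].
#' @param group_average Background-factor group average for
#'   [hierarchical_ip_factors()].
#' @return List with `results` (per-window differential table),
#'   `gene_summaries`, `factors`, `enriched` (tested window ids), and
#'   `unified` (the unified count table).
#' @export
flipper_pipeline <- function(table, samples, enriched = NULL,
                             q_threshold = 0.05, padj_threshold = 0.05,
                             lfc_threshold = 1,
                             group_average = "geometric") {
  if (is.null(enriched)) {
    enriched <- call_enriched_windows(table, samples,
                                      q_threshold = q_threshold)
  }
  enriched_ids <- if (is.data.frame(enriched)) unique(enriched$window_id)
  else unique(as.character(enriched))
  if (length(enriched_ids) == 0L)
    stop("no windows to test: enrichment calling found no enriched windows")

  ing <- aggregate_input_to_gene(table, samples)
  unified <- build_unified_table(table, enriched_ids, ing, samples)
  factors <- normalization_factors(table, samples, ing, enriched_ids,
                                   group_average = group_average)
  results <- fit_interaction_model(unified, samples, factors)
  results <- call_significant(results, padj_threshold = padj_threshold,
                              lfc_threshold = lfc_threshold)
  list(results = results,
       gene_summaries = summarize_genes(results),
       factors = factors,
       enriched = enriched_ids,
       unified = unified)
}
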