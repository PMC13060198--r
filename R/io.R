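# -- sample sheets ------------------------------------------------------------

#' Read and validate a sample sheet
#'
#' The sample sheet declares the samples of a pairwise eCLIP comparison:
#' one row per sequencing library with its assay fraction (IP or IN), its
#' condition, and a replicate index. Conditions are mapped onto the internal
#' `control` / `treatment` labels: if a logical `reference` column is present
#' the condition flagged `TRUE` becomes `control`; otherwise the first
#' condition in order of appearance is taken as the reference. The sign of the
#' reported interaction log2 fold change depends on this mapping, so an
#' explicit `reference` column is recommended.
#'
#' @param path Path to a tab-separated file with columns `sample_id`, `assay`
#'   (`IP` or `IN`), `condition`, `replicate`, and optionally `reference`
#'   (logical, `TRUE` on rows of the reference condition).
#' @return A `data.frame` with columns `sample_id`, `assay`, `condition`
#'   (mapped to `control`/`treatment`), `condition_label` (the original
#'   label), and `replicate`.
#' @export
load_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = list(character = "sample_id"))
  if (nrow(df) == 0L) stop("empty sample sheet: ", path)
  validate_sample_sheet(df)
}

#' Validate an in-memory sample sheet
#'
#' @param df A data.frame as described in [load_sample_sheet()].
#' @return The validated, condition-mapped data.frame.
#' @export
validate_sample_sheet <- function(df) {
  required <- c("sample_id", "assay", "condition", "replicate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  if (!all(df$assay %in% c("IP", "IN")))
    stop("unknown assay token (expected IP or IN): ",
         paste(setdiff(unique(df$assay), c("IP", "IN")), collapse = ", "))
  conds <- unique(df$condition)
  if (length(conds) != 2L)
    stop("exactly two conditions are required (pairwise design); found: ",
         paste(conds, collapse = ", "))
  if (!is.numeric(df$replicate) || any(df$replicate < 1) ||
      any(df$replicate != round(df$replicate)))
    stop("replicate must be a positive integer")

  if ("reference" %in% names(df)) {
    ref_flag <- as.logical(df$reference)
    ref <- unique(df$condition[ref_flag %in% TRUE])
    if (length(ref) != 1L)
      stop("the 'reference' column must flag exactly one condition")
  } else {
    ref <- conds[1L]
  }
  df$condition_label <- df$condition
  df$condition <- ifelse(df$condition_label == ref, "control", "treatment")

  cells <- table(df$assay, df$condition)
  if (!all(dim(cells) == c(2L, 2L)) || any(cells == 0L))
    stop("each assay x condition cell needs at least one sample; got: ",
         paste(utils::capture.output(print(cells)), collapse = "; "))
  df[, c("sample_id", "assay", "condition", "condition_label", "replicate")]
}

# -- window tables ------------------------------------------------------------

#' Construct a window table
#'
#' A window table is the unit of observation for window-level eCLIP analysis:
#' annotated ~100 bp transcriptomic windows with one integer count column per
#' sample. Coordinates follow the BED convention (0-based, half-open).
#'
#' @param meta data.frame with columns `window_id` (unique), `chrom`, `start`,
#'   `end`, `strand` (`+`, `-`, or `.`), `gene_id`, `feature_type`.
#' @param counts windows x samples matrix of non-negative integer counts;
#'   column names are sample ids.
#' @return An object of class `window_table`.
#' @export
window_table <- function(meta, counts) {
  stopifnot(is.data.frame(meta), is.matrix(counts))
  required <- c("window_id", "chrom", "start", "end", "strand", "gene_id",
                "feature_type")
  missing <- setdiff(required, names(meta))
  if (length(missing) > 0L)
    stop("window meta missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(meta) != nrow(counts))
    stop("meta and counts row counts differ")
  if (anyDuplicated(meta$window_id))
    stop("duplicate window_id in window table")
  bad <- which(meta$end <= meta$start)
  if (length(bad) > 0L)
    stop("window with end <= start: ", meta$window_id[bad[1L]])
  if (any(meta$start < 0))
    stop("negative window start coordinate")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"   # integer overflow safety for large sums
  rownames(counts) <- meta$window_id
  structure(list(meta = meta, counts = counts), class = "window_table")
}

#' @export
print.window_table <- function(x, ...) {
  cat(sprintf("window_table: %d windows x %d samples, %d genes\n",
              nrow(x$meta), ncol(x$counts), length(unique(x$meta$gene_id))))
  invisible(x)
}

#' @export
dim.window_table <- function(x) dim(x$counts)

#' Read a window count table
#'
#' Reads a Skipper-style tab-separated window table: annotation columns
#' (`window_id`, `chrom`, `start`, `end`, `strand`, `gene_id`,
#' `feature_type`) followed by one integer count column per declared sample.
#' Count columns are aligned to the order of `samples$sample_id`.
#'
#' @param path Path to the TSV file.
#' @param samples Validated sample sheet (see [load_sample_sheet()]).
#' @return A [window_table()].
#' @export
load_window_counts <- function(path, samples) {
  if (!file.exists(path)) stop("window count file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  anno <- c("window_id", "chrom", "start", "end", "strand", "gene_id",
            "feature_type")
  missing_anno <- setdiff(anno, names(df))
  if (length(missing_anno) > 0L)
    stop("window table missing annotation column(s): ",
         paste(missing_anno, collapse = ", "))
  missing_samp <- setdiff(samples$sample_id, names(df))
  if (length(missing_samp) > 0L)
    stop("window table missing count column for sample(s): ",
         paste(missing_samp, collapse = ", "))
  counts <- as.matrix(df[, samples$sample_id, drop = FALSE])
  if (!is.numeric(counts))
    stop("non-numeric count values in window table")
  neg <- which(rowSums(counts < 0 | counts != round(counts)) > 0)
  if (length(neg) > 0L)
    stop("negative or non-integer count at window ", df$window_id[neg[1L]])
  meta <- df[, anno]
  meta$window_id <- as.character(meta$window_id)
  meta$gene_id <- as.character(meta$gene_id)
  window_table(meta, counts)
}

#' Write a window table to TSV
#'
#' @param table A [window_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_window_counts <- function(table, path) {
  out <- cbind(table$meta,
               as.data.frame(table$counts, check.names = FALSE))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# -- gene-level input aggregation --------------------------------------------

#' Aggregate input counts to the gene level (INg)
#'
#' Size-matched input (IN) libraries are too sparse at single-window
#' resolution to estimate expression changes, so IN counts are summed over
#' all windows of a gene to produce a gene-level input value (INg) used as
#' the expression covariate. The sum runs over every window of the gene,
#' not only windows that pass enrichment filtering.
#'
#' @param table A [window_table()].
#' @param samples Validated sample sheet; rows with `assay == "IN"` select
#'   the input columns.
#' @return A genes x IN-samples numeric matrix with gene ids as row names.
#'   Genes whose IN counts are all zero are retained with zero rows.
#' @export
aggregate_input_to_gene <- function(table, samples) {
  in_ids <- samples$sample_id[samples$assay == "IN"]
  if (length(in_ids) == 0L) stop("no IN samples declared in the sample sheet")
  genes <- unique(table$meta$gene_id)
  if (nrow(table$meta) == 0L) {
    return(matrix(0, nrow = 0, ncol = length(in_ids),
                  dimnames = list(character(0), in_ids)))
  }
  m <- rowsum(table$counts[, in_ids, drop = FALSE],
              group = table$meta$gene_id, reorder = FALSE)
  m[genes, , drop = FALSE]
}

# -- unified IP / INg table ---------------------------------------------------

#' Build the unified IP / INg count table
#'
#' Restricts the analysis to windows showing significant IP enrichment in at
#' least one condition and joins, per window, the window-level IP counts with
#' the gene-level input (INg) of the window's gene. All rows of a gene
#' therefore share identical INg columns. Rows are ordered genomically
#' (chrom, start, end). Genes whose INg is zero in every IN sample are
#' dropped with a warning, as the IP/INg ratio is undefined for them.
#'
#' @param table A [window_table()].
#' @param enriched Character vector of enriched window ids, or a data.frame
#'   with a `window_id` column (e.g. from [call_enriched_windows()]).
#' @param ing Gene x IN-sample matrix from [aggregate_input_to_gene()].
#' @param samples Validated sample sheet.
#' @return An object of class `unified_table`: list with `meta` (window
#'   annotation), `counts` (windows x [IP samples, IN samples]), and
#'   `samples` (sample sheet rows matching the count columns).
#' @export
build_unified_table <- function(table, enriched, ing, samples) {
  if (is.data.frame(enriched)) enriched <- enriched$window_id
  enriched <- unique(as.character(enriched))
  if (length(enriched) == 0L) stop("no windows to test: enriched set is empty")
  absent <- setdiff(enriched, table$meta$window_id)
  if (length(absent) > 0L)
    stop("enriched window absent from window table: ", absent[1L])

  keep <- table$meta$window_id %in% enriched
  meta <- table$meta[keep, , drop = FALSE]
  ord <- order(meta$chrom, meta$start, meta$end)
  meta <- meta[ord, , drop = FALSE]

  ip_ids <- samples$sample_id[samples$assay == "IP"]
  in_ids <- samples$sample_id[samples$assay == "IN"]
  if (length(ip_ids) == 0L) stop("no IP samples declared in the sample sheet")

  ing_rows <- ing[meta$gene_id, , drop = FALSE]
  all_zero <- rowSums(ing_rows) == 0
  if (any(all_zero)) {
    dropped <- unique(meta$gene_id[all_zero])
    warning(length(dropped), " gene(s) dropped from the unified table: ",
            "INg is zero in every IN sample")
    meta <- meta[!all_zero, , drop = FALSE]
    ing_rows <- ing_rows[!all_zero, , drop = FALSE]
    if (nrow(meta) == 0L) stop("no windows to test after dropping zero-INg genes")
  }

  counts <- cbind(table$counts[meta$window_id, ip_ids, drop = FALSE],
                  ing_rows[, in_ids, drop = FALSE])
  colnames(counts) <- c(ip_ids, in_ids)
  rownames(counts) <- meta$window_id
  sample_order <- match(colnames(counts), samples$sample_id)
  structure(list(meta = meta, counts = counts,
                 samples = samples[sample_order, , drop = FALSE]),
            class = "unified_table")
}

#' @export
print.unified_table <- function(x, ...) {
  cat(sprintf("unified_table: %d enriched windows, %d IP + %d IN samples\n",
              nrow(x$meta), sum(x$samples$assay == "IP"),
              sum(x$samples$assay == "IN")))
  invisible(x)
}

# -- result writers -----------------------------------------------------------

#' Write differential binding outputs
#'
#' Writes the per-window results table, the per-gene summary table, and a
#' BED6 file of significant windows. BED scores are
#' `min(1000, round(-10 * log10(padj)))`, i.e. a Phred-like score capped at
#' 1000; coordinates are 0-based half-open as in the input.
#'
#' @param results Per-window results data.frame (see
#'   [fit_interaction_model()] / [call_significant()]).
#' @param gene_summaries Gene summary data.frame from [summarize_genes()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the files written.
#' @export
write_outputs <- function(results, gene_summaries, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  res_path <- file.path(out_dir, "differential_windows.tsv")
  cols <- c("window_id", "chrom", "start", "end", "strand", "gene_id",
            "feature_type", "baseMean", "log2FC", "lfcSE", "stat", "pvalue",
            "padj", "significant", "direction")
  data.table::fwrite(results[, cols], res_path, sep = "\t", quote = FALSE)

  gene_path <- file.path(out_dir, "gene_summaries.tsv")
  data.table::fwrite(gene_summaries, gene_path, sep = "\t", quote = FALSE)

  bed_path <- file.path(out_dir, "significant_windows.bed")
  sig <- results[!is.na(results$significant) & results$significant, ,
                 drop = FALSE]
  bed <- data.frame(chrom = sig$chrom, start = sig$start, end = sig$end,
                    name = sig$window_id,
                    score = pmin(1000, round(-10 * log10(pmax(sig$padj,
                                                              1e-300)))),
                    strand = sig$strand)
  data.table::fwrite(bed, bed_path, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(c(results = res_path, gene_summaries = gene_path, bed = bed_path))
}
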