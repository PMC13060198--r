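# Median-of-ratios size factors and the hierarchical IP normalization.
#
# IP libraries carry two distinct multiplicative nuisances: sequencing depth
# (shared with any count assay) and pulldown/washing efficiency, which moves
# binding-region signal and background in opposite directions. A single
# global factor confounds the two, so IP samples are normalized in two
# stages: within-condition factors from binding windows, between-condition
# depth from background windows. IN libraries have no pulldown step and are
# normalized jointly.

geomean <- function(x) exp(mean(log(x)))

#' Median-of-ratios size factors
#'
#' For each sample j the factor is the median over reference rows i of
#' `counts[i, j] / geomean_k(counts[i, k])`. Rows containing any zero are
#' excluded from the reference set (the same convention as standard
#' differential-expression size factors). Factors are returned unrescaled.
#'
#' @param counts rows x samples numeric matrix of counts.
#' @param zero_handling `"strict"` errors when no all-positive row exists;
#'   `"fallback"` then recomputes the per-row geometric mean over positive
#'   entries only and takes medians over positive ratios, with a warning.
#' @return Named numeric vector of positive per-sample factors.
#' @export
mor_size_factors <- function(counts, zero_handling = c("strict", "fallback")) {
  zero_handling <- match.arg(zero_handling)
  counts <- as.matrix(counts)
  if (ncol(counts) == 1L) {
    f <- 1
    names(f) <- colnames(counts)
    return(f)
  }
  usable <- rowSums(counts == 0) == 0L
  if (any(usable)) {
    sub <- counts[usable, , drop = FALSE]
    ref <- exp(rowMeans(log(sub)))
    factors <- apply(sub / ref, 2L, stats::median)
  } else {
    if (zero_handling == "strict")
      stop("median-of-ratios: every row contains a zero; relax the row ",
           "filter (zero_handling = \"fallback\") or supply pseudocounts")
    warning("median-of-ratios: no all-positive rows; ",
            "using per-row geometric means over positive entries only")
    pos <- counts > 0
    keep <- rowSums(pos) > 0L
    sub <- counts[keep, , drop = FALSE]
    logc <- log(sub)
    logc[!pos[keep, , drop = FALSE]] <- NA
    ref <- exp(rowMeans(logc, na.rm = TRUE))
    ratios <- sub / ref
    ratios[sub == 0] <- NA
    factors <- apply(ratios, 2L, stats::median, na.rm = TRUE)
    if (any(!is.finite(factors)) || any(factors <= 0, na.rm = TRUE))
      stop("median-of-ratios fallback failed: a sample has no positive counts")
  }
  names(factors) <- colnames(counts)
  factors
}

#' Hierarchical two-stage IP size factors
#'
#' Stage 1 normalizes replicates *within* each condition using binding
#' windows only (assumption: overall binding level is comparable between
#' replicates of the same condition), and rescales the stage-1 factors to
#' geometric mean 1 within each condition so that they carry no depth
#' information. Stage 2 estimates depth from background windows across all
#' IP samples jointly and collapses the background factors to one factor per
#' condition by a group average, so that no assumption about signal-to-noise
#' ratios crosses conditions. The final per-sample factor is the product of
#' its stage-1 factor and its condition's stage-2 factor, rescaled to overall
#' geometric mean 1.
#'
#' When `gene_id` is supplied, stage 2 sums the background windows of each
#' gene before taking median-of-ratios. Window-level background counts are
#' sparse, and the all-positive row filter of median-of-ratios then selects
#' rows in a way that correlates with per-gene expression changes; gene
#' aggregation removes most of that sparsity and, because it mirrors the
#' gene-level INg construction on the input side, leaves any residual
#' filter bias common to the IP and IN factor blocks, where it cancels out
#' of the interaction coefficient.
#'
#' @param ip_counts windows x IP-samples count matrix (all windows, binding
#'   and background).
#' @param classes Named character vector (or factor) over the rows of
#'   `ip_counts` with values `"binding"` or `"background"`, or a logical
#'   vector that is `TRUE` for binding windows.
#' @param groups Named character vector mapping IP sample id to condition.
#' @param gene_id Optional character vector of gene ids per row of
#'   `ip_counts`; when given, stage-2 background counts are aggregated per
#'   gene before median-of-ratios.
#' @param group_average `"geometric"` (default) or `"arithmetic"` mean for
#'   collapsing background factors within a condition.
#' @return Named numeric vector of per-IP-sample factors with attribute
#'   `provenance = "hierarchical_IP"` and attribute `stages` holding the
#'   stage-1 and stage-2 components.
#' @export
hierarchical_ip_factors <- function(ip_counts, classes, groups,
                                    gene_id = NULL,
                                    group_average = c("geometric",
                                                      "arithmetic")) {
  group_average <- match.arg(group_average)
  ip_counts <- as.matrix(ip_counts)
  samples <- colnames(ip_counts)
  if (is.null(samples)) stop("ip_counts must have sample column names")
  if (is.logical(classes)) {
    classes <- ifelse(classes, "binding", "background")
  }
  classes <- as.character(classes)
  if (length(classes) != nrow(ip_counts))
    stop("classes must label every row of ip_counts")
  if (!any(classes == "binding"))
    stop("hierarchical normalization needs at least one binding window")
  if (!any(classes == "background"))
    stop("hierarchical normalization needs at least one background window")
  groups <- groups[samples]
  if (any(is.na(groups))) stop("groups must cover every IP sample")

  binding <- ip_counts[classes == "binding", , drop = FALSE]
  background <- ip_counts[classes == "background", , drop = FALSE]
  if (!is.null(gene_id)) {
    if (length(gene_id) != nrow(ip_counts))
      stop("gene_id must label every row of ip_counts")
    background <- rowsum(background, gene_id[classes == "background"],
                         reorder = FALSE)
  }

  # stage 1: within-condition factors from binding windows
  f1 <- stats::setNames(rep(NA_real_, length(samples)), samples)
  for (g in unique(groups)) {
    cols <- samples[groups == g]
    f <- tryCatch(
      mor_size_factors(binding[, cols, drop = FALSE]),
      error = function(e)
        mor_size_factors(binding[, cols, drop = FALSE],
                         zero_handling = "fallback"))
    f1[cols] <- f / geomean(f)
  }

  # stage 2: depth from background windows, all IP samples jointly
  f2 <- tryCatch(
    mor_size_factors(background),
    error = function(e) mor_size_factors(background,
                                         zero_handling = "fallback"))
  group_factor <- vapply(unique(groups), function(g) {
    v <- f2[samples[groups == g]]
    if (group_average == "geometric") geomean(v) else mean(v)
  }, numeric(1))

  s <- f1 * group_factor[groups]
  s <- s / geomean(s)
  attr(s, "provenance") <- "hierarchical_IP"
  attr(s, "stages") <- list(within_group = f1, background = f2,
                            group_factor = group_factor)
  s
}

#' Joint input (IN) size factors
#'
#' IN libraries undergo no immunoprecipitation, so a single conventional
#' median-of-ratios scaling over the gene-level INg matrix is applied across
#' all IN samples jointly. Factors are rescaled to geometric mean 1.
#'
#' @param ing Gene x IN-sample matrix from [aggregate_input_to_gene()].
#' @return Named numeric vector of per-IN-sample factors with attribute
#'   `provenance = "joint_IN"`.
#' @export
input_size_factors <- function(ing) {
  ing <- as.matrix(ing)
  if (ncol(ing) == 1L) {
    warning("single IN sample: input size factor fixed at 1")
    f <- stats::setNames(1, colnames(ing))
    attr(f, "provenance") <- "joint_IN"
    return(f)
  }
  f <- tryCatch(
    mor_size_factors(ing),
    error = function(e) mor_size_factors(ing, zero_handling = "fallback"))
  f <- f / geomean(f)
  attr(f, "provenance") <- "joint_IN"
  f
}

#' Assemble per-sample normalization factors for the interaction model
#'
#' Combines [hierarchical_ip_factors()] over the IP columns of the window
#' table with [input_size_factors()] over the INg matrix. The relative scale
#' between the IP and IN factor blocks is arbitrary (both are rescaled to
#' geometric mean 1); it is absorbed by the assay main effect of the model
#' and does not move the interaction coefficient.
#'
#' @param table A [window_table()].
#' @param samples Validated sample sheet.
#' @param ing Gene x IN-sample matrix.
#' @param binding_windows Character vector of window ids treated as binding
#'   windows (typically the enriched set); all other windows are background.
#' @param group_average Passed to [hierarchical_ip_factors()].
#' @return data.frame with columns `sample_id`, `factor`, `provenance`.
#' @export
normalization_factors <- function(table, samples, ing, binding_windows,
                                  group_average = "geometric") {
  ip <- samples[samples$assay == "IP", , drop = FALSE]
  ip_counts <- table$counts[, ip$sample_id, drop = FALSE]
  classes <- ifelse(table$meta$window_id %in% binding_windows,
                    "binding", "background")
  groups <- stats::setNames(ip$condition, ip$sample_id)
  f_ip <- hierarchical_ip_factors(ip_counts, classes, groups,
                                  gene_id = table$meta$gene_id,
                                  group_average = group_average)
  f_in <- input_size_factors(ing)
  data.frame(
    sample_id = c(names(f_ip), names(f_in)),
    factor = c(as.numeric(f_ip), as.numeric(f_in)),
    provenance = c(rep("hierarchical_IP", length(f_ip)),
                   rep("joint_IN", length(f_in))),
    stringsAsFactors = FALSE)
}

#' Write or read normalization factors
#'
#' Factors are persisted as a three-column TSV (`sample_id`, `factor`,
#' `provenance`) for audit, and can be read back to override the built-in
#' estimation.
#'
#' @param factors data.frame from [normalization_factors()].
#' @param path TSV path.
#' @return `write_factors` returns `path` invisibly; `read_factors` the
#'   factors data.frame.
#' @export
write_factors <- function(factors, path) {
  data.table::fwrite(factors, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_factors
#' @export
read_factors <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "factor") %in% names(df)))
    stop("factor file needs sample_id and factor columns")
  if (any(!is.finite(df$factor)) || any(df$factor <= 0))
    stop("normalization factors must be positive and finite")
  df
}
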