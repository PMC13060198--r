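# Sensitivity/precision benchmark of differential binding methods against
# simulation ground truth.

#' Score a set of differential calls against simulation truth
#'
#' In `window` matching a call is a true positive exactly when it is the
#' recorded bound window of a true differential gene (each bound gene has
#' one injected window, so window and gene matching agree except for
#' neighbor-window calls). In `gene` matching calls are collapsed to genes:
#' any number of calls inside a true differential gene counts as one TP, and
#' each called gene that is not truly differential counts as one FP.
#'
#' @param called Character vector of called window ids (direction is not
#'   scored), or a data.frame with a `window_id` column.
#' @param truth Truth data.frame from [simulate_experiment()].
#' @param matching `"window"` (default) or `"gene"`.
#' @param window_gene Named character vector mapping window id to gene id;
#'   required for `gene` matching when calls include windows outside bound
#'   genes (taken from `window_id` prefixes of the simulator if omitted).
#' @return One-row data.frame with `TP`, `FP`, `FN`, `sensitivity`,
#'   `precision` (`NA` when nothing is called).
#' @export
evaluate_calls <- function(called, truth, matching = c("window", "gene"),
                           window_gene = NULL) {
  matching <- match.arg(matching)
  if (is.data.frame(called)) called <- called$window_id
  called <- unique(as.character(called))
  diff_truth <- truth[truth$differential, , drop = FALSE]
  n_true <- nrow(diff_truth)

  if (matching == "window") {
    tp <- sum(called %in% diff_truth$bound_window_id)
    fp <- length(called) - tp
    fn <- n_true - tp
  } else {
    if (is.null(window_gene)) {
      genes_called <- unique(sub("_w[0-9]+$", "", called))
    } else {
      genes_called <- unique(window_gene[called])
    }
    tp <- sum(genes_called %in% diff_truth$gene_id)
    fp <- length(genes_called) - tp
    fn <- n_true - tp
  }
  data.frame(TP = tp, FP = fp, FN = fn,
             sensitivity = if (n_true > 0) tp / (tp + fn) else NA_real_,
             precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}

#' Derive a per-cell simulation seed from a master seed
#'
#' A stable arithmetic hash (documented, not cryptographic) keeping the
#' result inside the 32-bit integer range, so grid cells are independent and
#' reorderable.
#'
#' @param master Master seed (integer).
#' @param ... Small non-negative integers identifying the cell (e.g. zeta
#'   index, beta index, replicate).
#' @return Integer seed.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.numeric(master) %% 2147483647
  for (v in idx) h <- (h * 1009 + as.numeric(v) + 1) %% 2147483647
  as.integer(h + 1)
}

run_methods_on_sim <- function(sim, methods, q_threshold = 0.05,
                               padj_threshold = 0.05, lfc_threshold = 1) {
  enriched <- call_enriched_windows(sim$table, sim$samples,
                                    q_threshold = q_threshold)
  tested <- unique(enriched$window_id)
  out <- list()

  if ("flipper" %in% methods) {
    fit <- flipper_pipeline(sim$table, sim$samples, enriched = tested,
                            padj_threshold = padj_threshold,
                            lfc_threshold = lfc_threshold)
    sig <- fit$results[fit$results$significant, , drop = FALSE]
    out$flipper <- list(called = sig$window_id, fit = fit)
  }
  if ("adhoc" %in% methods) {
    ctrl <- enriched$window_id[enriched$condition == "control"]
    trt <- enriched$window_id[enriched$condition == "treatment"]
    calls <- adhoc_differential(ctrl, trt)
    out$adhoc <- list(called = c(calls$up, calls$down))
  }
  if ("diffskipper" %in% methods) {
    calls <- diffskipper_differential(sim$table, sim$samples, tested,
                                      q_threshold = q_threshold)
    out$diffskipper <- list(called = c(calls$up, calls$down))
  }
  attr(out, "tested") <- tested
  out
}

#' Run the simulation benchmark grid
#'
#' For every combination of binding effect `zeta` and expression-effect
#' scale `beta_sd`, and for `n_sim_reps` independently seeded simulation
#' replicates, simulates an experiment, defines the tested windows with the
#' enrichment caller, runs the requested methods, and scores each against
#' truth.
#'
#' @param cfg Base [simulation_config()] (its `zeta`, `beta_sd`, and `seed`
#'   are overridden per cell).
#' @param zetas,beta_sds Grid axes.
#' @param n_sim_reps Simulation replicates per cell.
#' @param methods Subset of `c("flipper", "adhoc", "diffskipper")`.
#' @param master_seed Master seed; per-cell seeds come from [derive_seed()].
#' @param matching Truth-matching mode for [evaluate_calls()].
#' @param q_threshold,padj_threshold,lfc_threshold Analysis thresholds.
#' @return data.frame with one row per method x cell x replicate: `method`,
#'   `zeta`, `beta_sd`, `rep`, `TP`, `FP`, `FN`, `sensitivity`, `precision`,
#'   `n_tested`.
#' @export
run_benchmark <- function(cfg, zetas = c(2, 3, 4), beta_sds = c(0, 2),
                          n_sim_reps = 5,
                          methods = c("flipper", "adhoc", "diffskipper"),
                          master_seed = 1L,
                          matching = "window",
                          q_threshold = 0.05, padj_threshold = 0.05,
                          lfc_threshold = 1) {
  rows <- list()
  for (zi in seq_along(zetas)) {
    for (bi in seq_along(beta_sds)) {
      for (r in seq_len(n_sim_reps)) {
        cell_cfg <- cfg
        cell_cfg$zeta <- zetas[zi]
        cell_cfg$beta_sd <- beta_sds[bi]
        cell_cfg$seed <- derive_seed(master_seed, zi, bi, r)
        sim <- simulate_experiment(cell_cfg)
        runs <- run_methods_on_sim(sim, methods,
                                   q_threshold = q_threshold,
                                   padj_threshold = padj_threshold,
                                   lfc_threshold = lfc_threshold)
        for (m in names(runs)) {
          score <- evaluate_calls(runs[[m]]$called, sim$truth,
                                  matching = matching)
          rows[[length(rows) + 1L]] <- cbind(
            data.frame(method = m, zeta = zetas[zi], beta_sd = beta_sds[bi],
                       rep = r), score,
            data.frame(n_tested = length(attr(runs, "tested"))))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a benchmark table
#'
#' @param bench data.frame from [run_benchmark()].
#' @return data.frame with mean and sd of sensitivity and precision per
#'   method x zeta x beta_sd cell.
#' @export
summarize_benchmark <- function(bench) {
  key <- interaction(bench$method, bench$zeta, bench$beta_sd, drop = TRUE)
  parts <- split(bench, key)
  out <- do.call(rbind, lapply(parts, function(b) {
    data.frame(method = b$method[1L], zeta = b$zeta[1L],
               beta_sd = b$beta_sd[1L], n_reps = nrow(b),
               sensitivity_mean = mean(b$sensitivity, na.rm = TRUE),
               sensitivity_sd = stats::sd(b$sensitivity),
               precision_mean = mean(b$precision, na.rm = TRUE),
               precision_sd = stats::sd(b$precision))
  }))
  out <- out[order(out$method, out$beta_sd, out$zeta), , drop = FALSE]
  rownames(out) <- NULL
  out
}
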