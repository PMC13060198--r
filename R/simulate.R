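# Synthetic eCLIP experiment generator with known binding ground truth.
#
# Gene-level counts are drawn from negative binomial distributions with a
# log2-linear treatment effect on expression, thinned to eCLIP-like
# sparsity, spread over fixed-width windows through active/inactive regions
# with gamma-distributed window weights, and finally binding signal is
# injected into one window per bound gene in the IP replicates only. The
# recorded truth (bound window, binding strength kappa, treatment binding
# effect zeta, expression effect beta) drives the sensitivity/precision
# benchmark.

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_experiment()]. Defaults
#' describe a full-size experiment: 30,000 genes, 8 replicates split 4 IN /
#' 4 IP and evenly between control and treatment, 6,000 bound genes of which
#' half are differential. Gene-level baseline abundance is `2^a` with
#' `a ~ Normal(intercept_mean, intercept_sd)`; the per-gene dispersion trend
#' is `alpha(q) = dispersion_a0 + dispersion_a1 / q`. Gene lengths come from
#' a heavy-tailed log-normal emulating genomic (intron-inclusive) gene spans
#' and are rank-coupled to expression with Gaussian rank noise of standard
#' deviation `coupling_strength * n_genes`.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Total replicates; must be divisible by 4 (split into
#'   IN/IP and control/treatment).
#' @param intercept_mean,intercept_sd Normal parameters of the log2 baseline
#'   abundance intercept.
#' @param beta_sd SD of the per-gene log2 expression treatment effect
#'   (`0` = expression constant across conditions).
#' @param dispersion_a0,dispersion_a1 Dispersion trend coefficients.
#' @param downsample_rate Binomial thinning rate applied to gene counts.
#' @param length_meanlog,length_sdlog,length_min,length_max Log-normal gene
#'   length parameters (bp) and clamping bounds.
#' @param coupling_strength Rank-noise scale coupling expression and length.
#' @param window_size Window width in bp.
#' @param active_window_fraction Fraction of a gene's windows designated
#'   high-depth "active" (exon-like) regions.
#' @param active_read_fraction Fraction of a gene's reads falling into
#'   active regions.
#' @param peakiness_active,peakiness_inactive Gamma shape of the window
#'   weights per region; smaller = peakier.
#' @param n_bound Number of bound genes.
#' @param min_expression_for_binding Minimum baseline abundance `q` for a
#'   gene to be eligible for binding.
#' @param kappa_shift,kappa_shape,kappa_scale Shifted-gamma parameters of
#'   the baseline binding strength `kappa = shift + Gamma(shape, scale)`.
#' @param zeta Multiplicative treatment effect on binding for differential
#'   genes (1 = no differential binding).
#' @param differential_fraction Fraction of bound genes that are
#'   differential.
#' @param seed Integer seed; `simulate_experiment` is fully deterministic
#'   given it.
#' @return A list of class `flipper_sim_config`.
#' @export
simulation_config <- function(n_genes = 30000,
                              n_replicates = 8,
                              intercept_mean = 7,
                              intercept_sd = 3,
                              beta_sd = 0,
                              dispersion_a0 = 0.05,
                              dispersion_a1 = 3,
                              downsample_rate = 0.1,
                              length_meanlog = log(5000),
                              length_sdlog = 1.5,
                              length_min = 100,
                              length_max = 1e6,
                              coupling_strength = 0.3,
                              window_size = 100,
                              active_window_fraction = 0.2,
                              active_read_fraction = 0.8,
                              peakiness_active = 0.5,
                              peakiness_inactive = 2.0,
                              n_bound = 6000,
                              min_expression_for_binding = 20,
                              kappa_shift = 0.5,
                              kappa_shape = 2,
                              kappa_scale = 0.5,
                              zeta = 2,
                              differential_fraction = 0.5,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 1,
            cfg$n_replicates %% 4 == 0, cfg$n_replicates >= 4,
            cfg$beta_sd >= 0,
            cfg$dispersion_a0 > 0, cfg$dispersion_a1 >= 0,
            cfg$downsample_rate > 0, cfg$downsample_rate <= 1,
            cfg$coupling_strength >= 0,
            cfg$window_size >= 1,
            cfg$active_window_fraction > 0, cfg$active_window_fraction <= 1,
            cfg$active_read_fraction > 0, cfg$active_read_fraction <= 1,
            cfg$peakiness_active > 0, cfg$peakiness_inactive > 0,
            cfg$n_bound >= 0, cfg$n_bound <= cfg$n_genes,
            cfg$kappa_shift > 0, cfg$kappa_shape > 0, cfg$kappa_scale > 0,
            cfg$zeta > 0,
            cfg$differential_fraction >= 0, cfg$differential_fraction <= 1)
  structure(cfg, class = "flipper_sim_config")
}

sim_sample_sheet <- function(n_replicates) {
  per_cell <- n_replicates / 4
  grid <- expand.grid(replicate = seq_len(per_cell),
                      condition = c("control", "treatment"),
                      assay = c("IN", "IP"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_%s_%d", grid$assay, grid$condition,
                        grid$replicate),
    assay = grid$assay,
    condition = grid$condition,
    condition_label = grid$condition,
    replicate = grid$replicate,
    stringsAsFactors = FALSE)
}

#' Draw gene-level counts
#'
#' Per gene: intercept `a ~ N(intercept_mean, intercept_sd)` and expression
#' treatment effect `beta ~ N(0, beta_sd)`; baseline mean `q = 2^a`; mean in
#' treatment replicates `q * 2^beta`; dispersion `alpha(q)` held constant
#' across replicates; counts drawn independently per replicate from
#' `NB(mean m, variance m + alpha * m^2)`.
#'
#' @param cfg A [simulation_config()].
#' @param samples Sample sheet defining which replicates are treatment.
#' @return List with `params` (data.frame: `gene_id`, `intercept`, `beta`,
#'   `q`, `alpha`) and `counts` (genes x replicates matrix).
#' @export
draw_gene_counts <- function(cfg, samples = sim_sample_sheet(cfg$n_replicates)) {
  n <- cfg$n_genes
  a <- stats::rnorm(n, cfg$intercept_mean, cfg$intercept_sd)
  beta <- if (cfg$beta_sd > 0) stats::rnorm(n, 0, cfg$beta_sd) else
    numeric(n)
  q <- 2^a
  alpha <- cfg$dispersion_a0 + cfg$dispersion_a1 / q
  counts <- matrix(0, nrow = n, ncol = nrow(samples),
                   dimnames = list(NULL, samples$sample_id))
  trt <- samples$condition == "treatment"
  for (j in seq_len(nrow(samples))) {
    mu <- if (trt[j]) q * 2^beta else q
    counts[, j] <- stats::rnbinom(n, mu = mu, size = 1 / alpha)
  }
  params <- data.frame(gene_id = sprintf("G%06d", seq_len(n)),
                       intercept = a, beta = beta, q = q, alpha = alpha,
                       stringsAsFactors = FALSE)
  rownames(counts) <- params$gene_id
  list(params = params, counts = counts)
}

#' Binomial thinning of a count matrix
#'
#' Each count is independently thinned at probability `rate`, emulating the
#' sparsity of deduplicated eCLIP libraries relative to the generative
#' abundance scale.
#'
#' @param counts Integer matrix (or vector).
#' @param rate Retention probability in `(0, 1]`.
#' @return Thinned counts with the same shape.
#' @export
downsample_counts <- function(counts, rate) {
  stopifnot(rate > 0, rate <= 1)
  if (rate == 1) return(counts)
  out <- stats::rbinom(length(counts), size = as.vector(counts), prob = rate)
  if (is.matrix(counts)) {
    out <- matrix(out, nrow = nrow(counts), dimnames = dimnames(counts))
  }
  out
}

#' Assign gene lengths rank-coupled to expression
#'
#' Lengths are drawn from the configured log-normal, then matched to genes
#' by expression rank after perturbing the ranks with Gaussian noise of
#' standard deviation `coupling_strength * n_genes`, producing a strong but
#' imperfect positive correlation between abundance and gene span.
#'
#' @param q Baseline gene abundances.
#' @param cfg A [simulation_config()].
#' @return Integer vector of lengths (bp), aligned to `q`.
#' @export
assign_gene_lengths <- function(q, cfg) {
  n <- length(q)
  lengths <- sort(pmin(pmax(round(stats::rlnorm(n, cfg$length_meanlog,
                                                cfg$length_sdlog)),
                            cfg$length_min), cfg$length_max))
  noise <- if (cfg$coupling_strength > 0)
    stats::rnorm(n, 0, cfg$coupling_strength * n) else numeric(n)
  perturbed <- rank(q, ties.method = "first") + noise
  lengths[rank(perturbed, ties.method = "first")]
}

#' Distribute gene counts into windows
#'
#' Each gene of length `L` has `ceiling(L / window_size)` windows; a random
#' subset of `ceiling(active_window_fraction * W)` windows is designated
#' active (high depth, exon-like), the rest inactive. Window weights are
#' drawn once per gene from `Gamma(shape = region peakiness, scale = 1)` and
#' shared across replicates. Per replicate, the gene count is split between
#' regions with a binomial draw at `active_read_fraction` and distributed
#' within each region by a single multinomial draw, so window counts sum
#' exactly to the gene count.
#'
#' @param params Gene parameter data.frame from [draw_gene_counts()].
#' @param counts Genes x replicates (downsampled) count matrix.
#' @param lengths Gene lengths from [assign_gene_lengths()].
#' @param cfg A [simulation_config()].
#' @param samples Sample sheet (column order of `counts`).
#' @return A [window_table()] whose meta carries an extra logical
#'   `is_active` column.
#' @export
distribute_counts_to_windows <- function(params, counts, lengths, cfg,
                                         samples = sim_sample_sheet(cfg$n_replicates)) {
  n <- nrow(params)
  ws <- cfg$window_size
  n_windows <- pmax(ceiling(lengths / ws), 1L)
  offsets <- c(0L, cumsum(n_windows))
  total <- offsets[n + 1L]
  n_rep <- ncol(counts)

  win_counts <- matrix(0, nrow = total, ncol = n_rep,
                       dimnames = list(NULL, colnames(counts)))
  is_active <- logical(total)

  for (g in seq_len(n)) {
    W <- n_windows[g]
    rows <- (offsets[g] + 1L):(offsets[g + 1L])
    n_act <- min(W, max(1L, ceiling(cfg$active_window_fraction * W)))
    act_local <- if (W == 1L) 1L else sample.int(W, n_act)
    act_rows <- rows[act_local]
    inact_rows <- if (n_act < W) rows[-act_local] else integer(0)
    is_active[act_rows] <- TRUE

    w_act <- pmax(stats::rgamma(n_act, shape = cfg$peakiness_active,
                                scale = 1), 1e-12)
    w_inact <- if (length(inact_rows) > 0L)
      pmax(stats::rgamma(length(inact_rows),
                         shape = cfg$peakiness_inactive, scale = 1), 1e-12)
    else numeric(0)

    for (j in seq_len(n_rep)) {
      cnt <- counts[g, j]
      if (cnt == 0) next
      if (length(inact_rows) == 0L) {
        act_cnt <- cnt
      } else {
        act_cnt <- stats::rbinom(1L, cnt, cfg$active_read_fraction)
      }
      if (act_cnt > 0) {
        win_counts[act_rows, j] <- win_counts[act_rows, j] +
          stats::rmultinom(1L, act_cnt, w_act)[, 1L]
      }
      rest <- cnt - act_cnt
      if (rest > 0) {
        win_counts[inact_rows, j] <- win_counts[inact_rows, j] +
          stats::rmultinom(1L, rest, w_inact)[, 1L]
      }
    }
  }

  gene_starts <- c(0, cumsum(as.numeric(lengths)))[seq_len(n)]
  win_index <- sequence(n_windows)
  gene_rep <- rep.int(seq_len(n), n_windows)
  start <- gene_starts[gene_rep] + (win_index - 1L) * ws
  end <- pmin(gene_starts[gene_rep] + win_index * ws,
              gene_starts[gene_rep] + lengths[gene_rep])

  feature_type <- character(total)
  feature_type[!is_active] <- "intron"
  n_act_total <- sum(is_active)
  feature_type[is_active] <- sample(c("CDS", "UTR3", "UTR5"), n_act_total,
                                    replace = TRUE, prob = c(0.5, 0.3, 0.2))

  meta <- data.frame(
    window_id = paste0(params$gene_id[gene_rep], "_w", win_index),
    chrom = "chrS",
    start = start,
    end = end,
    strand = "+",
    gene_id = params$gene_id[gene_rep],
    feature_type = feature_type,
    is_active = is_active,
    stringsAsFactors = FALSE)
  window_table(meta, win_counts)
}

#' Inject binding signal into IP replicates
#'
#' Samples `n_bound` bound genes from the sufficiently expressed pool
#' (`q >= min_expression_for_binding`), draws per-gene binding strengths
#' `kappa` from the shifted gamma, designates a `differential_fraction` of
#' bound genes as differential (treatment binding effect `zeta`; the rest
#' keep `zeta = 1`), and adds `round(gene_count * kappa * multiplier)`
#' pulldown reads to one fixed active window per gene in each IP replicate
#' (`multiplier = zeta` only in treatment-condition IP replicates of
#' differential genes). IN replicates are left untouched.
#'
#' @param table Window table from [distribute_counts_to_windows()].
#' @param params Gene parameters.
#' @param gene_counts Genes x replicates downsampled gene-level counts (the
#'   basis of the pulldown expectation).
#' @param cfg A [simulation_config()].
#' @param samples Sample sheet.
#' @return List with the modified `table` and `truth` (per-gene data.frame:
#'   `gene_id`, `bound`, `kappa`, `zeta`, `differential`, `bound_window_id`,
#'   `beta`).
#' @export
inject_binding <- function(table, params, gene_counts, cfg,
                           samples = sim_sample_sheet(cfg$n_replicates)) {
  n <- nrow(params)
  truth <- data.frame(gene_id = params$gene_id,
                      bound = FALSE,
                      kappa = NA_real_,
                      zeta = 1,
                      differential = FALSE,
                      bound_window_id = NA_character_,
                      beta = params$beta,
                      stringsAsFactors = FALSE)
  if (cfg$n_bound == 0L) return(list(table = table, truth = truth))

  eligible <- which(params$q >= cfg$min_expression_for_binding)
  if (length(eligible) < cfg$n_bound)
    stop("only ", length(eligible), " sufficiently expressed genes for ",
         cfg$n_bound, " bound genes")
  bound <- sort(eligible[sample.int(length(eligible), cfg$n_bound)])
  kappa <- cfg$kappa_shift +
    stats::rgamma(cfg$n_bound, shape = cfg$kappa_shape,
                  scale = cfg$kappa_scale)
  n_diff <- round(cfg$differential_fraction * cfg$n_bound)
  differential <- logical(cfg$n_bound)
  if (n_diff > 0L) differential[sample.int(cfg$n_bound, n_diff)] <- TRUE

  # one fixed active window per bound gene, shared across replicates
  active_by_gene <- split(table$meta$window_id[table$meta$is_active],
                          table$meta$gene_id[table$meta$is_active])
  bound_window <- vapply(params$gene_id[bound], function(g) {
    w <- active_by_gene[[g]]
    if (length(w) == 1L) w else sample(w, 1L)
  }, character(1))

  ip <- samples$assay == "IP"
  ip_trt <- samples$condition[ip] == "treatment"
  ip_ids <- samples$sample_id[ip]
  rows <- match(bound_window, table$meta$window_id)
  base <- gene_counts[bound, ip_ids, drop = FALSE]
  mult <- matrix(1, nrow = cfg$n_bound, ncol = length(ip_ids))
  mult[differential, ip_trt] <- cfg$zeta
  pulldown <- round(base * kappa * mult)
  table$counts[rows, ip_ids] <- table$counts[rows, ip_ids] + pulldown

  truth$bound[bound] <- TRUE
  truth$kappa[bound] <- kappa
  truth$zeta[bound] <- ifelse(differential, cfg$zeta, 1)
  truth$differential[bound] <- differential
  truth$bound_window_id[bound] <- bound_window
  list(table = table, truth = truth)
}

#' Simulate a complete eCLIP experiment
#'
#' Composes the generator stages under a single seed: gene-level negative
#' binomial counts, binomial thinning, rank-coupled gene lengths, window
#' distribution, and IP-only binding injection. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `table` (window table), `samples` (sample sheet),
#'   `truth` (per-gene binding truth), `params` (gene parameters including
#'   `length` and per-replicate gene counts as attribute), and `config`.
#' @export
simulate_experiment <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "flipper_sim_config"))
  set.seed(cfg$seed)
  samples <- sim_sample_sheet(cfg$n_replicates)
  drawn <- draw_gene_counts(cfg, samples)
  counts_ds <- downsample_counts(drawn$counts, cfg$downsample_rate)
  lengths <- assign_gene_lengths(drawn$params$q, cfg)
  table <- distribute_counts_to_windows(drawn$params, counts_ds, lengths,
                                        cfg, samples)
  inj <- inject_binding(table, drawn$params, counts_ds, cfg, samples)
  params <- drawn$params
  params$length <- lengths
  attr(params, "gene_counts") <- counts_ds
  list(table = inj$table, samples = samples, truth = inj$truth,
       params = params, config = cfg)
}

#' Write a simulated experiment to disk
#'
#' Emits the window count TSV (readable by [load_window_counts()]), the
#' sample sheet, the per-gene truth TSV, and a YAML echo of the resolved
#' configuration.
#'
#' @param sim Result of [simulate_experiment()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named vector of the files written.
#' @export
write_simulation <- function(sim, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts_path <- file.path(out_dir, "window_counts.tsv")
  meta <- sim$table$meta
  meta$is_active <- NULL
  write_window_counts(structure(list(meta = meta, counts = sim$table$counts),
                                class = "window_table"), counts_path)
  samples_path <- file.path(out_dir, "samples.tsv")
  sheet <- sim$samples
  sheet$reference <- sheet$condition == "control"
  data.table::fwrite(sheet[, c("sample_id", "assay", "condition_label",
                               "replicate", "reference")],
                     samples_path, sep = "\t", quote = FALSE,
                     col.names = TRUE)
  # condition_label column doubles as the user-facing condition
  hdr <- readLines(samples_path, n = 1L)
  body <- readLines(samples_path)[-1L]
  writeLines(c(sub("condition_label", "condition", hdr), body), samples_path)
  truth_path <- file.path(out_dir, "truth.tsv")
  data.table::fwrite(sim$truth, truth_path, sep = "\t", quote = FALSE)
  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(sim$config), config_path)
  invisible(c(counts = counts_path, samples = samples_path,
              truth = truth_path, config = config_path))
}
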