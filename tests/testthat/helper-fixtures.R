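# Shared fixtures: everything is generated in code at test time.

# cache for expensive objects shared across test files (one process run)
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache, inherits = FALSE)
}

test_samples <- function() {
  data.frame(
    sample_id = c("IP_c1", "IP_c2", "IP_t1", "IP_t2",
                  "IN_c1", "IN_c2", "IN_t1", "IN_t2"),
    assay = rep(c("IP", "IN"), each = 4),
    condition = rep(c("control", "control", "treatment", "treatment"), 2),
    condition_label = rep(c("ctrl", "ctrl", "drug", "drug"), 2),
    replicate = rep(c(1, 2, 1, 2), 2),
    stringsAsFactors = FALSE)
}

# small window table: n windows, one gene per `windows_per_gene` windows
test_window_table <- function(counts, windows_per_gene = 1,
                              feature_type = "CDS") {
  n <- nrow(counts)
  gene <- sprintf("g%03d", rep(seq_len(ceiling(n / windows_per_gene)),
                               each = windows_per_gene)[seq_len(n)])
  meta <- data.frame(
    window_id = sprintf("w%03d", seq_len(n)),
    chrom = "chr1",
    start = (seq_len(n) - 1L) * 100L,
    end = seq_len(n) * 100L,
    strand = "+",
    gene_id = gene,
    feature_type = rep_len(feature_type, n),
    stringsAsFactors = FALSE)
  colnames(counts) <- test_samples()$sample_id[seq_len(ncol(counts))]
  window_table(meta, counts)
}

# unified table fixture: `base` rows of stable-ratio background plus
# explicitly specified focal rows; each window its own gene
test_unified <- function(focal_ip, focal_ing, n_background = 80,
                         seed = 400) {
  set.seed(seed)
  samples <- test_samples()
  n_focal <- nrow(focal_ip)
  n <- n_background + n_focal
  ip <- matrix(rnbinom(n_background * 4, mu = 50, size = 10),
               ncol = 4)
  ing <- matrix(rnbinom(n_background * 4, mu = 1000, size = 20),
                ncol = 4)
  counts <- cbind(rbind(ip, focal_ip), rbind(ing, focal_ing))
  colnames(counts) <- samples$sample_id
  meta <- data.frame(
    window_id = sprintf("w%03d", seq_len(n)),
    chrom = "chr1", start = (seq_len(n) - 1L) * 100L,
    end = seq_len(n) * 100L, strand = "+",
    gene_id = sprintf("g%03d", seq_len(n)),
    feature_type = "CDS", stringsAsFactors = FALSE)
  rownames(counts) <- meta$window_id
  structure(list(meta = meta, counts = counts, samples = samples),
            class = "unified_table")
}

unit_factors <- function(samples = test_samples()) {
  data.frame(sample_id = samples$sample_id, factor = 1,
             provenance = ifelse(samples$assay == "IP",
                                 "hierarchical_IP", "joint_IN"))
}

# independent brute-force Benjamini-Hochberg
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# independent beta-binomial upper tail by numerical integration over the
# mixing Beta distribution
betabinom_upper_integrate <- function(x, n, p0, rho) {
  a <- p0 * (1 - rho) / rho
  b <- (1 - p0) * (1 - rho) / rho
  f <- function(t) pbinom(x - 1, n, t, lower.tail = FALSE) * dbeta(t, a, b)
  stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
}

# reduced-scale study configuration shared by the heavy property tests
bench_config <- function(...) {
  simulation_config(n_genes = 3000, n_bound = 600, ...)
}

bench_small <- function() {
  cached("bench_small", {
    suppressWarnings(run_benchmark(bench_config(), zetas = c(2, 3, 4),
                                   beta_sds = c(0, 2), n_sim_reps = 3,
                                   master_seed = 101))
  })
}

sim_z4b0 <- function() {
  cached("sim_z4b0", {
    sim <- simulate_experiment(bench_config(zeta = 4, beta_sd = 0,
                                            seed = 2024))
    fit <- suppressWarnings(flipper_pipeline(sim$table, sim$samples))
    list(sim = sim, fit = fit)
  })
}
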