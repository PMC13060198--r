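test_that("gene-level counts match negative binomial moments", {
  cfg <- simulation_config(n_genes = 1e5, n_bound = 0, intercept_mean = 5,
                           intercept_sd = 0, beta_sd = 0, seed = 1)
  set.seed(cfg$seed)
  drawn <- draw_gene_counts(cfg)
  m <- 2^5
  alpha <- cfg$dispersion_a0 + cfg$dispersion_a1 / m
  v <- m + alpha * m^2
  counts <- drawn$counts[, 1]
  expect_equal(mean(counts), m, tolerance = 3 * sqrt(v / 1e5) / m)
  expect_equal(var(counts), v, tolerance = 0.05 * v)
  # beta_sd = 0: treatment and control means identical per gene
  expect_equal(drawn$params$beta, rep(0, 1e5))
})

test_that("expression treatment effects shift treatment means only", {
  cfg <- simulation_config(n_genes = 2e4, n_bound = 0, intercept_mean = 6,
                           intercept_sd = 0, beta_sd = 1, seed = 2)
  set.seed(cfg$seed)
  drawn <- draw_gene_counts(cfg)
  samples <- attr(drawn$counts, "dimnames")[[2]]
  trt <- grepl("treatment", samples)
  big <- drawn$params$beta > 1
  ratio <- rowMeans(drawn$counts[big, trt]) /
    rowMeans(drawn$counts[big, !trt])
  expect_equal(mean(log2(ratio) - drawn$params$beta[big]), 0,
               tolerance = 0.1)
})

test_that("binomial thinning preserves the expected rate", {
  set.seed(3)
  expect_equal(downsample_counts(matrix(7, 2, 2), 1),
               matrix(7, 2, 2))                      # rate 1 is identity
  expect_equal(downsample_counts(0L, 0.5), 0L)       # zero stays zero
  thinned <- downsample_counts(1e6L, 0.5)
  expect_lt(abs(thinned - 5e5), 3 * sqrt(1e6 * 0.25))
  x <- rep(100L, 1e5)
  th <- downsample_counts(x, 0.1)
  expect_equal(mean(th), 10, tolerance = 3 * sqrt(100 * 0.1 * 0.9 / 1e5))
})

test_that("gene lengths couple to expression through noisy ranks", {
  q <- 2^rnorm(5000, 7, 3)
  cfg0 <- simulation_config(n_genes = 5000, n_bound = 500,
                            coupling_strength = 1e-6, seed = 4)
  set.seed(4)
  l0 <- assign_gene_lengths(q, cfg0)
  expect_gt(cor(q, l0, method = "spearman"), 0.999)  # no-noise limit

  cfg3 <- simulation_config(n_genes = 5000, n_bound = 500,
                            coupling_strength = 0.3, seed = 4)
  set.seed(4)
  l3 <- assign_gene_lengths(q, cfg3)
  rho <- cor(q, l3, method = "spearman")
  expect_gt(rho, 0.4)
  expect_lt(rho, 0.95)

  cfg_inf <- simulation_config(n_genes = 5000, n_bound = 500,
                               coupling_strength = 1e3, seed = 4)
  set.seed(4)
  linf <- assign_gene_lengths(q, cfg_inf)
  expect_lt(abs(cor(q, linf, method = "spearman")), 0.1)
})

test_that("window distribution conserves counts exactly", {
  cfg <- simulation_config(n_genes = 200, n_bound = 0, seed = 5)
  set.seed(5)
  drawn <- draw_gene_counts(cfg)
  counts <- downsample_counts(drawn$counts, cfg$downsample_rate)
  lengths <- assign_gene_lengths(drawn$params$q, cfg)
  tab <- distribute_counts_to_windows(drawn$params, counts, lengths, cfg)
  sums <- rowsum(tab$counts, tab$meta$gene_id)
  expect_equal(unname(sums[drawn$params$gene_id, ]), unname(counts))
  # short gene: all counts in its single window
  expect_true(all(table(tab$meta$gene_id) == ceiling(lengths / 100)))
})

test_that("peakiness controls the inequality of window weights", {
  gini <- function(w) {
    w <- sort(w)
    n <- length(w)
    sum((2 * seq_len(n) - n - 1) * w) / (n * sum(w))
  }
  set.seed(6)
  g_low <- mean(replicate(50, gini(rgamma(100, shape = 0.5))))
  g_high <- mean(replicate(50, gini(rgamma(100, shape = 5))))
  g_huge <- mean(replicate(50, gini(rgamma(100, shape = 500))))
  expect_gt(g_low, g_high)    # smaller shape = peakier
  expect_gt(g_high, g_huge)   # shape -> infinity approaches uniform
  expect_lt(g_huge, 0.05)
})

test_that("binding injection touches only IP samples at the recorded window", {
  cfg <- simulation_config(n_genes = 400, n_bound = 50, zeta = 3,
                           min_expression_for_binding = 20, seed = 7)
  set.seed(7)
  samples <- flipper:::sim_sample_sheet(cfg$n_replicates)
  drawn <- draw_gene_counts(cfg, samples)
  counts <- downsample_counts(drawn$counts, cfg$downsample_rate)
  lengths <- assign_gene_lengths(drawn$params$q, cfg)
  tab <- distribute_counts_to_windows(drawn$params, counts, lengths, cfg,
                                      samples)
  before <- tab$counts
  inj <- inject_binding(tab, drawn$params, counts, cfg, samples)
  truth <- inj$truth

  in_ids <- samples$sample_id[samples$assay == "IN"]
  ip_ids <- samples$sample_id[samples$assay == "IP"]
  ip_trt <- samples$sample_id[samples$assay == "IP" &
                                samples$condition == "treatment"]
  # IN untouched, bit for bit
  expect_identical(inj$table$counts[, in_ids], before[, in_ids])

  expect_equal(sum(truth$bound), 50L)
  expect_equal(sum(truth$differential), 25L)
  expect_true(all(truth$differential[truth$differential] &
                    truth$bound[truth$differential]))
  expect_true(all(truth$zeta[truth$bound & !truth$differential] == 1))
  expect_true(all(truth$kappa[truth$bound] > cfg$kappa_shift))
  expect_true(all(is.na(truth$kappa[!truth$bound])))

  # added reads at the recorded window equal round(count * kappa * mult)
  rows <- match(truth$bound_window_id[truth$bound], tab$meta$window_id)
  gidx <- which(truth$bound)
  added <- inj$table$counts[rows, ip_ids] - before[rows, ip_ids]
  mult <- matrix(1, length(gidx), length(ip_ids),
                 dimnames = list(NULL, ip_ids))
  mult[truth$differential[gidx], ip_trt] <- cfg$zeta
  expect_equal(unname(added),
               unname(round(counts[gidx, ip_ids] * truth$kappa[gidx] *
                              mult)))
  # only eligible genes are bound
  expect_true(all(drawn$params$q[gidx] >= cfg$min_expression_for_binding))
})

test_that("pulldown arithmetic: count 100, kappa 2, zeta 3 adds 600 reads", {
  expect_equal(round(100 * 2 * 3), 600)
  cfg <- simulation_config(n_genes = 50, n_bound = 1, zeta = 3,
                           min_expression_for_binding = 0, seed = 8)
  set.seed(8)
  samples <- flipper:::sim_sample_sheet(8)
  params <- data.frame(gene_id = sprintf("G%02d", 1:50),
                       intercept = 7, beta = 0, q = 128, alpha = 0.07)
  counts <- matrix(100, 50, 8, dimnames = list(params$gene_id,
                                               samples$sample_id))
  tab <- distribute_counts_to_windows(params, counts, rep(500L, 50), cfg,
                                      samples)
  inj <- inject_binding(tab, params, counts, cfg, samples)
  truth <- inj$truth
  g <- which(truth$bound)
  row <- match(truth$bound_window_id[g], tab$meta$window_id)
  added <- inj$table$counts[row, ] - tab$counts[row, ]
  kappa <- truth$kappa[g]
  trt_ip <- samples$sample_id[samples$assay == "IP" &
                                samples$condition == "treatment"]
  ctrl_ip <- samples$sample_id[samples$assay == "IP" &
                                 samples$condition == "control"]
  expect_equal(unname(added[ctrl_ip]), rep(round(100 * kappa), 2))
  if (truth$differential[g]) {
    expect_equal(unname(added[trt_ip]), rep(round(100 * kappa * 3), 2))
  } else {
    expect_equal(unname(added[trt_ip]), rep(round(100 * kappa), 2))
  }
})

test_that("kappa follows the shifted gamma and zeta = 1 means no effect", {
  cfg <- simulation_config(n_genes = 4000, n_bound = 2000, zeta = 1,
                           min_expression_for_binding = 0, seed = 9)
  sim <- simulate_experiment(cfg)
  truth <- sim$truth
  k <- truth$kappa[truth$bound]
  want <- cfg$kappa_shift + cfg$kappa_shape * cfg$kappa_scale
  se <- sqrt(cfg$kappa_shape) * cfg$kappa_scale / sqrt(length(k))
  expect_lt(abs(mean(k) - want), 3 * se)
  # zeta = 1: differential genes exist by label but carry no effect
  expect_true(all(truth$zeta == 1))
})

test_that("the simulated experiment is deterministic given its seed", {
  cfg <- simulation_config(n_genes = 150, n_bound = 30, seed = 10)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$table$counts, s2$table$counts)
  expect_identical(s1$table$meta, s2$table$meta)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # different seed, different data
  s3 <- simulate_experiment(simulation_config(n_genes = 150, n_bound = 30,
                                              seed = 11))
  expect_false(identical(s1$table$counts, s3$table$counts))
})

test_that("simulated output files load back through the io layer", {
  cfg <- simulation_config(n_genes = 100, n_bound = 20, seed = 12)
  sim <- simulate_experiment(cfg)
  out <- withr::local_tempdir()
  files <- write_simulation(sim, out)
  samples <- load_sample_sheet(files[["samples"]])
  expect_equal(nrow(samples), 8L)
  expect_equal(sum(samples$assay == "IP" & samples$condition == "control"),
               2L)
  tab <- load_window_counts(files[["counts"]], samples)
  expect_equal(unname(tab$counts), unname(sim$table$counts))
})
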