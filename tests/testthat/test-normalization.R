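test_that("median-of-ratios matches the hand-computed oracle", {
  # identical columns -> all factors 1
  m <- matrix(c(3, 7, 11, 3, 7, 11), ncol = 2)
  expect_equal(unname(mor_size_factors(m)), c(1, 1))

  # rows (2,4),(4,8),(6,12): every row ratio is (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(2, 4, 6, 4, 8, 12), ncol = 2)
  expect_equal(unname(mor_size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)

  # agreement with the established implementation on a random fixture
  set.seed(5)
  m3 <- matrix(rpois(300, 40) + 1, ncol = 6)
  expect_equal(unname(mor_size_factors(m3)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m3)),
               tolerance = 1e-4)

  # all rows contain a zero -> strict errors, fallback succeeds
  m4 <- matrix(c(0, 5, 4, 0), ncol = 2)
  expect_error(mor_size_factors(m4), "pseudocounts")
  expect_warning(f4 <- mor_size_factors(m4, zero_handling = "fallback"))
  expect_true(all(is.finite(f4) & f4 > 0))
})

test_that("scaling one sample's counts scales its factor equivariantly", {
  set.seed(6)
  m <- matrix(rpois(200, 60) + 1, ncol = 4)
  f <- mor_size_factors(m)
  for (c_mult in c(0.5, 2, 7)) {
    m2 <- m
    m2[, 2] <- m[, 2] * c_mult
    f2 <- mor_size_factors(m2)
    # geometric-mean reference changes by c^(1/4) for every row
    expect_equal(f2[2] / f[2] * c_mult^(1 / 4), c_mult, tolerance = 1e-10)
    expect_equal(unname(f2[-2] / f[-2]), rep(c_mult^(-1 / 4), 3),
                 tolerance = 1e-10)
  }
})

test_that("hierarchical factors separate pulldown and depth stages", {
  groups <- c(a1 = "ctrl", a2 = "ctrl", b1 = "trt", b2 = "trt")
  set.seed(7)
  binding <- matrix(rpois(200, 200) + 1, ncol = 4)
  background <- matrix(rpois(400, 50) + 1, ncol = 4)

  # identical count distributions -> all final factors ~1
  m <- rbind(binding, background)
  colnames(m) <- names(groups)
  classes <- rep(c("binding", "background"), c(50, 100))
  f <- hierarchical_ip_factors(m, classes, groups)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  # treatment background uniformly x2, binding unchanged: the treatment
  # group factor doubles relative to control while stage-1 factors stay ~1
  m2 <- m
  m2[classes == "background", 3:4] <- m2[classes == "background", 3:4] * 2
  f2 <- hierarchical_ip_factors(m2, classes, groups)
  stages <- attr(f2, "stages")
  expect_equal(unname(stages$group_factor["trt"] /
                        stages$group_factor["ctrl"]), 2, tolerance = 0.1)
  expect_equal(unname(stages$within_group), rep(1, 4), tolerance = 0.1)
  expect_equal(unname(f2["b1"] / f2["a1"]), 2, tolerance = 0.15)

  # one replicate with binding counts x2 (washing/pulldown discordance):
  # its stage-1 factor doubles relative to its partner, depth unaffected
  m3 <- m
  m3[classes == "binding", 4] <- m3[classes == "binding", 4] * 2
  f3 <- hierarchical_ip_factors(m3, classes, groups)
  st3 <- attr(f3, "stages")
  expect_equal(unname(st3$within_group["b2"] / st3$within_group["b1"]), 2,
               tolerance = 0.1)
  expect_equal(unname(st3$group_factor["trt"] / st3$group_factor["ctrl"]),
               1, tolerance = 0.1)

  expect_error(hierarchical_ip_factors(m, rep("binding", 150), groups),
               "background")
  expect_error(hierarchical_ip_factors(m, rep("background", 150), groups),
               "binding")
})

test_that("background-only normalization distorts binding means where the
           hierarchical scheme recovers them", {
  # discordance scenario: replicate b2 has background x2 (washing) and
  # binding x0.5 (pulldown). True binding signal is identical across
  # replicates after pulldown correction.
  groups <- c(a1 = "ctrl", a2 = "ctrl", b1 = "trt", b2 = "trt")
  set.seed(8)
  binding_base <- matrix(rpois(200, 400) + 1, ncol = 4)
  background_base <- matrix(rpois(400, 80) + 1, ncol = 4)
  binding <- binding_base
  binding[, 4] <- round(binding[, 4] * 0.5)
  background <- background_base
  background[, 4] <- background[, 4] * 2
  m <- rbind(binding, background)
  colnames(m) <- names(groups)
  classes <- rep(c("binding", "background"), c(50, 100))

  f_hier <- hierarchical_ip_factors(m, classes, groups)
  f_bg <- mor_size_factors(background)
  f_bg <- f_bg / exp(mean(log(f_bg)))

  norm_hier <- sweep(m[classes == "binding", ], 2, f_hier, "/")
  norm_bg <- sweep(m[classes == "binding", ], 2, f_bg, "/")
  # error of replicate b2's binding mean relative to its partner b1
  err_hier <- abs(log2(mean(norm_hier[, 4]) / mean(norm_hier[, 3])))
  err_bg <- abs(log2(mean(norm_bg[, 4]) / mean(norm_bg[, 3])))
  expect_lt(err_hier, err_bg)
  expect_lt(err_hier, 0.2)   # hierarchical recovers ~equal binding means
  expect_gt(err_bg, 1.5)     # background-only misses by ~2 log2 units
})

test_that("input factors track sequencing depth", {
  set.seed(9)
  ing <- matrix(rnbinom(4000, mu = 80, size = 5), ncol = 4)
  f <- input_size_factors(ing)
  expect_equal(unname(f), rep(1, 4), tolerance = 0.05,
               ignore_attr = TRUE)

  # one IN sample binomially thinned to half depth
  ing2 <- ing
  ing2[, 3] <- rbinom(nrow(ing), ing[, 3], 0.5)
  f2 <- input_size_factors(ing2)
  expect_equal(unname(f2[3] / exp(mean(log(f2[-3])))), 0.5,
               tolerance = 0.05)

  expect_warning(f1 <- input_size_factors(ing[, 1, drop = FALSE]),
                 "single IN sample")
  expect_equal(unname(f1), 1, ignore_attr = TRUE)
})

test_that("rescaling all IP (or IN) factors leaves the interaction LFC
           unchanged", {
  focal_ip <- matrix(c(10, 10, 40, 40), nrow = 1)
  focal_ing <- matrix(c(1000, 1000, 2000, 2000), nrow = 1)
  uni <- test_unified(focal_ip, focal_ing, n_background = 40)
  f0 <- unit_factors()
  res0 <- fit_interaction_model(uni, factors = f0)

  f_ip <- f0
  f_ip$factor[1:4] <- f_ip$factor[1:4] * 3.7
  res_ip <- fit_interaction_model(uni, factors = f_ip)
  expect_lt(max(abs(res0$log2FC - res_ip$log2FC)), 1e-4)

  f_in <- f0
  f_in$factor[5:8] <- f_in$factor[5:8] * 0.41
  res_in <- fit_interaction_model(uni, factors = f_in)
  expect_lt(max(abs(res0$log2FC - res_in$log2FC)), 1e-4)
})

test_that("factor tables round-trip through TSV", {
  f <- data.frame(sample_id = c("a", "b"), factor = c(0.8, 1.25),
                  provenance = c("hierarchical_IP", "joint_IN"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_factors(f, path)
  back <- read_factors(path)
  expect_equal(back$factor, f$factor)
  f_bad <- f
  f_bad$factor[1] <- -1
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_factors(f_bad, path2)
  expect_error(read_factors(path2), "positive")
})
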