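# Simplified beta-binomial enrichment caller.
#
# A deliberately simple stand-in for a full peak caller: replicates are
# pooled by summation, a single global foreground fraction p0 and a single
# method-of-moments overdispersion rho are estimated, and each window gets a
# one-sided upper-tail beta-binomial p-value for its foreground count out of
# foreground + background. No GC-stratified nulls and no window retesting
# are attempted. The same engine defines the tested-window set for the
# interaction model and realizes the ad-hoc and IP-vs-IP comparator methods.

#' Upper-tail beta-binomial probability
#'
#' Computes `P(X >= x)` for `X ~ BetaBinomial(n, p0, rho)` where `rho` is the
#' intra-class correlation (`rho = 1/(a + b + 1)` in shape parameters). At
#' `rho = 0` this is the exact binomial upper tail. For `rho > 0` the tail is
#' accumulated from whichever side of `x` has fewer terms, so the cost per
#' window is `min(x, n - x + 1)` pmf evaluations.
#'
#' @param x Observed foreground counts (vector).
#' @param n Totals (vector, recycled against `x`).
#' @param p0 Null foreground fraction.
#' @param rho Overdispersion in `[0, 1)`.
#' @return Vector of p-values in `(0, 1]`; windows with `n = 0` get 1.
#' @export
pbetabinom_upper <- function(x, n, p0, rho = 0) {
  stopifnot(p0 > 0, p0 < 1, rho >= 0, rho < 1)
  k <- max(length(x), length(n))
  x <- rep_len(x, k)
  n <- rep_len(n, k)
  p <- rep_len(1, k)
  if (rho == 0) {
    has <- n > 0 & x > 0
    p[has] <- stats::pbinom(x[has] - 1, n[has], p0, lower.tail = FALSE)
    return(pmax(pmin(p, 1), 1e-300))
  }
  ab <- (1 - rho) / rho
  a <- p0 * ab
  b <- (1 - p0) * ab
  lbeta_ab <- lbeta(a, b)
  logpmf <- function(kk, nn) {
    lchoose(nn, kk) + lbeta(kk + a, nn - kk + b) - lbeta_ab
  }
  todo <- which(n > 0 & x > 0)
  if (length(todo) > 0L) {
    xx <- x[todo]; nn <- n[todo]
    upper_terms <- nn - xx + 1
    use_upper <- upper_terms <= xx
    # expand k-sequences per window and reduce with rowsum on the pmf
    from <- ifelse(use_upper, xx, 0)
    len <- ifelse(use_upper, upper_terms, xx)
    id <- rep.int(seq_along(todo), len)
    kseq <- sequence(len) - 1L + rep.int(from, len)
    mass <- rowsum(exp(logpmf(kseq, rep.int(nn, len))), id)[, 1L]
    p[todo] <- ifelse(use_upper, mass, 1 - mass)
  }
  pmax(pmin(p, 1), 1e-300)
}

#' Method-of-moments overdispersion estimate
#'
#' Given per-window foreground counts `x` out of totals `n` and a common
#' null fraction `p0`, the beta-binomial variance is
#' `n * p0 * (1 - p0) * (1 + (n - 1) * rho)`. Solving the pooled moment
#' equation over windows with `n >= min_total` gives
#' `rho = sum((x - n p0)^2 / (p0 (1 - p0)) - n) / sum(n (n - 1))`,
#' clamped to `[0, 0.99]` (negative estimates collapse to 0).
#'
#' @param x Foreground counts.
#' @param n Totals.
#' @param p0 Null foreground fraction; estimated as `sum(x)/sum(n)` over the
#'   usable windows when omitted.
#' @param min_total Minimum total count for a window to enter the estimate.
#' @param min_windows Minimum number of usable windows; below it the
#'   estimate falls back to 0 with a warning.
#' @return Scalar `rho` in `[0, 0.99]`.
#' @export
estimate_overdispersion <- function(x, n, p0 = NULL, min_total = 10,
                                    min_windows = 30) {
  use <- which(n >= min_total)
  if (length(use) < min_windows) {
    warning("fewer than ", min_windows, " windows with total >= ", min_total,
            "; overdispersion set to 0")
    return(0)
  }
  x <- x[use]; n <- n[use]
  if (is.null(p0)) p0 <- sum(x) / sum(n)
  if (p0 <= 0 || p0 >= 1) return(0)
  num <- sum((x - n * p0)^2 / (p0 * (1 - p0)) - n)
  den <- sum(n * (n - 1))
  if (den <= 0) return(0)
  min(max(num / den, 0), 0.99)
}

pool_counts <- function(table, sample_ids) {
  m <- table$counts[, sample_ids, drop = FALSE]
  if (ncol(m) == 1L) m[, 1L] else rowSums(m)
}

#' Robust joint estimation of the null fraction and overdispersion
#'
#' The pooled global fraction `sum(x)/sum(n)` is contaminated by the very
#' windows the test is meant to find: a minority of strongly enriched
#' windows can dominate the pooled read mass and inflate both `p0` and the
#' moment estimate of `rho`. This estimator starts from the median
#' per-window fraction, iterates an outlier trim on the per-window moment
#' ratio `rho_i = (r2_i - n_i) / (n_i (n_i - 1))` (windows above
#' `Q3 + 3 IQR` are dropped), re-pools `p0` over the kept windows, and
#' finally applies the weighted method-of-moments estimate on the kept set.
#' The trim biases `rho` slightly downward on heavily overdispersed null
#' data; in exchange the estimate is stable when a few percent of windows
#' carry real signal.
#'
#' @param x Foreground counts per window.
#' @param n Totals per window.
#' @param min_total Minimum total for a window to enter the estimation.
#' @param iters Trim/re-pool iterations.
#' @return List with `p0`, `rho`, and `n_trimmed`.
#' @export
estimate_null <- function(x, n, min_total = 10, iters = 3) {
  use <- which(n >= min_total)
  small <- which(n < min_total)
  clamp <- function(p) min(max(p, 1e-6), 1 - 1e-6)
  if (length(use) < 30) {
    warning("fewer than 30 windows with total >= ", min_total,
            "; falling back to pooled p0 and rho = 0")
    return(list(p0 = clamp(sum(x) / sum(n)), rho = 0, n_trimmed = 0L))
  }
  p0 <- clamp(stats::median(x[use] / n[use]))
  keep <- use
  for (i in seq_len(iters)) {
    r2 <- (x[use] - n[use] * p0)^2 / (p0 * (1 - p0))
    rho_i <- (r2 - n[use]) / (n[use] * (n[use] - 1))
    q <- stats::quantile(rho_i, c(0.25, 0.75))
    keep <- use[rho_i <= q[2L] + 3 * (q[2L] - q[1L])]
    p0 <- clamp(sum(x[c(keep, small)]) / sum(n[c(keep, small)]))
  }
  nk <- n[keep]
  r2k <- (x[keep] - nk * p0)^2 / (p0 * (1 - p0))
  rho_ik <- (r2k - nk) / (nk * (nk - 1))
  rho <- min(max(sum(r2k - nk) / sum(nk * (nk - 1)), 0), 0.99)
  # re-weight with variance-saturating weights: under overdispersion the
  # sampling variance of a window's moment ratio stops shrinking with n, so
  # n^2 weights would let a handful of ultra-deep windows dominate
  for (i in seq_len(5L)) {
    w <- ((nk - 1) / (1 + (nk - 1) * rho))^2
    rho_new <- min(max(sum(w * rho_ik) / sum(w), 0), 0.99)
    if (abs(rho_new - rho) < 1e-8) {
      rho <- rho_new
      break
    }
    rho <- rho_new
  }
  list(p0 = p0, rho = rho, n_trimmed = length(use) - length(keep))
}

#' Technical overdispersion from within-condition replicate splits
#'
#' Splits a condition's replicate set in half, treats the first half's
#' pooled counts as "foreground" out of the condition total, and estimates
#' the beta-binomial overdispersion of that split. Replicates of one
#' condition share all biological effects, so the estimate reflects
#' technical variation only — the null a repurposed peak caller carries
#' into a cross-condition comparison.
#'
#' @param table A [window_table()].
#' @param sample_ids Sample ids of one condition's replicates (>= 2).
#' @return Scalar `rho`.
#' @export
replicate_split_rho <- function(table, sample_ids) {
  if (length(sample_ids) < 2L)
    stop("replicate-split overdispersion needs at least two replicates")
  half <- sample_ids[seq_len(floor(length(sample_ids) / 2))]
  rest <- setdiff(sample_ids, half)
  x <- pool_counts(table, half)
  n <- x + pool_counts(table, rest)
  estimate_null(x, n)$rho
}

#' Window enrichment test (foreground vs background)
#'
#' Pools replicate counts by summation on both sides, estimates the null
#' foreground fraction `p0` and overdispersion `rho` (robustly via
#' [estimate_null()] by default, or as the pooled global ratio
#' `sum(fg) / (sum(fg) + sum(bg))` with the plain moment estimator when
#' `null_method = "pooled"`), and tests each window's foreground count
#' against the upper beta-binomial tail. Enrichment is called at
#' `q < q_threshold` after Benjamini-Hochberg adjustment across windows.
#'
#' @param fg,bg Numeric vectors of pooled foreground / background counts per
#'   window (same length and order).
#' @param window_id Optional window ids carried into the result.
#' @param q_threshold BH-adjusted significance cutoff (default 0.05).
#' @param p0,rho Null parameter overrides; estimated from the data when
#'   `NULL`.
#' @param null_method `"robust"` (default) or `"pooled"` null estimation.
#' @return data.frame with `window_id`, `x`, `y`, `n`, `p0`, `rho`,
#'   `pvalue`, `qvalue`, `enriched`.
#' @export
window_enrichment_test <- function(fg, bg, window_id = NULL,
                                   q_threshold = 0.05, p0 = NULL,
                                   rho = NULL,
                                   null_method = c("robust", "pooled")) {
  null_method <- match.arg(null_method)
  if (length(fg) != length(bg))
    stop("fg and bg must have one pooled count per window each")
  if (is.null(window_id)) window_id <- as.character(seq_along(fg))
  n <- fg + bg
  tot <- sum(fg) + sum(bg)
  if (tot == 0) stop("enrichment test: all counts are zero")
  if (is.null(p0) || is.null(rho)) {
    if (null_method == "robust") {
      est <- estimate_null(fg, n)
      if (is.null(p0)) p0 <- est$p0
      if (is.null(rho)) rho <- est$rho
    } else {
      if (is.null(p0)) p0 <- sum(fg) / tot
      if (is.null(rho)) rho <- estimate_overdispersion(fg, n, p0 = p0)
    }
  }
  pvalue <- pbetabinom_upper(fg, n, p0, rho)
  qvalue <- stats::p.adjust(pvalue, method = "BH")
  data.frame(window_id = window_id, x = fg, y = bg, n = n, p0 = p0,
             rho = rho, pvalue = pvalue, qvalue = qvalue,
             enriched = qvalue < q_threshold,
             row.names = NULL)
}

#' Call enriched windows per condition (IP vs IN)
#'
#' Runs the enrichment test separately within each condition — pooled IP
#' replicates as foreground against pooled window-level IN replicates as
#' background — and returns the windows enriched in at least one condition.
#' This defines both the tested-window set of the interaction model and the
#' binding/background partition of the hierarchical normalization.
#'
#' @param table A [window_table()].
#' @param samples Validated sample sheet.
#' @param q_threshold BH cutoff per condition run.
#' @param rho Overdispersion override passed to [window_enrichment_test()].
#' @return data.frame with columns `window_id` and `condition`, one row per
#'   (enriched window, condition) pair. The full per-condition test tables
#'   are attached as attribute `tests`.
#' @export
call_enriched_windows <- function(table, samples, q_threshold = 0.05,
                                  rho = NULL) {
  conds <- unique(samples$condition)
  tests <- list()
  hits <- list()
  for (cond in conds) {
    ip <- samples$sample_id[samples$assay == "IP" & samples$condition == cond]
    inn <- samples$sample_id[samples$assay == "IN" & samples$condition == cond]
    res <- window_enrichment_test(pool_counts(table, ip),
                                  pool_counts(table, inn),
                                  window_id = table$meta$window_id,
                                  q_threshold = q_threshold, rho = rho)
    tests[[cond]] <- res
    if (any(res$enriched))
      hits[[cond]] <- data.frame(window_id = res$window_id[res$enriched],
                                 condition = cond)
  }
  out <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(window_id = character(0), condition = character(0))
  rownames(out) <- NULL
  attr(out, "tests") <- tests
  out
}

#' Ad-hoc differential calls by per-condition set difference
#'
#' The classical qualitative strategy: windows enriched exclusively in the
#' treatment condition are "up", windows enriched exclusively in the control
#' condition are "down".
#'
#' @param control_enriched,treatment_enriched Character vectors of enriched
#'   window ids per condition (computed with identical test settings).
#' @return List with `method = "adhoc"`, `up`, `down` (disjoint character
#'   vectors).
#' @export
adhoc_differential <- function(control_enriched, treatment_enriched) {
  list(method = "adhoc",
       up = setdiff(treatment_enriched, control_enriched),
       down = setdiff(control_enriched, treatment_enriched))
}

#' Repurposed IP-vs-IP differential calls ("Diff-Skipper" style)
#'
#' Repurposes the one-directional enrichment test for differential analysis:
#' one run takes pooled treatment IP as foreground against pooled control IP
#' as background (hits = increased binding), a second run swaps the roles
#' (hits = decreased binding). Both runs are performed over the full window
#' table — the null fraction and overdispersion must be estimated on the
#' genome-wide background, exactly as a repurposed peak caller would run —
#' and the resulting calls are then restricted to the tested-window set. A
#' window significant in both directions would contradict the one-sided
#' design; such conflicts are dropped with a warning.
#'
#' The null overdispersion of both runs is calibrated on within-condition
#' replicate splits ([replicate_split_rho()], averaged over the two IP
#' groups): a peak caller's null describes technical variation around its
#' input, so condition-level expression shifts deliberately fall outside it.
#' This is the failure mode the comparator exists to exhibit — expression
#' driven IP changes are indistinguishable from binding changes to an
#' IP-only test.
#'
#' @param table A [window_table()].
#' @param samples Validated sample sheet.
#' @param tested Character vector of window ids to evaluate (or data.frame
#'   with a `window_id` column).
#' @param q_threshold BH cutoff per directional run.
#' @param rho Overdispersion override passed to [window_enrichment_test()].
#' @return List with `method = "diffskipper"`, `up`, `down`.
#' @export
diffskipper_differential <- function(table, samples, tested,
                                     q_threshold = 0.05, rho = NULL) {
  if (is.data.frame(tested)) tested <- tested$window_id
  tested <- unique(as.character(tested))
  ids <- table$meta$window_id
  ctrl_ip <- samples$sample_id[samples$assay == "IP" &
                                 samples$condition == "control"]
  trt_ip <- samples$sample_id[samples$assay == "IP" &
                                samples$condition == "treatment"]
  ctrl <- pool_counts(table, ctrl_ip)
  trt <- pool_counts(table, trt_ip)
  if (is.null(rho)) {
    rho <- mean(c(replicate_split_rho(table, ctrl_ip),
                  replicate_split_rho(table, trt_ip)))
  }

  up_run <- window_enrichment_test(trt, ctrl, window_id = ids,
                                   q_threshold = q_threshold, rho = rho)
  down_run <- window_enrichment_test(ctrl, trt, window_id = ids,
                                     q_threshold = q_threshold, rho = rho)
  up <- intersect(up_run$window_id[up_run$enriched], tested)
  down <- intersect(down_run$window_id[down_run$enriched], tested)
  both <- intersect(up, down)
  if (length(both) > 0L) {
    warning(length(both), " window(s) significant in both IP-vs-IP ",
            "directions; dropped from both sets")
    up <- setdiff(up, both)
    down <- setdiff(down, both)
  }
  list(method = "diffskipper", up = up, down = down)
}
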