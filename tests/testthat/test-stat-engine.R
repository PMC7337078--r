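test_that("branch diversity of two samples is twice the TMRCA", {
  t_mrca <- 3.7
  ts <- tree_sequence(
    nodes = data.frame(is_sample = c(TRUE, TRUE, FALSE),
                       time = c(0, 0, t_mrca)),
    edges = data.frame(left = 0, right = 1, parent = 2, child = 0:1),
    L = 1)
  S <- sample_set("pair", 0:1)
  expect_equal(diversity(ts, S, mode = "branch")$values[1, 1], 2 * t_mrca)
})

test_that("the zero summary gives zero in every window and mode", {
  ts <- random_mutated_ts(6, 4, seed = 11)
  W <- indicator_weights(ts, list(ts$samples))
  f0 <- summary_function(function(M) numeric(ncol(M)), m = 1, name = "zero")
  wb <- equal_windows(ts$L, 3)
  for (mode in c("site", "branch", "node"))
    expect_true(all(stat_compute(ts, W, f0, mode, wb)$values == 0))
})

test_that("site and branch modes enforce strictness unless overridden", {
  ts <- fig_divergence_ts()
  W <- indicator_weights(ts, list(red_set()))
  f_bad <- summary_function(function(M) M[1, ] / 3, m = 1, strict = FALSE,
                            name = "mean_freq")
  expect_error(site_stat(ts, W, f_bad), "not strict")
  expect_error(branch_stat(ts, W, f_bad), "not strict")
  expect_silent(site_stat(ts, W, f_bad, strict_override = TRUE))
  # node mode never enforces strictness
  expect_silent(node_stat(ts, W, f_bad))
})

test_that("incremental engine matches the brute-force oracle", {
  set.seed(4242)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    ts <- random_mutated_ts(n, sample(1:8, 1), seed = 5000 + i,
                            mu = runif(1, 0.3, 1.5))
    m <- sample(1:4, 1)
    W <- sample_weights(matrix(runif(n * m), n, m), ts$samples)
    f <- strict_product_summary(W$w_total)
    wb <- ts_windows(c(0, sort(runif(sample(1:3, 1), 0, ts$L)), ts$L),
                     ts$L)
    pol <- i %% 2 == 0
    for (mode in c("site", "branch", "node")) {
      a <- stat_compute(ts, W, f, mode, wb, polarized = pol, verify = TRUE)
      b <- naive_stats(ts, W, f, mode, wb, polarized = pol)
      expect_stat_equal(a, b, tol = 1e-9)
    }
  }
})

test_that("whole-genome value is the length-weighted mean over windows", {
  ts <- random_mutated_ts(6, 5, seed = 77)
  S <- sample_set("all", ts$samples)
  W <- indicator_weights(ts, list(S))
  f <- summary_diversity(S$n)
  wb <- ts_windows(c(0, 0.83, 1.9, 3.2, ts$L), ts$L)
  wlen <- diff(wb)
  for (mode in c("site", "branch")) {
    whole <- stat_compute(ts, W, f, mode)$values[1, 1]
    per <- stat_compute(ts, W, f, mode, wb)$values[, 1]
    expect_equal(sum(per * wlen) / ts$L, whole, tolerance = 1e-12)
  }
  # node mode: same identity per node
  whole_n <- stat_compute(ts, W, f, "node")$values
  per_n <- stat_compute(ts, W, f, "node", wb)$values
  expect_equal(as.numeric(per_n %*% wlen) / ts$L, as.numeric(whole_n),
               tolerance = 1e-12)
})

test_that("allele weights are conserved and handle recurrent/back mutations", {
  # recurrent: T->G above node 5 (samples {0,1}) and above sample 4
  base <- list(sites = data.frame(position = 0.5, ancestral_state = "T"))
  ts_rec <- caterpillar5_ts(
    sites = base$sites,
    mutations = data.frame(site = c(0, 0), node = c(5, 4),
                           derived_state = c("G", "G"), parent = c(-1, -1)))
  W <- indicator_weights(ts_rec, list(0:4))
  aw <- allele_weights(ts_rec, 0, W)
  expect_equal(aw$weights$G, 3)
  expect_equal(aw$weights$T, 2)

  # plus a back mutation G->T above sample 0 (inside the first subtree)
  ts_back <- caterpillar5_ts(
    sites = base$sites,
    mutations = data.frame(site = c(0, 0, 0), node = c(5, 4, 0),
                           derived_state = c("G", "G", "T"),
                           parent = c(-1, -1, 0)))
  aw2 <- allele_weights(ts_back, 0, W)
  expect_equal(aw2$weights$G, 2)
  expect_equal(aw2$weights$T, 3)

  # agreement with the genotype-decoding oracle, and conservation
  for (ts in list(ts_rec, ts_back)) {
    g <- decode_genotypes(ts)
    aw <- allele_weights(ts, 0, W)
    for (a in names(aw$weights))
      expect_equal(aw$weights[[a]], sum(g[1, ] == a))
    expect_equal(Reduce(`+`, aw$weights), W$w_total)
  }
})

test_that("allele weights sum to w_total at every site of random inputs", {
  for (seed in 1:5) {
    n <- 6
    ts <- random_mutated_ts(n, 4, seed = 600 + seed, mu = 1)
    W <- sample_weights(matrix(runif(2 * n), n, 2), ts$samples)
    for (j in seq_len(nrow(ts$sites))) {
      aw <- allele_weights(ts, j - 1L, W)
      expect_equal(Reduce(`+`, aw$weights), W$w_total, tolerance = 1e-12)
    }
  }
})

test_that("removing all edges restores the initial engine state", {
  ts <- random_tree_sequence(7, 6, seed = 31)
  n <- length(ts$samples)
  W <- sample_weights(matrix(runif(n * 2), n, 2), ts$samples)
  f <- strict_product_summary(W$w_total)
  res <- branch_stat(ts, W, f, final_state = TRUE)
  fin <- attr(res, "final_state")
  x0 <- matrix(0, nrow(ts$nodes), 2)
  x0[ts$samples + 1, ] <- W$W
  expect_equal(fin$x, x0, tolerance = 1e-12)
  expect_true(all(fin$parent == -1L))
  expect_true(all(fin$branch_length == 0))
})

test_that("edges leave oldest-first and enter youngest-first at breakpoints", {
  for (seed in 1:6) {
    ts <- random_tree_sequence(6, 5, seed = 700 + seed)
    pt <- ts$nodes$time[ts$edges$parent + 1]
    ins <- ts$insertion; rem <- ts$removal
    for (grp in split(seq_along(ins), ts$edges$left[ins]))
      expect_false(is.unsorted(pt[ins[grp]]))        # youngest first
    for (grp in split(seq_along(rem), ts$edges$right[rem]))
      expect_false(is.unsorted(-pt[rem[grp]]))       # oldest first
  }
})

test_that("several summaries sharing weights are computed in one pass", {
  ts <- random_mutated_ts(8, 4, seed = 55)
  S <- sample_set("all", ts$samples)
  W <- indicator_weights(ts, list(S))
  fs <- list(summary_diversity(S$n), summary_segregating(S$n))
  for (mode in c("site", "branch")) {
    both <- stat_compute(ts, W, fs, mode)
    expect_equal(both$values[, 1],
                 stat_compute(ts, W, fs[[1]], mode)$values[, 1],
                 ignore_attr = TRUE)
    expect_equal(both$values[, 2],
                 stat_compute(ts, W, fs[[2]], mode)$values[, 1],
                 ignore_attr = TRUE)
  }
})

test_that("window breakpoints are validated", {
  ts <- fig_divergence_ts()
  W <- indicator_weights(ts, list(red_set()))
  f <- summary_diversity(3)
  expect_error(branch_stat(ts, W, f, windows = c(0, 0.5, 0.4, 1)),
               "breakpoints")
  expect_error(branch_stat(ts, W, f, windows = c(0.2, 1)), "breakpoints")
})
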