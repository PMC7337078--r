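test_that("named summary functions are strict", {
  checks <- list(
    list(f = summary_diversity(5), wt = 5),
    list(f = summary_segregating(5), wt = 5),
    list(f = summary_divergence(3, 2), wt = c(3, 2)),
    list(f = summary_f4(2, 2, 2, 2), wt = c(2, 2, 2, 2)))
  for (ck in checks) {
    m <- length(ck$wt)
    expect_equal(ck$f$fn(matrix(0, m, 1)), 0)
    expect_equal(ck$f$fn(matrix(ck$wt, m, 1)), 0)
  }
})

test_that("site diversity counts pairwise differences per unit length", {
  # two samples differing at 3 of 10 positions
  ts <- tree_sequence(
    nodes = data.frame(is_sample = c(TRUE, TRUE, FALSE),
                       time = c(0, 0, 1)),
    edges = data.frame(left = 0, right = 10, parent = 2, child = 0:1),
    sites = data.frame(position = c(1, 4, 7),
                       ancestral_state = rep("A", 3)),
    mutations = data.frame(site = 0:2, node = 0, derived_state = "C",
                           parent = -1),
    L = 10)
  S <- sample_set("pair", 0:1)
  expect_equal(diversity(ts, S)$values[1, 1], 3 / 10)
  expect_equal(pairwise_from_genotypes(ts, S), 3 / 10)
})

test_that("divergence reproduces the worked single-site value", {
  ts <- fig_divergence_ts()
  expect_equal(divergence(ts, red_set(), blue_set())$values[1, 1], 1 / 2)
  # symmetric in the two sets
  expect_equal(divergence(ts, blue_set(), red_set())$values[1, 1], 1 / 2)
  # identical haplotypes: zero
  ts0 <- caterpillar5_ts()
  expect_equal(divergence(ts0, sample_set("a", 0:1),
                          sample_set("b", 2:4))$values[1, 1], 0)
  expect_error(divergence(ts, red_set(), sample_set("x", c(2, 3))),
               "disjoint")
})

test_that("segregating sites follow the k - 1 polyallelic rule", {
  all5 <- sample_set("all", 0:4)
  expect_equal(segregating_sites(fig_divergence_ts(),
                                 sample_set("all", 0:4))$values[1, 1], 1)
  expect_equal(segregating_sites(triallelic_ts(), all5)$values[1, 1], 2)
  # monomorphic genome
  expect_equal(segregating_sites(caterpillar5_ts(), all5)$values[1, 1], 0)
  # branch mode on a tree where every branch subtends 0 < x < n samples:
  # every branch contributes f(x) + f(n - x) = 1, so the statistic is the
  # total branch length
  ts <- caterpillar5_ts()
  tr <- trees(ts)[[1]]
  expect_equal(segregating_sites(ts, all5, mode = "branch")$values[1, 1],
               sum(tr$branch_length))
})

test_that("f4 satisfies its antisymmetry identities", {
  ts <- random_mutated_ts(8, 5, seed = 81, mu = 1.2)
  ss <- lapply(1:4, function(i)
    sample_set(paste0("q", i), ts$samples[(2 * i - 1):(2 * i)]))
  for (mode in c("site", "branch")) {
    v <- f4(ts, ss[[1]], ss[[2]], ss[[3]], ss[[4]], mode = mode)$values[1, 1]
    expect_equal(f4(ts, ss[[2]], ss[[1]], ss[[3]], ss[[4]],
                    mode = mode)$values[1, 1], -v)
    expect_equal(f4(ts, ss[[1]], ss[[2]], ss[[4]], ss[[3]],
                    mode = mode)$values[1, 1], -v)
    expect_equal(f4(ts, ss[[3]], ss[[4]], ss[[1]], ss[[2]],
                    mode = mode)$values[1, 1], v)
  }
})

test_that("branch f4 of ((A,C),(B,D)) is the summed internal branch length", {
  ts <- tree_sequence(
    nodes = data.frame(is_sample = c(rep(TRUE, 4), rep(FALSE, 3)),
                       time = c(rep(0, 4), 1, 2, 3)),
    edges = data.frame(left = 0, right = 1,
                       parent = c(4, 4, 5, 5, 6, 6),
                       child = c(0, 2, 1, 3, 4, 5)),
    L = 1)
  sets <- lapply(0:3, function(i) sample_set(paste0("s", i), i))
  v <- f4(ts, sets[[1]], sets[[2]], sets[[3]], sets[[4]],
          mode = "branch")$values[1, 1]
  expect_equal(v, (3 - 1) + (3 - 2))  # the two internal branches
})

test_that("trait correlation equals the squared sample correlation", {
  ts <- fig_divergence_ts()
  # constant phenotype: zero variance
  zc <- setNames(rep(2, 5), 0:4)
  expect_error(trait_correlation(ts, zc), "zero variance")

  # phenotype affine in the genotype indicator: perfect correlation
  g <- decode_genotypes(ts)
  z <- setNames(3 * as.numeric(g[1, ] == "G") - 1, ts$samples)
  expect_equal(trait_correlation(ts, z)$values[1, 1], 1)

  # random phenotype on a random mutated tree sequence, per site
  set.seed(99)
  ts2 <- random_mutated_ts(7, 3, seed = 91, mu = 1)
  z2 <- setNames(rnorm(7), ts2$samples)
  res <- trait_correlation(ts2, z2)
  g2 <- decode_genotypes(ts2)
  r2 <- vapply(seq_len(nrow(ts2$sites)), function(j) {
    ind <- as.numeric(g2[j, ] == "1")
    if (var(ind) == 0) 0 else cor(z2, ind)^2
  }, numeric(1))
  expect_equal(res$values[1, 1], sum(r2) / ts2$L, tolerance = 1e-9)
})

test_that("Tajima's D matches a textbook computation from genotypes", {
  ts <- random_mutated_ts(8, 4, seed = 121, mu = 2)
  S <- sample_set("all", ts$samples)
  wb <- equal_windows(ts$L, 2)
  D <- tajimas_d(ts, S, wb)$values[, 1]
  # independent computation from the decoded genotype matrix
  g <- decode_genotypes(ts)
  pos <- ts$sites$position
  n <- S$n
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  for (w in 1:2) {
    js <- which(pos >= wb[w] & pos < wb[w + 1])
    segs <- 0; pi_tot <- 0
    for (j in js) {
      tab <- table(g[j, ])
      if (length(tab) >= 2) segs <- segs + 1
      het <- 1 - sum((tab / n)^2)
      pi_tot <- pi_tot + het * n / (n - 1)
    }
    expected <- if (segs == 0) NaN else
      (pi_tot - segs / a1) / sqrt(e1 * segs + e2 * segs * (segs - 1))
    expect_equal(D[w], expected, tolerance = 1e-9)
  }
})

test_that("Tajima's D is a missing value where nothing segregates", {
  ts <- caterpillar5_ts()   # no sites at all
  D <- tajimas_d(ts, sample_set("all", 0:4))$values[, 1]
  expect_true(is.nan(D))
})

test_that("ancestry proportions are span-weighted subtree fractions", {
  ts <- caterpillar5_ts()
  S <- sample_set("all", 0:4)
  ap <- ancestry_proportions(ts, S)
  expect_equal(ap$values[9, 1], 1)       # root subtends everyone
  expect_equal(ap$values[1, 1], 1 / 5)   # a leaf carries itself
  # random tree sequence against the per-tree brute force
  ts2 <- random_tree_sequence(5, 4, seed = 17)
  S2 <- sample_set("s", ts2$samples[1:3])
  ap2 <- ancestry_proportions(ts2, S2)$values[, 1]
  trs <- trees(ts2)
  W <- indicator_weights(ts2, list(S2))
  brute <- Reduce(`+`, lapply(trs, function(tr)
    tr$span * subtree_weights_naive(tr, W)[, 1])) / (3 * ts2$L)
  expect_equal(ap2, brute, tolerance = 1e-12)
  # nodes of other trees are never ancestral to this tree's samples
  expect_true(any(ap2 == 0))
})

test_that("diversity stays within [0,1] per base and equals its oracle", {
  # the per-base bound needs discrete sites (at most one site per base)
  for (seed in 1:4) {
    base <- random_tree_sequence(6, 4, seed = 130 + seed, L = 200)
    ts <- drop_mutations(base, mu = 0.01, seed = 230 + seed,
                         discrete = TRUE)
    S <- sample_set("all", ts$samples)
    v <- diversity(ts, S)$values[1, 1]
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(v, pairwise_from_genotypes(ts, S), tolerance = 1e-9)
    h1 <- sample_set("h1", ts$samples[1:3])
    h2 <- sample_set("h2", ts$samples[4:6])
    expect_equal(divergence(ts, h1, h2)$values[1, 1],
                 pairwise_from_genotypes(ts, h1, h2), tolerance = 1e-9)
  }
})
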