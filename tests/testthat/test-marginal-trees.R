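test_that("tree iteration tiles the sequence, including gaps", {
  ts <- tree_sequence(
    nodes = data.frame(is_sample = c(TRUE, FALSE), time = c(0, 1)),
    edges = data.frame(left = 0, right = 1, parent = 1, child = 0), L = 1)
  trs <- trees(ts)
  expect_equal(length(trs), 1)
  expect_equal(trs[[1]]$parent[1], 1)
  expect_equal(trs[[1]]$branch_length[1], 1.0)

  # replacement edge at x = 5: two trees of span 5
  ts2 <- tree_sequence(
    nodes = data.frame(is_sample = c(TRUE, FALSE, FALSE),
                       time = c(0, 1, 2)),
    edges = data.frame(left = c(0, 5), right = c(5, 10),
                       parent = c(1, 2), child = c(0, 0)), L = 10)
  expect_equal(vapply(trees(ts2), function(t) t$span, numeric(1)), c(5, 5))

  # edges covering only [0,3) and [7,10): middle tree is all roots
  ts3 <- tree_sequence(
    nodes = data.frame(is_sample = c(TRUE, TRUE, FALSE),
                       time = c(0, 0, 1)),
    edges = data.frame(left = c(0, 0, 7, 7), right = c(3, 3, 10, 10),
                       parent = 2, child = c(0, 1, 0, 1)), L = 10)
  trs3 <- trees(ts3)
  expect_equal(length(trs3), 3)
  expect_equal(trs3[[2]]$interval, c(3, 7))
  expect_true(all(trs3[[2]]$parent == -1L))
  # brute force: which edges contain x, at sampled points
  for (x in c(0.5, 3.5, 5, 6.9, 8)) {
    k <- findInterval(x, c(0, 3, 7))
    covering <- ts3$edges$left <= x & ts3$edges$right > x
    expect_equal(sum(trs3[[k]]$parent != -1L), sum(covering))
  }
})

test_that("tree spans always sum to the sequence length exactly", {
  for (seed in 1:8) {
    ts <- random_tree_sequence(4, sample(1:7, 1), seed = 100 + seed)
    expect_equal(sum(vapply(trees(ts), function(t) t$span, numeric(1))),
                 ts$L)
  }
})

test_that("naive subtree weights sum sample weights along root paths", {
  ts <- fig_divergence_ts()
  W <- sample_weights(matrix(c(2, 3, 5, 7, 11), 5, 1), samples = 0:4)
  x <- subtree_weights_naive(trees(ts)[[1]], W)
  expect_equal(x[1, 1], 2)                 # a leaf carries its own weight
  expect_equal(x[7, 1], 2 + 3 + 5 + 7 + 11) # root = w_total
  expect_equal(x[6, 1], 2 + 3 + 7)         # node 5 subtends {0,1,3}

  # worked single-site example: node under the mutation has (red, blue)
  # counts (2, 1)
  Wrb <- indicator_weights(ts, list(red_set(), blue_set()))
  xrb <- subtree_weights_naive(trees(ts)[[1]], Wrb)
  expect_equal(xrb[6, ], c(2, 1))
})

test_that("indicator subtree weights equal direct leaf counts", {
  for (seed in 1:6) {
    ts <- random_tree_sequence(6, 3, seed = 200 + seed)
    W <- indicator_weights(ts, list(ts$samples))
    for (tr in trees(ts)) {
      x <- subtree_weights_naive(tr, W)
      # direct count: samples whose root path passes through u
      for (u in seq_along(tr$parent)) {
        cnt <- 0
        for (v in ts$samples) {
          p <- v + 1L
          repeat {
            if (p == u) { cnt <- cnt + 1; break }
            if (tr$parent[p] == -1L) break
            p <- tr$parent[p] + 1L
          }
        }
        expect_equal(x[u, 1], cnt)
      }
    }
  }
})

test_that("genotype decoding follows nearest mutation above each sample", {
  # no mutations: everyone ancestral
  ts0 <- caterpillar5_ts(sites = data.frame(position = 0.5,
                                            ancestral_state = "A"))
  expect_true(all(decode_genotypes(ts0) == "A"))

  # single mutation above an internal node: exactly its subtree is derived
  ts1 <- fig_divergence_ts()
  g <- decode_genotypes(ts1)
  expect_equal(unname(g[1, ]), c("G", "G", "T", "G", "T"))

  # back mutation: A->G on node 7 ({0,1,2,3}), G->A on node 5 ({0,1})
  ts2 <- caterpillar5_ts(
    sites = data.frame(position = 0.5, ancestral_state = "A"),
    mutations = data.frame(site = c(0, 0), node = c(7, 5),
                           derived_state = c("G", "A"), parent = c(-1, 0)))
  g2 <- decode_genotypes(ts2)
  expect_equal(unname(g2[1, ]), c("A", "A", "G", "G", "A"))
})

test_that("one mutation per site means derived = samples below the node", {
  for (seed in 1:5) {
    ts <- random_mutated_ts(5, 3, seed = 300 + seed, mu = 0.8)
    if (nrow(ts$sites) == 0) next
    g <- decode_genotypes(ts)
    trs <- trees(ts)
    lefts <- vapply(trs, function(t) t$interval[1], numeric(1))
    for (j in seq_len(nrow(ts$sites))) {
      tr <- trs[[findInterval(ts$sites$position[j], lefts)]]
      mnode <- ts$mutations$node[ts$mutations$site == j - 1]
      below <- vapply(ts$samples, function(v) {
        p <- v
        while (p != -1L) {
          if (p == mnode) return(TRUE)
          p <- tr$parent[p + 1L]
        }
        FALSE
      }, logical(1))
      expect_equal(unname(g[j, ] == "1"), below)
    }
  }
})
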