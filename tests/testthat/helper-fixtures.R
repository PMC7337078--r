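# Fixtures built in code.

# Five-leaf tree with red samples {0,1,2} (triangles) and blue {3,4}
# (squares); node 5 subtends two red samples and one blue; a single T->G
# mutation sits on the branch above node 5.
fig_divergence_ts <- function() {
  tree_sequence(
    nodes = data.frame(is_sample = c(rep(TRUE, 5), FALSE, FALSE),
                       time = c(rep(0, 5), 1, 2)),
    edges = data.frame(left = 0, right = 1,
                       parent = c(5, 5, 5, 6, 6, 6),
                       child = c(0, 1, 3, 2, 4, 5)),
    sites = data.frame(position = 0.5, ancestral_state = "T"),
    mutations = data.frame(site = 0, node = 5, derived_state = "G",
                           parent = -1),
    L = 1)
}

red_set <- function() sample_set("red", 0:2)
blue_set <- function() sample_set("blue", 3:4)

# Same topology, one site with ancestral A and two derived alleles: C above
# node 5 and T above sample 2 (triallelic among the five samples).
triallelic_ts <- function() {
  tree_sequence(
    nodes = data.frame(is_sample = c(rep(TRUE, 5), FALSE, FALSE),
                       time = c(rep(0, 5), 1, 2)),
    edges = data.frame(left = 0, right = 1,
                       parent = c(5, 5, 5, 6, 6, 6),
                       child = c(0, 1, 3, 2, 4, 5)),
    sites = data.frame(position = 0.25, ancestral_state = "A"),
    mutations = data.frame(site = c(0, 0), node = c(5, 2),
                           derived_state = c("C", "T"), parent = c(-1, -1)),
    L = 1)
}

# Balanced five-sample tree used for recurrent/back-mutation cases:
# cherries (0,1) under node 5 and (2,3) under node 6; 7 = (5, 6); root
# 8 = (7, 4).
caterpillar5_ts <- function(sites = NULL, mutations = NULL) {
  tree_sequence(
    nodes = data.frame(is_sample = c(rep(TRUE, 5), rep(FALSE, 4)),
                       time = c(rep(0, 5), 1, 1.5, 2, 3)),
    edges = data.frame(left = 0, right = 1,
                       parent = c(5, 5, 6, 6, 7, 7, 8, 8),
                       child = c(0, 1, 2, 3, 5, 6, 7, 4)),
    sites = sites, mutations = mutations, L = 1)
}

# Random mutated tree sequence for property tests.
random_mutated_ts <- function(n, num_trees, seed, mu = 1) {
  ts <- random_tree_sequence(n, num_trees, seed = seed)
  drop_mutations(ts, mu = mu, seed = seed + 7919L)
}

# A strict product summary for arbitrary weight dimension m, relative to a
# total-weight vector wt: f(x) = prod_i x_i (wt_i - x_i).
strict_product_summary <- function(wt) {
  summary_function(function(M) apply(M * (wt - M), 2, prod),
                   m = length(wt), strict = TRUE, name = "product")
}

expect_stat_equal <- function(a, b, tol = 1e-9) {
  expect_equal(dim(a$values), dim(b$values))
  expect_lt(max(abs(a$values - b$values) / pmax(1e-12, abs(b$values))), tol)
}
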