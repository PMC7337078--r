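#' Marginal trees of a tree sequence
#'
#' Replays the edge insertion/removal indexes left to right and returns the
#' sequence of marginal trees.  Each tree covers a half-open interval; the
#' intervals tile \code{[0, L)} exactly.  Regions spanned by no edges yield
#' a tree in which every node is a root (a "gap" tree), so windowed
#' statistics over gaps are well defined.
#'
#' @param ts a \code{\link{tree_sequence}}.
#' @return list of \code{marginal_tree} objects, each a list with fields
#'   \code{interval} (length-2 numeric), \code{parent} (integer vector over
#'   nodes, 0-based ids, -1 = root), \code{branch_length} (numeric vector,
#'   0 at roots) and \code{span}.
#' @export
trees <- function(ts) {
  N <- nrow(ts$nodes)
  E <- nrow(ts$edges)
  e <- ts$edges
  nt <- ts$nodes$time
  P <- rep(-1L, N)
  out <- list()
  j <- 1L; k <- 1L; tl <- 0
  repeat {
    while (k <= E && e$right[ts$removal[k]] == tl) {
      u <- e$child[ts$removal[k]] + 1L
      k <- k + 1L
      P[u] <- -1L
    }
    while (j <= E && e$left[ts$insertion[j]] == tl) {
      r <- ts$insertion[j]
      u <- e$child[r] + 1L
      j <- j + 1L
      if (P[u] != -1L)
        stopf("corrupt indexes: node %d assigned two parents at %g",
              u - 1L, tl)
      P[u] <- e$parent[r]
    }
    tr <- ts$L
    if (j <= E) tr <- min(tr, e$left[ts$insertion[j]])
    if (k <= E) tr <- min(tr, e$right[ts$removal[k]])
    B <- numeric(N)
    has_par <- P != -1L
    B[has_par] <- nt[P[has_par] + 1L] - nt[has_par]
    out[[length(out) + 1L]] <- structure(
      list(interval = c(tl, tr), parent = P, branch_length = B,
           span = tr - tl),
      class = "marginal_tree")
    tl <- tr
    if (tl >= ts$L) break
  }
  out
}

#' Subtree weights by independent per-sample traversal
#'
#' The reference ("naive") computation of subtree weights: for every sample
#' \code{v}, its weight vector is added to every node on the path from
#' \code{v} to its root, including \code{v} itself.  This is the oracle used
#' to check the incremental engine; it never shares state with it.
#'
#' @param tree a \code{marginal_tree} from \code{\link{trees}}.
#' @param W a \code{\link{sample_weights}} object.
#' @return numeric matrix, one row per node, one column per weight
#'   dimension.
#' @export
subtree_weights_naive <- function(tree, W) {
  N <- length(tree$parent)
  x <- matrix(0, N, W$m)
  for (i in seq_along(W$samples)) {
    u <- W$samples[i] + 1L
    wv <- W$W[i, ]
    while (u != 0L) {
      x[u, ] <- x[u, ] + wv
      u <- tree$parent[u] + 1L
    }
  }
  x
}

#' Decode per-sample genotypes from sites and mutations
#'
#' The allele carried by sample \code{v} at site \code{j} is the derived
#' state of the mutation at site \code{j} whose node is nearest above (or
#' at) \code{v} on the path to the root of the tree covering the site's
#' position; if there is no such mutation the site's ancestral state.  When
#' several mutations at one site sit on the same node, the latest table row
#' (parents precede children) is nearest the sample.  Handles recurrent and
#' back mutations.
#'
#' @param ts a \code{\link{tree_sequence}}.
#' @return character matrix of alleles, sites x samples, with the site
#'   positions in attribute \code{positions} and sample ids in
#'   \code{colnames} (as \code{s<id>}).
#' @export
decode_genotypes <- function(ts) {
  S <- nrow(ts$sites)
  samp <- ts$samples
  G <- matrix(character(0), nrow = S, ncol = length(samp))
  colnames(G) <- paste0("s", samp)
  if (S == 0) {
    attr(G, "positions") <- numeric(0)
    return(G)
  }
  trs <- trees(ts)
  lefts <- vapply(trs, function(t) t$interval[1], numeric(1))
  tree_of_site <- findInterval(ts$sites$position, lefts)
  mut_rows <- split(seq_len(nrow(ts$mutations)), ts$mutations$site)
  for (j in seq_len(S)) {
    anc <- ts$sites$ancestral_state[j]
    rows <- mut_rows[[as.character(j - 1L)]]
    if (is.null(rows)) {
      G[j, ] <- anc
      next
    }
    if (any(ts$mutations$node[rows] >= nrow(ts$nodes)))
      stopf("site %d: mutation node out of range", j - 1L)
    P <- trs[[tree_of_site[j]]]$parent
    # last-listed mutation per node wins (nearest the sample)
    node_allele <- new.env(parent = emptyenv())
    for (r in rows)
      assign(as.character(ts$mutations$node[r]),
             ts$mutations$derived_state[r], envir = node_allele)
    for (i in seq_along(samp)) {
      u <- samp[i]
      allele <- anc
      while (u != -1L) {
        key <- as.character(u)
        if (!is.null(node_allele[[key]])) {
          allele <- node_allele[[key]]
          break
        }
        u <- P[u + 1L]
      }
      G[j, i] <- allele
    }
  }
  attr(G, "positions") <- ts$sites$position
  G
}
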