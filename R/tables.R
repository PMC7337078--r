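#' Construct a tree sequence from its four tables
#'
#' A succinct tree sequence encodes the correlated genealogies of a set of
#' sample genomes along a recombining chromosome through four tables: nodes
#' (haplotypes, ancient and modern), edges (parent--child relationships over
#' half-open genomic intervals), sites (positions with an ancestral allele)
#' and mutations (allele changes on a node at a site).  Node, site and
#' mutation ids are implicit 0-based row numbers; \code{-1} is the null id.
#'
#' The constructor validates every table invariant (see
#' \code{\link{validate_tree_sequence}}) and builds the edge insertion and
#' removal index vectors that drive marginal-tree iteration: edges sorted by
#' left endpoint with parents appearing later the closer they are to the
#' root (insertion), and by right endpoint with parents closer to the root
#' appearing sooner (removal).
#'
#' @param nodes data.frame with columns \code{is_sample} (logical),
#'   \code{time} (numeric, generations before present, >= 0) and optionally
#'   \code{population} (integer, -1 = unspecified).
#' @param edges data.frame with columns \code{left}, \code{right} (real
#'   positions, \code{0 <= left < right <= L}), \code{parent}, \code{child}
#'   (0-based node ids).
#' @param sites data.frame with columns \code{position} (real in
#'   \code{[0, L)}, strictly increasing) and \code{ancestral_state}
#'   (arbitrary non-empty allele label).
#' @param mutations data.frame with columns \code{site}, \code{node}
#'   (0-based ids), \code{derived_state} and \code{parent} (mutation id at
#'   the same site, or -1).
#' @param L sequence length (real > 0).
#' @return An object of class \code{tree_sequence}.
#' @examples
#' ts <- tree_sequence(
#'   nodes = data.frame(is_sample = c(TRUE, TRUE, FALSE),
#'                      time = c(0, 0, 1)),
#'   edges = data.frame(left = 0, right = 1, parent = 2, child = 0:1),
#'   L = 1)
#' ts
#' @export
tree_sequence <- function(nodes, edges = NULL, sites = NULL,
                          mutations = NULL, L) {
  nodes <- as_node_table(nodes)
  edges <- as_edge_table(edges)
  sites <- as_site_table(sites)
  mutations <- as_mutation_table(mutations)
  if (!(length(L) == 1 && is.numeric(L) && is.finite(L) && L > 0))
    stopf("sequence length L must be a single finite real > 0")
  ts <- structure(list(
    L = as.numeric(L),
    nodes = nodes, edges = edges, sites = sites, mutations = mutations,
    samples = which(nodes$is_sample) - 1L,
    insertion = integer(0), removal = integer(0)
  ), class = "tree_sequence")
  bad <- validate_tree_sequence(ts)
  if (length(bad) > 0)
    stopf("invalid tree sequence:\n%s", paste(" -", bad, collapse = "\n"))
  idx <- build_edge_indexes(ts$edges, ts$nodes$time)
  ts$insertion <- idx$insertion
  ts$removal <- idx$removal
  ts
}

as_node_table <- function(x) {
  if (is.null(x)) x <- data.frame(is_sample = logical(0), time = numeric(0))
  x <- as.data.frame(x)
  need <- c("is_sample", "time")
  if (!all(need %in% names(x)))
    stopf("node table needs columns %s", paste(need, collapse = ", "))
  if (is.null(x$population)) x$population <- rep(-1L, nrow(x))
  data.frame(is_sample = as.logical(x$is_sample),
             time = as.numeric(x$time),
             population = as.integer(x$population))
}

as_edge_table <- function(x) {
  if (is.null(x))
    x <- data.frame(left = numeric(0), right = numeric(0),
                    parent = integer(0), child = integer(0))
  x <- as.data.frame(x)
  need <- c("left", "right", "parent", "child")
  if (!all(need %in% names(x)))
    stopf("edge table needs columns %s", paste(need, collapse = ", "))
  data.frame(left = as.numeric(x$left), right = as.numeric(x$right),
             parent = as.integer(x$parent), child = as.integer(x$child))
}

as_site_table <- function(x) {
  if (is.null(x))
    x <- data.frame(position = numeric(0), ancestral_state = character(0))
  x <- as.data.frame(x)
  need <- c("position", "ancestral_state")
  if (!all(need %in% names(x)))
    stopf("site table needs columns %s", paste(need, collapse = ", "))
  data.frame(position = as.numeric(x$position),
             ancestral_state = as.character(x$ancestral_state))
}

as_mutation_table <- function(x) {
  if (is.null(x))
    x <- data.frame(site = integer(0), node = integer(0),
                    derived_state = character(0), parent = integer(0))
  x <- as.data.frame(x)
  need <- c("site", "node", "derived_state")
  if (!all(need %in% names(x)))
    stopf("mutation table needs columns %s", paste(need, collapse = ", "))
  if (is.null(x$parent)) x$parent <- rep(-1L, nrow(x))
  data.frame(site = as.integer(x$site), node = as.integer(x$node),
             derived_state = as.character(x$derived_state),
             parent = as.integer(x$parent))
}

#' Validate a tree sequence against its table invariants
#'
#' Checks every invariant of the table data model and returns a character
#' vector of human-readable violations (empty when the tree sequence is
#' valid).  Each violation names the table, the offending row (0-based, as
#' ids are) and the rule.  Nothing is raised; use \code{\link{tree_sequence}}
#' if you want violations to be errors.
#'
#' @param ts a \code{tree_sequence} (or a structurally equivalent list).
#' @return character vector of violation descriptions, empty if valid.
#' @export
validate_tree_sequence <- function(ts) {
  v <- character(0)
  say <- function(fmt, ...) v[[length(v) + 1]] <<- sprintf(fmt, ...)
  N <- nrow(ts$nodes); E <- nrow(ts$edges)
  L <- ts$L
  nt <- ts$nodes$time

  bad <- which(!is.finite(nt) | nt < 0)
  for (r in bad) say("nodes row %d: time must be finite and >= 0", r - 1L)
  if (N > 0 && !any(ts$nodes$is_sample))
    say("nodes: at least one node must be a sample")
  bad <- which(ts$nodes$population < -1L)
  for (r in bad) say("nodes row %d: population must be >= -1", r - 1L)

  e <- ts$edges
  for (r in seq_len(E)) {
    if (!(e$left[r] >= 0 && e$left[r] < e$right[r] && e$right[r] <= L))
      say("edges row %d: left < right violated or interval outside [0, L]",
          r - 1L)
    if (e$parent[r] < 0 || e$parent[r] >= N || e$child[r] < 0 ||
        e$child[r] >= N) {
      say("edges row %d: parent/child node id out of range", r - 1L)
      next
    }
    if (!(nt[e$parent[r] + 1L] > nt[e$child[r] + 1L]))
      say("edges row %d: parent must be older than child", r - 1L)
  }
  # per-child parent intervals must not overlap
  if (E > 1) {
    ord <- order(e$child, e$left)
    for (i in seq_len(E - 1)) {
      a <- ord[i]; b <- ord[i + 1]
      if (e$child[a] == e$child[b] && e$right[a] > e$left[b])
        say("edges row %d: overlapping parent intervals for child %d",
            b - 1L, e$child[b])
    }
  }

  s <- ts$sites
  for (r in seq_len(nrow(s))) {
    if (!(s$position[r] >= 0 && s$position[r] < L))
      say("sites row %d: position outside [0, L)", r - 1L)
    if (!nzchar(s$ancestral_state[r]))
      say("sites row %d: empty ancestral state", r - 1L)
  }
  if (nrow(s) > 1 && any(diff(s$position) <= 0))
    say("sites: positions must be strictly increasing")

  m <- ts$mutations
  for (r in seq_len(nrow(m))) {
    if (m$site[r] < 0 || m$site[r] >= nrow(s)) {
      say("mutations row %d: site id out of range", r - 1L)
      next
    }
    if (m$node[r] < 0 || m$node[r] >= N)
      say("mutations row %d: node id out of range", r - 1L)
    if (!nzchar(m$derived_state[r]))
      say("mutations row %d: empty derived state", r - 1L)
    p <- m$parent[r]
    if (p < -1L || p >= nrow(m))
      say("mutations row %d: parent mutation id out of range", r - 1L)
    else if (p >= 0) {
      if (p >= r - 1L)
        say("mutations row %d: parent mutation must precede it", r - 1L)
      else if (m$site[p + 1L] != m$site[r])
        say("mutations row %d: parent mutation at a different site", r - 1L)
    }
  }
  # rows for the same site must be contiguous
  if (nrow(m) > 1) {
    runs <- rle(m$site)$values
    if (anyDuplicated(runs))
      say("mutations: rows for the same site must be contiguous")
  }
  v
}

#' Build the edge insertion and removal index vectors
#'
#' The insertion index orders edges by (left ascending, parent time
#' ascending, parent id, child id): edges closer to the root appear later,
#' so subtrees are connected youngest-first.  The removal index orders edges
#' by (right ascending, parent time descending, parent id descending, child
#' id descending): edges closer to the root appear sooner, so subtrees are
#' disconnected oldest-first.  Ties beyond parent time are broken by ids so
#' the orderings are deterministic.
#'
#' @param edges an edge table (see \code{\link{tree_sequence}}).
#' @param node_time numeric vector of node times indexed by node id + 1.
#' @return list with integer components \code{insertion} and \code{removal},
#'   both 1-based permutations of the edge rows.
#' @export
build_edge_indexes <- function(edges, node_time) {
  if (nrow(edges) == 0)
    return(list(insertion = integer(0), removal = integer(0)))
  pt <- node_time[edges$parent + 1L]
  ins <- order(edges$left, pt, edges$parent, edges$child)
  rem <- order(edges$right, -pt, -edges$parent, -edges$child)
  list(insertion = as.integer(ins), removal = as.integer(rem))
}

#' @export
print.tree_sequence <- function(x, ...) {
  cat(sprintf(
    "tree_sequence: L = %g, %d nodes (%d samples), %d edges, %d sites, %d mutations\n",
    x$L, nrow(x$nodes), length(x$samples), nrow(x$edges),
    nrow(x$sites), nrow(x$mutations)))
  invisible(x)
}
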