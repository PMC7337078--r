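# Coalescent simulators and stress-test generators.  Times are in
# generations throughout (pairwise coalescence rate 1/(2*Ne) for diploid
# population size Ne); the single-population simulator is a Hudson
# ancestral-recombination-graph simulation holding ancestral segments per
# lineage.

#' Demography for the structured coalescent
#'
#' Populations with diploid sizes, per-population sample counts at time 0,
#' an initial backward migration-rate matrix, and a backward-time event
#' list (\code{merge}: all lineages of population \code{a} move into
#' \code{b}; \code{migration_on}/\code{migration_off}: switch symmetric
#' migration between \code{a} and \code{b}).
#'
#' @param populations data.frame with columns \code{id} (1-based) and
#'   \code{size} (diploid).
#' @param sample_counts integer vector, samples per population id.
#' @param migration initial square matrix of per-lineage backward migration
#'   rates (row = source population of the lineage).
#' @param events data.frame with columns \code{time}, \code{type},
#'   \code{a}, \code{b}, \code{rate} (rate used by \code{migration_on}).
#' @return object of class \code{demography}.
#' @export
demography <- function(populations, sample_counts, migration = NULL,
                       events = NULL) {
  populations <- as.data.frame(populations)
  P <- max(populations$id)
  if (is.null(migration)) migration <- matrix(0, P, P)
  if (is.null(events))
    events <- data.frame(time = numeric(0), type = character(0),
                         a = integer(0), b = integer(0), rate = numeric(0))
  events <- as.data.frame(events)
  if (nrow(events) > 1 && any(diff(events$time) < 0))
    stopf("demography: event times must be non-decreasing")
  if (length(sample_counts) < P)
    sample_counts <- c(sample_counts, rep(0L, P - length(sample_counts)))
  structure(list(populations = populations,
                 sample_counts = as.integer(sample_counts),
                 migration = migration, events = events),
            class = "demography")
}

#' The four-population split-and-migration admixture demography
#'
#' Forward in time: population 1 of diploid size N splits off population 2;
#' N generations later population 3 splits from population 2; after another
#' N generations population 4 splits from population 3; and for the final N
#' generations before sampling, populations 2 and 3 exchange migrants at
#' per-capita rate 4/N each way.  Gene flow between the middle populations
#' makes Patterson's f4(1,2;3,4) negative.
#'
#' @param N diploid population size (all four populations).
#' @param samples_per_pop haploid samples drawn from each population at
#'   time 0.
#' @return a \code{\link{demography}}.
#' @export
f4_admixture_demography <- function(N = 1000, samples_per_pop = 2) {
  M <- matrix(0, 4, 4)
  M[2, 3] <- M[3, 2] <- 4 / N
  demography(
    populations = data.frame(id = 1:4, size = N),
    sample_counts = rep(samples_per_pop, 4),
    migration = M,
    events = data.frame(
      time = c(N, N, 2 * N, 3 * N),
      type = c("migration_off", "merge", "merge", "merge"),
      a = c(2L, 4L, 3L, 2L),
      b = c(3L, 3L, 2L, 1L),
      rate = NA_real_))
}

#' Single-population coalescent with recombination
#'
#' Hudson's ancestral-recombination-graph simulation: each lineage carries
#' its set of ancestral genome segments; recombination (rate \code{r} per
#' base per generation, acting on the span between a lineage's outermost
#' ancestral material) splits a lineage at a uniform breakpoint; common
#' ancestor events (pair rate \code{1/(2*Ne)}) merge segment sets, emitting
#' an edge wherever the two lineages overlap.  Segments are retired once
#' fully coalesced; output edges are squashed.  With \code{r = 0} the
#' result is a single tree.
#'
#' @param n number of (haploid) samples, 2..200.
#' @param Ne diploid effective population size.
#' @param L sequence length.
#' @param r per-base per-generation recombination rate.
#' @param seed integer seed.
#' @return a \code{\link{tree_sequence}} with no sites.
#' @export
sim_single_pop <- function(n, Ne, L, r = 0, seed = NULL) {
  stopifnot(n >= 2, Ne > 0, L > 0, r >= 0)
  if (n > 200) stopf("scale guard exceeded: n must be <= 200")
  est_rec <- 4 * Ne * r * L * sum(1 / seq_len(n - 1))
  if (est_rec > 5000)
    stopf("scale guard exceeded: ~%d expected recombinations (max 5000)",
          round(est_rec))
  with_seed(seed, {
    lin <- lapply(seq_len(n) - 1L,
                  function(i) data.frame(left = 0, right = L, node = i))
    node_time <- rep(0, n)
    edges <- vector("list", 0)
    t <- 0
    while (length(lin) >= 2) {
      k <- length(lin)
      spans <- vapply(lin, function(s) max(s$right) - min(s$left),
                      numeric(1))
      rr <- r * sum(spans)
      cr <- k * (k - 1) / 2 / (2 * Ne)
      t <- t + stats::rexp(1, rr + cr)
      if (stats::runif(1) < rr / (rr + cr)) {
        li <- sample.int(k, 1, prob = spans)
        segs <- lin[[li]]
        bp <- stats::runif(1, min(segs$left), max(segs$right))
        lp <- segs[segs$left < bp, , drop = FALSE]
        lp$right <- pmin(lp$right, bp)
        rp <- segs[segs$right > bp, , drop = FALSE]
        rp$left <- pmax(rp$left, bp)
        if (nrow(lp) > 0 && nrow(rp) > 0) {
          lin[[li]] <- lp
          lin[[k + 1L]] <- rp
        }
      } else {
        pair <- sample.int(k, 2)
        A <- lin[[pair[1]]]; B <- lin[[pair[2]]]
        others <- lin[-pair]
        # elementary intervals w.r.t. every lineage's breakpoints, so that
        # full coalescence is detected exactly
        lo_all <- min(A$left, B$left); hi_all <- max(A$right, B$right)
        bps <- sort(unique(c(A$left, A$right, B$left, B$right,
                             unlist(lapply(others, function(s)
                               c(s$left, s$right))))))
        bps <- bps[bps >= lo_all & bps <= hi_all]
        u <- NA_integer_
        merged <- vector("list", length(bps) - 1L)
        for (ii in seq_len(length(bps) - 1L)) {
          lo <- bps[ii]; hi <- bps[ii + 1L]
          na <- A$node[A$left <= lo & A$right >= hi]
          nb <- B$node[B$left <= lo & B$right >= hi]
          if (length(na) + length(nb) == 0) next
          if (length(na) == 1 && length(nb) == 1) {
            if (is.na(u)) {
              u <- length(node_time)      # 0-based id of the new node
              node_time <- c(node_time, t)
            }
            edges[[length(edges) + 1L]] <-
              data.frame(left = lo, right = hi, parent = u,
                         child = c(na, nb))
            n_other <- sum(vapply(others, function(s)
              any(s$left <= lo & s$right >= hi), logical(1)))
            if (n_other > 0)
              merged[[ii]] <- data.frame(left = lo, right = hi, node = u)
          } else {
            merged[[ii]] <- data.frame(left = lo, right = hi,
                                       node = c(na, nb))
          }
        }
        merged <- do.call(rbind, merged)
        lin <- others
        if (!is.null(merged) && nrow(merged) > 0)
          lin[[length(lin) + 1L]] <- merged
      }
    }
    e <- do.call(rbind, edges)
    e <- squash_edges(e)
    nn <- length(node_time)
    tree_sequence(
      nodes = data.frame(is_sample = seq_len(nn) <= n, time = node_time,
                         population = 0L),
      edges = e, L = L)
  })
}

# Merge adjacent edge fragments with the same parent and child.
squash_edges <- function(e) {
  if (is.null(e) || nrow(e) <= 1) return(e)
  e <- e[order(e$parent, e$child, e$left), , drop = FALSE]
  keep <- rep(TRUE, nrow(e))
  for (i in 2:nrow(e)) {
    j <- max(which(keep[1:(i - 1)]))
    if (e$parent[i] == e$parent[j] && e$child[i] == e$child[j] &&
        e$left[i] == e$right[j]) {
      e$right[j] <- e$right[i]
      keep[i] <- FALSE
    }
  }
  rownames(e) <- NULL
  e[keep, , drop = FALSE]
}

#' Structured coalescent over independent loci
#'
#' Simulates \code{loci} statistically independent genealogies of equal
#' span under a structured coalescent with migration and population
#' mergers, and assembles them into one tree sequence (shared sample nodes,
#' per-locus internal nodes).  Used for expectation-level reproduction of
#' multi-population statistics, trading linkage structure for desk-scale
#' runtime.
#'
#' @param demog a \code{\link{demography}}.
#' @param loci number of independent loci (>= 1).
#' @param locus_span genomic span of each locus.
#' @param seed integer seed.
#' @return a \code{\link{tree_sequence}} with \code{L = loci * locus_span};
#'   samples are grouped by population in id order (see
#'   \code{\link{population_sample_sets}}).
#' @export
sim_structured <- function(demog, loci, locus_span = 1, seed = NULL) {
  stopifnot(inherits(demog, "demography"), loci >= 1, locus_span > 0)
  sc <- demog$sample_counts
  ntot <- sum(sc)
  if (ntot < 2) stopf("need at least two samples in total")
  sample_pop <- rep(seq_along(sc), sc)
  sizes <- numeric(max(demog$populations$id))
  sizes[demog$populations$id] <- demog$populations$size
  with_seed(seed, {
    max_nodes <- ntot + loci * (ntot - 1L)
    node_time <- numeric(max_nodes)
    node_pop <- integer(max_nodes)
    node_pop[seq_len(ntot)] <- sample_pop
    nn <- ntot                      # nodes allocated so far
    max_edges <- 2L * loci * (ntot - 1L)
    el <- numeric(max_edges); er <- numeric(max_edges)
    ep <- integer(max_edges); ec <- integer(max_edges)
    ne <- 0L
    for (lc in seq_len(loci)) {
      left <- (lc - 1) * locus_span
      right <- lc * locus_span
      lin_node <- seq_len(ntot) - 1L
      lin_pop <- sample_pop
      M <- demog$migration
      ev <- demog$events
      ei <- 1L
      t <- 0
      guard <- 0L
      while (length(lin_node) > 1) {
        guard <- guard + 1L
        if (guard > 1e6) stopf("non-coalescing demography (timeout guard)")
        kpop <- tabulate(lin_pop, nbins = length(sizes))
        crates <- kpop * (kpop - 1) / 2 / (2 * sizes)
        mrates <- (kpop %o% rep(1, ncol(M))) * M   # lineage-count weighted
        tot <- sum(crates) + sum(mrates)
        if (tot == 0) {
          if (ei > nrow(ev))
            stopf("non-coalescing demography: no rates and no events left")
          t <- ev$time[ei]
        } else {
          dt <- stats::rexp(1, tot)
          if (ei <= nrow(ev) && t + dt >= ev$time[ei]) {
            t <- ev$time[ei]
          } else {
            t <- t + dt
            pick <- stats::runif(1, 0, tot)
            if (pick <= sum(crates)) {
              pop <- which(cumsum(crates) >= pick)[1]
              idx <- which(lin_pop == pop)
              ch <- sample(idx, 2)
              u <- nn                 # 0-based id of the new node
              nn <- nn + 1L
              node_time[u + 1L] <- t
              node_pop[u + 1L] <- pop
              el[ne + 1:2] <- left; er[ne + 1:2] <- right
              ep[ne + 1:2] <- u; ec[ne + 1:2] <- lin_node[ch]
              ne <- ne + 2L
              lin_node <- c(lin_node[-ch], u)
              lin_pop <- c(lin_pop[-ch], pop)
            } else {
              pick <- pick - sum(crates)
              ij <- which(cumsum(t(mrates)) >= pick)[1] - 1L
              from <- ij %/% ncol(M) + 1L
              to <- ij %% ncol(M) + 1L
              cand <- which(lin_pop == from)
              lin_pop[cand[sample.int(length(cand), 1)]] <- to
            }
            next
          }
        }
        # apply all scheduled events at time t
        while (ei <= nrow(ev) && ev$time[ei] <= t) {
          a <- ev$a[ei]; b <- ev$b[ei]
          switch(ev$type[ei],
            merge = {
              lin_pop[lin_pop == a] <- b
              M[a, ] <- 0; M[, a] <- 0
            },
            migration_on = {
              M[a, b] <- M[b, a] <- ev$rate[ei]
            },
            migration_off = {
              M[a, b] <- M[b, a] <- 0
            },
            stopf("unknown demographic event type '%s'", ev$type[ei]))
          ei <- ei + 1L
        }
      }
    }
    tree_sequence(
      nodes = data.frame(is_sample = seq_len(nn) <= ntot,
                         time = node_time[seq_len(nn)],
                         population = node_pop[seq_len(nn)]),
      edges = data.frame(left = el[seq_len(ne)], right = er[seq_len(ne)],
                         parent = ep[seq_len(ne)], child = ec[seq_len(ne)]),
      L = loci * locus_span)
  })
}

#' Sample sets of a structured simulation, one per population
#'
#' @param ts a \code{tree_sequence} whose sample nodes carry population
#'   ids.
#' @return named list of \code{\link{sample_set}}s, one per population
#'   present among the samples.
#' @export
population_sample_sets <- function(ts) {
  pops <- ts$nodes$population[ts$samples + 1L]
  out <- list()
  for (p in sort(unique(pops)))
    out[[paste0("pop", p)]] <- sample_set(paste0("pop", p),
                                          ts$samples[pops == p])
  out
}

#' Random tree sequences for engine stress tests
#'
#' Draws \code{num_trees} independent random genealogies (standard
#' coalescent merge order with occasional multifurcations) over random
#' breakpoints.  Every output passes validation and every sample has a path
#' to a root in every tree.
#'
#' @param n number of samples (>= 2).
#' @param num_trees number of marginal trees (>= 1).
#' @param seed integer seed.
#' @param L sequence length (default \code{num_trees}).
#' @return a \code{\link{tree_sequence}} with no sites.
#' @export
random_tree_sequence <- function(n, num_trees, seed = NULL, L = num_trees) {
  stopifnot(n >= 2, num_trees >= 1, L > 0)
  with_seed(seed, {
    repeat {
      bk <- c(0, sort(stats::runif(num_trees - 1, 0, L)), L)
      if (!any(diff(bk) == 0)) break
    }
    node_time <- rep(0, n)
    edges <- vector("list", 0)
    for (k in seq_len(num_trees)) {
      active <- seq_len(n) - 1L
      t <- 0
      while (length(active) > 1) {
        t <- t + stats::rexp(1)
        nm <- if (length(active) >= 3 && stats::runif(1) < 0.2) 3L else 2L
        ch <- sample(active, nm)
        u <- length(node_time)
        node_time <- c(node_time, t)
        edges[[length(edges) + 1L]] <-
          data.frame(left = bk[k], right = bk[k + 1], parent = u,
                     child = ch)
        active <- c(setdiff(active, ch), u)
      }
    }
    e <- do.call(rbind, edges)
    tree_sequence(
      nodes = data.frame(is_sample = seq_along(node_time) <= n,
                         time = node_time, population = -1L),
      edges = e, L = L)
  })
}
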