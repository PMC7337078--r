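# The incremental statistics engine: maintains subtree weights x, the
# per-node summary caches F (and the complementary cache for unpolarized
# statistics) and the running sum s across adjacent marginal trees, by
# replaying edge removals (oldest first) and insertions (youngest first) at
# each breakpoint.  Site, Branch, and Node statistics in windows are all
# computed from this one state.

#' Sample weights
#'
#' A list of sample weights assigns a numeric vector of length \code{m} to
#' every sample; the subtree weight of a node is the sum of the weights of
#' all samples in its subtree.  Indicator weights of a sample set give
#' subtree sample counts.
#'
#' @param W numeric matrix (samples x m) or vector (m = 1).
#' @param samples integer vector of 0-based sample node ids, one per row of
#'   \code{W}.
#' @return object of class \code{sample_weights} with fields \code{samples},
#'   \code{W}, \code{m} and \code{w_total} (column sums).
#' @export
sample_weights <- function(W, samples) {
  if (is.vector(W)) W <- matrix(W, ncol = 1)
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (nrow(W) != length(samples))
    stopf("weights: one row per sample required")
  if (anyDuplicated(samples)) stopf("weights: duplicate sample ids")
  if (any(!is.finite(W))) stopf("weights: entries must be finite")
  structure(list(samples = as.integer(samples), W = W, m = ncol(W),
                 w_total = colSums(W)),
            class = "sample_weights")
}

#' Indicator weights for one or more sample sets
#'
#' @param ts a \code{\link{tree_sequence}}.
#' @param sets list of integer vectors of 0-based sample ids (or
#'   \code{\link{sample_set}} objects).
#' @return a \code{\link{sample_weights}} with one column per set, defined
#'   over all samples of \code{ts}.
#' @export
indicator_weights <- function(ts, sets) {
  sets <- lapply(sets, function(s) if (inherits(s, "sample_set")) s$members
                 else as.integer(s))
  for (s in sets)
    if (!all(s %in% ts$samples)) stopf("set member is not a sample")
  W <- vapply(sets, function(s) as.numeric(ts$samples %in% s),
              numeric(length(ts$samples)))
  W <- matrix(W, nrow = length(ts$samples))
  sample_weights(W, ts$samples)
}

#' Summary functions
#'
#' A summary function maps a subtree- or allele-weight vector of length
#' \code{m} to a real number.  It is \emph{strict} if it vanishes at the
#' zero vector and at the total weight, so that parts of the tree ancestral
#' to none or to all of the samples contribute nothing.  Site and branch
#' statistics require strict summaries (unless explicitly overridden); node
#' statistics do not.
#'
#' For efficiency the function is called with an \code{m x k} matrix and
#' must return a length-\code{k} numeric vector (column-wise evaluation).
#'
#' @param fn function taking an \code{m x k} matrix, returning length-k
#'   numeric.
#' @param m weight dimension.
#' @param strict logical, declared strictness (verified numerically at the
#'   zero and total-weight arguments when the statistic is computed).
#' @param name optional label.
#' @return object of class \code{summary_function}.
#' @export
summary_function <- function(fn, m, strict = TRUE, name = "f") {
  stopifnot(is.function(fn), is_count(m), m >= 1)
  structure(list(fn = fn, m = as.integer(m), strict = isTRUE(strict),
                 name = name),
            class = "summary_function")
}

#' Window breakpoints
#'
#' @param breakpoints strictly increasing numeric vector starting at 0 and
#'   ending at \code{L}.
#' @param L sequence length.
#' @return validated numeric breakpoint vector.
#' @export
ts_windows <- function(breakpoints, L) {
  b <- as.numeric(breakpoints)
  if (length(b) < 2 || any(diff(b) <= 0) || b[1] != 0 || b[length(b)] != L)
    stopf("windows: breakpoints must increase strictly from 0 to L = %g", L)
  b
}

#' @rdname ts_windows
#' @param M number of equal-width windows.
#' @export
equal_windows <- function(L, M) ts_windows(seq(0, L, length.out = M + 1), L)

# ---------------------------------------------------------------------------

check_strictness <- function(fl, wtot, mode, strict_override, tol = 1e-8) {
  if (mode == "node") return(invisible(TRUE))
  m <- length(wtot)
  for (f in fl) {
    dev <- max(abs(f$fn(matrix(0, m, 1))), abs(f$fn(matrix(wtot, m, 1))))
    if (!is.finite(dev) || dev > tol) {
      if (!strict_override)
        stopf(paste0("summary function '%s' is not strict ",
                     "(|f(0)| or |f(w_total)| = %g > %g); site and branch ",
                     "statistics require f(0) = f(w_total) = 0 unless ",
                     "strict_override = TRUE"), f$name, dev, tol)
    }
  }
  invisible(TRUE)
}

# Allele weights at one site from current subtree weights X (m x N) and the
# current parent vector P: start from {ancestral: w_total}, then walk the
# site's mutations in table order (parents precede children), moving each
# mutation's subtree weight from the allele it overrides onto its derived
# state.  Handles recurrent and back mutations; never scans samples.
allele_weights_from_x <- function(rows, muts, anc, X, P, wtot) {
  m <- length(wtot)
  aw <- list()
  aw[[anc]] <- wtot
  node_of <- muts$node[rows]
  der <- muts$derived_state[rows]
  parm <- muts$parent[rows]
  for (idx in seq_along(rows)) {
    v <- node_of[idx]
    if (v + 1L > ncol(X)) stopf("mutation node %d out of range", v)
    xv <- X[, v + 1L]
    d <- der[idx]
    aw[[d]] <- (aw[[d]] %||% numeric(m)) + xv
    pm <- parm[idx]
    if (pm >= 0L) {
      pa <- muts$derived_state[pm + 1L]
    } else {
      earlier <- which(node_of == v)
      earlier <- earlier[earlier < idx]
      if (length(earlier) > 0) {
        pa <- der[max(earlier)]
      } else {
        u <- P[v + 1L]
        pa <- anc
        while (u != -1L) {
          hits <- which(node_of == u)
          if (length(hits) > 0) {
            pa <- der[max(hits)]
            break
          }
          u <- P[u + 1L]
        }
      }
    }
    aw[[pa]] <- (aw[[pa]] %||% numeric(m)) - xv
  }
  aw
}

#' Allele weights at a site
#'
#' Computes, for each allele present at a site, the summed weight of the
#' samples inheriting it, derived from subtree weights with back- and
#' recurrent-mutation corrections (each mutation's subtree weight is
#' subtracted from the allele it overrides).  The allele weights always sum
#' to the total sample weight.
#'
#' @param ts a \code{\link{tree_sequence}}.
#' @param site 0-based site id.
#' @param W a \code{\link{sample_weights}}.
#' @return object of class \code{allele_weights}: list with \code{site},
#'   \code{ancestral}, \code{weights} (named list allele -> weight vector)
#'   and \code{derived} (allele labels except the ancestral).
#' @export
allele_weights <- function(ts, site, W) {
  if (!(site >= 0 && site < nrow(ts$sites))) stopf("site id out of range")
  pos <- ts$sites$position[site + 1L]
  trs <- trees(ts)
  lefts <- vapply(trs, function(t) t$interval[1], numeric(1))
  tree <- trs[[findInterval(pos, lefts)]]
  X <- t(subtree_weights_naive(tree, W))
  rows <- which(ts$mutations$site == site)
  aw <- allele_weights_from_x(rows, ts$mutations,
                              ts$sites$ancestral_state[site + 1L],
                              X, tree$parent, W$w_total)
  structure(list(site = site, ancestral = ts$sites$ancestral_state[site + 1L],
                 weights = aw,
                 derived = setdiff(names(aw),
                                   ts$sites$ancestral_state[site + 1L])),
            class = "allele_weights")
}

# ---------------------------------------------------------------------------

#' Compute a windowed statistic with the incremental engine
#'
#' The workhorse behind \code{\link{branch_stat}}, \code{\link{site_stat}}
#' and \code{\link{node_stat}}: a single left-to-right pass over the edge
#' insertion/removal indexes maintaining the subtree-weight vectors, the
#' summary caches, and (for branch mode) the running sum
#' \code{s = sum(beta * f(x))}, with span-weighted contributions flushed
#' into windows.  Several summary functions sharing one set of weights are
#' evaluated in the same pass.
#'
#' @param ts a \code{\link{tree_sequence}}.
#' @param W a \code{\link{sample_weights}}.
#' @param fs a \code{\link{summary_function}} or list of them (all with
#'   \code{m} equal to \code{W$m}).
#' @param mode one of \code{"site"}, \code{"branch"}, \code{"node"}.
#' @param windows breakpoints (see \code{\link{ts_windows}}); default one
#'   window spanning the whole sequence.
#' @param polarized if TRUE, count only the subtree term (branch/node) or
#'   only derived alleles (site).
#' @param strict_override allow non-strict summaries in site/branch mode.
#' @param verify recompute the running sum from scratch at every tree and
#'   stop if the incremental value drifts beyond 1e-6 relative (branch mode
#'   only).
#' @param per_site (site mode) also return per-site statistic values.
#' @param final_state after the pass, remove all remaining edges and attach
#'   the restored engine state as attribute \code{final_state} (the weights
#'   must return to their initial values).
#' @return object of class \code{ts_stat}: list with \code{mode},
#'   \code{polarized}, \code{windows} and \code{values} (windows x
#'   statistics matrix; node mode: nodes x windows matrix, or a 3-d array
#'   for several summaries).
#' @export
stat_compute <- function(ts, W, fs, mode = c("site", "branch", "node"),
                         windows = NULL, polarized = FALSE,
                         strict_override = FALSE, verify = FALSE,
                         per_site = FALSE, final_state = FALSE) {
  mode <- match.arg(mode)
  fl <- if (inherits(fs, "summary_function")) list(fs) else fs
  stopifnot(length(fl) >= 1)
  for (f in fl) {
    if (!inherits(f, "summary_function"))
      stopf("fs must be summary_function objects")
    if (f$m != W$m)
      stopf("summary function '%s' has m = %d but weights have m = %d",
            f$name, f$m, W$m)
  }
  wb <- if (is.null(windows)) c(0, ts$L) else ts_windows(windows, ts$L)
  wlen <- diff(wb)
  nwin <- length(wlen)
  nf <- length(fl)
  m <- W$m
  N <- nrow(ts$nodes)
  E <- nrow(ts$edges)
  wtot <- W$w_total
  check_strictness(fl, wtot, mode, strict_override)

  e <- ts$edges
  e_left <- e$left; e_right <- e$right
  e_parent <- e$parent; e_child <- e$child
  nt <- ts$nodes$time
  ins <- ts$insertion
  rem <- ts$removal
  spos <- ts$sites$position
  sanc <- ts$sites$ancestral_state

  evalmat <- function(M) {
    out <- matrix(0, nf, ncol(M))
    for (fi in seq_len(nf)) out[fi, ] <- fl[[fi]]$fn(M)
    out
  }

  P <- rep(-1L, N)
  Bv <- numeric(N)
  X <- matrix(0, m, N)
  X[, W$samples + 1L] <- t(W$W)
  use_cache <- mode != "site"
  track_s <- mode == "branch"
  if (use_cache) {
    Fm <- evalmat(X)
    Fc <- evalmat(wtot - X)
    G <- if (polarized) Fm else Fm + Fc
  }
  s <- numeric(nf)

  ACC <- matrix(0, nwin, nf)
  if (mode == "node") ACC3 <- array(0, dim = c(N, nwin, nf))
  S <- nrow(ts$sites)
  if (mode == "site") {
    mut_rows <- split(seq_len(nrow(ts$mutations)), ts$mutations$site)
    site_win <- if (S > 0)
      findInterval(ts$sites$position, wb, rightmost.closed = TRUE)
    else integer(0)
    # single fresh mutation whose derived state differs from the ancestral:
    # the allele weights are just (x[node], w_total - x[node]); batched
    msite <- ts$mutations$site + 1L
    nmut <- tabulate(msite, nbins = S)
    row1 <- integer(S)
    row1[msite] <- seq_along(msite)
    site_simple <- nmut == 1L
    idx1 <- which(site_simple)
    r1 <- row1[idx1]
    site_simple[idx1] <- ts$mutations$parent[r1] == -1L &
      ts$mutations$derived_state[r1] != sanc[idx1]
    site_mnode <- integer(S)
    site_mnode[idx1] <- ts$mutations$node[r1]
    if (per_site) PS <- matrix(0, S, nf)
    sp <- 1L
  }

  refresh <- function(u1) {
    # update caches for node (1-based index) u1 after X[, u1] changed
    Fm[, u1] <<- evalmat(X[, u1, drop = FALSE])
    Fc[, u1] <<- evalmat(wtot - X[, u1, drop = FALSE])
    G[, u1] <<- if (polarized) Fm[, u1] else Fm[, u1] + Fc[, u1]
  }

  remove_edge <- function(r) {
    u1 <- e_child[r] + 1L
    v <- e_parent[r]
    if (track_s) s <<- s - Bv[u1] * G[, u1]
    P[u1] <<- -1L
    Bv[u1] <<- 0
    xu <- X[, u1]
    while (v != -1L) {
      v1 <- v + 1L
      if (track_s) s <<- s - Bv[v1] * G[, v1]
      X[, v1] <<- X[, v1] - xu
      if (use_cache) refresh(v1)
      if (track_s) s <<- s + Bv[v1] * G[, v1]
      v <- P[v1]
    }
  }

  insert_edge <- function(r) {
    u1 <- e_child[r] + 1L
    v <- e_parent[r]
    if (P[u1] != -1L)
      stopf("corrupt indexes: node %d assigned two parents", u1 - 1L)
    P[u1] <<- v
    Bv[u1] <<- nt[v + 1L] - nt[u1]
    if (track_s) s <<- s + Bv[u1] * G[, u1]
    xu <- X[, u1]
    while (v != -1L) {
      v1 <- v + 1L
      if (track_s) s <<- s - Bv[v1] * G[, v1]
      X[, v1] <<- X[, v1] + xu
      if (use_cache) refresh(v1)
      if (track_s) s <<- s + Bv[v1] * G[, v1]
      v <- P[v1]
    }
  }

  j <- 1L; k <- 1L; tl <- 0
  repeat {
    while (k <= E && e_right[rem[k]] == tl) {
      remove_edge(rem[k])
      k <- k + 1L
    }
    while (j <= E && e_left[ins[j]] == tl) {
      insert_edge(ins[j])
      j <- j + 1L
    }
    tr <- ts$L
    if (j <= E) tr <- min(tr, e_left[ins[j]])
    if (k <= E) tr <- min(tr, e_right[rem[k]])

    if (verify && track_s) {
      s2 <- as.numeric(G %*% Bv)
      if (any(abs(s - s2) > 1e-6 * pmax(1, abs(s2))))
        stopf("running-sum drift beyond 1e-6 relative at tree [%g, %g)",
              tl, tr)
    }

    if (mode == "site") {
      sp2 <- sp
      while (sp2 <= S && spos[sp2] < tr) sp2 <- sp2 + 1L
      if (sp2 > sp) {
        block <- sp:(sp2 - 1L)      # sites are sorted: position >= tl here
        simp <- block[site_simple[block]]
        if (length(simp) > 0) {
          xd <- X[, site_mnode[simp] + 1L, drop = FALSE]
          vd <- evalmat(xd)
          if (!polarized) vd <- vd + evalmat(wtot - xd)
          grp <- site_win[simp]
          for (fi in seq_len(nf)) {
            gs <- rowsum(vd[fi, ], grp)
            ACC[as.integer(rownames(gs)), fi] <-
              ACC[as.integer(rownames(gs)), fi] + gs[, 1]
            if (per_site) PS[simp, fi] <- vd[fi, ]
          }
        }
        for (jx in setdiff(block, simp)) {
          jw <- site_win[jx]
          anc <- sanc[jx]
          rows <- mut_rows[[as.character(jx - 1L)]]
          if (nmut[jx] == 0L) {
            val <- if (polarized) numeric(nf) else
              evalmat(matrix(wtot, m, 1))[, 1]
          } else {
            aw <- allele_weights_from_x(rows, ts$mutations, anc, X, P, wtot)
            keys <- names(aw)
            if (polarized) keys <- setdiff(keys, anc)
            val <- numeric(nf)
            if (length(keys) > 0) {
              Mw <- vapply(keys, function(a) aw[[a]], numeric(m))
              Mw <- matrix(Mw, nrow = m)
              val <- rowSums(evalmat(Mw))
            }
          }
          ACC[jw, ] <- ACC[jw, ] + val
          if (per_site) PS[jx, ] <- val
        }
        sp <- sp2
      }
    } else {
      wi <- findInterval(tl, wb, rightmost.closed = TRUE)
      while (wi <= nwin && wb[wi] < tr) {
        seg <- min(tr, wb[wi + 1L]) - max(tl, wb[wi])
        if (seg > 0) {
          if (mode == "branch") {
            ACC[wi, ] <- ACC[wi, ] + seg * s
          } else {
            for (fi in seq_len(nf)) {
              contrib <- if (polarized) Fm[fi, ] else Fm[fi, ] + Fc[fi, ]
              ACC3[, wi, fi] <- ACC3[, wi, fi] + seg * contrib
            }
          }
        }
        wi <- wi + 1L
      }
    }
    tl <- tr
    if (tl >= ts$L) break
  }

  if (final_state) {
    while (k <= E) {
      remove_edge(rem[k])
      k <- k + 1L
    }
    fin <- list(x = t(X), parent = P, branch_length = Bv, s = s)
  }

  stat_names <- vapply(fl, function(f) f$name, character(1))
  if (mode == "node") {
    vals <- sweep(ACC3, 2, wlen, "/")
    if (nf == 1) vals <- vals[, , 1, drop = TRUE]
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = nwin)
  } else {
    vals <- ACC / wlen
    if (nf > 1) colnames(vals) <- stat_names
  }
  out <- structure(list(mode = mode, polarized = polarized, windows = wb,
                        values = vals, stat_names = stat_names),
                   class = "ts_stat")
  if (mode == "site" && per_site) {
    ps <- data.frame(position = ts$sites$position)
    for (fi in seq_len(nf)) ps[[stat_names[fi]]] <- PS[, fi]
    out$per_site <- ps
  }
  if (final_state) attr(out, "final_state") <- fin
  out
}

#' Branch, site, and node statistics
#'
#' \code{branch_stat} computes, per window, the span-weighted average over
#' trees of the sum over branches of branch length times the summary of the
#' subtree weight (plus the complementary term unless polarized),
#' normalized by window length.  \code{site_stat} sums the summary over
#' allele weights at every site in the window (all alleles, or only derived
#' alleles if polarized) and normalizes by window length.  \code{node_stat}
#' returns, per node and window, the span-weighted average of the summary
#' of that node's subtree weight (plus the complement unless polarized).
#'
#' @inheritParams stat_compute
#' @param ... passed through to \code{\link{stat_compute}}.
#' @return a \code{ts_stat} object.
#' @export
branch_stat <- function(ts, W, fs, windows = NULL, polarized = FALSE, ...)
  stat_compute(ts, W, fs, "branch", windows, polarized, ...)

#' @rdname branch_stat
#' @export
site_stat <- function(ts, W, fs, windows = NULL, polarized = FALSE, ...)
  stat_compute(ts, W, fs, "site", windows, polarized, ...)

#' @rdname branch_stat
#' @export
node_stat <- function(ts, W, fs, windows = NULL, polarized = FALSE, ...)
  stat_compute(ts, W, fs, "node", windows, polarized, ...)

#' @export
print.ts_stat <- function(x, ...) {
  cat(sprintf("%s statistic%s (%s), %d window(s)\n", x$mode,
              if (length(x$stat_names) > 1)
                paste0("s [", paste(x$stat_names, collapse = ", "), "]")
              else paste0(" [", x$stat_names, "]"),
              if (x$polarized) "polarized" else "unpolarized",
              length(x$windows) - 1L))
  if (x$mode == "node") {
    cat(sprintf("values: %d nodes x %d windows\n", dim(x$values)[1],
                length(x$windows) - 1L))
  } else {
    print(utils::head(data.frame(window_start = x$windows[-length(x$windows)],
                                 window_end = x$windows[-1],
                                 x$values, check.names = FALSE)))
  }
  invisible(x)
}
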