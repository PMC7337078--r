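# Infinite-sites mutation dropping, brute-force reference implementations,
# and Monte-Carlo checks of the site/branch duality and its variance
# decomposition.

#' Drop infinite-sites mutations onto a tree sequence
#'
#' Under a neutral infinite-sites model with rate \code{mu} per unit time
#' per unit sequence length, the number of mutations is Poisson with mean
#' \code{mu} times the total branch area (sum over edges of span times
#' branch length).  Each mutation picks an edge with probability
#' proportional to its area, a fresh position uniform on the edge's genomic
#' interval (distinct from all other positions), ancestral state "0" and
#' derived state "1".
#'
#' @param ts a \code{\link{tree_sequence}} with no pre-existing sites.
#' @param mu mutation rate (> 0) per unit time per unit sequence length.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param discrete if TRUE, positions are integers (collisions rejected and
#'   redrawn), for genotype-export realism.
#' @return a new \code{tree_sequence} sharing nodes and edges with
#'   \code{ts}, with the generated sites and mutations.
#' @export
drop_mutations <- function(ts, mu, seed = NULL, discrete = FALSE) {
  stopifnot(is.numeric(mu), mu > 0, is.finite(mu))
  if (nrow(ts$sites) > 0)
    stopf("drop_mutations: tree sequence already has sites")
  e <- ts$edges
  area <- (e$right - e$left) * (ts$nodes$time[e$parent + 1L] -
                                  ts$nodes$time[e$child + 1L])
  total <- sum(area)
  with_seed(seed, {
    nm <- if (total > 0) stats::rpois(1, mu * total) else 0L
    ts2 <- ts
    if (nm == 0) {
      ts2$sites <- as_site_table(NULL)
      ts2$mutations <- as_mutation_table(NULL)
      return(ts2)
    }
    eid <- sample.int(nrow(e), nm, replace = TRUE, prob = area)
    pos <- stats::runif(nm, e$left[eid], e$right[eid])
    if (discrete) pos <- floor(pos)
    for (tries in 1:1000) {
      dup <- duplicated(pos)
      if (!any(dup)) break
      if (tries == 1000)
        stopf("drop_mutations: cannot place %d distinct discrete sites", nm)
      # redraw colliding mutations afresh (edge and position), so that
      # collisions on short edges can still resolve elsewhere
      eid[dup] <- sample.int(nrow(e), sum(dup), replace = TRUE, prob = area)
      pos[dup] <- stats::runif(sum(dup), e$left[eid[dup]], e$right[eid[dup]])
      if (discrete) pos[dup] <- floor(pos[dup])
    }
    ord <- order(pos)
    ts2$sites <- data.frame(position = pos[ord],
                            ancestral_state = rep("0", nm))
    ts2$mutations <- data.frame(site = seq_len(nm) - 1L,
                                node = e$child[eid[ord]],
                                derived_state = rep("1", nm),
                                parent = rep(-1L, nm))
    ts2
  })
}

#' Brute-force statistics (the engine's oracle)
#'
#' Identical contract to \code{\link{stat_compute}}, computed with no
#' incremental state: every marginal tree is rebuilt from scratch and its
#' subtree weights recomputed by per-sample traversal; site-mode allele
#' weights are summed directly over the decoded genotype matrix.
#'
#' @inheritParams stat_compute
#' @return a \code{ts_stat}.
#' @export
naive_stats <- function(ts, W, fs, mode = c("site", "branch", "node"),
                        windows = NULL, polarized = FALSE,
                        strict_override = FALSE) {
  mode <- match.arg(mode)
  fl <- if (inherits(fs, "summary_function")) list(fs) else fs
  wb <- if (is.null(windows)) c(0, ts$L) else ts_windows(windows, ts$L)
  wlen <- diff(wb)
  nwin <- length(wlen)
  nf <- length(fl)
  m <- W$m
  N <- nrow(ts$nodes)
  wtot <- W$w_total
  check_strictness(fl, wtot, mode, strict_override)
  evalmat <- function(M) {
    out <- matrix(0, nf, ncol(M))
    for (fi in seq_len(nf)) out[fi, ] <- fl[[fi]]$fn(M)
    out
  }
  stat_names <- vapply(fl, function(f) f$name, character(1))

  if (mode == "site") {
    G <- decode_genotypes(ts)
    ACC <- matrix(0, nwin, nf)
    site_win <- findInterval(ts$sites$position, wb, rightmost.closed = TRUE)
    for (j in seq_len(nrow(ts$sites))) {
      alleles <- unique(G[j, ])
      if (polarized)
        alleles <- setdiff(alleles, ts$sites$ancestral_state[j])
      if (length(alleles) == 0) next
      aw <- vapply(alleles,
                   function(a) colSums(W$W[G[j, ] == a, , drop = FALSE]),
                   numeric(m))
      aw <- matrix(aw, nrow = m)
      ACC[site_win[j], ] <- ACC[site_win[j], ] + rowSums(evalmat(aw))
    }
    vals <- ACC / wlen
    if (nf > 1) colnames(vals) <- stat_names
  } else {
    trs <- trees(ts)
    if (mode == "branch") ACC <- matrix(0, nwin, nf)
    else ACC3 <- array(0, dim = c(N, nwin, nf))
    for (tree in trs) {
      x <- t(subtree_weights_naive(tree, W))   # m x N
      Fx <- evalmat(x)
      contrib <- if (polarized) Fx else Fx + evalmat(wtot - x)
      a <- tree$interval[1]; b <- tree$interval[2]
      for (wi in seq_len(nwin)) {
        seg <- max(0, min(b, wb[wi + 1]) - max(a, wb[wi]))
        if (seg == 0) next
        if (mode == "branch") {
          bk <- as.numeric(contrib %*% tree$branch_length)
          ACC[wi, ] <- ACC[wi, ] + seg * bk
        } else {
          for (fi in seq_len(nf))
            ACC3[, wi, fi] <- ACC3[, wi, fi] + seg * contrib[fi, ]
        }
      }
    }
    if (mode == "branch") {
      vals <- ACC / wlen
      if (nf > 1) colnames(vals) <- stat_names
    } else {
      vals <- sweep(ACC3, 2, wlen, "/")
      if (nf == 1) vals <- vals[, , 1, drop = TRUE]
      if (is.null(dim(vals))) vals <- matrix(vals, ncol = nwin)
    }
  }
  structure(list(mode = mode, polarized = polarized, windows = wb,
                 values = vals, stat_names = stat_names),
            class = "ts_stat")
}

#' Genome-wide recipe for a named statistic
#'
#' Builds a closure \code{function(ts, mode)} returning the genome-wide
#' (single-window) value of a named statistic, for use with
#' \code{\link{duality_check}} and the CLI.
#'
#' @param name one of \code{"diversity"}, \code{"divergence"},
#'   \code{"segregating_sites"}, \code{"f4"}, \code{"trait_correlation"}.
#' @param sets list of \code{\link{sample_set}}s (as many as the statistic
#'   needs).
#' @param z phenotype vector (for \code{"trait_correlation"}).
#' @return function of \code{(ts, mode)} returning a scalar.
#' @export
stat_recipe <- function(name, sets = NULL, z = NULL) {
  switch(name,
    diversity = function(ts, mode)
      diversity(ts, sets[[1]], mode = mode)$values[1, 1],
    divergence = function(ts, mode)
      divergence(ts, sets[[1]], sets[[2]], mode = mode)$values[1, 1],
    segregating_sites = function(ts, mode)
      segregating_sites(ts, sets[[1]], mode = mode)$values[1, 1],
    f4 = function(ts, mode)
      f4(ts, sets[[1]], sets[[2]], sets[[3]], sets[[4]],
         mode = mode)$values[1, 1],
    trait_correlation = function(ts, mode)
      trait_correlation(ts, z, mode = mode)$values[1, 1],
    stopf("unknown statistic '%s'; available: %s", name,
          paste(c("diversity", "divergence", "segregating_sites", "f4",
                  "trait_correlation"), collapse = ", ")))
}

#' Monte-Carlo check of the site/branch duality
#'
#' The branch statistic equals the expected site statistic divided by the
#' mutation rate, conditionally on the trees, under infinite-sites
#' mutation.  This check computes the branch value once, then drops
#' mutations \code{reps} times, computes the site value each time divided
#' by \code{mu}, and reports the Monte-Carlo z-score of the difference.
#'
#' @param ts a fixed \code{\link{tree_sequence}} with no sites.
#' @param recipe a closure \code{function(ts, mode) -> scalar}, e.g. from
#'   \code{\link{stat_recipe}}.
#' @param mu mutation rate.
#' @param reps number of mutation-dropping replicates (>= 2).
#' @param seed integer seed (replicates consume the seeded RNG stream).
#' @return object of class \code{duality_report}: \code{branch_value},
#'   \code{site_mean}, \code{site_se}, \code{reps}, \code{z_score}.
#' @export
duality_check <- function(ts, recipe, mu, reps, seed = NULL) {
  stopifnot(reps >= 2)
  branch_value <- recipe(ts, "branch")
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(i)
      recipe(drop_mutations(ts, mu), "site") / mu, numeric(1))
  })
  site_mean <- mean(vals)
  site_se <- stats::sd(vals) / sqrt(reps)
  z <- if (site_se > 0) (site_mean - branch_value) / site_se else
    if (site_mean == branch_value) 0 else Inf
  structure(list(branch_value = branch_value, site_mean = site_mean,
                 site_se = site_se, reps = reps, z_score = z),
            class = "duality_report")
}

#' @export
print.duality_report <- function(x, ...) {
  cat(sprintf(
    "duality check: branch = %.6g, site/mu = %.6g +/- %.3g (reps = %d), z = %.2f\n",
    x$branch_value, x$site_mean, x$site_se, x$reps, x$z_score))
  invisible(x)
}

#' Monte-Carlo check of the variance decomposition
#'
#' Conditionally on the trees, the per-branch mutation counts are
#' independent Poisson, so the variance of the (genome-wide) site statistic
#' equals \code{mu/L} times the polarized branch statistic of the squared
#' per-site contribution \code{g(x) = (f(x) + f(w_total - x))^2} (just
#' \code{f(x)^2} for a polarized statistic).  Compares that prediction with
#' the empirical variance across mutation-dropping replicates.
#'
#' @param ts a fixed \code{\link{tree_sequence}} with no sites.
#' @param W a \code{\link{sample_weights}}.
#' @param f a \code{\link{summary_function}}.
#' @param mu mutation rate.
#' @param reps replicates (>= 10).
#' @param seed integer seed.
#' @param polarized whether the site statistic is polarized.
#' @return object of class \code{variance_report}: \code{empirical},
#'   \code{predicted}, \code{se} (Monte-Carlo SE of the empirical
#'   variance), \code{z_score}, \code{rel_dev}, \code{reps}.
#' @export
variance_check <- function(ts, W, f, mu, reps, seed = NULL,
                           polarized = FALSE) {
  stopifnot(reps >= 10)
  wtot <- W$w_total
  m <- W$m
  g <- summary_function(function(M) {
    v <- f$fn(M)
    if (!polarized) v <- v + f$fn(wtot - M)
    v^2
  }, m = m, strict = TRUE, name = paste0(f$name, "_sq"))
  predicted <- (mu / ts$L) *
    branch_stat(ts, W, g, polarized = TRUE)$values[1, 1]
  vals <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      tsm <- drop_mutations(ts, mu)
      site_stat(tsm, W, f, polarized = polarized)$values[1, 1]
    }, numeric(1))
  })
  emp <- stats::var(vals)
  cc <- vals - mean(vals)
  m4 <- mean(cc^4)
  se <- sqrt(max(0, m4 - (reps - 3) / (reps - 1) * emp^2) / reps)
  z <- if (se > 0) (emp - predicted) / se else
    if (emp == predicted) 0 else Inf
  structure(list(empirical = emp, predicted = predicted, se = se,
                 z_score = z,
                 rel_dev = if (predicted != 0) emp / predicted - 1 else NA,
                 reps = reps),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf(
    "variance check: empirical = %.6g, predicted = %.6g +/- %.3g (reps = %d), z = %.2f\n",
    x$empirical, x$predicted, x$se, x$reps, x$z_score))
  invisible(x)
}

#' Mean pairwise difference density from decoded genotypes
#'
#' Direct double-loop oracle for diversity/divergence: the mean, over pairs
#' of samples (within \code{S1}, or across \code{S1 x S2}), of the fraction
#' of the sequence at which the two decoded haplotypes differ.
#'
#' @param ts a \code{\link{tree_sequence}}.
#' @param S1 a \code{\link{sample_set}}.
#' @param S2 a second, disjoint set for cross-pair divergence, or NULL for
#'   within-set diversity.
#' @return scalar mean per-base pairwise difference.
#' @export
pairwise_from_genotypes <- function(ts, S1, S2 = NULL) {
  if (S1$n == 0 || (!is.null(S2) && S2$n == 0)) stopf("empty sample set")
  G <- decode_genotypes(ts)
  col_of <- function(ids) match(ids, ts$samples)
  tot <- 0; np <- 0
  if (is.null(S2)) {
    cols <- col_of(S1$members)
    for (i in seq_along(cols)) for (jj in seq_along(cols)) {
      if (jj <= i) next
      tot <- tot + sum(G[, cols[i]] != G[, cols[jj]])
      np <- np + 1
    }
  } else {
    c1 <- col_of(S1$members); c2 <- col_of(S2$members)
    for (i in c1) for (jj in c2) {
      tot <- tot + sum(G[, i] != G[, jj])
      np <- np + 1
    }
  }
  tot / np / ts$L
}
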