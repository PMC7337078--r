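# Named single-site statistics as (weights, summary function, mode)
# recipes delegating to the engine.

#' Sample sets
#'
#' @param name set label.
#' @param members integer vector of 0-based sample node ids (distinct).
#' @return object of class \code{sample_set} with fields \code{name},
#'   \code{members}, \code{n}.
#' @export
sample_set <- function(name, members) {
  members <- as.integer(members)
  if (anyDuplicated(members)) stopf("sample set '%s': duplicate members", name)
  structure(list(name = name, members = members, n = length(members)),
            class = "sample_set")
}

check_disjoint <- function(...) {
  sets <- list(...)
  all_ids <- unlist(lapply(sets, function(s) s$members))
  if (anyDuplicated(all_ids))
    stopf("sample sets must be disjoint")
  for (s in sets) if (s$n == 0) stopf("sample set '%s' is empty", s$name)
  invisible(TRUE)
}

#' Summary functions of the named statistics
#'
#' Factories for the summary functions used by the named statistics, as
#' functions of subtree/allele weights (column-wise over an m x k matrix):
#' \itemize{
#'   \item diversity: \code{f(x) = x(n-x)/(n(n-1))}; with indicator weights
#'     the unpolarized site statistic is mean nucleotide diversity.
#'   \item divergence: \code{f(x1,x2) = (x1/n1)(1 - x2/n2)}.
#'   \item segregating sites: \code{f(x) = 1 - x/n} if \code{x > 0}, else 0;
#'     a site with k alleles contributes k - 1.
#'   \item f4: \code{p1(1-p2)p3(1-p4) - (1-p1)p2 p3 (1-p4)} with
#'     \code{pi = xi/ni}; the unpolarized sum over an allele and its
#'     complement equals \code{(p1-p2)(p3-p4)} (BABA minus ABBA).
#' }
#' All four are strict: they vanish at \code{x = 0} and at the total weight.
#'
#' @param n,n1,n2,n3,n4 sample-set sizes.
#' @return a \code{\link{summary_function}}.
#' @export
summary_diversity <- function(n) {
  stopifnot(n >= 2)
  summary_function(function(M) M[1, ] * (n - M[1, ]) / (n * (n - 1)),
                   m = 1, strict = TRUE, name = "diversity")
}

#' @rdname summary_diversity
#' @export
summary_divergence <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  summary_function(function(M) (M[1, ] / n1) * (1 - M[2, ] / n2),
                   m = 2, strict = TRUE, name = "divergence")
}

#' @rdname summary_diversity
#' @export
summary_segregating <- function(n) {
  stopifnot(n >= 1)
  summary_function(function(M) ifelse(M[1, ] > 1e-12, 1 - M[1, ] / n, 0),
                   m = 1, strict = TRUE, name = "segregating_sites")
}

#' @rdname summary_diversity
#' @export
summary_f4 <- function(n1, n2, n3, n4) {
  stopifnot(n1 >= 1, n2 >= 1, n3 >= 1, n4 >= 1)
  summary_function(function(M) {
    p1 <- M[1, ] / n1; p2 <- M[2, ] / n2
    p3 <- M[3, ] / n3; p4 <- M[4, ] / n4
    p1 * (1 - p2) * p3 * (1 - p4) - (1 - p1) * p2 * p3 * (1 - p4)
  }, m = 4, strict = TRUE, name = "f4")
}

#' Nucleotide diversity
#'
#' Mean density of pairwise differences within a sample set (site mode),
#' its branch-length dual -- twice the mean TMRCA of a random pair, for
#' contemporaneous samples -- (branch mode), or the per-node decomposition
#' (node mode).
#'
#' @param ts a \code{\link{tree_sequence}}.
#' @param S a \code{\link{sample_set}} with at least two members.
#' @param mode \code{"site"}, \code{"branch"} or \code{"node"}.
#' @param windows breakpoints (default: whole sequence).
#' @param polarized non-default; the statistic is unpolarized by
#'   construction.
#' @return a \code{ts_stat}.
#' @export
diversity <- function(ts, S, mode = "site", windows = NULL,
                      polarized = FALSE) {
  if (S$n < 2) stopf("diversity needs a sample set with n >= 2")
  W <- indicator_weights(ts, list(S))
  stat_compute(ts, W, summary_diversity(S$n), mode, windows, polarized)
}

#' Nucleotide divergence between two disjoint sample sets
#'
#' @inheritParams diversity
#' @param S1,S2 disjoint non-empty \code{\link{sample_set}}s.
#' @return a \code{ts_stat}.
#' @export
divergence <- function(ts, S1, S2, mode = "site", windows = NULL,
                       polarized = FALSE) {
  check_disjoint(S1, S2)
  W <- indicator_weights(ts, list(S1, S2))
  stat_compute(ts, W, summary_divergence(S1$n, S2$n), mode, windows,
               polarized)
}

#' Density of segregating sites
#'
#' Site mode gives the minimum number of derived mutations per unit length
#' (the density of segregating sites when all sites are biallelic); a site
#' with k distinct alleles contributes k - 1.  Branch mode gives the
#' expected density per unit mutation rate.
#'
#' @inheritParams diversity
#' @param S a non-empty \code{\link{sample_set}}.
#' @return a \code{ts_stat}.
#' @export
segregating_sites <- function(ts, S, mode = "site", windows = NULL,
                              polarized = FALSE) {
  if (S$n < 1) stopf("segregating_sites needs a non-empty sample set")
  W <- indicator_weights(ts, list(S))
  stat_compute(ts, W, summary_segregating(S$n), mode, windows, polarized)
}

#' Patterson's f4
#'
#' BABA-minus-ABBA statistic for four disjoint sample sets, well defined
#' for polyallelic sites.  In branch mode, branches separating S1 and S3
#' from S2 and S4 count positively (weighted by how cleanly they separate),
#' branches separating S1 and S4 from S2 and S3 negatively.
#'
#' @inheritParams diversity
#' @param S1,S2,S3,S4 disjoint non-empty \code{\link{sample_set}}s.
#' @return a \code{ts_stat}.
#' @export
f4 <- function(ts, S1, S2, S3, S4, mode = "site", windows = NULL,
               polarized = FALSE) {
  check_disjoint(S1, S2, S3, S4)
  W <- indicator_weights(ts, list(S1, S2, S3, S4))
  stat_compute(ts, W, summary_f4(S1$n, S2$n, S3$n, S4$n), mode, windows,
               polarized)
}

#' Squared correlation between a phenotype and each allele
#'
#' The phenotype is standardized internally to mean zero and unit variance
#' (sample variance, denominator n - 1); the weights are
#' \code{w(u) = (z(u), 1/n)} and the summary is
#' \code{f(x1, x2) = x1^2 / (2 x2 (1 - x2) n (n - 1))}, defined as 0 when
#' \code{x2} is 0 or 1 (monomorphic guard).  The unpolarized site value at
#' a biallelic site equals the squared sample correlation between the
#' phenotype and the derived-allele indicator.
#'
#' @inheritParams diversity
#' @param z named numeric vector of phenotypes; names are sample ids.  Must
#'   cover every sample of \code{ts}.
#' @return a \code{ts_stat} (site or branch mode).
#' @export
trait_correlation <- function(ts, z, mode = "site", windows = NULL) {
  ids <- as.integer(names(z))
  if (!setequal(ids, ts$samples))
    stopf("phenotype must be defined for exactly the samples")
  z <- z[match(ts$samples, ids)]
  n <- length(z)
  zc <- z - mean(z)
  v <- sum(zc^2) / (n - 1)
  if (v < 1e-12) stopf("zero variance: phenotype is constant")
  zs <- zc / sqrt(v)
  W <- sample_weights(cbind(zs, rep(1 / n, n)), ts$samples)
  f <- summary_function(function(M) {
    x1 <- M[1, ]; x2 <- M[2, ]
    d <- 2 * x2 * (1 - x2) * n * (n - 1)
    ifelse(x2 < 1e-12 | x2 > 1 - 1e-12, 0, x1^2 / d)
  }, m = 2, strict = TRUE, name = "trait_correlation")
  stat_compute(ts, W, f, mode, windows, polarized = FALSE)
}

#' Tajima's D
#'
#' Computed per window as a ratio of additive site statistics:
#' \code{D = (pi - S/a1) / sqrt(e1 S + e2 S (S - 1))}, where \code{pi} is
#' the summed pairwise-difference density over the window (site diversity
#' times window length), \code{S} the number of segregating sites (k >= 2
#' alleles) in the window, and a1, a2, b1, b2, c1, c2, e1, e2 the standard
#' constants for sample size n.  Windows with \code{S = 0} yield \code{NaN}.
#'
#' @inheritParams diversity
#' @param S a \code{\link{sample_set}} with n >= 2.
#' @return a \code{ts_stat} with one value per window (possibly \code{NaN}).
#' @export
tajimas_d <- function(ts, S, windows = NULL) {
  if (S$n < 2) stopf("tajimas_d needs a sample set with n >= 2")
  n <- S$n
  W <- indicator_weights(ts, list(S))
  res <- stat_compute(ts, W,
                      list(summary_diversity(n), summary_segregating(n)),
                      "site", windows, polarized = FALSE, per_site = TRUE)
  wb <- res$windows
  wlen <- diff(wb)
  pi_tot <- res$values[, 1] * wlen
  ps <- res$per_site
  seg <- ps$position[ps$segregating_sites >= 0.5]
  win_of <- findInterval(seg, wb, rightmost.closed = TRUE)
  Sc <- tabulate(win_of, nbins = length(wlen))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * Sc + e2 * Sc * (Sc - 1))
  D <- ifelse(Sc == 0, NaN, (pi_tot - Sc / a1) / denom)
  vals <- matrix(D, ncol = 1)
  structure(list(mode = "site", polarized = FALSE, windows = wb,
                 values = vals, stat_names = "tajimas_d"),
            class = "ts_stat")
}

#' Ancestry proportions per node
#'
#' Polarized node statistic with indicator weights and the (non-strict)
#' summary \code{f(x) = x/n}: for each node and window, the proportion of
#' the genomes of the sample set inherited from that node.
#'
#' @inheritParams diversity
#' @param S a non-empty \code{\link{sample_set}}.
#' @return a \code{ts_stat} with a nodes x windows value matrix.
#' @export
ancestry_proportions <- function(ts, S, windows = NULL) {
  if (S$n < 1) stopf("ancestry_proportions needs a non-empty sample set")
  W <- indicator_weights(ts, list(S))
  f <- summary_function(function(M) M[1, ] / S$n, m = 1, strict = FALSE,
                        name = "ancestry")
  stat_compute(ts, W, f, "node", windows, polarized = TRUE)
}
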