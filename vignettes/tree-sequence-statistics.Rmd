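---
title: "Site, branch, and node statistics on tree sequences: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site, branch, and node statistics on tree sequences: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsdual)
```

## The statistical framework

A succinct tree sequence stores the genealogies of a set of sample genomes
along a recombining chromosome in four tables: **nodes** (haplotypes, with
a birth time in generations), **edges** (parent--child relationships over
half-open genomic intervals `[left, right)`), **sites** (positions with an
ancestral allele) and **mutations** (allele changes on a node at a site).
Between recombination breakpoints the edges whose intervals cover a point
define a *marginal tree*; adjacent marginal trees differ by a small number
of edge removals and insertions.

A single-site statistic in this framework is specified by two ingredients:

* **sample weights** $w$: a numeric vector (dimension $m$) attached to each
  sample.  The *subtree weight* $x(u)$ of a node $u$ in a tree is the sum
  of the weights of all samples descending from (and including) $u$.
  Indicator weights of a sample set make $x(u)$ a subtree sample count; a
  phenotype can be used directly as a weight.
* a **summary function** $f$: a real-valued function of a weight vector.
  $f$ is *strict* if $f(0) = f(w_\mathrm{total}) = 0$, so that parts of a
  tree ancestral to none or to all of the samples contribute nothing.
  Genetic variation carries no information about those parts of the tree,
  which is why site and branch statistics require strictness (an override
  flag exists for deliberate exceptions); node statistics do not.

Three dual modes evaluate the pair $(w, f)$:

* **Site**: at each site, alleles get *allele weights* -- the summed weight
  of the samples carrying them -- and the site contributes
  $\sum_a f(\bar x(a))$ over its alleles (only non-ancestral alleles if
  *polarized*).  Window values are sums over the sites in the window
  divided by the window length, so they are densities per unit of
  sequence.
* **Branch**: each branch contributes its length times
  $f(x(u)) + f(w_\mathrm{total} - x(u))$ (the complementary term is
  dropped if polarized), summed over branches, span-averaged over the
  trees overlapping the window, and divided by the window length.
* **Node**: for each node separately, the span-weighted average of
  $f(x(u))$ (plus the complement unless polarized) over the trees in the
  window.

Under neutral infinite-sites mutation at rate $\mu$ per unit time and
sequence length, a branch of length $\beta$ and genomic span $\ell$
receives a Poisson number of mutations with mean $\mu\beta\ell$, and each
mutation creates a site whose derived-allele weight is the subtree weight
of the branch's child.  Conditionally on the trees, therefore,

$$\mathrm{Branch}(f,w) = \frac{1}{\mu}\,
  \mathbb{E}\left[\mathrm{Site}(f,w)\mid \text{trees}\right],$$

and the law of total variance splits $\mathrm{Var}[\mathrm{Site}]$ into a
demographic term $\mu^2\,\mathrm{Var}[\mathrm{Branch}(f,w)]$ and a
mutational term $\tfrac{\mu}{j-i}\,\mathbb{E}[\mathrm{Branch}(g,w)]$ over a
window $[i,j)$.  Because the per-site contribution of a mutation on a
branch with subtree weight $x$ is $h(x) = f(x) + f(w_\mathrm{total}-x)$
(just $f(x)$ when polarized), the squared summary in the mutational term
is $g = h^2$, evaluated as a *polarized* branch statistic.  Writing the
term as "the branch statistic of $f^2$" is the common shorthand; for
symmetric summaries like diversity the two readings differ by a constant
factor, and the package implements the exact form, which is what
`variance_check()` verifies (and what the analytic single-branch case in
the test suite pins down).

## The incremental engine

`stat_compute()` makes one left-to-right pass over the edges.  Edge
*insertion* order is (left endpoint, parent time ascending) and *removal*
order is (right endpoint, parent time descending), with remaining ties
broken by parent then child id so the orderings are deterministic.  At
each breakpoint, removals are processed before insertions; removals detach
subtrees oldest-first and insertions reattach them youngest-first, which
bounds the root-ward propagation work.  The engine maintains

* the parent vector and branch lengths of the current tree,
* per-node subtree weights $x$, adjusted along the path from an edge's
  parent to its root when a subtree is cut or attached,
* per-node caches of $f(x(u))$ and $f(w_\mathrm{total}-x(u))$, invalidated
  only along those propagation paths, and
* for branch mode, the running sum $s = \sum_u \beta_u\,(\cdots)$,
  updated by subtracting a node's contribution before its weight changes
  and adding it back after.

Window accumulation flushes span-weighted contributions of the current
tree into every window it overlaps, so window breakpoints need not align
with tree breakpoints.  Gaps covered by no edge yield trees in which every
node is a root: they contribute no branch length and no sites, but keep
windowed averages well defined.

Site mode derives allele weights from subtree weights.  At a site whose
mutations are nested (back or recurrent mutation), each mutation's subtree
weight is moved from the allele it overrides -- its parent mutation's
derived state, located through the `parent` column or, failing that, a
genealogy walk -- onto its own derived state.  This never scans samples,
and the weights always sum to $w_\mathrm{total}$.  Sites carrying a single
fresh mutation (the overwhelming majority under infinite sites) are
evaluated in one vectorized batch per tree; summary functions therefore
use a column-wise contract (an $m \times k$ matrix in, $k$ values out).

Numerical policy: the running sum is a plain floating-point accumulator;
`verify = TRUE` recomputes it from scratch at every tree and stops if the
incremental value drifts beyond $10^{-6}$ relative, which bounds
cancellation error on pathological inputs.  Strictness is checked
numerically at $0$ and $w_\mathrm{total}$ with tolerance $10^{-8}$.
Summary functions are responsible for their own removable singularities:
the trait-correlation summary defines $f = 0$ when the allele frequency
argument is 0 or 1.

Two open points are resolved as follows.  Trees need not contain all
samples (gaps, dangling subtrees): $w_\mathrm{total}$ is always the global
sum over samples, roots carry zero branch length, and the complementary
term of unpolarized statistics uses the global total.  Positions are
real-valued, and windowed site statistics normalize by real window length.

## Named statistics

| statistic | weights | summary | notes |
|---|---|---|---|
| `diversity` | $1_S$ | $x(n-x)/(n(n-1))$ | site: mean pairwise difference density; branch: twice mean pair TMRCA |
| `divergence` | $(1_{S_1}, 1_{S_2})$ | $\frac{x_1}{n_1}(1-\frac{x_2}{n_2})$ | cross-pair difference density |
| `segregating_sites` | $1_S$ | $1-x/n$ if $x>0$, else 0 | a site with $k$ alleles adds $k-1$ |
| `f4` | four indicators | $p_1(1-p_2)p_3(1-p_4) - (1-p_1)p_2p_3(1-p_4)$ | unpolarized sum equals $(p_1-p_2)(p_3-p_4)$; BABA$-$ABBA, valid for polyallelic sites |
| `trait_correlation` | $(z, 1/n)$ | $x_1^2/(2x_2(1-x_2)n(n-1))$ | squared phenotype--allele correlation per site |
| `ancestry_proportions` | $1_S$ | $x/n$, polarized node mode | non-strict, permitted for node statistics |

`tajimas_d` is a ratio of two additive site statistics computed in one
engine pass: $\pi$ (diversity times window length) and the count $S$ of
sites with at least two alleles, combined with the standard 1989 constants
$a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$; windows with $S = 0$ give `NaN`
rather than an error.  $S$ counts segregating sites, not minimum
mutations, which differ only when a site has more than two alleles.

The phenotype for `trait_correlation` is standardized internally to mean
zero and unit *sample* variance (denominator $n-1$).  With that
normalization the site value at a biallelic site equals the squared sample
correlation between the phenotype and the derived-allele indicator
exactly, which is the property the test suite verifies against a direct
correlation oracle; normalizing with denominator $n$ would miss the
$(n-1)$ in the summary's denominator by a factor $n/(n-1)$.

Polarized variants of diversity, divergence and f4 are available but
non-default: their definitions are unpolarized by construction, and the
polarized forms are only meaningful when ancestral states are trusted.

## Synthetic data: what it emulates and what it does not

`sim_single_pop()` is a continuous-time Hudson coalescent with
recombination (an ancestral-recombination-graph simulation) for a single
panmictic population: pair coalescence rate $1/(2N_e)$ per generation,
recombination rate $r$ per base per generation acting on each lineage's
ancestral span.  It produces correlated adjacent trees -- the regime the
incremental engine exists for -- with times in generations.  A scale
guard rejects runs expected to produce more than a few thousand
recombination events; the package targets desk-scale verification, not
chromosome-scale production simulation.

`sim_structured()` draws statistically *independent* loci from a
structured coalescent with per-population sizes, symmetric migration
switches, and population mergers.  Independence across loci replaces the
linkage structure of a recombining genome: expectations of statistics are
unchanged (they are per-locus expectations), but the noise structure
along the genome is not reproduced.  This is a deliberate scaled-down
design: the four-population admixture analysis reproduces the
*expectation* of branch f4 with small samples (expectations of f4 do not
depend on sample size), at a tiny fraction of the cost of the original
100 Mb, 1000-diploid setting.

The shipped demography (`f4_admixture_demography()`, also as a parsed
fixture in `inst/extdata/`) reads the split-and-migration scenario as:
population 2 splits from 1, then 3 from 2, then 4 from 3, each N
generations apart, with symmetric migration $4/N$ between populations 2
and 3 during the final N generations before sampling.  The prose being
reproduced is ambiguous about the source of each split; this reading is
the one in which mid-tree gene flow between the inner populations drives
f4(1,2;3,4) negative, and the acceptance tolerance is correspondingly
generous (the quantity is only characterized as "around" a value).
Defaults are N = 1000 and two haploid samples per population; 2000 loci
give a Monte-Carlo standard error of roughly 45 generations on the mean.

`random_tree_sequence()` draws independent random genealogies (with
occasional multifurcations) over random breakpoints.  Because adjacent
trees share nothing, every breakpoint exercises the full
remove-all/insert-all path of the engine, complementing the
few-edges-change regime of the recombining simulator.  Passing tests on
both generators shows the engine handles arbitrary valid edge replay, but
none of the generators emulate selection, gene conversion, variable rates
along the genome, or mutation-model realism beyond infinite sites
(`drop_mutations(discrete = TRUE)` adds integer positions with collision
rejection, nothing more).

`drop_mutations()` implements the infinite-sites model used by the
duality: Poisson mutation counts with mean $\mu$ times total branch area,
edges chosen proportionally to area, positions uniform within the edge's
interval, each at a fresh site with ancestral state "0" and derived state
"1".  Mutation times are not modeled; no statistic here needs them.

## Verification strategy and problem sizes

The central correctness property is that the incremental engine and
`naive_stats()` -- an independent implementation that rebuilds every tree,
recomputes subtree weights by per-sample traversal, and sums allele
weights directly over decoded genotypes -- agree to $10^{-9}$ relative on
random configurations across all modes, window layouts and polarizations.
The test suite runs 200 such configurations, plus exact window
additivity, allele-weight conservation, f4 antisymmetry, and closed-form
coalescent calibration (pair TMRCA $2N_e$; total branch length
$4N_e H_{n-1}$) over 2000 replicates.

The Monte-Carlo checks run at fixed desk-scale conditions chosen to keep
the whole suite in minutes: a 20-sample genealogy with population-scaled
recombination $\rho L = 20$ and a mutation rate tuned to about 5000
mutations per replicate, 200 replicates for the duality z-scores and 500
for the variance decomposition.  The $|z| < 4$ thresholds are a test-suite
policy giving well under 1% false-failure probability per check, not a
claim about the science.

## Known limitations

* Pure R implementation: suitable for the tens-of-samples,
  thousands-of-trees scale it targets; it does not attempt the
  large-cohort performance of compiled tree-sequence toolkits.
* Two-site statistics (linkage disequilibrium), haplotype statistics, and
  covariances between site statistics are out of scope; the covariance of
  two site statistics is *not* the product of the branch statistics.
* Trees are iterated left-to-right only; there is no random access.
* The structured simulator guarantees termination only through a timeout
  guard; a demography whose lineages can never meet errors out rather
  than running forever.
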