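---
title: "Estimating individual semantic networks from repeated fluency data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individual semantic networks from repeated fluency data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluenet)
```

## The problem

A semantic fluency task asks a person to name as many members of a category
(here, animals) as they can in a fixed time. The order in which items come
out is not random: retrieval is well described as a search process over a
semantic network in which concepts are nodes and associations are edges.
`fluenet` implements the full analysis chain used to ask whether individual
differences in that network relate to behavioral traits such as creativity:
clean repeated fluency lists, estimate one network per participant, measure
the networks, and test associations with default Bayes factors.

## The retrieval model and its likelihood

The generative model is a *censored random walk*. The first retrieved item is
drawn with probability proportional to its degree,

$$P(x_1) = \frac{\deg(x_1)}{\sum_v \deg(v)},$$

and the walk then moves uniformly at random over the neighbors of the current
node. Revisits to already-produced items are suppressed from output
("censored"), so the observed list is the sequence of first visits. Lists are
time-limited prefixes, so truncation carries no stopping penalty, and a
participant's several lists are independent restarts.

Each list factor is a first-passage probability of an absorbing Markov
chain: with $V$ the set of already-produced items and $U$ the rest, split the
transition matrix into $T_{VV}$ (moves within $V$) and $T_{VU}$ (moves into
$U$). The probability that a walk at $c \in V$ first enters $U$ at node $u$
is row $c$ of $(I - T_{VV})^{-1} T_{VU}$. `first_hit_distribution()` computes
this by a linear solve, never by an explicit inverse, and
`list_log_likelihood()` chains the factors in log space — both matter
numerically for lists of 30–45 items.

## The network prior and the MAP search

The prior over candidate networks is an independent Bernoulli prior per node
pair anchored to a reference association network: probability 2/3 for a pair
that is an edge of the reference, 2/5 for a pair of reference nodes that is
not, and 1/2 when either node is unknown to the reference (`prior_spec()`,
all three configurable). The package ships a small toy reference over its
bundled animal lexicon; any reference edge list can be supplied in its place,
and per-participant vocabularies are the union of that participant's cleaned
items.

`estimate_network()` maximizes likelihood times prior. The search is a pure
hill-climb over single-edge toggles:

* initialization is the consecutive-adjacency graph (`build_init_network()`),
  which makes every observed transition an edge and hence the starting
  likelihood finite;
* each sweep visits all vocabulary pairs in seeded-random order and accepts a
  toggle only if it improves the log posterior by more than a tolerance
  (default `1e-12`; ties reject);
* the search stops after a full acceptance-free sweep, or after `max_sweeps`
  (default 100; in practice convergence takes well under ten sweeps).

Published descriptions of this estimator family call only for a stochastic
search, without fixing a schedule; the seeded sweep hill-climb is this
package's concrete choice. It guarantees the returned network never scores below the
initialization and is bit-reproducible given the seed, but it is a local
maximizer, not an exhaustive one.

Internally the sweep is evaluated in compiled code: per list and step the
inverse $W = (I - T_{VV})^{-1}$ is grown by block inversion as the visited
set grows, and a candidate edge toggle — which changes at most two rows of
$[T_{VV} \mid t_u]$ — is scored through a rank-$\le 2$ Woodbury correction in
$O(k)$ per affected step. Any toggle that screens as an improvement is
confirmed by a full guarded recomputation before being committed, so
screening round-off cannot accumulate along the accepted trajectory, and
degenerate systems (a visited set sealed off from the rest of the graph)
are detected and scored as impossible.

## Cleaning rules

Cleaning is deliberately minimal and deterministic (`clean_lists()`):
responses are lower-cased and whitespace-canonicalized, out-of-lexicon
responses are removed as intrusions, and within-list repeats are removed as
perseverations, preserving order otherwise. No spell correction or plural
folding is attempted; intrusion status is purely lexicon membership, so the
lexicon is the user's single point of control. How spelling variants of the
same animal should be reconciled is left to the lexicon author — the package
takes no position.

## Network metrics and their conventions

`network_metrics()` computes, per network: average shortest path length
(ASPL) and the small-world index on the largest connected component
(ties broken toward the component containing the lexicographically smallest
node); average local clustering and best-found modularity on the full graph;
plus node/edge/component counts. Conventions worth stating:

* *Clustering* is the average local (Watts–Strogatz) coefficient, with
  degree-<2 nodes contributing 0 — the dominant convention in this
  literature; global transitivity is available via a switch.
* *Optimal modularity* is approximated by seeded multi-restart multilevel
  (Louvain) maximization (default 10 restarts over random vertex orders),
  floored at the single-community partition's score of 0; exact modularity
  maximization is infeasible in general.
* *Small-world index* $\sigma = (C/\bar C_{rand})/(L/\bar L_{rand})$ uses a
  $G(n, m)$ Erdős–Rényi null with matched node and edge counts (default 100
  replicates, largest component per replicate, triangle-free replicates
  redrawn up to a retry cap so the denominator stays defined). It needs at
  least 4 nodes and 3 edges; below that the pipeline reports `NA`.

Whether clustering and modularity should also be restricted to the largest
component is not settled in the source literature; this package computes them
on the full graph and documents the switch.

## Default Bayes factors

`bayes`-module tests are computed from summary statistics, not raw data, so
any published (t, n) or (r, n) pair can be re-analyzed.

* `jzs_ttest_bf()`: the JZS independent-samples t-test. Under H1 the
  standardized effect $\delta$ has a Cauchy prior (default scale
  $\sqrt{2}/2$); the Bayes factor is the ratio of the noncentral-t marginal
  likelihood of the observed $t$ (noncentrality $\delta\sqrt{n_1 n_2/(n_1 +
  n_2)}$, integrated by adaptive quadrature split at the likelihood peak) to
  the central-t density. The pooled-variance (Student) form is used
  throughout, matching the degrees of freedom reported in the target
  analyses.
* `pearson_bf()`: the correlation test uses the exact sampling density of the
  Pearson $r$ given the population correlation $\rho$ — its
  Gaussian-hypergeometric form, with $_2F_1$ evaluated by its power series
  under explicit convergence control and the integrand exponentiated in log
  space around its mode so large $n$ cannot overflow. The default prior on
  $\rho$ is the stretched beta of width 1, i.e. uniform on $(-1, 1)$.
* Directional tests truncate and renormalize the symmetric prior to a
  half-line (a factor of 2), for both test families. The two one-sided Bayes
  factors therefore average exactly to the two-sided one — a property the
  test suite checks against quadrature tolerance.

Both routines are validated against independent oracles in the test suite: a
fine-grid trapezoid quadrature for the t-test and a Monte-Carlo marginal
likelihood for the correlation test. Reported values reproduce published
Bayes factors to a few percent when the published inputs are exact; where
only rounded summaries (2–3 significant digits) are available the
reproduction error is bounded by the input rounding, which for Bayes factors
at large $|t|$ can reach tens of percent — the local log-slope
$\partial \log \mathrm{BF}/\partial t \approx 2$ near $|t| = 4$ amplifies a
$\pm 0.13$ rounding of $t$ into roughly $\pm 30\%$ of the Bayes factor.

## The synthetic cohort generator

`simulate_cohort()` generates the kind of dataset this analysis consumes, so
every stage is testable without any participant data. Its defaults encode the
study conditions the pipeline targets:

* 92 participants: monolingual $n=25$, English-Spanish (ES) $n=13$,
  Spanish-English (SE) $n=28$, plus $n=26$ proficiency-unclassified
  participants who join the correlation sample but not the labeled group
  comparisons;
* three lists per participant with group length means 42.1 (ES), 33.3 (SE)
  and SD 6.5; the monolingual and unclassified means (40) are not pinned by
  the published summaries and are set to native-language-like values;
* creativity means 14.5 (ES), 16.7 (SE), 15.6 (others), SD 6.5 — the SD is
  back-solved from the published $t(39) = 1.0$ for the 16.7 vs 14.5 group
  difference; intelligence is a 12-item matrix-reasoning-like integer score
  (mean 9, SD 2.5);
* intrusions (out-of-category tokens such as "house", "unicorn") and
  perseverations are injected at rates 0.005 and 0.01 per response,
  matching a sub-0.6% intrusion rate at cohort scale;
* each participant's ground-truth network is the largest component of a
  perturbed copy (edges dropped at 0.15, non-edges added at 0.005) of a
  shared 60-node Watts–Strogatz-style reference over the bundled animal
  lexicon — the same reference that anchors the estimation prior, mirroring
  the role of a group-level association network.

List lengths are fixed-length draws (Gaussian, clipped to at least 5 and at
most the component size) rather than simulated time budgets: the
censored-walk likelihood treats lists as prefixes, so length is ancillary to
the network inference.

Creativity and intelligence are tied to the realized per-participant
covariates (mean list length and the ground-truth network's metrics) through
a Gaussian copula. The *target correlations* are pooled, cohort-level
correlations: because the group score means themselves covary with group
fluency (SE participants have the highest creativity mean and the shortest
lists), the latent loadings are solved with that group-offset covariance
removed, via a short fixed point on the offset-dependent total variance.
Infeasible targets (implied residual variance below zero) error before any
data are generated. The all-null preset — every creativity–metric target at
zero, intelligence–creativity at 0.185 — reproduces the null world the
pipeline is designed to detect.

What the generator does *not* emulate: word frequency effects, semantic
subcategories (no clustering of "pets" vs "safari animals"), cross-language
lists, and any systematic group difference in network structure. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline recovers
the structure it assumes, not that real fluency data satisfy those
assumptions.

## Problem sizes used by the test suite

The package's property tests run at sizes chosen to exercise the claims
meaningfully while staying desk-scale: walk-sum oracle equivalence on every
graph with up to 5 nodes; 10^5 simulated walks for the generator/likelihood
cross-check; parameter recovery on 10-node truths with up to 50 lists over
50 seeds; and the null-world pipeline property on 20 replicates of the full
92-participant cohort with 30 small-world null replicates and 5 modularity
restarts per network during those replicates. The estimator itself is
exercised at the study's native scale (3 lists of 33–42 items, ~60-node
vocabularies) throughout.

## Known limitations

* The hill-climb is a deterministic local search; the published analyses used
  a stochastic-search implementation whose schedule is not public, so
  per-participant networks are faithful in model but not bit-identical in
  estimator.
* Group-level vocabularies (items a participant never produced) are not
  modeled; vocabularies are per-participant.
* The walk model has no jump or priming components; such extensions exist in
  the literature but are deliberately out of scope.
* Bayes factors recomputed from rounded published inputs inherit the input
  rounding; exactness is claimed only against the package's own oracles.
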