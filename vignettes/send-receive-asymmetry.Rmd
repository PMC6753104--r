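---
title: "Send-receive communication asymmetry: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Send-receive communication asymmetry: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcomm)
```

## The problem

Structural connectomes mapped with in vivo diffusion imaging are undirected:
tractography cannot resolve which way an axon points. Yet neural information
flow is directional. The observation this package builds on is that
*decentralized* communication models — signal-propagation rules that use only
local knowledge of the network — are asymmetric even on undirected networks:
the efficiency of sending from region $i$ to region $j$ can differ from the
efficiency of the reverse route, because the two endpoints occupy different
topological and geometric neighbourhoods. Quantifying that asymmetry
statistically across a cohort yields putative *senders* (regions biased
towards outgoing efficiency), *receivers* (incoming bias) and *neutral*
regions, without any knowledge of axonal directionality.

## Communication measures

All measures operate on a weighted network $W$ (affinity units, zero
diagonal) and return an $N \times N$ matrix whose $(i,j)$ entry is the
efficiency of communicating *from* $i$ *to* $j$.

**Connection lengths.** Path-based measures need costs, not affinities. The
remapping

$$L_{ij} = -\log_{10}\!\left(\frac{W_{ij}}{\max(W) + \min(W_{>0})}\right)$$

is monotone decreasing (strong connections are short), attenuates extreme
weights, and is strictly positive because the $\min(W_{>0})$ term keeps the
strongest connection away from zero length. Non-edges have infinite length.
When a cohort is thresholded to a target connection density, the transform
is applied to the *thresholded* matrix, so $\max$ and $\min_{>0}$ refer to
the retained weights; we treat the thresholded connectome as the object
under study throughout.

**Shortest-path efficiency** $E_{sp}(i,j) = 1/d(i,j)$, with $d$ the
shortest-path distance over $L$. On undirected networks this is symmetric —
it carries no directional information and serves as the reference measure.
The implementation enforces exact (bitwise) symmetry by taking the
elementwise minimum of the two directions, which are mathematically equal
and can differ only through floating-point summation order.

**Navigation (greedy routing).** From the current node, forward the signal
to the neighbour geometrically closest to the target; success on reaching
the target, failure as soon as any node is revisited. Navigation efficiency
is the reciprocal of the accumulated connection length along the realized
route (reciprocal hop count in the binary variant), and $0$ on failure —
failed routes stay in downstream averages as zeros, consistent with
$1/\infty$. Navigation needs node coordinates; no other measure does.

**Diffusion efficiency.** For an unbiased random walker with transition
probabilities $T_{ij} = W_{ij} / \sum_n W_{in}$, the expected number of hops
to first reach $j$ from $i$ is obtained per target from one linear solve:
zeroing column $j$ of $T$ (call it $T_j$) makes $j$ absorbing, and the
geometric series of survival probabilities closes to

$$H_{ij} = \sum_n \left[(I - T_j)^{-1}\right]_{in},$$

with $E_{dif}(i,j) = 1/H_{ij}$. The solve is restricted to $j$'s connected
component; cross-component pairs get $H = \infty$, $E = 0$. The test suite
checks this route against two independent oracles: the first-step linear
equations solved on the $(N-1)$-subsystem, and Monte-Carlo walker
simulation.

**Search information.** The probability that a walker spontaneously follows
the shortest path $\Omega_{ij}$ is the *product* of the transition
probabilities along it; search information is $SI_{ij} = -\log_2
P(\Omega_{ij})$ (bits) and the efficiency is its negation,
$E_{si} = -SI \le 0$.

## The asymmetry statistics

Given a cohort tensor $C \in \mathbb{R}^{N \times N \times K}$ (one
efficiency matrix per subject), the pairwise differential is
$\Delta(i,j,k) = C(i,j,k) - C(j,i,k)$ and the asymmetry statistic
$A(i,j)$ is the one-sample $t$ statistic of $\Delta(i,j,\cdot)$ against
zero ($K-1$ degrees of freedom, two-sided $p$). By construction
$A(i,j) = -A(j,i)$ exactly. Bonferroni correction controls the
$N(N-1)/2$ distinct pairs. A Wilcoxon signed-rank variant (the paired
analogue appropriate for a location test of $\Delta$ against zero) is
provided for robustness to non-normality; an unpaired rank-sum test is
available separately for group comparisons of node-level values.

The regional statistic aggregates each node's outgoing and incoming
efficiencies, $S(i,k)$ and $R(i,k)$, as means over the $N-1$ *other* nodes
— the diagonal is undefined for every measure, so the divisor is $N-1$
rather than $N$ — and tests $\delta(i,k) = S(i,k) - R(i,k)$ the same way,
with Bonferroni over $N$ regions. Significant positive (negative)
statistics classify senders (receivers). Reported aggregate send/receive
efficiencies average over subjects; for navigation the median is used
because failed-path zeros produce heavy-tailed distributions.

Subsystem analyses average the efficiency matrix over blocks,
$E'_{uv} = \operatorname{mean}\{E_{ij} : i \in M_u, j \in M_v\}$, excluding
the self-pairs $i = j$ from within-subsystem blocks for the same reason the
regional divisor is $N-1$. Downsampling is linear, so it commutes with
averaging over subjects.

For a *single* directed network (tract-tracing connectomes,
effective-connectivity estimates), where no cohort exists, the normalized
index

$$A(i,j) = \frac{E(i,j) - E(j,i)}{E(i,j) + E(j,i)} \in [-1, 1]$$

replaces the statistical test, with an option to mask node pairs sharing a
direct connection (single-connection routing is trivially symmetric, so
such pairs are uninformative under navigation). A regional reduction
applies the same normalization to each node's mean outgoing and incoming
efficiencies.

## Null models

Three randomized ensembles isolate which properties drive an observed
association: degree-preserving double-edge swaps (weights travel with their
edges); the same swaps constrained to keep total network cost — the summed
Euclidean length of all connections — within a relative tolerance (default
2.5%), with swaps that reduce the current cost deviation always accepted so
the ensemble anneals back if it drifts; and spatial repositioning, a
permutation of the existing coordinates over node identities, which
preserves topology and the coordinate multiset exactly (uniform resampling
in the bounding box is available behind a flag, but the permutation is the
more conservative reading). Empirical $p$-values use the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\text{null}})$.

## Synthetic data: what it emulates, and what it does not

`generate_geometric_cohort()` emulates the statistical structure the
analyses assume: nodes uniform in the unit cube, connection probability
decaying as $e^{-\lambda d}$ (default $\lambda = 3$ on unit-cube
distances), exact target density (default 15%, a standard connectome
thresholding level), log-normal weights inversely rank-coupled with
connection length (long connections weak), connectivity enforced, and
subjects formed by multiplicative log-normal weight noise around the group
network (default `sdlog` 0.05, i.e. roughly 5% weight noise). Defaults of
$N = 60$ nodes and $K = 20$ subjects keep a full pipeline run in seconds.

`generate_directed_geometric_network()` plants ground-truth polarity on a
reciprocal geometric substrate: 15% of nodes receive extra outgoing-only
connections (senders), 15% extra incoming-only connections (receivers), and
the rest extra reciprocal ones so total connectivity stays comparable. The
default planting strength (extra connections to 35% of the network per
planted node) is deliberately strong: it is meant to define a regime where
recovery *should* succeed, not to probe the detection threshold.

These generators reproduce the qualitative features that matter for the
machinery — spatial embedding, density, weight-distance coupling,
subject-level noise, planted directionality — and nothing else. They do not
match empirical degree distributions, hemispheric structure, community
organization, or tractography biases; passing tests demonstrate that the
machinery is correct and calibrated, not that any particular empirical
finding generalizes.

## Numerical choices

* **Search information, product vs sum.** $P(\Omega)$ must be a probability
  for $-\log_2 P$ to be information; it is computed as the product of
  per-step transition probabilities. An optional mode sums the traversal
  probability over all co-optimal shortest paths via dynamic programming on
  the shortest-path DAG; with weighted lengths exact ties are rare and the
  two modes coincide.
* **Determinism.** Shortest-path ties settle the lowest-index node first
  and keep the lowest-index predecessor; navigation distance ties pick the
  lowest-index neighbour; density-threshold ties at the cutoff break
  lexicographically by (row, column). All generators and null models are
  bit-reproducible given a seed, and restore the caller's RNG state.
* **Degenerate statistics.** Zero-variance differentials with nonzero mean
  (reachable on tiny fixtures) map to a large finite sentinel ($10^{15}$)
  with $p = 0$; all-zero differentials give $A = 0$, $p = 1$.
* **Failure encoding.** Failed navigation and unreachable walkers encode as
  infinite path length / hitting time and efficiency 0; unreachable search
  information uses a $-\infty$ sentinel. Self-pairs are stored as 0 and
  excluded from every aggregation.
* **Diagonals.** Weight-matrix diagonals are forced to zero on load; all
  measures are defined between distinct regions only.

## Problem sizes

The test suite exercises exact oracles on graphs of up to 15 nodes
(exhaustive path enumeration, first-step hitting-time equations,
$10^5$-walker Monte-Carlo runs), calibration of the pairwise test on 200
replicate cohorts of $N = 20$, $K = 20$, and recovery/null analyses on
geometric cohorts of 30–60 nodes with 199-member null ensembles. These
sizes were chosen so the full suite runs in about a minute while leaving
every statistical check adequately powered; the implementation itself
handles the connectome scales the measures are normally applied to
(hundreds of nodes) without modification.

## Limitations

Send-receive asymmetry is a cohort-level construct; the package deliberately
provides no subject-level asymmetry score. The single-network index is not a
statistical test. Asymmetry is weakly defined between directly connected
node pairs (hence the exclusion option). Navigation outcomes depend on the
choice of distance — Euclidean centroid distance here; fibre-length
distances would need to be supplied as a precomputed matrix. Estimating
directed couplings from functional data is out of scope: directed matrices
enter only as externally produced inputs.
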