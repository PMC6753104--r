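# netcomm

Send-receive communication asymmetry in weighted brain networks.

Structural connectomes mapped with diffusion MRI are undirected — the
imaging cannot resolve axonal direction — yet neural signalling is
directional. **netcomm** infers putative signalling directionality from
undirected, weighted, spatially embedded networks by exploiting a property
of *decentralized* communication models: unlike shortest-path routing,
greedy spatial navigation, random-walk diffusion and search information are
asymmetric even on undirected networks, because the two endpoints of a
route occupy different topological and geometric neighbourhoods.

The package is aimed at network neuroscientists (and network scientists
generally) who have per-subject connectivity matrices, node coordinates and
optionally a subsystem partition, and want to classify nodes as senders,
receivers or neutral, map pairwise directionality, and check findings
against randomized-network null models.

## The core statistic

For a cohort of `K` subjects, let `C(i, j, k)` be the communication
efficiency from node `i` to node `j` in subject `k` under one of four
measures:

| tag | measure | efficiency |
|-----|---------|-----------|
| `sp` | shortest paths | `1 / d(i, j)` — symmetric reference |
| `nav` | greedy spatial navigation | `1 / Λ(i, j)`; `0` on failure |
| `dif` | random-walk diffusion | `1 / H(i, j)` (mean first-passage hops) |
| `si` | search information | `−SI(i, j) = log2 P(Ω(i, j))` |

The pairwise send-receive asymmetry is the one-sample *t* statistic of the
differential `Δ(i, j, k) = C(i, j, k) − C(j, i, k)` across subjects, giving
an antisymmetric matrix `A` with `A(i, j) = −A(j, i)`, Bonferroni-corrected
over the `N(N−1)/2` node pairs. The regional variant tests the difference
between each node's mean outgoing and mean incoming efficiency and
classifies significant nodes as senders (`a > 0`) or receivers (`a < 0`).
For single directed networks (tract tracing, effective connectivity) the
normalized index `(E(i,j) − E(j,i)) / (E(i,j) + E(j,i))` replaces the test.
Weights are remapped to connection lengths by
`L = −log10(W / (max(W) + min(W>0)))` before any path-based measure.

Degree-preserving, cost-preserving and node-repositioning null models, an
empirical p-value helper, and seeded generators for spatially embedded
cohorts (and directed networks with planted polarity) round out the
framework. See `vignette("send-receive-asymmetry")` for the models,
assumptions and design decisions.

## Worked example

A six-node spatially embedded toy network makes the asymmetry visible by
hand. Greedy navigation from `i` to `j` routes `i-c-b-j` (3 hops), but the
return route is `j-b-i` (2 hops):

```r
library(netcomm)

fix <- make_toy_network()
nav <- navigate(fix, lengths = unit_length_matrix(fix))
round(navigation_efficiency(nav, binary = TRUE)[c("i", "j"), c("i", "j")], 2)
#>     i    j
#> i 0.0 0.33
#> j 0.5 0.00
```

Navigating is half again as efficient from `j` to `i` (0.5) as from `i` to
`j` (0.33), although every connection is undirected.

At cohort scale, with a synthetic spatially embedded cohort standing in for
per-subject connectomes:

```r
sim  <- generate_geometric_cohort(n_nodes = 40, n_subjects = 25,
                                  noise_sd = 0.3, seed = 10)
tens <- cohort_communication(sim$subjects, "dif")
res  <- pairwise_asymmetry_test(tens)
summary(res)
#> Send-receive asymmetry (t test, bonferroni correction)
#>   nodes: 40   subjects: 25   pairs: 780
#>   significant pairs at alpha = 0.05: 708 (90.8%)
#>   statistic range: [-74.1, 7.43e+03]

roles <- regional_asymmetry_test(tens)
table(roles$role)
#>  neutral receiver   sender
#>        3       13       24
```

Most node pairs communicate significantly more efficiently in one direction
than the other, purely through the interaction of the diffusion model with
the undirected topology; the role table pins the bias to individual nodes.
`subsystem_downsample()` aggregates the tensor to a partition,
`single_network_asymmetry()` handles directed matrices, and
`run_pipeline()` drives the whole workflow (with provenance and logging)
from one YAML/JSON config; `inst/cli/netcomm.R` wraps the same functions
for shell use.

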