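---
title: "Ranking influential spreaders with KTD: model, evaluation protocol, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking influential spreaders with KTD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ktdrank)
```

## The problem

In epidemic and information-spreading processes on networks, a few nodes
account for a disproportionate share of eventual outbreak size. K-shell
(coreness) decomposition is the classic low-cost way to find them: peel
degree-1 nodes until none remain (shell 1), then degree-2 nodes (shell 2),
and so on; nodes surviving into deeper shells sit closer to the network core
and tend to be better spreaders. Its weakness is coarseness — a 34-node
network may have only 4 shells, so most nodes tie.

The KTD score implemented here refines k-shell in two steps while staying
near-linear in cost.

## The model

**Decomposition with a global iteration factor.** During peeling, every
*pass* (simultaneous removal of all nodes whose residual degree is at most
the current shell index k) increments a global round counter that never
resets between shells. Each node records its shell `KS` and the round `IT`
in which it fell. Peripheral nodes peeled early carry small `IT`; the core
is removed in the final round `ITmax`. Because shell k is exhausted before
shell k+1 starts, `KS` order is always respected: `KS_i < KS_j` implies
`IT_i < IT_j`.

**Direct influence.** With `deg` the *original* degree and the maxima taken
over the whole network,

$$C_i = KS_i + \frac{IT_i}{IT_{max}}\cdot\frac{deg_i}{deg_{max}}.$$

The refinement term lies in (0, 1], so it separates nodes within a shell
without ever reordering shells.

**Final influence (KTD).** Direct influences are aggregated over the
original graph's neighborhoods:

$$E_i = C_i + \sum_{j\in N_i} C_j,$$

which separates even nodes with identical `(KS, IT, deg)` whenever their
neighborhoods differ. `table1_fixture()` ships an 18-node worked example
illustrating exactly these cases (two nodes alike in `(IT, KS)` but not
degree; two alike in all three but with different neighbors). The example's
edge list is not recoverable from the table — its printed degrees sum to an
odd number — so the fixture feeds the scoring layer directly and is never
recomputed from a graph.

```{r}
g <- karate_graph()
head(sort(ktd_score(g)$scores, decreasing = TRUE), 5)
```

## Evaluation stack

* **Monotonicity** $M(R) = \big(1 - \sum_r n_r(n_r-1) / (N(N-1))\big)^2$
  over dense ranks measures how finely a method separates nodes (1 = all
  distinct, 0 = all tied). It is invariant under monotone transforms of the
  scores, so normalization conventions don't matter.
* **CCDF and rank-frequency** summaries expose the same tie structure as
  plottable curves.
* **SIR ground truth.** A discrete-time
  susceptible–infected–recovered simulation assigns each node a spreading
  power: the mean final recovered count over repeated runs seeded at that
  node alone. Method rankings are scored against this ordering with the
  **Kendall rank correlation** (tau-a is the plain pair-concordance form;
  tau-b corrects for ties).
* **Epidemic threshold** $\beta_{th} = \langle k\rangle/\langle k^2\rangle$,
  the mean-field outbreak condition; spreading experiments run slightly
  above it so that outbreak sizes vary informatively.

```{r}
network_summary(g)
monotonicity(ktd_score(g))
```

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `beta` | per-contact infection probability | `1.1 * beta_th(g)` | "slightly supercritical"; small enough that rankings differ |
| `gamma` | per-step recovery probability | 1 | each node infectious exactly one step — the convention of the original k-shell spreading studies; the top-k seed experiments use 0.5 |
| `reps` | repetitions per node / seed set | 100 | the standard protocol size; raise to tighten Monte-Carlo error |
| `tol_digits` | rounding before tie grouping | 10 | betweenness/closeness are floating point; exact-equality grouping is brittle (see below) |

## Numerical and design choices

* **SIR update rule.** Synchronous, infect-then-recover: each step, every
  infected node exposes each susceptible neighbor independently with
  probability beta, then nodes infected *before* the step recover with
  probability gamma. Newly infected nodes cannot recover in their infection
  step. This makes the `beta = 1, gamma = 1` limit an exact breadth-first
  wave, which the tests exploit as a deterministic oracle. The literature
  is usually silent on this convention; it is declared here, not inferred.
* **Tie handling in rankings.** Scores are rounded to 10 decimals before
  dense-rank grouping. This is deliberate: grouping raw doubles by exact
  equality can split mathematically tied nodes on accumulation-order noise.
  Karate betweenness is the cautionary example — two nodes tie exactly at
  35/3 + 25/2 + ... in exact arithmetic, and whether a library's
  floating-point result splits them changes M(bc) from 0.7723 to 0.7754.
  Rounded grouping reports the mathematically correct tie structure.
* **Original degrees in Eq. C.** The degree entering the refinement term is
  the full-graph degree, not the residual degree at removal time (a node
  whose degree has dropped to 0 when peeled still contributes its original
  connectivity).
* **Isolated nodes** get shell 0 in a first removal round; benchmark
  networks have none, but the contract is total.
* **tau-b as headline.** The printed pair-concordance formula is tau-a, but
  SIR spreading powers and several centralities tie heavily, where tau-a is
  bounded away from 1. Both variants are computed; `compare_methods()`
  reports both, and tau-b is the default elsewhere, matching standard
  statistical software.
* **Betweenness/closeness normalization** is left at igraph's raw values:
  every reported metric is rank-based, so any strictly monotone rescaling
  gives identical results (property-tested).
* **ks+ baseline** is implemented as `KS + deg/deg_max` — the refinement of
  coreness by degree relative to the maximum degree. Other published
  k-shell refinements (iteration-factor-weighted variants, local-global
  hybrids, clustering-based scores) are *not* reimplemented from secondary
  descriptions; `resolve_method()` accepts plug-in scoring functions so
  they can be compared when their reference implementations are available.
* **RNG scheme.** `spreading_power()` derives one sub-seed per node from
  the master seed via an integer hash, so per-node results are reproducible
  and independent of the order nodes are visited.

## What the synthetic generators do and do not cover

Property tests run on Erdős–Rényi and Barabási–Albert graphs (20–300
nodes), plus paths, cycles, stars, cliques and random recursive trees.
These exercise degree heterogeneity, shell depth from 1 (trees) to n−1
(cliques), disconnectedness, and automorphic symmetry. They do **not**
emulate the community structure, degree–degree correlations, or
high clustering of real social networks — so a passing suite certifies the
algorithmic contracts (decomposition correctness, score formulas, simulator
limits, metric identities), while the benchmark claims about real networks
are checked only on the bundled karate club network (34 nodes, 78 edges),
whose summary statistics, per-method monotonicity values, and
KTD-beats-degree-and-coreness Kendall ordering all reproduce. The larger
benchmark networks (dolphins, jazz, USAir, ...) are deliberately not
vendored; `fetch_network()` loads and validates a locally downloaded copy.

Problem sizes in the test suite (up to 300-node graphs, 10^5 single-edge
repetitions, 1000 repetitions per karate node) were chosen so the whole
suite completes in a few minutes on one core while keeping Monte-Carlo
standard errors well inside the asserted tolerances.

## Known limitations

* The SIR simulator is discrete-time and synchronous only; no
  continuous-time (Gillespie) dynamics, SIS/SEIR variants, or immunization
  strategies.
* Kendall tau uses an O(n²) vectorized pair count — fine for the network
  sizes here, quadratic memory for very large graphs.
* Directed, weighted, and temporal semantics are out of scope; such inputs
  are coerced to simple undirected graphs with a warning.
* Exact Kendall tau values against SIR ground truth depend on unstated
  simulation conventions (update order, gamma); only the *ordering* of
  methods is treated as a reproducible claim.
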