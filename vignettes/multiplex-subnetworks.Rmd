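---
title: "Detecting FDR-bounded perturbed subnetworks on multiplex PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting FDR-bounded perturbed subnetworks on multiplex PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of the science it implements: the
model, its assumptions, the parameters that matter, the numerical choices,
and what the synthetic benchmark does and does not establish.

## The model

### Multiplex random walk

A set of PPI networks is modelled as a multiplex network
`M = (VM, EM, V, L)`: the physical nodes `V` are the union of all gene
sets, each layer `α ∈ L` holds a copy of its input network's edges, and
every gene `i` owns one state node `i_α` per layer — including layers where
the gene was never observed. This is deliberate: the point of the multiplex
model is that a gene's evidence in one network can stand in for missing
topology in another, which is what lets an incomplete context-specific
network borrow structure from genome-scale ones.

The walk used throughout is the *classic* random walk: the weighted
adjacency `A` contains intralayer edges at their layer weight `w_α` and
interlayer edges of weight 1 between every pair of a gene's state nodes,
and `T = D⁻¹A`. Because the walk is a reversible walk on an undirected
weighted graph, its stationary distribution is degree-proportional,
`p(i_α) = deg(i_α)/Σ deg`. The package computes `p` in closed form; power
iteration survives only as an independent oracle in the test suite (on the
lazy walk `(I + T)/2`, since small multiplexes can be bipartite and plain
iteration then oscillates). The generalized conductance of a state-node set
`S`,

```
Φ(S) = Σ_{iα∈S} Σ_{jβ∉S} T[iα,jβ] p[iα] / Σ_{iα∈S} p[iα],
```

is the stationary outflow relative to the mass inside. For this walk the
normalizers cancel and `Φ(S) = cut(S)/volume(S)` exactly, which is how it
is evaluated (the tests verify the identity term by term to 1e-12).

Assumptions worth stating: networks are undirected and unweighted within a
layer (weights act per layer only); gene identifiers are matched as trimmed,
case-sensitive strings — symbol-alias curation is upstream of this package.

### Two-groups local FDR

Gene p-values are transformed one-sidedly, `z = Φ⁻¹(1 − p)` (inputs are
MutSig-style significance p-values, so small p means perturbed), clipped to
`[1e-15, 1 − 1e-15]` to keep z finite. The marginal density `f(z)` is
estimated by Lindsey's method — histogram counts on 120 bins spanning
`[min(z) − 0.1, max(z) + 0.1]`, Poisson regression on a degree-7 polynomial
basis — and the null `f0` is standard normal by default, with an
empirical-null option (centre/scale from the central half of the z range)
for data with a distorted bulk. The null proportion `π₀` is the largest
constant with `π₀ f0 ≤ f` over the central 50% of the z range, capped at 1;
then `lfdr(i) = min(1, π₀ f0(z_i)/f(z_i))`. A subnetwork's estimated FDR is
the mean lfdr of its distinct physical genes, so the bound `B` has the
interpretation "at most a fraction B of reported genes are expected to be
null".

The estimator needs a few hundred p-values to be stable (it warns below
200). If the Poisson fit fails to converge, a kernel density with an
isotonic tail correction is substituted with a warning — a deliberately
conservative fallback, not the primary path.

### Local graphs by PPR push

Conductance alone does not force internal density, so the search is
confined to a dense local graph around each seed. Residual mass `1/|L|` is
placed on each of the seed's state nodes and pushed through `T` with
continuation parameter `c = 0.998` until every residual satisfies
`r(u) ≤ ε·deg(u)`; the per-state-node score error is then at most
`ε·deg(u)`. The parameter 0.998 is the *continuation* (walk) probability —
a restart probability of 0.998 would make exploration absurdly local, so
the package follows the local-clustering literature's reading. The ε
schedule starts at `1/(50K)` and divides by 10 until the score vector has
at least `K` nonzeros or ε reaches 1e-10 (the seed's component may simply
be smaller than `K`; then the whole component is used and a warning
emitted). The top-`K` state nodes by raw PPR score are kept (ties broken by
gene identifier then layer index; degree-normalized ranking is available
behind a flag) and the selection is augmented to layer-completeness. Push
order is largest residual-to-degree ratio first with deterministic
tie-breaking, scores and residuals stay sparse, and the push state is
resumable across ε rounds, so repeated calls never restart from scratch.

### The search: Dinkelbach over MILPs

Within a local graph the problem is: find the gene set `P` containing the
seed such that `S = P × L` (the cover constraint — every chosen gene is
taken in *all* layers, which is what makes a subnetwork "supported by all
networks") minimises `Φ(S)` subject to `FDR(P) ≤ B` and connectivity.
Because state nodes move in per-gene blocks, the program collapses to one
binary `x_i` per gene with coefficients

* `c_ij` — summed layer weights of edges between local genes `i, j`
  (cut when exactly one endpoint is selected),
* `b_i` — intralayer weight from `i` to genes outside the local graph
  (always cut when `i` is selected),
* `d_i` — full multiplex degree of `i`'s state nodes (volume; interlayer
  edges contribute to volume but never to the cut).

Then `Φ = N(x)/D(x)` with `N = Σ c_ij|x_i − x_j| + Σ b_i x_i`,
`D = Σ d_i x_i`, exactly. The fractional objective is minimised by
Dinkelbach iteration: solve `min N(x) − λD(x)`, update `λ ← N(x*)/D(x*)`,
stop when the parametric optimum is ≥ −1e-9 (λ is then the optimal ratio;
λ is non-increasing across iterations and the loop is capped at 50, though
5–10 iterations are typical). Each subproblem is a pure MILP: `|x_i − x_j|`
is linearized with continuous `y_ij` bounded below by `±(x_i − x_j)` (the
upper bounds are unnecessary since cut coefficients are nonnegative and the
objective is minimised), and connectivity is enforced by single-commodity
flow on the physical adjacency — the seed supplies `Σ_{u≠s} x_u` units,
every selected gene consumes one, and arcs of capacity `n − 1` are gated by
the selection variables at both ends. Gene-level connectivity is equivalent
to state-level (`Tadj`) connectivity under the cover constraint, because
interlayer edges always link a gene's copies; running the flow on genes
shrinks the MILP |L|-fold. A Dinkelbach subproblem was chosen over a single
Charnes–Cooper transformation because it keeps every subproblem a plain
MILP with an unchanged constraint matrix.

The MILPs are solved by HiGHS branch-and-bound via `scipy.optimize.milp`,
called through a bundled Python helper (`inst/python/milp_dinkelbach.py`)
with JSON interchange — one interpreter invocation per seed, the Dinkelbach
loop running inside it. The MIP gap is 0 for instances of up to 40 genes
and 1e-6 above; the per-seed wall budget defaults to 600 s, after which the
best incumbent is returned (status `incumbent`), falling back to the seed
alone (`singleton-fallback`) if nothing feasible was found. The test suite
checks the whole chain against exhaustive enumeration of all connected,
seed-containing, FDR-feasible subsets on instances small enough to
enumerate.

One boundary case is handled explicitly: if the seed's component spans the
entire multiplex, selecting *every* gene would make `S` the whole state
space, where the conductance ratio is undefined (zero cut over full
volume); that selection is excluded by one extra constraint. In real use
the local graph is a small fraction of the network and the case never
arises.

Seeds are processed in descending order of how many *other* seeds they
neighbour in the aggregated (union) network, ties lexicographic, and a seed
already contained in an earlier subnetwork is skipped — seeds inside the
same perturbed module thus produce one subnetwork, not many near-copies.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `B` | 0.1 | fraction | subnetwork FDR bound; also the seed threshold (`lfdr < B`) |
| `K` | 400 | state nodes | local-graph exploration size (see scaling note below) |
| `teleport` | 0.998 | probability | PPR continuation parameter `c` |
| layer weight `w_α` | 1 | — | > 1 emphasises one network's structure |
| `interlayer_weight` | 1 | — | coupling between a gene's copies (see below) |
| `df`, `bins` | 7, 120 | — | Lindsey density fit (polynomial degree, histogram cells) |
| `time_limit` | 600 | s | per-seed solver budget |

The interlayer edge weight is a genuine model choice with no canonical
value: interlayer edges exist solely so the walk can change layers. The
package fixes it at 1 and exposes it as a knob; raising it makes layers
agree more strongly (a gene's copies share fate regardless) and mainly
rescales volumes, since interlayer edges never cross a cover-respecting
cut. Similarly, when a layer is emphasised with `w > 1`, interlayer edges
keep weight 1 — emphasis is meant to weight that network's *topology*, not
the coupling.

## The synthetic benchmark

`generate_scenario()` emulates the signal structure of driver-module
simulations at desk scale: disjoint planted modules (default 5, sizes
10–20) as dense Erdős–Rényi blocks (intra-module edge probability 0.6) on a
sparse background (mean degree 4, the order of magnitude of genome-scale
PPI medians), three layers derived from the shared scaffold by
degree-preserving rewiring of 10% of edges (so layers agree on most but not
all structure), and p-values `Beta(a, 1)` for module genes versus `U(0, 1)`
for the rest, with `a` sweeping 0.01 (strong) to 0.11 (weak). Defaults are
the reference conditions used by the tests and the acceptance script:
500 genes, 3 layers, `a = 0.01`, `B = 0.1`.

What it does *not* emulate: real PPI degree distributions are heavy-tailed
(hubs of degree hundreds), planted complexes are not Erdős–Rényi blocks,
layer disagreement in real networks is systematic rather than random
rewiring, and real genomes have ~19,000 genes. Passing benchmarks therefore
demonstrates that the pipeline's statistics and optimization behave as
designed — FDR control, signal-strength response, robustness to one
randomized layer — not that absolute F/Fsub values transfer to genome-scale
data.

**Scaling `K` at desk scale.** `K = 400` state nodes is the right default
for genome-scale networks, where it covers ~0.5% of the state space. On a
500-gene, 3-layer benchmark the same value covers 27% of the state space:
the local graph then contains several planted modules at once and the
optimizer, correctly minimising conductance, merges them through the
inter-module background edges — gene recovery stays high but module
*resolution* is lost. The reduced-scale experiments therefore use
`K = 120` (local graph ≈ 40 genes, two to three modules' worth),
preserving the proportionality between exploration size and module size
that `K = 400` has at genome scale. The FDR-control experiments keep
`K = 400`, since FDR control is guaranteed by the search constraint at any
`K`.

Problem sizes used by the checked experiments: 20 replicates of the
500-gene reference scenario for FDR control; 10 replicates per signal
strength `a ∈ {0.01, 0.05, 0.11}` for the decline-with-noise property
(mean F and Fsub non-increasing, Fsub ≥ 0.8 at the strongest signal);
5 paired replicates for the one-layer-randomized robustness check
(Fsub drop < 0.2); 50 random instances of ≤ 12 genes for optimizer-vs-
enumeration equivalence.

## Numerical choices and degenerate inputs

* p-values clipped at 1e-15; lfdr capped at 1; `π₀` capped at 1.
* All-identical p-values abort with a diagnostic (no density can be fit).
* Isolated genes are walkable through interlayer edges when `|L| ≥ 2`; in a
  single-layer multiplex they are unwalkable, excluded from seeding and
  local graphs with a warning.
* A gene set whose state nodes have zero total cut (e.g. a gene with no
  intralayer edges, alone) has conductance 0 — interlayer edges are
  internal to the cover.
* Ties: top-K ranking breaks ties by gene identifier then layer index; seed
  ordering lexicographically; push order by state index. Fixed seeds make
  scenario generation bit-identical; detection is deterministic given the
  solver's determinism (HiGHS is deterministic for a fixed instance).
* Dinkelbach tolerance 1e-9 on the parametric optimum; solver statuses are
  propagated (`optimal` / `incumbent` / `singleton-fallback`) rather than
  silently merged.

## Known limitations

* Directed, signed, or edge-confidence-weighted networks are out of scope;
  confidence filtering (e.g. STRING > 900) is left to the user.
* The MILP backend requires a Python with scipy on the PATH; there is no
  pure-R solver path (no MILP solver is available as an R dependency here).
* Per-seed MILPs on very dense local graphs can hit the time limit; the
  incumbent is returned and flagged, so downstream FDR guarantees hold but
  optimality may not.
* The empirical-Bayes defaults (bins, polynomial degree, null window) are
  sensible for genome-scale p-value sets; for small gene panels the lfdr
  estimates are unstable and the package warns rather than refuses.
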