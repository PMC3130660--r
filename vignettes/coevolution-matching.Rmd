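---
title: "Methods: exact coevolution matching between distance matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact coevolution matching between distance matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmm2)
```

## The model

Two interacting protein families accumulate substitutions at correlated
rates, so the phylogenetic subtree of the coevolving members of family A
is, up to a scale factor on branch lengths, a copy of the corresponding
subtree in family B. `mmm2` looks for this signature in the families'
distance matrices: it seeks the largest set of one-to-one A-to-B pairings
such that the submatrix of A-distances among the paired proteins is a
scaled copy of the paired B-distances, within tolerance.

Formally, for pairings $(a_u, b_x)$ and $(a_v, b_y)$ the ratio of paired
distances (RPD) is $R = d(a_u,a_v) / d(b_x,b_y)$. A set of $k$ pairings
is a *match of size $k$* when every one of its $\binom{k}{2}$ RPDs is
compatible with every other. The maximum match size is the coevolution
(MMM) score. Species tags, when configured, restrict pairings to
same-species proteins; this constraint is deliberately optional because
identifier conventions differ between sources. Zero distances (identical
sequences) are legal input but can never participate in an RPD: vertex
pairs whose RPD would have a zero numerator or denominator simply carry
no edge.

## The tolerance model

Compatibility is controlled by a single parameter $\alpha \in [0,1]$,
mapped to a multiplicative band $\delta(\alpha) = 1/(1-\alpha)$
($\infty$ at $\alpha = 1$):

* **compatible**: $\max(R_1,R_2) \le \delta \cdot \min(R_1,R_2)$ —
  symmetric; exact equality at $\alpha = 0$; unconditional at
  $\alpha = 1$.
* **forward-compatible** (one-sided, used by the solver):
  $R_{\min} \le R \le \delta \cdot R_{\min}$. If every edge of a set is
  forward-compatible with the set's minimum-RPD edge, all its edges lie
  in $[R_{\min}, \delta R_{\min}]$ and are therefore pairwise compatible
  — the lemma that lets the sweep anchor each clique subproblem on a
  candidate minimum edge.

The specific $\delta(\alpha)$ mapping is a design choice of this package:
it is the simplest function satisfying every behaviour the model demands
(exactness at 0, no restriction at 1, monotone nondecreasing, symmetric
band). Alternatives such as $\delta = (1+\alpha)/(1-\alpha)$ share those
properties; the mapping is isolated in `tolerance()` so swapping it is a
one-line change and all downstream code is agnostic. The default
$\alpha = 0.1$ follows the value commonly used in interaction screens;
$\alpha = 0.108$ is documented as a slightly relaxed setting that
compensates for the all-pairs criterion being stricter than the older
triplet-based one.

Compatibility is invariant under simultaneous reciprocals, which gives
the A/B swap symmetry of the score, and the band is unchanged when every
B distance is multiplied by a constant, which gives scale invariance —
both are property-tested, not assumed.

## The algorithm

The compatibility graph has one vertex per admissible pairing, indexed in
row-major $(a, b)$ lexicographic order (a total order is needed by the
deduplication rules below), and an RPD-labelled edge between any two
vertices not sharing a protein and not involving a zero distance. The
sweep:

1. For each vertex $v_i$, sort its neighbours by ascending RPD of their
   edge to $v_i$, ties by ascending vertex index. The tie order matters:
   the index rules below presuppose a stable, deterministic order, and a
   neighbour tied with $v_j$ but sorted before it is recovered through
   the anchor rooted at that neighbour instead.
2. For each neighbour $v_j$ with $j > i$, declare
   $e_{\min} = (v_i, v_j)$ the minimum-RPD edge of all matches searched
   in this iteration.
3. Scan neighbours strictly after $v_j$ in the sorted list; admit $v_k$
   into the subgraph $H$ when its edges to both $v_i$ and $v_j$ exist
   and are forward-compatible with $e_{\min}$. Because the list is
   sorted by the $v_i$-edge RPD, the scan stops at the first $v_k$
   whose $v_i$-edge fails — and only that condition terminates the scan;
   a failing $v_j$-edge merely skips the vertex. On an exact RPD tie
   with $R(e_{\min})$, $v_k$ is admitted only if $k > i$.
4. $H$'s edges join members whose mutual RPD is forward-compatible with
   $e_{\min}$; on an exact tie both endpoint indices must exceed $i$.
5. If $|H| + 2$ cannot reach the incumbent score, skip the clique
   search. (Tighter bounds exist in the literature; only this simple
   count is implemented.)
6. The maximum cliques of $H$, each extended by $\{v_i, v_j\}$, are
   matches; globally largest ones are kept, ties collected.

The tie rules in steps 3–4 ensure each match is generated from exactly
one anchor. Tie detection uses **exact floating-point equality** of the
RPD quotients: the ties that matter arise from identical distance values
in the input, which produce bit-identical quotients; an epsilon would
silently merge near-ties and break the completeness/uniqueness contract.
Uniqueness and completeness of the enumeration are verified against
brute force on hundreds of randomized instances whose distances are
rounded to 1–3 decimals precisely to mass-produce such ties.

### Scores below 3

A single edge is trivially a match of size 2 (there is no RPD pair to
test), an isolated vertex a match of size 1, an empty graph scores 0.
The solver reports these with a `trivial` flag rather than suppressing
them, since screening pipelines typically filter at size ≥ 3; the
`min_size` CLI option (default 3) controls which match lists are written
out.

### The clique engine

`H` is solved with an Östergård-style branch and bound: vertices are
processed in descending index order, and `c[i]` — the maximum clique
size within the suffix subgraph `{i..n}` — prunes the recursion. Two
modes exist. The all-maxima mode relaxes both pruning inequalities from
"cannot beat" to "cannot reach" the record, records a clique whenever
its candidate set runs dry, collects ties and evicts them on
improvement; every maximum clique ends at such a leaf and is reached
from exactly one root (its minimum vertex), so each is reported once.
The single-witness mode (`maxtrees = "one"`) keeps the classical
early-exit and accepts a lower bound, which the solver sets to the
incumbent score so non-improving subproblems return immediately.

## The synthetic generator

`generate_pair()` states the world the tests assume: family A's
distances come from a random additive tree (sequential random joins,
Exponential branch lengths with mean 0.1 substitutions/site — the
typical magnitude of protein distances; any positive distribution would
do); family B's come from an independent random tree except that the
planted block is overwritten with `scale * d_A * f`,
`f ~ U[1 − noise, 1 + noise]` independently per distance. Noise is
multiplicative because compatibility is a ratio criterion: planted RPDs
are `1/(scale · f)`, so the survive/drop condition is analytic —
`(1 + eps)/(1 − eps) ≤ delta(alpha)` — and the constructor rejects specs
that break their own planting. Defaults (8×10 families, 6 shared
species, planted size 5, scale 2, noise 0.02, alpha 0.1) describe a
modest screen instance with paralog-style decoys; noise 0.02 sits
comfortably inside the alpha = 0.1 band (which tolerates up to ≈0.053).

What the generator does **not** emulate: alignment error, rate
heterogeneity across sites, correlated noise between distances sharing a
branch, and non-additive distance estimates. A green planted-recovery
test therefore establishes the solver's combinatorial correctness, not
the biological error characteristics of real Protdist matrices.

## Numerical and interface choices

* RPDs are computed in double precision and compared without rounding.
* The PHYLIP reader accepts both strict and relaxed square dialects,
  tolerates rows wrapped across lines, symmetrizes asymmetries up to
  1e-6 by averaging (text round-off), and rejects anything worse;
  lower-triangular files are out of scope. The writer emits the relaxed
  dialect at 12 significant digits (round-trips below 1e-9).
* RPD orientation is always `d_A / d_B` with A the first family given;
  swap symmetry is a tested property.
* The brute-force reference solver enumerates vertex subsets
  depth-first with hereditary-feasibility pruning and refuses graphs
  over 20 vertices; it exists as the oracle for the exactness contract
  and for small interactive checks, never as a production path.
* The legacy triplet-based criterion is implemented only as a
  comparator. It never compares RPDs of vertex-disjoint edges, which is
  exactly the loophole `example_legacy_witness()` exhibits: four
  pairings whose within-triplet RPDs all agree but whose two disjoint
  edges differ by more than $\delta$.

## Limitations

Worst-case time is exponential (maximum clique is NP-hard); practical
inputs behave far better, but the package performs no approximation and
offers no anytime mode. The sweep is single-threaded per matrix pair;
large screens should parallelize across pairs. Sub-3 scores follow this
package's convention (flagged trivial) since the underlying definition
only speaks of size ≥ 3 matches.
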