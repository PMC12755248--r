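---
title: "Monotone Robinson-Foulds paths in rearrangement graphs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monotone Robinson-Foulds paths in rearrangement graphs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfpaths)
```

## Model and representation

`rfpaths` works with unrooted binary phylogenetic trees: connected acyclic
graphs whose leaves are bijectively labeled by a set $X$ of taxa and whose
internal nodes all have degree three. Such a tree on $n = |X| \ge 3$ leaves
has $2n - 2$ nodes and $2n - 3$ edges, of which $n - 3$ are internal.

Cutting any edge partitions $X$ into a bipartition $A\mid B$, the *split*
induced by that edge. The split set $\Gamma(T)$ of all $2n - 3$ splits
identifies the topology uniquely, so the package takes the split set as
the *primary representation*: a `treetop` object stores the sorted leaf
labels and one canonical side per split (the smaller side; ties broken by
the side containing the smallest label). Branch lengths carry no
information here and are discarded on input. This representation makes
the three operations the package lives on — symmetric differences of
split sets, split replacement under rearrangement moves, and
leaf-for-subtree substitution — exact set manipulations with no graph
bookkeeping, at the cost of $O(n)$ work per split where pointer-based
structures could sometimes do better. Topology is materialized only when
writing Newick, by assembling the laminar family of clades seen from the
smallest leaf.

The Robinson–Foulds distance is
$d_{RF}(T, R) = |\Gamma(T) \,\Delta\, \Gamma(R)|$. Trivial splits (one
side a single leaf) are common to all trees on the same leaf set and
cancel in the symmetric difference, so including them changes nothing
numerically while keeping $\Gamma$ faithful to its definition. Trees on
different leaf sets are rejected rather than compared on a restriction.
$d_{RF}$ is an even metric with maximum $2(n-3)$, attained exactly when
no non-trivial split is shared.

## Rearrangement moves

All moves are *declarative* — identified by splits, not by internal node
identities — so they survive re-parsing and canonicalization:

* **NNI** acts on an internal edge $e$; the two subtrees on each end of
  $e$ can be exchanged across it in two non-identity ways. An NNI move
  replaces exactly the one split induced by $e$, so every NNI neighbor is
  at RF distance 2. The adjacency oracle `is_nni_adjacent()` implements
  the contraction characterization directly: two trees are adjacent when
  deleting one non-trivial split from each leaves identical split sets.
* **SPR** removes an edge, names the pruned component explicitly by its
  leaf set (the component keeps its attachment point), and regrafts it on
  an edge of the remaining component. In split space the result is
  assembled from three parts: the pruned component's internal clades
  (kept intact), the restriction of the remaining component, and the
  membership rule that adds the pruned leaves to whichever side of each
  remaining split contains the regraft edge. Regrafting onto the edge
  that absorbed the original attachment point recreates the source tree;
  such moves apply cleanly but are excluded from neighborhoods, since the
  rearrangement graph has no self-loops.
* **TBR** bisects an edge and reattaches the two now-rootless components
  at one chosen edge each. Components with at most two leaves have at
  most one candidate attachment, expressed as a `NULL` reattachment
  edge. Every SPR move equals the TBR move that bisects the pruned edge
  and reattaches the pruned component at the edge its suppressed root
  leaves behind; `spr_as_tbr()` performs that translation and the tests
  verify the containment chain NNI $\subseteq$ SPR $\subseteq$ TBR
  exhaustively on six-leaf trees.

## The monotone NNI path

`nni_monotone_path(t, r)` returns a path $T \cong T_0, \dots, T_k \cong R$
in the NNI graph with $d_{RF}(T_{i+1}, R) \le d_{RF}(T_i, R)$, built by
induction on $n$:

1. *Base cases.* Isomorphic trees give the singleton path. On four
   leaves any two distinct topologies are NNI-adjacent, giving a one-move
   path.
2. *Shared split* ($\Gamma(t) \cap \Gamma(r)$ contains a non-trivial
   $A\mid B$). Collapse side $A$ in both trees to a fresh leaf and solve
   the smaller instance; do the same with side $B$; lift the first
   solution by substituting $t$'s $A$-subtree for the fresh leaf and the
   second by substituting $r$'s $B$-subtree. Substitution of a fixed
   pendant subtree for a leaf is a bijection on the affected splits, so
   it preserves symmetric differences — each lifted path inherits its
   monotone profile. The last tree of the first lifted path and the
   first tree of the second both consist of $t$'s $A$-side and $r$'s
   $B$-side glued across $A\mid B$; their isomorphism is *asserted* at
   run time rather than assumed, so any implementation defect would
   surface immediately. Because the lift never touches splits outside
   the active side, every split shared by the endpoints is present in
   every tree of the path.
3. *No shared split* (maximum RF distance). Pick a cherry $(c_1, c_2)$
   of $r$; in the current tree perform an NNI on the second edge of the
   $c_1$-to-$c_2$ path that exchanges the far-side component containing
   $c_2$ with the sibling subtree of $c_1$, shortening that path by one
   edge per move. The walk stops at the first tree strictly closer to
   $r$ — at the latest when the cherry forms, since the cherry split is
   then shared. The profile cannot rise above its starting value because
   it already sits at the maximum. Afterwards a shared split exists and
   case 2 applies.

The swap orientation in case 3 deserves a note: the wording "swap the
$c_2$-side component across the second edge" and "move $c_1$ towards
$c_2$" admit two different move sequences, both of which shorten the
cherry path and both of which keep the profile at the maximum until it
drops. The implementation exchanges the $c_2$-containing far component
with $c_1$'s near-side sibling, which realizes both readings at once;
the choice is recorded here because nothing in the monotonicity argument
distinguishes the alternatives.

Determinism matters for reproducibility and testing, so every free
choice is pinned: the shared split of case 2 is the minimum-size one
(lexicographic tie-break on the canonical side), the cherry of case 3 is
the lexicographically smallest pair with $c_1$ the smaller label, and
fresh collapse labels come from a reserved `.a`/`.b` namespace checked
against $X$ and eliminated entirely by the lift, so they never appear in
emitted trees.

Monotone is the strongest guarantee available in the NNI graph:
`find_nni_counterexamples(6)` exhaustively certifies ordered pairs
$(T, R)$ for which *no* NNI neighbor of $T$ is strictly closer to $R$,
so a strictly decreasing path cannot exist. All maximally distant stuck
pairs have every neighbor of $T$ at distance exactly 6. The search also
turns up stuck pairs at RF distance 4 — being stuck does not require
maximal distance — which is why the tests assert the existence and the
properties of the maximal class rather than an exclusive
characterization.

## The strict SPR path

`spr_strict_path(t, r)` decreases $d_{RF}$ to the target by at least 2
at every move, so its length is at most $d_{RF}(t, r)/2$. One step
(`spr_strict_step()`):

1. Among the non-trivial splits of the *target* absent from the current
   tree, select one of minimum size, $A\mid B$ with $|A| \le |B|$
   (lexicographic tie-break). In the target, $A$ is the union of its two
   child clades $A_1 \cup A_2$.
2. Minimality makes both $A_1$ and $A_2$ pendant in the *current* tree:
   a non-pendant $A_i$ with $|A_i| \ge 2$ would witness a smaller absent
   split, and singletons are pendant in every tree. This invariant is
   asserted, not assumed.
3. Prune the current tree's $A_1$-subtree (the smaller of the two; ties
   lexicographic) and regraft it on the edge joining $A_2$ to the rest.
   The move creates the split $A\mid B$, and every split it disturbs
   lies on the $A_1$-to-$A_2$ path of the current tree — each of the
   form $A_1 \cup X \mid A_2 \cup Y$ and therefore incompatible with
   $A \mid B$, hence absent from the target. The RF distance thus
   strictly drops; when the path between $A_1$ and $A_2$ crosses several
   such splits, a single move may repair more than one of them and the
   profile can fall by more than 2.

The construction is stated in the direction current $\to$ target
(equivalently, one may modify the target towards the source and reverse;
the symmetric argument is identical, and keeping the emitted path
oriented from `t` to `r` avoids reversing a profile whose monotonicity
is defined relative to one endpoint). Because disturbed splits are never
shared ones, strict SPR paths preserve every split common to the two
endpoints — unlike shortest SPR paths, which may break shared splits.
Since every SPR move is a TBR move, the same path is a strictly
decreasing TBR path.

## Exhaustive machinery and the synthetic generators

Enumeration builds all topologies by stepwise leaf insertion: each tree
on $k$ leaves has $2k - 3$ edges, and inserting the next leaf on each
edge yields every $(k+1)$-leaf topology exactly once, giving the
double-factorial count $(2n-5)!!$ with no deduplication needed
(deduplication is nevertheless *checked* in the tests via canonical
serialization). The same insertion step drives `random_tree()`, which
draws the attachment edge uniformly at each stage and is therefore
exactly uniform over topologies; a seed makes the draw a pure function
of `(labels, seed)` without disturbing the caller's RNG stream.

`graph_distance()` is a breadth-first search over canonical
serializations, deliberately capped at $n \le 7$ — NNI and SPR distances
are NP-hard in general and this oracle exists to validate small
instances, not to scale. Single-pair BFS is cross-checked in the tests
against an independent all-pairs computation on the explicit 105-vertex
graph.

These generators define the package's test conditions. The exhaustive
layer covers every ordered pair on 6 leaves (10,920 paths per
construction — the scale at which the stuck pairs live), and the sampled
layer uses seeded uniform random pairs at $n \in \{10, 20, 50\}$ for the
SPR construction and $n$ up to 10 for the NNI construction, 500 and 45
pairs respectively, sizes chosen so the full suite exercises every code
path at depth while remaining a routine local run. Uniform random
topologies are maximally unstructured: they contain no signal, clocklike
shape, or taxon-sampling bias, so passing these tests demonstrates the
combinatorial guarantees (adjacency, monotonicity, strictness, length
bounds, shared-split preservation) on arbitrary topologies, and — the
guarantees being theorems, not statistical properties — nothing further
about inference on real data.

## Numerical and degenerate-input policy

There is no floating point anywhere: all quantities are integer set
cardinalities, so tolerances do not arise. Degenerate inputs are handled
by contract rather than silently: trees need $n \ge 3$ (the 3-leaf star
is the unique, edge-case topology; paths and neighborhoods need
$n \ge 4$); multifurcating or degree-2 input Newick is rejected;
isomorphic path endpoints return the singleton path with an empty
profile rather than a zero-length error; SPR pruning must leave at least
two leaves so a regraft edge exists; TBR components with at most one
edge take `NULL` as their reattachment. Internal invariants whose
failure would indicate a bug — the junction isomorphism, the pendant
$A_1/A_2$ clades, the strict decrease itself — are `stop()`s, not
warnings.

## Limitations

* The constructed paths come with monotonicity guarantees, not length
  optimality; they are generally longer than shortest NNI/SPR paths, and
  the relationship between monotone and shortest paths is an open
  question out of scope here.
* Exhaustive tools (enumeration, BFS, counterexample search) are bounded
  at $n \le 9$ / $n \le 7$ by design; the path constructions themselves
  run comfortably into hundreds of leaves.
* Only unrooted binary trees are supported: no rooted RF or rSPR
  variants, no multifurcations beyond the transient contracted trees
  inside the NNI adjacency check, and no branch-length-aware distances.
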