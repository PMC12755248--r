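# rfpaths

Paths of decreasing Robinson–Foulds distance in tree rearrangement graphs.

## The problem

Phylogenetic treespace is usually explored with local tree rearrangements:
Nearest Neighbor Interchange (NNI), Subtree Prune and Regraft (SPR) and
Tree Bisection and Reconnection (TBR). The graph distances these moves
induce are biologically meaningful but NP-hard to compute, so in practice
tree collections are compared with the Robinson–Foulds (RF) distance
instead: for unrooted binary trees `T`, `R` on the same leaf set,

```
d_RF(T, R) = |Γ(T) Δ Γ(R)|
```

the size of the symmetric difference of their split (bipartition) sets
`Γ(·)`. RF is computable in linear time but relates awkwardly to
rearrangement distances — a single SPR move can connect two trees at the
*maximum* RF distance `2(n − 3)`.

`rfpaths` is a library for studying how RF behaves *along paths* in the
NNI and SPR graphs. Its core is two constructive algorithms:

* **`nni_monotone_path(t, r)`** — for any two trees on the same leaf set,
  an NNI path `T ≅ T0, T1, …, Tk ≅ R` with
  `d_RF(T(i+1), R) ≤ d_RF(Ti, R)` at every step (monotone, plateaus
  allowed). It recurses on a shared split `A|B`: both sides are collapsed
  to single leaves, the smaller instances are solved, and the solutions
  are lifted back and concatenated; if the trees share no split, a
  *cherry walk* first drives two leaves forming a cherry of `R` together
  in `T` until the RF distance drops below its maximum.
* **`spr_strict_path(t, r)`** — an SPR path on which the RF distance to
  `R` *strictly* decreases (by at least 2) at every step, hence at most
  `d_RF(t, r)/2` moves. Each step realizes a minimum-size split of the
  target that is missing from the current tree, by pruning one of its two
  child clades and regrafting it next to the other; every split disturbed
  by that move is already absent from the target, so none of the shared
  structure is ever broken.

Strictness is not achievable in the NNI graph:
**`find_nni_counterexamples(n)`** exhaustively finds ordered pairs
`(T, R)` for which *no* NNI neighbor of `T` is strictly closer to `R` —
at `n = 6` such "stuck" pairs exist, so any monotone NNI path through
them must contain a plateau.

Everything operates on split sets: a tree object *is* its canonical set
of `2n − 3` bipartitions, which identifies the topology uniquely. The
package also provides Newick I/O (`read_newick`, `write_newick`),
RF distance and isomorphism, move application and neighborhood
enumeration for NNI/SPR/TBR, exhaustive enumeration of all `(2n − 5)!!`
topologies, BFS graph distances for small `n`, a path validator, and
seeded uniform random topologies.

## Worked example

```r
library(rfpaths)

t <- read_newick("(a,(b,(c,(d,(e,f)))));")   # caterpillar a..f
r <- read_newick("(b,(c,(d,(e,(f,a)))));")   # leaf a moved to the far end
rf_distance(t, r)
#> [1] 6                                      # the maximum, 2(n - 3)

p <- nni_monotone_path(t, r)
p$rf_profile
#> [1] 6 4 2 0                                # never increases
validate_path(p)
#> Path validation (nni_monotone): PASS
#>   steps: 3; RF profile: 6 4 2 0

q <- spr_strict_path(t, r)
q$rf_profile
#> [1] 6 0                                    # strictly decreasing: one SPR move
path_table(q)
#>   step               newick                      move rf_to_target
#> 1    0 (a,b,(c,(d,(e,f))));                                      6
#> 2    1 (a,(((b,c),d),e),f); SPR prune={a} regraft={f}            0
```

Strict decrease is impossible for some NNI pairs. The exhaustive search
certifies it and the monotone path then shows the unavoidable plateau:

```r
cx <- find_nni_counterexamples(6)
length(cx)                       # ordered stuck pairs among all 105 x 104
#> [1] 3630
best <- cx[[which.max(sapply(cx, `[[`, "rf"))]]
write_newick(best$t); write_newick(best$r)
#> [1] "(a,(((b,c),d),e),f);"
#> [1] "(a,(((b,f),c),e),d);"
best$rf; best$neighbor_rf        # every NNI neighbor of T stays at RF 6
#> [1] 6
#> [1] 6 6 6 6 6 6
nni_monotone_path(best$t, best$r)$rf_profile
#> [1] 6 6 4 2 0                  # the first step cannot make progress
```

A command-line front end wrapping these functions is installed at
`system.file("cli", "treepaths.R", package = "rfpaths")`, e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","treepaths.R",package="rfpaths"))')" \
    rf '((a,b),(c,d));' '((a,c),(b,d));'
#> 2
```

## Documentation

The methods vignette (`vignettes/rf-monotone-paths.Rmd`) describes the
algorithms, their invariants, the deterministic tie-breaking rules, and
the scope and limitations of the exhaustive test machinery.
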