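# graphaln — bit-parallel sequence-to-graph matching and alignment

`graphaln` aligns query sequences (reads) to **directed, node-labeled
sequence graphs** — the common denominator of variation graphs and de
Bruijn graphs — including graphs with cycles. It is written for people who
need *provably optimal* graph alignments at desk scale: method developers,
teaching, and validation of heuristic graph aligners.

Two problems are solved, both bit-parallel (processing `w ≤ 64` query
characters per machine-word operation):

* **Exact matching (SGM)** — find all paths `p` with `σ(p) = s`, by a
  generalized Shift-And automaton: per-node NFA state vectors updated as
  `((S[v] << 1) + 1) AND P_σ(y)`, OR-merged over in-neighbors; one
  topological pass for DAGs, a worklist fixed point for cyclic graphs
  (`O(|V| + m|E|)`).
* **Semi-global alignment (SGA)** — find a path minimizing the unit-cost
  edit distance `d(σ(p), s)`, the query consumed entirely, path start and
  end free. The DP matrix `C[v, j]` (minimum edit distance between the
  length-`j` query prefix and any path ending at `v`) is held in Myers
  bitvector form per node (`VP`/`VN` step vectors plus a scalar
  `S_before`), advanced along edges with the Myers block step, merged at
  in-degree ≥ 2 nodes by a bit-parallel elementwise minimum
  (`O(log w)` word operations via chunked score differences), and driven
  to convergence on cyclic graphs by a bucket priority queue keyed on the
  *minimum changed score*. The matrix is processed in `w`-row slices,
  giving `O(|V| + ⌈m/w⌉|E| log w)` on DAGs and `O(|V| + m|E| log w)` on
  arbitrary graphs.

Correctness is anchored to two independent oracles shipped in the
package: a Dijkstra shortest-path solver on the edit graph (via `igraph`)
and the classical row-wise cell-by-cell algorithm in plain R. The test
suite compares all three cell-for-cell on hundreds of random cyclic and
acyclic graphs.

## Worked example

The bundled `example.gfa` is a small variation graph with a SNP bubble
(`altA`/`refC`) and a tandem duplication (a back edge on segment `ref2`),
which makes the graph cyclic:

```r
library(graphaln)
g <- read_gfa(system.file("extdata", "example.gfa", package = "graphaln"))
g
#> <seq_graph> 22 nodes, 23 edges
#>   labels: ACGTTGCAACGGATCTTACG...
#>   provenance: 5 GFA segment(s)
is_acyclic(g)
#> [1] FALSE
```

A read spelling the duplicated segment twice aligns exactly — the path
revisits the `ref2` nodes, which only a cyclic-graph aligner can do:

```r
align_graph(g, "ACGTTGCACGGATCGGATCTTACG", query_id = "demo", crosscheck = TRUE)
#> <alignment_result> demo: edit distance 0 over 24 node(s)
#>   ops: ========================
```

A noisy read takes the bubble's alternative branch and drops one base;
the traceback reports the branch in segment space and the single deletion:

```r
res <- align_graph(g, "ACGTTGAAGGATCTTACGGA", query_id = "noisy")
res
#> <alignment_result> noisy: edit distance 1 over 21 node(s)
#>   ops: ======D==============
write_gaf(list(res), "out.gaf", g)
#> noisy  20  0  20  +  >ref1>altA>ref2>ref3  21  0  21  20  21  NM:i:1  cg:Z:6=1D14=
```

The GAF-style line reads: query `noisy`, length 20, aligned end-to-end
(`0..20`, semi-global), through the path `ref1 → altA → ref2 → ref3`
(21 bp), 20 matches in a 21-column alignment block, edit distance 1
(`NM`), operations `6=1D14=` (`cg`).

Exact matching through the duplication:

```r
st <- shift_and_cyclic(g, "GGATCGGATC")
extract_matches(st, g)$witnesses[[1]]
#> [1] 11 12 13 14 15 11 12 13 14 15    # the ref2 nodes, twice around the cycle
```

Benchmark graph generators (`generate_linear()`, `generate_snp()`,
`generate_twopath()`, `generate_tangle()`, plus
`add_reverse_complement()`), read simulation (`simulate_reads()`), and a
thin command-line wrapper (`exec/graphaln` with `generate`,
`simulate-reads`, `exact`, `align` subcommands) round out the toolbox.
See the vignette `vignettes/graph-alignment.Rmd` for the model, the
bit-parallel merge construction, and all design decisions.

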