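---
title: "Bit-parallel sequence-to-graph matching and alignment: methods"
author: "graphaln"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-parallel sequence-to-graph matching and alignment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphaln)
```

# The problem

A *sequence graph* is a directed graph $G = (V, E, \sigma)$ whose nodes each
carry one character; a path $p = (p_1, \dots, p_k)$ (repeats allowed) spells
$\sigma(p) = \sigma(p_1)\cdots\sigma(p_k)$. Variation graphs and
overlap-trimmed de Bruijn graphs both reduce to this form once segments are
expanded to one node per character. `graphaln` solves two problems on such
graphs, including cyclic ones:

* **Exact matching**: find all paths whose label equals a pattern $s$
  ($|s| = m$).
* **Semi-global alignment**: find a path $p$ minimizing the unit-cost edit
  distance $d(\sigma(p), s)$, and report the alignment. The query is
  consumed entirely; the path's start and end are free.

Both solvers process $w$ query characters per machine-word operation
($w \le 64$), generalizing the Shift-And automaton and Myers' bitvector
edit-distance algorithm from sequences to graphs. An aligned pair of
independent solvers — a Dijkstra shortest-path solver on the edit graph
(via `igraph`) and a row-wise cell-by-cell solver in plain R — serves as
the correctness oracle for everything the bit-parallel path computes.

# The dynamic program

For node $v_i$ and query prefix length $j$, define
$C_{i,j} = \min_p d(\sigma(p), s[1..j])$ over non-empty paths ending at
$v_i$. $C$ satisfies, with $\Delta_{i,j}$ the mismatch indicator between
$\sigma(v_i)$ and $s_j$,

$$C_{i,j} = \min \begin{cases}
C_{k,j-1} + \Delta_{i,j} & k \in \delta^{in}_i \quad \text{(diagonal)}\\
C_{k,j} + 1 & k \in \delta^{in}_i \quad \text{(horizontal)}\\
C_{i,j-1} + 1 & \text{(vertical)}\\
(j-1) + \Delta_{i,j} & \text{(fresh start)}
\end{cases}$$

with $C_{i,1} = \Delta_{i,1}$. The *fresh start* term deserves a note: a
path may begin anywhere in the query, paying $j-1$ leading insertions
before its first node. Without it, the single-node path "C" aligned
against the prefix "GTATC" would cost 5 instead of its true edit distance
4, and alignment against a linear chain graph would *not* reduce to
textbook semi-global sequence alignment. For nodes with in-neighbors the
term is redundant — initializing every column to the empty-path scores
$(1, 2, \dots, m)$ and propagating along edges produces it automatically —
but in-degree-0 nodes and slice boundaries need it explicitly, so every
solver in this package carries it as a first-class term. The package's
equivalence tests (bitvector $\equiv$ Dijkstra $\equiv$ cell-by-cell
$\equiv$ classic DP on chains) gate this choice.

Despite cyclic dependencies (the horizontal term can run around a cycle),
the system has a unique solution, and the **vertical property** holds:
$C_{i,j} - C_{i,j-1} \in \{-1, 0, 1\}$. That property is what makes the
bitvector encoding possible.

# Bitvector representation

A column (one node, $k$ rows) is stored as `bit_column(vp, vn, s_before)`:
bit $j$ of `vp`/`vn` records a $+1$/$-1$ step from row $j-1$ into row $j$,
and `s_before` anchors the score just above the top row, so
$S_j = S_{before} + \mathrm{popcount}(VP_{0..j}) -
\mathrm{popcount}(VN_{0..j})$. In whole-column mode a column spans all $m$
rows ($S_{before} = 0$); in sliced mode it spans one $w$-row slice and
`s_before` carries the converged score of the slice above. `encode_scores()`
fails loudly if fed scores violating the vertical property — on pipeline
output that failure would falsify the theorem, so tests re-encode every
computed column.

## Column step

`myers_step()` advances a column across one edge $(v \to y)$ with the
block formulation of Myers' algorithm (the edlib variant, with a
horizontal carry `hin` entering at the boundary row and a carry chain
across words for multi-word columns). Its contract, enforced by a
3000-case randomized test against a scalar evaluator, is: the decoded
output equals the direct recurrence restricted to the single predecessor
column plus the vertical continuation from the boundary row.

## Merging columns

Nodes with several in-neighbors take the elementwise minimum of candidate
columns. The transparent reference (`merge_reference`) decodes, takes
`pmin`, re-encodes. The bit-parallel path (`merge_bitparallel`) never
decodes: it tracks the running difference $d_j = S^A_j - S^B_j$ (which
moves by at most $\pm 2$ per row) in parallel chunks of
$\lceil\log_2 k\rceil + 2$ rows:

1. $g$ rounds accumulate each chunk's total row-delta in parallel;
2. an exclusive prefix over the $\lceil k/g \rceil \le 13$ chunk sums
   anchors each chunk's absolute difference;
3. $g$ more rounds advance all chunks one row at a time, extracting the
   sign masks $M_{A>B}$, $M_{A\ge 2}$, $M_{B>A}$ bit-parallel.

From the masks, a picking mask selects output bits per row, with $+1/+2$
step corrections exactly at rows where the picked source switches (a
switch $A{\to}B$ at row $j$ implies $d_{j-1} \in \{-1, 0\}$ and
$B{\to}A$ implies $d_{j-1} \in \{1, 2\}$, which the masks distinguish).
Two implementation choices are deliberate: chunk *storage* uses 16-bit
lanes (twice the chunk's row width) so the arithmetic is exact with guard
bits and needs no saturation logic; and the initial difference is clamped
to $\pm(2k+2)$, beyond which neither the sign nor the $\ge 2$
classification at switch rows can change within $k$ rows, so the clamp is
lossless. The bit-parallel merge is gated by exhaustive randomized
equivalence against the reference (10 000+ pairs at $k = 8$ and $64$,
including multi-word columns and extreme `s_before` offsets), and a
`merge = "check"` mode runs both on every in-pipeline merge.

## Changed minimum

`changed_min(old, new)` is the smallest score of `new` at rows where
`new` improved on `old` ($\infty$ if none) — the priority with which a
node is re-queued, since only improved cells can propagate further. The
fast path computes the difference mask with the chunk machinery and then
evaluates only *local minima* of the new column (rows whose incoming step
is not $+1$ and outgoing step is not $-1$; an argmin over the changed rows
always has this shape, by the vertical property of the old column). Each
candidate is scored by popcount. A brute-force decoded mode is kept as
the test reference.

# Algorithms

**Exact matching.** Each node holds an $m$-bit NFA state; bit $i$ means
"some path of length $i$ ending here spells the length-$i$ prefix".
Updates are `((state << 1) + 1) AND mask`, OR-merged over in-neighbors;
the `+1` lets a match start at every step, and bit 0 of every node is
seeded from the empty state so in-degree-0 nodes can start matches. DAGs
take one topological pass; cyclic graphs run a worklist to the fixed
point. Bits are only ever set, so each node re-enters the list at most
$m$ times, giving $O(|V| + m|E|)$; the worklist order (LIFO default,
FIFO available) cannot change the fixed point, and tests assert it does
not.

**Alignment, cyclic case.** A bucket priority queue (one bucket per
score, per-node current priority, lazy decrease-key, a forward scan
pointer) is seeded with every node at priority 0. Columns are initialized
to the vertical continuation chain from each node's `s_before`, lowered by
one from the node's first in-slice match row on when `s_before` still
equals the slice's top row index — this realizes the fresh-start term.
Each popped node propagates its column over its out-edges
(`myers_step` then merge); if the destination improved, it is re-queued at
its changed-minimum score. Scores never increase and each cell converges
once, so a node is re-popped at most $k$ times per slice; the engine
counts re-pops per node and the tests assert the bound. The scan pointer
can in principle move backward on a push below it; the engine counts
those events (observed: essentially none beyond queue seeding).

**Slices.** The matrix is processed in $\lceil m/w \rceil$ slices of $w$
rows, top to bottom, each node's bottom score feeding the next slice's
`s_before`. The horizontal carry into an edge's step is
$\mathrm{clamp}(S_{before}[y] - S_{before}[v], -1, +1)$. Clamping is
exact here: the difference never exceeds $+1$ (the horizontal property
holds at converged boundary rows), and when it is below $-1$, the only
information lost is the vertical continuation through $y$'s own boundary
cell — which is precisely the column every node is initialized with, so
the subsequent merge restores it. This argument is backed by the
oracle-equivalence tests rather than trusted: every decoded matrix is
compared cell-for-cell against the Dijkstra solver across hundreds of
random cyclic and acyclic graphs at $w = 8$ and $w = 64$. Acyclic graphs
(detected automatically) take a single topological pass per slice with no
queue.

**Traceback.** All slices are decoded into a $|V| \times m$ integer
matrix (memory $O(|V| m)$; deliberately simple at desk scale) and one
optimal alignment is walked backwards, preferring diagonal over fresh
start over horizontal over vertical moves and the smallest node id among
ties, so outputs are deterministic. Operations are reported per base
(`=`, `X`, `I`, `D`); a validator replays them against the spelled path
and the reported distance after every pipeline run.

# Oracles

`dijkstra_align()` rephrases the recurrence as shortest paths on an edit
graph with states (node, row) and nonnegative arc costs, including
source arcs for every fresh start, and lets `igraph::distances()` solve
it — no code shared with the bitvector path. `cellwise_align()` is the
classical row-wise algorithm: per row, one vectorized sweep applies
diagonal/vertical/fresh-start terms, then a depth-first worklist relaxes
horizontal terms to the fixed point (relaxing only on strict improvement,
which terminates on cycles). It keeps plain integer matrices throughout
and refuses instances beyond $10^7$ cells. The two oracles are compared
against each other as well as against the bitvector engine.

# Synthetic data as study conditions

The generators reproduce the four benchmark topologies used to
characterize the algorithm, built from a random backbone sequence:

* `generate_linear()` — a chain; alignment reduces to sequence-to-sequence.
* `generate_snp()` — chain with Bernoulli(0.1) single-nucleotide bubbles
  (one SNP per 10 bp on average, the default condition), the alternative
  node wired in parallel to the kept reference node.
* `generate_twopath()` — two full-cross-wired chains, so every
  non-initial node has in-degree 2 and the merge runs for every node (the
  merge-bound worst case); second-chain labels random by default.
* `generate_tangle()` — the $k$-mer de Bruijn graph of the backbone
  ($k = 11$ at the 10 kb scale, chosen small to make the graph heavily
  cyclic), unitigs compacted, the last $k-1$ characters of every non-tip
  unitig trimmed; topology and path labels of the de Bruijn graph are
  preserved (checked by exhaustive walk-label enumeration on small
  inputs). A unitig always contains a full $k$-mer, so trimming never
  empties a node.

All graphs can be doubled with `add_reverse_complement()` (disjoint union
with complemented labels and reversed edges) to accommodate
reverse-strand reads with a single mechanism; reads are never
reverse-complemented at align time. `sample_path()` +
`mutate_sequence()` provide reads: uniform random walks with i.i.d.
substitutions/insertions/deletions. This emulates coverage-uniform reads
with position-independent errors; it does not emulate instrument error
profiles, length distributions, chimeras, or coverage bias, so passing
tests certify algorithmic correctness, not robustness to real-data
artifacts.

# Numerical and design choices

* Node ids are dense 1-based integers at the R surface (0-based inside
  the C++ kernels); DP rows are 1-based in prose, 0-based in bit
  positions.
* Word size $w$ is a parameter (2..64, default 64); tests run $w = 8$
  throughout to exercise multi-word carries. Words are explicit: all
  kernels move carries word-by-word so the stated complexities are real.
* $\infty$ priorities are represented as a sentinel above $m + w + 1$;
  scores are bounded by $m$, present scores by $S_{before} + k$.
* Alphabet: strict A,C,G,T by default; the lenient policy maps other
  IUPAC codes to N, and N mismatches everything including N (the
  unit-cost model has no ambiguity semantics).
* GFA dialect: GFA 1.0, S-lines with explicit sequences, L-line overlaps
  `0M` or `*` only; `-` orientations materialize reverse-complement
  segment copies. P-lines and GFA 2.0 are out of scope.
* Full path enumeration for exact matching is exponential; the default
  output is one witness per match end, with opt-in enumeration capped
  (default 1000) and a truncation flag.

# Problem sizes in the test suite

The suite fixes seeds and uses: 600 random graphs ($|V| \le 30$, edge
density up to $3|V|$, $m \le 40$) for the three-way oracle equivalence at
$w \in \{8, 64\}$; 200+ graphs for the Shift-And oracle; 10 000 random
column pairs at $k \in \{8, 64\}$ for merge and changed-min equivalence;
100 pairs each for sliced-vs-whole and linear-vs-classic checks; and one
10 kb tangle graph with simulated 400 bp reads for the end-to-end timing
comparison. These sizes make the whole suite complete in a few minutes on
one CPU while keeping every equivalence exact (cell-for-cell, not
statistical).

# Limitations

* Unit costs only: no affine gaps, no generalized integer costs, no
  banding or seeding heuristics; the full matrix is always computed.
* The cell-by-cell baseline is implemented in R (vectorized first sweep,
  scalar relaxation) while the bitvector engine is compiled, so the
  observed speedup between the two modes mixes language and algorithm
  effects and is not a calibrated reimplementation benchmark; the
  comparison is reported as a directional check only.
* Traceback decodes the full matrix; memory grows as $|V| \times m$
  integers, which is fine at desk scale but not for mammalian genomes.
* The bidirected semantics of GFA are emulated by reverse-complement
  doubling, not represented natively.
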