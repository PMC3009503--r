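---
title: "Reaction graph kernels: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction graph kernels: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgk)
```

## The problem

Enzymatic reactions are classified by EC numbers, four hierarchical
fields of which the first three carry the chemistry (the fourth is
largely a serial number). When a reaction's enzyme is unknown, a
similarity-based look-up against annotated reactions can propose EC
numbers. The quality of that look-up rests entirely on the similarity
metric, which must see both *what the compounds are* and *what roles
they play* in the reaction. `rgk` implements such a metric as a
two-level random-walk graph kernel and the nearest-neighbor prediction
protocol on top of it.

## The random-walk kernel

A labeled graph is compared to another by generating random walks on
each and asking how likely the two walks are to emit a matching label
sequence. On each graph the walk starts from the uniform distribution
over vertices, moves along the degree-normalized adjacency matrix
$T$ (column-stochastic; isolated vertices get a zero column and simply
terminate after emitting their label), and stops with probability
$1-\lambda$ at each step. For the pair of graphs the joint walk lives
on the Kronecker product of the two state spaces; matching is gated at
every step by the vertex-match matrix $M \in [0,1]^{|V_1|\times|V_2|}$.
The matched joint mass satisfies

$$V \;=\; V^{(0)} + M \ast \left(\lambda_1\lambda_2\, T_1 V T_2^\top\right),
\qquad V^{(0)} = M \ast \left(u_1^{(0)} {u_2^{(0)}}^\top\right),$$

where $\ast$ is the Hadamard product, and the kernel is
$k(G_1,G_2) = (1-\lambda_1)(1-\lambda_2)\sum_{ij} V_{ij}$ — the
probability that both walks terminate having produced a common, fully
matched label sequence. Including the termination weights makes the
value a genuine probability; it is a global positive scale, so it
cannot change any ranking after cosine normalization. The fixed-point
iteration starts at $V^{(0)}$ and contracts with factor
$\lambda_1\lambda_2$; each update is two sparse matrix products plus an
elementwise mask, $O(|E_1||V_2| + |E_2||V_1| + |V_1||V_2|)$.

Because the engine assumes vertex labels only, labeled edges are first
*promoted*: each edge $(u,v)$ with label $\ell$ becomes a new vertex
labeled $\ell$ with edges $(u,w),(w,v)$, giving exactly $|V|+|E|$
vertices and $2|E|$ edges. Promoted labels live in disjoint namespaces
(`bond:`, `rel:`) so a Dirac match can never confuse an atom with a
bond.

### Non-tottering walks

Plain random walks can "totter" ($a \to b \to a$), inflating
similarity through degenerate repetition. The package applies the
standard directed edge-graph transform: vertices become $V$ plus one
vertex per arc, an arc vertex $(u,v)$ carries the label of $v$, arcs
connect $v \to (v,u)$ and $(u,v) \to (v,w)$ for $w \neq u$, and walks
may start only on original vertices. Label sequences on the transformed
graph correspond exactly to non-tottering walks on the original, which
the test-suite verifies by brute-force enumeration up to length 5. The
transform is on by default and applied at both kernel levels.

## Two levels

* **Compound level.** Atoms are vertices labeled by element symbol;
  bonds (`single`, `double`, `triple`, `aromatic`) are promoted to
  vertices. $M$ is the Dirac kernel on labels. Hydrogens are kept when
  the structure file lists them and never added; charges, isotopes and
  stereochemistry are deliberately ignored — under Dirac matching any
  inferred attribute would silently change the semantics.
* **Reaction level.** A reaction graph has compounds as vertices
  (separate vertices per side, so a compound occurring on both sides
  appears twice) and typed relation edges. After promotion, $M$ is
  blockwise: compound–compound entries are the *normalized* lower-level
  kernel values, relation–relation entries are Dirac on the relation
  label, cross entries are zero. The compound Gram matrix is computed
  once over the union of all compounds, cosine-normalized
  ($k'_{ij} = k_{ij}/\sqrt{k_{ii}k_{jj}}$) so entries lie in $[0,1]$
  as the match matrix requires, and cached.

Three reaction-graph variants model decreasing knowledge about the
reaction: `full_edge` (all typed pairs plus `group` edges joining every
two same-side compounds), `rpair` (typed pairs only), and `main_pair`
(only the core transformation, other compounds dropped). Their edge
sets nest, which the tests assert on every generated fixture.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `lambda_lower`, `lambda_upper` | 0.9 | walk continuation probability at each level; values in (0,1). Higher λ weights longer walks; 0.9 is the default at both levels and `rgk sweep` evaluates a grid. |
| `tol` | 1e-9 | L1 residual threshold of the fixed-point iteration. With λ² = 0.81 contraction this needs ≈ 100 iterations worst case, a few dozen typically. |
| `max_iter` | 100 | iteration cap; hitting it emits a warning and flags the value as non-converged in the run manifest. |
| `non_tottering` | TRUE | apply the edge-graph transform at both levels. |
| `top_k` | 5 | distinct candidate ECs reported per query. |
| `min_score` | 0 | rejection threshold: a query whose best similarity falls below it is abstained from, trading coverage for accuracy. |

## Prediction protocol

Nearest neighbor on the normalized upper-level kernel. Candidates are
the distinct ECs of the ranked neighbors (first occurrence wins, so
each candidate's raw score is its best neighbor's similarity); ties
break by database insertion order, deterministically. Z-scores
$(x-\mu)/\sigma$ use the population standard deviation over the
*candidate* scores; a constant candidate list is degenerate and yields
zeros with a flag. Leave-one-out evaluation computes the Gram matrix
once and masks the held-out row/column per fold — exact, because
kernel values between the remaining reactions do not involve the
held-out one; the suite asserts bitwise agreement with per-fold
recomputation. Accuracy at level $d$ is top-1 agreement on the first
$d$ EC fields, so level accuracies nest by construction.

Database filtering before evaluation removes (i) reactions without an
EC, (ii) reactions with unavailable structures, (iv) ECs containing a
97/99 component (the catch-all categories; top-level EC classes run
1–6, so 97/99 can only occur in trailing fields), and (v) reactions
alone in their subsubclass — (v) last and iterated to a fixed point
because earlier removals can orphan a subsubclass. The gap in the
numbering is kept on purpose: these four are the filter set.

## The synthetic benchmark

Real KEGG-scale evaluation needs the REACTION/RPAIR/COMPOUND databases;
the package instead ships a generator whose output has the one property
the method relies on: *reactions in the same EC subsubclass share a
conserved structural transformation*. Each class owns a substrate
scaffold (classes sharing the leading EC digit share a base scaffold,
so the EC hierarchy is reflected in structure space) and a fixed
product-side extension; within-class reactions differ by random
decorations applied identically to both sides, plus class-determined
cofactor/leave participants from a shared pool. Everything is a pure
function of the seed, and serialization is byte-identical across runs.

The default benchmark (3 classes × 6 reactions, 5–8 atom scaffolds,
decoration rate 0.2, λ = 0.9) is small enough that the whole pipeline
runs in seconds:

```{r benchmark, eval = FALSE}
fix <- generate_reaction_classes(fixture_spec(seed = 42))
cgram <- compound_gram_matrix(fix$compounds)
graphs <- lapply(fix$records, build_reaction_graph, mode = "full_edge")
loo_evaluate(graphs, cgram)$accuracy
```

What passing this benchmark shows: the two-level kernel machinery, the
normalization, the masking and the candidate protocol are correct, and
the kernel's ranking recovers class structure from conserved
transformations under moderate structural noise. What it does **not**
show: performance on real metabolic data — real compounds are an order
of magnitude larger, class sizes are wildly imbalanced, RPAIR role
annotations are noisy, and distinct subsubclasses can share near-
identical chemistry. At the benchmark's separation the three graph
variants typically all saturate (100% at all levels), so the benchmark
demonstrates correctness, not the full-edge variant's real-data
advantage; the variant ordering is asserted only as a
majority-of-seeds property.

## Numerical choices and degenerate inputs

* Fixed-point convergence is measured as the L1 norm of the update;
  the residual sequence is non-increasing after the first step
  (contraction), which is property-tested.
* The enumeration oracle evaluates the truncated series with dense
  Kronecker operator powers and is guarded (state space ≤ 100,
  length ≤ 30); the geometric tail bound
  $(\lambda_1\lambda_2)^{L+1}/(1-\lambda_1\lambda_2)$ bounds its
  distance to the fixed point, which is the acceptance check for the
  solver.
* An all-zero match start ($M \ast U^{(0)} = 0$) short-circuits to
  kernel 0 — no propagated term can become nonzero.
* Cosine normalization requires strictly positive self-kernels; a
  zero diagonal names the offending graph. Values are clamped to
  $[0,1]$ only within 1e-8 of the boundary; larger excursions raise an
  error because they indicate an invalid Gram matrix.
* Isolated vertices get zero transition columns (emit one label, then
  stop) rather than an undefined normalization.
* Reactions are stored as written (left side = substrates); the flipped
  orientation is not additionally evaluated.

## Known limitations

* Multi-step reactions with several correct EC numbers are out of
  scope; one truth EC per reaction.
* No atom–atom mapping or reaction-center detection — similarity is
  purely walk-based.
* Aromaticity is taken from the structure file's bond flags; there is
  no perception, no SMILES handling, no 3D information.
* The `main_pair` variant requires at least one annotated main pair;
  reactions without one are rejected in that mode rather than guessed.
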