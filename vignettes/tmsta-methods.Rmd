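---
title: "Methods: two-stage multiple structure alignment in tmsta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage multiple structure alignment in tmsta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsta)
```

## The problem

Given a set of protein structures known only through their C-alpha traces,
we want (i) a residue-level correspondence between every pair of structures
together with similarity scores, and (ii) a joint multiple structure
alignment (MSTA) whose columns identify the residues that occupy equivalent
positions in all members — the common structural core of, say, a SCOP
superfamily or a set of homology models. Sequence identity in such sets is
often below 50%, so the alignment must come from geometry, not sequence.

`tmsta` implements this as the classic two-stage design: an all-to-all
pairwise stage whose TM-scores define a dissimilarity matrix, a UPGMA guide
tree built from that matrix, and a progressive profile-merging stage that
walks the tree from the leaves to the root. Both stages can run in parallel
over partitioned work lists, under a strict contract: **parallelism
settings (workers, partitions, coalesce target, traversal cutoff) may only
change wall-clock time, never a single output byte.**

## Stage 1: pairwise alignment

### Scores

The TM-score of an alignment with pair distances $d_i$ is

$$\mathrm{TM} = \frac{1}{L_{\mathrm{norm}}} \sum_i
  \frac{1}{1 + (d_i/d_0)^2}, \qquad
  d_0(L) = \max\!\bigl(1.24\,(L - 15)^{1/3} - 1.8,\; 0.5\bigr)\ \text{Å},$$

reported under both chain-length normalizations ($L_1$ and $L_2$, each with
its own $d_0$). Internally, candidate alignments are ranked by the score
normalized by the shorter chain, the standard choice when the question is
"do these two share a core". `rmsd_aligned` is defined as the
least-squares (Kabsch) RMSD over the mapped pairs — not the RMSD under the
TM-optimal rotation — so that the two-structure reduction of the MSTA
metrics reproduces the pairwise numbers exactly.

Superpositions use the Kabsch SVD solution with the determinant-sign
correction, so reflections are never returned; collinear point sets still
yield a minimizer but are flagged.

### Search

A pairwise alignment is found by iterating two steps until the residue
mapping revisits a previous state (fingerprint cycle detection, cap 30):

1. **TM-score-optimal superposition** of the current mapping: seed
   superpositions on contiguous mapped fragments of lengths
   $\{m, m/2, m/4\}$ (minimum 4, starts every half fragment), refine each
   by re-superposing on the pairs closer than $\max(d_0, 4.5\ \text{Å})$
   until the selected subset is stable (at most 20 rounds), keep the best.
2. **Needleman–Wunsch dynamic programming** over the score matrix
   $S_{ij} = 1/(1 + (\lVert x_i - T(y_j)\rVert/d_0)^2)$ with gap opening
   $-0.6$ and free gap extension. Traceback ties prefer match, then a gap
   in the second structure, then a gap in the first — pinned so results
   are bit-reproducible.

The iteration starts from three seed families: the best gapless diagonal
threading, a secondary-structure alignment (H/E/C states called from pure
CA geometry with fixed distance windows), and a hybrid of the two. The
candidate with the highest shorter-chain TM-score wins. The returned
mapping is always strictly monotone in both indices; non-sequential
alignments are out of scope.

### The engine

All $n(n-1)/2$ unordered pairs are enumerated lexicographically, split
into contiguous partitions of near-equal size (optionally fused to a
smaller count, mirroring how over-subdivided work lists behave in
distributed settings), and consumed by forked worker processes. Results
are re-sorted into enumeration order before anything is serialized, which
is what enforces the determinism contract regardless of completion order.
A failing pair aborts the whole run with the pair's identity: a missing
pair would silently corrupt the distance matrix downstream.

The distance matrix is $d_{ij} = 1 - (\mathrm{TM}_{ij}^{(1)} +
\mathrm{TM}_{ij}^{(2)})/2 \in [0, 1]$. Averaging the two normalizations is
the one symmetric choice that uses both reported scores; it is isolated
behind `to_distance_matrix()` so an alternative transform touches exactly
one function.

## Stage 2: guide tree and progressive merging

`upgma()` performs classic average-linkage agglomeration
($d(A \cup B, C)$ = size-weighted mean), with merge heights $d/2$, so the
tree is ultrametric and every branch length non-negative. Nodes use the
binary-tree index convention: leaves $0..N-1$, internal nodes $N..2N-2$
in merge order, so `index >= N` marks a non-leaf without any name
bookkeeping. Equal-distance ties take the lexicographically smallest
(min index, max index) cluster pair; the smaller index becomes the left
child. Both rules are arbitrary but pinned — UPGMA ties are otherwise a
reproducibility trap.

Progressive alignment evaluates the tree in post-order. A leaf is a
one-row profile; an internal node merges its children:

* **Seed**: the cross-profile structure pair with the smallest stage-1
  distance; its stored pairwise mapping initializes the rigid placement of
  profile B in profile A's frame via the TM-score-optimal superposition.
* **Singleton merges** (both profiles are single structures — always the
  case for the tree's cherries) reuse the stored stage-1 alignment
  directly: re-iterating would only replay the pairwise refinement, and
  direct reuse makes the two-structure MSTA an exact reduction to
  `align_pair()`.
* **Profile merges** iterate: column-by-column score matrix (mean of the
  distance score over all non-gap cross pairs, gaps contribute nothing,
  empty column pairs score 0, each structure pair using $d_0$ of its
  shorter chain), column NWDP with gap opening $-0.6$, re-superposition on
  all residue pairs implied by the matched columns — until the column
  mapping repeats or 10 iterations. Matched columns merge; unmatched
  columns are inserted with gaps in the other profile's rows (A-side runs
  first). Row-internal residue order is preserved, every residue appears
  exactly once, and no column is ever all gaps.

The traversal can evaluate the two children of any node at depth below
`cutoff` concurrently (a parent never starts before both children
finish). Because profiles are merged in tree order, not completion order,
the result is identical to the serial traversal for every cutoff and
worker count. The default is `cutoff = 0` — fully serial — because most
of the work sits near the root where no task parallelism is available:
on a fully balanced binary tree of $n$ nodes and height
$h = \log_2(n+1) - 1$ the best possible traversal speedup is only
$(n-1)/(2h)$ (`theoretical_balanced_speedup()`), e.g. 1.5 for $n = 7$,
and real guide trees are rarely balanced. Pair-level parallelism in
stage 1 and in the metrics loop is where workers actually pay off.

### Metrics

`compute_metrics()` restricts the MSTA to its core columns (no gap in any
row) and, for every structure pair, superposes the core residues (Kabsch)
for the RMSD and maximises the core TM-score normalized by the shorter
chain. `avg_rmsd` and `avg_tm` are plain means over pairs, reduced in
canonical pair order; with fewer than 3 core columns the superposition is
underdetermined and the function raises a "core too small" error rather
than returning numbers from a degenerate fit — the honest failure mode
when inputs are too divergent to share a core.

## Synthetic structures and what the tests show

Because real benchmark sets cannot be assumed present, every stage is
exercised on generated data with known ground truth:

* `make_backbone(L, seed)`: a self-avoiding walk with steps of exactly
  3.8 Å (the CA-CA virtual bond), bend angles uniform in [80°, 150°],
  uniform dihedrals, and a 3.5 Å minimum non-adjacent separation —
  protein-like local geometry without pretending to be physics.
* `make_helix(L)`: an ideal alpha-helix (radius 2.3 Å, rise 1.5 Å/residue,
  100°/residue), the fixture for secondary-structure calls.
* `perturb()` / `make_family()`: rigid motion (uniform quaternion
  rotation, translation uniform in [-15, 15] Å per axis) plus isotropic
  Gaussian coordinate noise and optional single-residue indels, returning
  the surviving-residue truth mapping. Residue identities are uniform over
  the 20 standard amino acids so sequence identity is exercised without
  carrying information.

Default family conditions used throughout the tests and the acceptance
script: 8 members of length 80 at $\sigma = 0.3$ Å without indels for
recovery checks (at that noise the correct correspondence is
unambiguous — recovery below 0.9 would indicate an implementation fault,
not hard data); a 12-member, length-60, $\sigma = 0.5$ Å, 2-indel set for
the determinism contract (indels force real gap handling into the merged
profiles). Oracle suites run at deliberately tiny sizes where brute force
is exact: 5-point Kabsch instances against a random-restart rotation
search, score matrices up to 4×4 against exhaustive enumeration of all
monotone alignments, 5-leaf UPGMA against a full-rescan oracle.

What passing these tests does **not** show: performance on real,
full-atom, multi-domain proteins; robustness to chain breaks, missing
residues, or alternative conformations; the quality of the pinned
secondary-structure windows outside ideal geometry. The generator
produces compact random coils, not native folds, so absolute TM-scores
between unrelated synthetic backbones are not calibrated against the
familiar 0.5 "same fold" threshold.

## Numerical choices and limitations

* Gap model: opening $-0.6$ (stage-internal NWDP), $-1$ for the
  secondary-structure seed, extension always free. Values follow the
  published TM-align convention.
* All tolerance-sensitive comparisons (cycle detection, tie-breaks) use
  exact fingerprints or pinned lexicographic rules, never
  floating-point "close enough" tests, which is what makes the
  determinism contract testable byte-for-byte.
* Problem sizes in the default test run are kept small (structures of
  20-80 residues, families of up to 12) so the whole suite runs in well
  under a minute; the algorithms themselves have no size-specific code
  paths.
* Known limitations: sequence-order-independent alignment is not
  attempted; mmCIF input is not read; the reader takes the first model
  and one chain of a PDB file only; no iterative refinement after the
  progressive pass.

## Worked example

```{r example, eval = FALSE}
fam <- make_family(n = 6, L = 50, noise_sigma = 0.3, seed = 2)
psa <- run_all_to_all(fam$members, workers = 2, partitions = 4)
tree <- upgma(to_distance_matrix(psa))
msta <- progressive_align(tree, fam$members, psa)
compute_metrics(msta, fam$members)
truth_recovery(msta, fam)
autoplot(msta)
```
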