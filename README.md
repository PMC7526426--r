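# tmsta

Scalable pairwise and progressive **multiple protein structure alignment**
from C-alpha traces.

Structural biologists routinely need residue-level correspondences across a
set of related protein structures whose sequences have diverged past the
reach of sequence alignment — superfamily members, decoy sets, homology
models. `tmsta` provides the classic two-stage solution as a self-contained
R package:

1. **Stage 1 — pairwise structure alignment.** Every unordered pair is
   aligned TM-align-style: seed alignments (gapless threading,
   secondary-structure, hybrid), Needleman–Wunsch dynamic programming over
   the distance score `1/(1 + (d/d0)^2)` with gap opening −0.6 and free
   extension, alternated with TM-score-optimal superposition (fragment
   seeding plus distance-cutoff refinement) until the mapping cycles. The
   TM-score is

   ```
   TM = (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2),
   d0(L) = max(1.24 (L − 15)^(1/3) − 1.8, 0.5) Å
   ```

   reported under both chain-length normalizations. Pairs are partitioned
   into ordered chunks (with an optional coalesce step) and executed by
   parallel workers; the TM-score-derived distance matrix
   `d = 1 − (TM1 + TM2)/2` feeds stage 2.

2. **Stage 2 — guide tree and progressive merge.** A UPGMA tree (stored as
   an indexed binary tree: leaves `0..N−1`, internal nodes `N..2N−2`) is
   traversed in post-order; each internal node merges its children's
   alignment profiles by column-level dynamic programming with iterative
   re-superposition. Core columns (gap-free in every row) yield the
   alignment metrics: average pairwise RMSD and average TM-score.

**Determinism contract:** workers, partitions, coalesce targets and the
tree-parallelism cutoff change wall-clock time only — every serialized
output (pairwise TSV, distance matrix, Newick tree, gapped FASTA, metrics
JSON) is byte-identical across all settings.

A deterministic synthetic-structure generator (self-avoiding CA backbones,
ideal helices, rigid + noise + indel perturbed families with known
ground-truth correspondences) makes the whole pipeline testable without any
external data.

## Worked example

```r
library(tmsta)

fam  <- make_family(n = 6, L = 50, noise_sigma = 0.3, seed = 2)
psa  <- run_all_to_all(fam$members, workers = 2, partitions = 4)
psa
#> # A tibble: 15 × 10
#>       i     j id1      id2      aligned_length rmsd_aligned tm_norm1 tm_norm2
#>   <int> <int> <chr>    <chr>             <int>        <dbl>    <dbl>    <dbl>
#> 1     1     2 fam2_m01 fam2_m02             50        0.740    0.908    0.908
#> 2     1     3 fam2_m01 fam2_m03             50        0.702    0.915    0.915
#> # ...

tree <- upgma(to_distance_matrix(psa))
msta <- progressive_align(tree, fam$members, psa)
compute_metrics(msta, fam$members)
#> <msta_metrics> 6 structures, 50 columns (50 core): avg RMSD 0.689 A, avg TM 0.9181
truth_recovery(msta, fam)
#> [1] 1
```

All 15 pairs align full-length (50 residues) with sub-Angstrom RMSD, as
expected for a family generated by 0.3 Å coordinate noise; all 50 alignment
columns are core columns and every one recovers the planted ground-truth
correspondence (`truth_recovery = 1`). `autoplot()` methods draw the
distance heatmap (`psa`), the dendrogram (`tree`) and the gap structure of
the alignment (`msta`); `tidy()`/`glance()` return tibbles for downstream
analysis.

A command-line front end is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tmsta.R", package = "tmsta"))')" \
    simulate --output family/ --n 8 --length 80 --sigma 0.3 --seed 1
Rscript .../tmsta.R psa  --input family/ --output out/ --workers 4
Rscript .../tmsta.R msta --input family/ --output out/
```

`msta` writes `alignment.fasta`, `tree.nwk`, `metrics.json`, `pairs.tsv`,
`distance_matrix.tsv` and a per-stage `timing.log`.

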