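#' Assign secondary-structure states from CA geometry
#'
#' Labels each residue H (helix), E (strand) or C (coil) from CA-only
#' distance patterns. Residue k is 'H' when the distances (k-2,k),
#' (k-1,k+1), (k,k+2) and (k-2,k+2) fall in the helical ranges
#' 5.45 +/- 0.5, 5.45 +/- 0.5, 5.45 +/- 0.5 and 6.1 +/- 0.65 Angstrom;
#' 'E' when (k-2,k), (k,k+2), (k-2,k+2) fall in 6.1 +/- 0.65,
#' 6.1 +/- 0.65 and 11.7 +/- 1.4 Angstrom; otherwise 'C'. The first and
#' last two residues are 'C'.
#'
#' @param s A `protein_structure`.
#' @return A character scalar over {H, E, C}, one letter per residue.
#' @export
assign_secondary_structure <- function(s) {
  X <- s$coords
  L <- nrow(X)
  lab <- rep("C", L)
  if (L >= 5) {
    dst <- function(a, b) sqrt(rowSums((X[a, , drop = FALSE] - X[b, , drop = FALSE])^2))
    k <- 3:(L - 2)
    d_m2_0 <- dst(k - 2, k)
    d_m1_p1 <- dst(k - 1, k + 1)
    d_0_p2 <- dst(k, k + 2)
    d_m2_p2 <- dst(k - 2, k + 2)
    in_rng <- function(d, mid, half) abs(d - mid) <= half
    helix <- in_rng(d_m2_0, 5.45, 0.5) & in_rng(d_m1_p1, 5.45, 0.5) &
      in_rng(d_0_p2, 5.45, 0.5) & in_rng(d_m2_p2, 6.1, 0.65)
    strand <- in_rng(d_m2_0, 6.1, 0.65) & in_rng(d_0_p2, 6.1, 0.65) &
      in_rng(d_m2_p2, 11.7, 1.4)
    lab[k] <- ifelse(helix, "H", ifelse(strand, "E", "C"))
  }
  paste(lab, collapse = "")
}

#' Global alignment by Needleman-Wunsch dynamic programming
#'
#' Maximises the sum of matched scores plus `gap_open` per gap opening
#' (gap extension is free). Traceback ties prefer match over a gap in the
#' second structure over a gap in the first.
#'
#' @param score n1 x n2 finite score matrix.
#' @param gap_open Gap-opening penalty (<= 0), default -0.6.
#' @return An m x 2 integer matrix of matched (i, j) pairs, 1-based,
#'   strictly increasing in both columns. Empty matrix for an empty input.
#' @export
#' @examples
#' nwdp(matrix(c(1, 0, 0, 1), 2, 2), gap_open = -0.6)
nwdp <- function(score, gap_open = -0.6) {
  score <- as.matrix(score)
  if (length(score) && !all(is.finite(score))) stop("score matrix must be finite")
  if (gap_open > 0) stop("gap_open must be <= 0")
  m <- cpp_nwdp(score, gap_open)
  as_mapping(m)
}

#' Generate seed alignments for a structure pair
#'
#' Three families of seeds: (a) the best gapless diagonal threading (the
#' offset maximising the TM-score of the implied ungapped mapping under its
#' own superposition); (b) a secondary-structure alignment (NWDP over +1
#' for equal H/E/C labels, gap opening -1); (c) a hybrid of the
#' secondary-structure match score and the distance score under the
#' gapless seed's superposition. Duplicates are removed.
#'
#' @param s1,s2 `protein_structure` objects of length >= 5.
#' @return List of mapping matrices.
#' @export
seed_alignments <- function(s1, s2) {
  L1 <- nrow(s1$coords); L2 <- nrow(s2$coords)
  if (L1 < 5 || L2 < 5) stop("structure too short to align (need >= 5 residues)")
  Lmin <- min(L1, L2)
  d0 <- d0_from_length(Lmin)

  gs <- cpp_gapless_seed(s1$coords, s2$coords, Lmin, d0)
  o <- gs$offset
  j <- max(1, 1 - o):min(L2, L1 - o)
  gapless <- cbind(j + o, j)

  ss1 <- strsplit(assign_secondary_structure(s1), "")[[1]]
  ss2 <- strsplit(assign_secondary_structure(s2), "")[[1]]
  ss_match <- outer(ss1, ss2, `==`) * 1.0
  ss_map <- nwdp(ss_match, gap_open = -1)

  sup <- kabsch_superpose(s1$coords[gapless[, 1], , drop = FALSE],
                          s2$coords[gapless[, 2], , drop = FALSE])
  dist_sc <- cpp_score_matrix(s1$coords, s2$coords,
                              sup$transform$rotation, sup$transform$translation, d0)
  hybrid <- nwdp(0.5 * ss_match + 0.5 * dist_sc, gap_open = -0.6)

  seeds <- list(as_mapping(gapless), ss_map, hybrid)
  seeds <- seeds[vapply(seeds, nrow, integer(1)) >= 3]
  seeds[!duplicated(vapply(seeds, mapping_fingerprint, character(1)))]
}

mapping_fingerprint <- function(m) {
  paste(m[, 1], m[, 2], sep = ":", collapse = ",")
}

#' Iterative refinement of a pairwise alignment
#'
#' Alternates TM-score-optimal superposition on the current mapping with
#' NWDP over the distance score matrix
#' `1 / (1 + (|x1_i - T(x2_j)| / d0)^2)` (d0 from the shorter chain,
#' gap opening -0.6) until a mapping repeats (fingerprint cycle detection)
#' or `max_iter` iterations. Returns the visited mapping with the highest
#' TM-score normalized by the shorter chain.
#'
#' @param s1,s2 `protein_structure` objects.
#' @param seed Non-empty mapping matrix.
#' @param max_iter Iteration cap (default 30).
#' @return The best visited mapping.
#' @export
refine_alignment <- function(s1, s2, seed, max_iter = 30) {
  seed <- as_mapping(seed)
  if (nrow(seed) < 3L) stop("seed mapping too small (need >= 3 pairs)")
  Lmin <- min(nrow(s1$coords), nrow(s2$coords))
  d0 <- d0_from_length(Lmin)
  current <- seed
  seen <- character(0)
  best <- NULL
  best_score <- -Inf
  for (it in seq_len(max_iter)) {
    fp <- mapping_fingerprint(current)
    if (fp %in% seen) break  # cycle detected
    seen <- c(seen, fp)
    opt <- cpp_tm_search(s1$coords, s2$coords, current[, 1], current[, 2],
                         Lmin, d0)
    if (opt$score > best_score) {
      best_score <- opt$score
      best <- current
    }
    S <- cpp_score_matrix(s1$coords, s2$coords, opt$rotation,
                          drop(opt$translation), d0)
    nxt <- nwdp(S, gap_open = -0.6)
    if (nrow(nxt) < 3L) break
    current <- nxt
  }
  best
}

#' Align a pair of protein structures (TM-align style)
#'
#' Runs [refine_alignment()] from every seed of [seed_alignments()] and
#' keeps the candidate maximising the TM-score normalized by the shorter
#' chain. Reports TM-scores under both chain-length normalizations (each
#' with its own d0 and its own optimal superposition), the Kabsch-minimal
#' RMSD over the mapped pairs, and the sequence identity over mapped pairs.
#'
#' @param s1,s2 `protein_structure` objects of length >= 5.
#' @return A `pairwise_alignment`: list with `id1`, `id2`, `mapping`,
#'   `tm_norm1`, `tm_norm2`, `rmsd_aligned`, `aligned_length`,
#'   `seq_identity`.
#' @export
align_pair <- function(s1, s2) {
  L1 <- nrow(s1$coords); L2 <- nrow(s2$coords)
  Lmin <- min(L1, L2)
  seeds <- seed_alignments(s1, s2)
  cands <- lapply(seeds, function(sd) refine_alignment(s1, s2, sd))
  cands <- cands[!vapply(cands, is.null, logical(1))]
  cands <- cands[!duplicated(vapply(cands, mapping_fingerprint, character(1)))]
  scores <- vapply(cands, function(m) {
    tm_score_optimal(s1, s2, m, L_norm = Lmin)$score
  }, numeric(1))
  mapping <- cands[[which.max(scores)]]
  tm1 <- tm_score_optimal(s1, s2, mapping, L_norm = L1)$score
  tm2 <- tm_score_optimal(s1, s2, mapping, L_norm = L2)$score
  sup <- kabsch_superpose(s1$coords[mapping[, 1], , drop = FALSE],
                          s2$coords[mapping[, 2], , drop = FALSE])
  seq_id <- mean(s1$residue_names[mapping[, 1]] == s2$residue_names[mapping[, 2]])
  structure(list(id1 = s1$id, id2 = s2$id, mapping = mapping,
                 tm_norm1 = tm1, tm_norm2 = tm2,
                 rmsd_aligned = sup$rmsd,
                 aligned_length = nrow(mapping),
                 seq_identity = seq_id),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> ", x$id1, " vs ", x$id2,
      ": ", x$aligned_length, " aligned pairs, TM(1)=",
      sprintf("%.4f", x$tm_norm1), ", TM(2)=", sprintf("%.4f", x$tm_norm2),
      ", RMSD=", sprintf("%.3f", x$rmsd_aligned), " A\n", sep = "")
  invisible(x)
}

#' Tidy a pairwise alignment into a table of matched residue pairs
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return A tibble with columns `id1`, `id2`, `i`, `j`.
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  tibble::tibble(id1 = x$id1, id2 = x$id2,
                 i = x$mapping[, 1], j = x$mapping[, 2])
}

#' One-row summary of a pairwise alignment
#'
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @return A one-row tibble of scores.
#' @export
glance.pairwise_alignment <- function(x, ...) {
  tibble::tibble(id1 = x$id1, id2 = x$id2,
                 aligned_length = x$aligned_length,
                 rmsd_aligned = x$rmsd_aligned,
                 tm_norm1 = x$tm_norm1, tm_norm2 = x$tm_norm2,
                 seq_identity = x$seq_identity)
}
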