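# Independent oracles used to validate the numerical core. These stay
# deliberately naive (brute force / exhaustive / full rescans) and never
# share code paths with the package implementation.

rodrigues <- function(r) {
  th <- sqrt(sum(r^2))
  if (th < 1e-12) return(diag(3))
  k <- r / th
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Brute-force rotation search for the minimal superposition RMSD of Q onto
# P: random rotation-vector starts refined by quasi-Newton descent.
brute_force_rmsd <- function(P, Q, n_starts = 40) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  obj <- function(r) {
    R <- rodrigues(r)
    sqrt(mean(rowSums((Pc - Qc %*% t(R))^2)))
  }
  best <- Inf
  for (k in seq_len(n_starts)) {
    r0 <- runif(3, -pi, pi)
    fit <- suppressWarnings(
      stats::optim(r0, obj, method = "BFGS",
                   control = list(reltol = 1e-14, maxit = 500)))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Gap openings implied by a monotone mapping inside an n1 x n2 global
# alignment, grouping unaligned runs (extension is free, so only the
# number of runs matters).
n_gap_openings <- function(pairs, n1, n2) {
  if (nrow(pairs) == 0) return((n1 > 0) + (n2 > 0))
  i <- pairs[, 1]; j <- pairs[, 2]
  opens <- (i[1] > 1) + (j[1] > 1)
  if (nrow(pairs) > 1) {
    opens <- opens + sum(diff(i) > 1) + sum(diff(j) > 1)
  }
  opens + (n1 - i[nrow(pairs)] > 0) + (n2 - j[nrow(pairs)] > 0)
}

# Exhaustive enumeration of every monotone alignment of an n1 x n2 score
# matrix under the opening-only gap model; returns the maximal total score.
exhaustive_alignment_score <- function(S, gap_open) {
  n1 <- nrow(S); n2 <- ncol(S)
  best <- gap_open * n_gap_openings(matrix(0, 0, 2), n1, n2)
  for (k in seq_len(min(n1, n2))) {
    rows <- utils::combn(n1, k)
    cols <- utils::combn(n2, k)
    for (a in seq_len(ncol(rows))) {
      for (b in seq_len(ncol(cols))) {
        pairs <- cbind(rows[, a], cols[, b])
        sc <- sum(S[pairs]) + gap_open * n_gap_openings(pairs, n1, n2)
        if (sc > best) best <- sc
      }
    }
  }
  best
}

dp_mapping_score <- function(S, mapping, gap_open) {
  sum(S[mapping]) + gap_open * n_gap_openings(mapping, nrow(S), ncol(S))
}

# Naive UPGMA: every step recomputes all cluster-cluster averages from the
# original matrix over member sets, ties broken on (min index, max index).
# Returns the merge sequence as a data frame (left, right, height) in
# spec/paper index convention (leaves 0..n-1, internal n..2n-2).
upgma_oracle <- function(D) {
  n <- nrow(D)
  clusters <- lapply(seq_len(n) - 1L, function(k) k)   # member sets
  idx <- seq_len(n) - 1L
  merges <- NULL
  next_idx <- n
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in (a + 1):length(clusters)) {
        dd <- mean(D[clusters[[a]] + 1L, clusters[[b]] + 1L])
        key <- c(dd, min(idx[a], idx[b]), max(idx[a], idx[b]))
        if (is.null(best) || key[1] < best$key[1] - 1e-15 ||
            (abs(key[1] - best$key[1]) <= 1e-15 &&
             (key[2] < best$key[2] ||
              (key[2] == best$key[2] && key[3] < best$key[3])))) {
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    a <- best$a; b <- best$b
    merges <- rbind(merges,
                    data.frame(left = min(idx[a], idx[b]),
                               right = max(idx[a], idx[b]),
                               height = best$key[1] / 2))
    clusters[[a]] <- sort(c(clusters[[a]], clusters[[b]]))
    idx[a] <- next_idx
    next_idx <- next_idx + 1L
    clusters[[b]] <- NULL
    idx <- idx[-b]
  }
  merges
}

# Random rigid copy of a structure (seeded outside).
rigid_copy <- function(s, id = paste0(s$id, "_rigid")) {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  t <- runif(3, -20, 20)
  tmsta:::new_protein_structure(id, s$residue_names, s$residue_numbers,
                                sweep(s$coords %*% t(R), 2, t, `+`))
}

pdb_fixture_lines <- function(coords, resnames = NULL, chain = "A",
                              altloc = " ") {
  if (is.null(resnames)) resnames <- rep("ALA", nrow(coords))
  sprintf("ATOM  %5d  CA %s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          seq_len(nrow(coords)), altloc, resnames, chain,
          seq_len(nrow(coords)), coords[, 1], coords[, 2], coords[, 3])
}
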