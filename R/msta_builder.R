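# Profiles are intermediate alignments: structure indices (into the input
# list), a rows x columns table of 1-based residue indices (NA = gap), and
# one rigid transform per row placing that structure's coordinates into the
# profile's common frame (the frame of its first member).
new_profile <- function(struct_idx, table, transforms) {
  list(struct_idx = struct_idx, table = table, transforms = transforms)
}

leaf_profile <- function(struct_idx, structures) {
  L <- nrow(structures[[struct_idx]]$coords)
  new_profile(struct_idx, matrix(seq_len(L), nrow = 1),
              list(identity_transform()))
}

profile_frame_coords <- function(prof, structures) {
  lapply(seq_along(prof$struct_idx), function(r) {
    transform_coords(structures[[prof$struct_idx[r]]]$coords,
                     prof$transforms[[r]])
  })
}

#' Profile-to-profile score matrix
#'
#' Entry (p, q) is the mean, over all cross pairs (structure a of A with a
#' residue at column p, structure b of B with a residue at column q), of
#' the distance score `1 / (1 + (d / d0_pair)^2)`, where d is the CA
#' distance once B is placed in A's frame by `transform` and `d0_pair`
#' derives from the shorter of the two chains. Gapped entries contribute
#' nothing; a column pair with no residue pair scores 0.
#'
#' @param profA,profB Profiles as built by [progressive_align()] (rows x
#'   columns tables of residue indices with NA gaps, plus per-row frame
#'   transforms).
#' @param structures List of `protein_structure` objects.
#' @param transform Rigid transform from B's frame into A's frame.
#' @return A colsA x colsB numeric matrix.
#' @export
profile_score_matrix <- function(profA, profB, structures, transform) {
  coordsA <- profile_frame_coords(profA, structures)
  coordsB <- profile_frame_coords(profB, structures)
  nA <- ncol(profA$table); nB <- ncol(profB$table)
  acc <- matrix(0, nA, nB)
  cnt <- matrix(0, nA, nB)
  for (a in seq_along(profA$struct_idx)) {
    resA <- profA$table[a, ]
    pa <- which(!is.na(resA))
    La <- nrow(coordsA[[a]])
    for (b in seq_along(profB$struct_idx)) {
      resB <- profB$table[b, ]
      pb <- which(!is.na(resB))
      Lb <- nrow(coordsB[[b]])
      d0p <- d0_from_length(min(La, Lb))
      S <- cpp_score_matrix(coordsA[[a]], coordsB[[b]],
                            transform$rotation, transform$translation, d0p)
      acc[pa, pb] <- acc[pa, pb] + S[resA[pa], resB[pb], drop = FALSE]
      cnt[pa, pb] <- cnt[pa, pb] + 1
    }
  }
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- 0
  out
}

# Residue point pairs implied by matched core columns of a column mapping:
# for each matched (p, q), every (row a with residue at p, row b with
# residue at q) contributes one point pair (A frame vs B frame).
column_point_pairs <- function(profA, profB, coordsA, coordsB, colmap) {
  P <- list(); Q <- list()
  for (k in seq_len(nrow(colmap))) {
    p <- colmap[k, 1]; q <- colmap[k, 2]
    for (a in seq_along(profA$struct_idx)) {
      ra <- profA$table[a, p]
      if (is.na(ra)) next
      for (b in seq_along(profB$struct_idx)) {
        rb <- profB$table[b, q]
        if (is.na(rb)) next
        P[[length(P) + 1L]] <- coordsA[[a]][ra, ]
        Q[[length(Q) + 1L]] <- coordsB[[b]][rb, ]
      }
    }
  }
  list(P = do.call(rbind, P), Q = do.call(rbind, Q))
}

#' Merge two alignment profiles
#'
#' Seeds the relative placement from the structure pair (a in A, b in B)
#' with the smallest stage-1 distance, using that pair's stored pairwise
#' mapping and TM-score-optimal superposition; then iterates profile score
#' matrix -> column NWDP (gap opening -0.6) -> re-superposition on all
#' residue pairs implied by the matched columns, until the column mapping
#' repeats (fingerprint cycle detection) or 10 iterations. Output columns
#' follow the NWDP path: matched columns are merged, unmatched columns are
#' inserted with gaps in the other profile's rows (A-side runs first);
#' row-internal residue order is preserved.
#'
#' @param profA,profB Profiles over disjoint structure sets.
#' @param structures List of `protein_structure` objects.
#' @param psa Stage-1 `psa_result_set` covering the structures.
#' @param max_iter Merge iteration cap (default 10).
#' @return The merged profile.
#' @export
merge_nodes <- function(profA, profB, structures, psa, max_iter = 10) {
  if (!length(profA$struct_idx) || !length(profB$struct_idx)) {
    stop("cannot merge an empty profile")
  }
  # seed pair: minimum stage-1 distance across the two member sets
  cand <- psa[(psa$i %in% profA$struct_idx & psa$j %in% profB$struct_idx) |
              (psa$i %in% profB$struct_idx & psa$j %in% profA$struct_idx), ]
  if (!nrow(cand)) stop("stage-1 results missing for this merge")
  dist <- 1 - (cand$tm_norm1 + cand$tm_norm2) / 2
  row <- which(dist == min(dist))[1]
  i <- cand$i[row]; j <- cand$j[row]
  m <- cand$mapping[[row]]
  if (i %in% profA$struct_idx) { a <- i; b <- j; map_ab <- m }
  else { a <- j; b <- i; map_ab <- m[, 2:1, drop = FALSE] }
  sa <- structures[[a]]; sb <- structures[[b]]
  opt <- tm_score_optimal(sa, sb, map_ab)  # sb coords -> sa frame
  # compose into profile frames: Bframe -> bOrig -> aOrig -> Aframe
  Ta <- profA$transforms[[match(a, profA$struct_idx)]]
  Tb <- profB$transforms[[match(b, profB$struct_idx)]]
  M <- compose_transforms(compose_transforms(Ta, opt$transform),
                          invert_transform(Tb))

  if (nrow(profA$table) == 1L && nrow(profB$table) == 1L) {
    # singleton-singleton merge: reuse the stage-1 alignment directly (the
    # profile iteration would just replay the pairwise refinement)
    return(build_merged_profile(profA, profB, as_mapping(map_ab), M))
  }

  coordsA <- profile_frame_coords(profA, structures)
  coordsB_own <- profile_frame_coords(profB, structures)
  seen <- character(0)
  colmap <- NULL
  for (it in seq_len(max_iter)) {
    S <- profile_score_matrix(profA, profB, structures, M)
    colmap <- nwdp(S, gap_open = -0.6)
    fp <- mapping_fingerprint(colmap)
    if (fp %in% seen) break
    seen <- c(seen, fp)
    if (nrow(colmap) < 3L) break
    pp <- column_point_pairs(profA, profB, coordsA, coordsB_own, colmap)
    if (nrow(pp$P) < 3L) break
    sup <- kabsch_superpose(pp$P, pp$Q)
    M <- sup$transform
  }

  build_merged_profile(profA, profB, colmap, M)
}

# Assemble the merged profile along a column mapping path: matched columns
# merged, unmatched columns inserted with gaps in the other profile's rows
# (A-side runs first).
build_merged_profile <- function(profA, profB, colmap, M) {
  nA <- ncol(profA$table); nB <- ncol(profB$table)
  colsA <- integer(0); colsB <- integer(0)
  pa <- 1L; pb <- 1L
  emit <- function(ca, cb) {
    colsA <<- c(colsA, ca); colsB <<- c(colsB, cb)
  }
  for (k in seq_len(nrow(colmap))) {
    while (pa < colmap[k, 1]) { emit(pa, NA_integer_); pa <- pa + 1L }
    while (pb < colmap[k, 2]) { emit(NA_integer_, pb); pb <- pb + 1L }
    emit(pa, pb); pa <- pa + 1L; pb <- pb + 1L
  }
  while (pa <= nA) { emit(pa, NA_integer_); pa <- pa + 1L }
  while (pb <= nB) { emit(NA_integer_, pb); pb <- pb + 1L }

  rowsA <- nrow(profA$table); rowsB <- nrow(profB$table)
  tab <- matrix(NA_integer_, rowsA + rowsB, length(colsA))
  okA <- !is.na(colsA)
  tab[seq_len(rowsA), okA] <- profA$table[, colsA[okA], drop = FALSE]
  okB <- !is.na(colsB)
  tab[rowsA + seq_len(rowsB), okB] <- profB$table[, colsB[okB], drop = FALSE]

  new_profile(c(profA$struct_idx, profB$struct_idx), tab,
              c(profA$transforms,
                lapply(profB$transforms, function(Tr) compose_transforms(M, Tr))))
}

#' Progressive multiple structure alignment over a guide tree
#'
#' Post-order evaluation: leaves yield single-row profiles and each
#' internal node merges its children ([merge_nodes()]). Children of nodes
#' at depth below `cutoff` may be evaluated concurrently; deeper subtrees
#' run serially, and a parent never starts before both children finish.
#' The result is identical to the fully serial traversal for every cutoff
#' and worker count (parallelism is a time-only knob). The default
#' `cutoff = 0` keeps the traversal serial.
#'
#' @param tree A `guide_tree` whose leaves index `structures` in order.
#' @param structures List of `protein_structure` objects.
#' @param psa Complete all-to-all `psa_result_set` for `structures`.
#' @param cutoff Maximum depth at which child subtrees may run
#'   concurrently (default 0 = serial).
#' @param workers Worker process bound used when `cutoff > 0`.
#' @return An `msta_alignment`: list with `structure_ids`, `table`
#'   (rows x columns matrix of 1-based residue indices, NA = gap),
#'   `n_columns`, and per-row `transforms` into the common frame.
#' @export
progressive_align <- function(tree, structures, psa, cutoff = 0L, workers = 1L) {
  n <- tree$n_leaves
  if (n != length(structures)) stop("tree leaves do not match structures")
  if (nrow(psa) != n * (n - 1) / 2) {
    stop("incomplete stage-1 result set: expected ", n * (n - 1) / 2,
         " pairs, got ", nrow(psa))
  }
  eval_node <- function(node, depth) {
    if (is_leaf(tree, node)) return(leaf_profile(node + 1L, structures))
    ch <- node_children(tree, node)
    if (depth < cutoff && workers > 1L && .Platform$OS.type == "unix") {
      kids <- parallel::mclapply(ch, function(c) eval_node(c, depth + 1L),
                                 mc.cores = 2L)
      # surface child errors (mclapply returns try-errors)
      for (k in kids) if (inherits(k, "try-error")) stop(k)
    } else {
      kids <- lapply(ch, function(c) eval_node(c, depth + 1L))
    }
    merge_nodes(kids[[1]], kids[[2]], structures, psa)
  }
  prof <- eval_node(tree$root, 0L)
  ids <- vapply(structures, function(s) s$id, character(1))
  structure(list(structure_ids = ids[prof$struct_idx],
                 table = prof$table,
                 n_columns = ncol(prof$table),
                 transforms = prof$transforms),
            class = "msta_alignment")
}

#' @export
print.msta_alignment <- function(x, ...) {
  cat("<msta_alignment> ", length(x$structure_ids), " structures x ",
      x$n_columns, " columns (", length(core_columns(x)), " core)\n", sep = "")
  invisible(x)
}

#' Core columns of a multiple alignment
#'
#' Columns where every row holds a residue (no gaps), in order; the common
#' structural core used for metrics.
#'
#' @param msta An `msta_alignment` (or a profile table).
#' @return Integer vector of column indices.
#' @export
core_columns <- function(msta) {
  tab <- if (is.matrix(msta)) msta else msta$table
  which(colSums(is.na(tab)) == 0L)
}

#' Alignment-quality metrics for a multiple structure alignment
#'
#' For every unordered structure pair the core-column residue pairs are
#' superposed (Kabsch) for the RMSD, and the TM-score over the core pairs
#' is maximised with normalization by the shorter chain. `avg_rmsd` and
#' `avg_tm` are means over pairs, reduced in canonical pair order, so the
#' values are independent of worker count and processing order.
#'
#' @param msta An `msta_alignment`.
#' @param structures List of `protein_structure` objects (>= 2 rows used).
#' @param workers Worker process count for the pair loop (default 1).
#' @return An `msta_metrics`: list with `avg_rmsd`, `avg_tm`, `n_columns`,
#'   `n_core_columns`, `n_structures`.
#' @export
compute_metrics <- function(msta, structures, workers = 1L) {
  ids <- vapply(structures, function(s) s$id, character(1))
  rows <- match(msta$structure_ids, ids)
  nr <- length(rows)
  if (nr < 2) stop("need at least 2 structures for metrics")
  core <- core_columns(msta)
  if (length(core) < 3) stop("core too small for superposition (need >= 3 core columns)")
  pairs <- enumerate_pairs(nr)
  one <- function(k) {
    r1 <- pairs$i[k]; r2 <- pairs$j[k]
    s1 <- structures[[rows[r1]]]; s2 <- structures[[rows[r2]]]
    map <- cbind(msta$table[r1, core], msta$table[r2, core])
    sup <- kabsch_superpose(s1$coords[map[, 1], , drop = FALSE],
                            s2$coords[map[, 2], , drop = FALSE])
    tm <- tm_score_optimal(s1, s2, map,
                           L_norm = min(nrow(s1$coords), nrow(s2$coords)))$score
    c(rmsd = sup$rmsd, tm = tm)
  }
  vals <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(pairs)), one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(pairs)), one)
  }
  vals <- do.call(rbind, vals)  # canonical pair order
  structure(list(avg_rmsd = mean(vals[, "rmsd"]),
                 avg_tm = mean(vals[, "tm"]),
                 n_columns = msta$n_columns,
                 n_core_columns = length(core),
                 n_structures = nr),
            class = "msta_metrics")
}

#' @export
print.msta_metrics <- function(x, ...) {
  cat("<msta_metrics> ", x$n_structures, " structures, ", x$n_columns,
      " columns (", x$n_core_columns, " core): avg RMSD ",
      sprintf("%.3f", x$avg_rmsd), " A, avg TM ",
      sprintf("%.4f", x$avg_tm), "\n", sep = "")
  invisible(x)
}

#' One-row summary of MSTA metrics
#'
#' @param x An `msta_metrics` or `msta_alignment` (the latter requires
#'   `structures`).
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.msta_metrics <- function(x, ...) {
  tibble::tibble(avg_rmsd = x$avg_rmsd, avg_tm = x$avg_tm,
                 n_columns = x$n_columns, n_core_columns = x$n_core_columns,
                 n_structures = x$n_structures)
}

#' Metrics as a canonical JSON string
#'
#' @param metrics An `msta_metrics`.
#' @param path Optional output path.
#' @return JSON text `{avg_rmsd, avg_tm, n_columns, n_core_columns,
#'   n_structures}` (invisibly when `path` is given).
#' @export
metrics_json <- function(metrics, path = NULL) {
  txt <- jsonlite::toJSON(
    list(avg_rmsd = metrics$avg_rmsd, avg_tm = metrics$avg_tm,
         n_columns = metrics$n_columns,
         n_core_columns = metrics$n_core_columns,
         n_structures = metrics$n_structures),
    auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Tidy a multiple alignment into a long residue table
#'
#' @param x An `msta_alignment`.
#' @param ... Unused.
#' @return A tibble with `structure_id`, `row`, `column`, `residue_index`
#'   (NA at gaps) and `is_core`.
#' @export
tidy.msta_alignment <- function(x, ...) {
  core <- core_columns(x)
  tibble::tibble(
    structure_id = rep(x$structure_ids, each = x$n_columns),
    row = rep(seq_along(x$structure_ids), each = x$n_columns),
    column = rep(seq_len(x$n_columns), times = length(x$structure_ids)),
    residue_index = as.vector(t(x$table)),
    is_core = rep(seq_len(x$n_columns) %in% core,
                  times = length(x$structure_ids)))
}

#' Gap-structure plot of a multiple alignment
#'
#' @param object An `msta_alignment`.
#' @param ... Unused.
#' @return A ggplot object (rows = structures, columns = alignment
#'   positions; core columns highlighted).
#' @export
autoplot.msta_alignment <- function(object, ...) {
  df <- tidy.msta_alignment(object)
  df$state <- ifelse(is.na(df$residue_index), "gap",
                     ifelse(df$is_core, "core", "aligned"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$structure_id,
                                   fill = .data$state)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(core = "#1b7837", aligned = "#a6dba0",
                                          gap = "grey90")) +
    ggplot2::labs(x = "alignment column", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
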