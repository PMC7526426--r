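#' Enumerate all unordered structure pairs
#'
#' All pairs (i, j) with i < j in lexicographic order; self-pairs and
#' duplicates of the cartesian product are removed, leaving n(n-1)/2 pairs.
#'
#' @param n Number of structures (>= 0).
#' @return A tibble with integer columns `i`, `j` (1-based).
#' @export
#' @examples
#' nrow(enumerate_pairs(100))  # 4950
enumerate_pairs <- function(n) {
  stopifnot(n >= 0)
  if (n < 2) return(tibble::tibble(i = integer(0), j = integer(0)))
  idx <- utils::combn(n, 2)
  tibble::tibble(i = idx[1, ], j = idx[2, ])
}

#' Split an ordered work list into contiguous partitions
#'
#' `min(k, n_items)` contiguous chunks whose sizes differ by at most one,
#' larger chunks first, preserving order.
#'
#' @param items A data frame (rows are items) or a list.
#' @param k Requested partition count (>= 1).
#' @return List of `work_partition` objects: `list(index, items)`.
#' @export
partition_work <- function(items, k) {
  if (k < 1) stop("partition count must be >= 1")
  n <- if (is.data.frame(items)) nrow(items) else length(items)
  kk <- min(k, n)
  if (kk == 0L) return(list())
  sizes <- rep(n %/% kk, kk)
  extra <- n %% kk
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(kk), function(p) {
    sel <- starts[p]:ends[p]
    chunk <- if (is.data.frame(items)) items[sel, , drop = FALSE] else items[sel]
    structure(list(index = p, items = chunk), class = "work_partition")
  })
}

#' Fuse adjacent partitions to a target count
#'
#' Merges adjacent partitions into `m` partitions with near-equal item
#' counts while preserving the global item order. Asking for more
#' partitions than exist is a no-op with a warning (coalescing never
#' expands).
#'
#' @param partitions List of `work_partition` objects.
#' @param m Target count, 1 <= m <= length(partitions).
#' @return List of `work_partition` objects, re-indexed 1..m.
#' @export
coalesce_partitions <- function(partitions, m) {
  np <- length(partitions)
  if (m > np) {
    warning("coalesce target exceeds partition count; no-op")
    return(partitions)
  }
  if (m < 1) stop("coalesce target must be >= 1")
  counts <- vapply(partitions, function(p) {
    if (is.data.frame(p$items)) nrow(p$items) else length(p$items)
  }, integer(1))
  total <- sum(counts)
  groups <- integer(np)
  g <- 1L
  acc <- 0L
  done <- 0L   # items assigned to closed + current groups so far
  for (p in seq_len(np)) {
    if (g < m && acc > 0L) {
      # close the group at its fair cumulative share, or early enough that
      # every remaining group still receives at least one partition
      must_close <- (m - g) >= (np - p + 1L)
      if (must_close || done >= total * g / m - 1e-9) {
        g <- g + 1L
        acc <- 0L
      }
    }
    groups[p] <- g
    acc <- acc + counts[p]
    done <- done + counts[p]
  }
  lapply(seq_len(m), function(gi) {
    chunks <- lapply(partitions[groups == gi], `[[`, "items")
    merged <- if (is.data.frame(chunks[[1]])) do.call(rbind, chunks) else do.call(c, chunks)
    structure(list(index = gi, items = merged), class = "work_partition")
  })
}

# Align one (i, j) pair, failing fast with the pair id.
align_one <- function(structures, i, j) {
  tryCatch(align_pair(structures[[i]], structures[[j]]),
           error = function(e) {
             stop("pair (", i, ", ", j, ") failed: ", conditionMessage(e),
                  call. = FALSE)
           })
}

run_partitions <- function(partitions, workers, fun) {
  if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(partitions, fun, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(partitions, fun)
  }
}

#' All-to-all pairwise structure alignment
#'
#' Aligns every unordered pair exactly once. Work is split into ordered
#' partitions consumed by worker processes; results are collected and
#' re-sorted into enumeration order, so the result set is identical for
#' any (workers, partitions, coalesce) setting - parallelism affects time
#' only, never values. Any failing pair aborts the run naming the pair.
#'
#' @param structures List of `protein_structure` objects.
#' @param workers Worker process count (default 1).
#' @param partitions Initial partition count (default `workers`).
#' @param coalesce_to Optional target partition count after fusion.
#' @return A `psa_result_set`: tibble with one row per pair (`i`, `j`,
#'   `id1`, `id2`, `aligned_length`, `rmsd_aligned`, `tm_norm1`,
#'   `tm_norm2`, `seq_identity`, list-column `mapping`), with attribute
#'   `n_structures`.
#' @export
run_all_to_all <- function(structures, workers = 1L, partitions = workers,
                           coalesce_to = NULL) {
  stopifnot(workers >= 1, partitions >= 1)
  pairs <- enumerate_pairs(length(structures))
  parts <- partition_work(pairs, partitions)
  if (!is.null(coalesce_to)) parts <- coalesce_partitions(parts, coalesce_to)
  chunks <- run_partitions(parts, workers, function(p) {
    lapply(seq_len(nrow(p$items)), function(r) {
      align_one(structures, p$items$i[r], p$items$j[r])
    })
  })
  alns <- do.call(c, c(chunks, list(list())))
  res <- dplyr::bind_rows(lapply(alns, glance))
  res <- dplyr::bind_cols(
    tibble::tibble(
      i = unlist(lapply(parts, function(p) p$items$i)),
      j = unlist(lapply(parts, function(p) p$items$j))),
    res)
  res$mapping <- lapply(alns, `[[`, "mapping")
  res <- dplyr::arrange(res, .data$i, .data$j)  # enumeration order
  new_psa_result_set(res, length(structures))
}

new_psa_result_set <- function(tbl, n_structures) {
  out <- tibble::as_tibble(tbl)
  attr(out, "n_structures") <- as.integer(n_structures)
  class(out) <- c("psa_result_set", class(out))
  out
}

#' One-to-all pairwise structure alignment
#'
#' Aligns a query against every database entry, preserving database order,
#' under the same determinism contract as [run_all_to_all()].
#'
#' @param query A `protein_structure`.
#' @param db List of `protein_structure` objects.
#' @inheritParams run_all_to_all
#' @return A tibble with one row per database entry, in database order.
#' @export
run_one_to_all <- function(query, db, workers = 1L, partitions = workers,
                           coalesce_to = NULL) {
  stopifnot(workers >= 1, partitions >= 1)
  idx <- tibble::tibble(j = seq_along(db))
  parts <- partition_work(idx, partitions)
  if (!is.null(coalesce_to)) parts <- coalesce_partitions(parts, coalesce_to)
  chunks <- run_partitions(parts, workers, function(p) {
    lapply(p$items$j, function(j) {
      tryCatch(align_pair(query, db[[j]]),
               error = function(e) stop("db entry ", j, " failed: ",
                                        conditionMessage(e), call. = FALSE))
    })
  })
  alns <- do.call(c, c(chunks, list(list())))
  ord <- order(unlist(lapply(parts, function(p) p$items$j)))
  alns <- alns[ord]
  res <- dplyr::bind_rows(lapply(alns, glance))
  res$mapping <- lapply(alns, `[[`, "mapping")
  res
}

#' Distance matrix from an all-to-all result set
#'
#' `d[i, j] = 1 - (tm_norm1 + tm_norm2) / 2` for i != j, zero diagonal,
#' symmetric by construction, entries in \[0, 1\].
#'
#' @param resultset A complete `psa_result_set`.
#' @return An n x n numeric matrix with structure ids as dimnames.
#' @export
to_distance_matrix <- function(resultset) {
  n <- attr(resultset, "n_structures")
  expected <- enumerate_pairs(n)
  key <- paste(resultset$i, resultset$j)
  miss <- setdiff(paste(expected$i, expected$j), key)
  if (length(miss)) {
    stop("incomplete result set: missing pair(s) ",
         paste(head(miss, 5), collapse = "; "), call. = FALSE)
  }
  ids <- character(n)
  ids[resultset$i] <- resultset$id1
  ids[resultset$j] <- resultset$id2
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  d <- 1 - (resultset$tm_norm1 + resultset$tm_norm2) / 2
  D[cbind(resultset$i, resultset$j)] <- d
  D[cbind(resultset$j, resultset$i)] <- d
  D
}

#' Serialize / parse pairwise results as TSV
#'
#' Columns: `id1`, `id2`, `aligned_length`, `rmsd_aligned`, `tm_norm1`,
#' `tm_norm2`, `seq_identity`, `mapping` (compact `"i:j,i:j,..."` with
#' 0-based residue indices). The round-trip is lossless.
#'
#' @param resultset A `psa_result_set`.
#' @param path Optional output path.
#' @return The TSV text (invisibly when `path` is given).
#' @export
write_results_tsv <- function(resultset, path = NULL) {
  map_str <- vapply(resultset$mapping, function(m) {
    paste(m[, 1] - 1L, m[, 2] - 1L, sep = ":", collapse = ",")
  }, character(1))
  lines <- c(
    "id1\tid2\taligned_length\trmsd_aligned\ttm_norm1\ttm_norm2\tseq_identity\tmapping",
    sprintf("%s\t%s\t%d\t%.17g\t%.17g\t%.17g\t%.17g\t%s",
            resultset$id1, resultset$id2, resultset$aligned_length,
            resultset$rmsd_aligned, resultset$tm_norm1, resultset$tm_norm2,
            resultset$seq_identity, map_str))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_results_tsv
#' @param text TSV text or path produced by [write_results_tsv()].
#' @param structure_ids Ordered ids of the aligned structures (recovers the
#'   `i`, `j` indices); inferred from the table when omitted.
#' @export
read_results_tsv <- function(text, structure_ids = NULL) {
  lines <- if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
               file.exists(text)) {
    readLines(text, warn = FALSE)
  } else if (length(text) == 1L) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else text
  lines <- lines[nzchar(lines)]
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  want <- c("id1", "id2", "aligned_length", "rmsd_aligned", "tm_norm1",
            "tm_norm2", "seq_identity", "mapping")
  if (!identical(header, want)) stop("malformed header row")
  rows <- lapply(seq_along(lines[-1]), function(r) {
    f <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1]]
    if (length(f) != 8L) stop("malformed row ", r, ": expected 8 fields")
    f
  })
  parse_map <- function(str, row) {
    if (!nzchar(str)) return(matrix(integer(0), 0, 2))
    toks <- strsplit(strsplit(str, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    m <- do.call(rbind, lapply(toks, function(t) {
      v <- suppressWarnings(as.integer(t))
      if (length(v) != 2L || anyNA(v)) stop("malformed mapping in row ", row)
      v
    }))
    as_mapping(m + 1L)
  }
  tbl <- tibble::tibble(
    id1 = vapply(rows, `[[`, character(1), 1),
    id2 = vapply(rows, `[[`, character(1), 2),
    aligned_length = as.integer(vapply(rows, `[[`, character(1), 3)),
    rmsd_aligned = as.numeric(vapply(rows, `[[`, character(1), 4)),
    tm_norm1 = as.numeric(vapply(rows, `[[`, character(1), 5)),
    tm_norm2 = as.numeric(vapply(rows, `[[`, character(1), 6)),
    seq_identity = as.numeric(vapply(rows, `[[`, character(1), 7)))
  tbl$mapping <- lapply(seq_along(rows), function(r) parse_map(rows[[r]][8], r))
  if (is.null(structure_ids)) {
    structure_ids <- unique(c(rbind(tbl$id1, tbl$id2)))
  }
  tbl <- dplyr::bind_cols(
    tibble::tibble(i = match(tbl$id1, structure_ids),
                   j = match(tbl$id2, structure_ids)), tbl)
  tbl <- dplyr::arrange(tbl, .data$i, .data$j)
  new_psa_result_set(tbl, length(structure_ids))
}

#' Heatmap of pairwise TM-score distances
#'
#' @param object A `psa_result_set`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_result_set <- function(object, ...) {
  D <- to_distance_matrix(object)
  df <- tibble::tibble(
    id1 = rep(rownames(D), times = ncol(D)),
    id2 = rep(colnames(D), each = nrow(D)),
    distance = as.vector(D))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id1, y = .data$id2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "1 - mean TM") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
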