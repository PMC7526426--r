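# End-to-end pipeline surface behind the command-line front end
# (inst/cli/tmsta.R). Each command writes its outputs plus a structured
# per-stage timing log; timings are informational only, results are
# byte-reproducible for any parallelism setting.

read_structure_dir <- function(input) {
  files <- sort(list.files(input, pattern = "\\.(pdb|ent)$", full.names = TRUE))
  if (!length(files)) stop("no PDB files found in ", input)
  lapply(files, read_structure)
}

stage_log <- function(stages, path) {
  lines <- sprintf("%s\t%.3f s", names(stages), as.numeric(stages))
  writeLines(lines, path)
  invisible(lines)
}

write_distance_tsv <- function(D, path) {
  lines <- c(paste(c("id", colnames(D)), collapse = "\t"),
             vapply(seq_len(nrow(D)), function(r) {
               paste(c(rownames(D)[r], sprintf("%.17g", D[r, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Stage 1: pairwise structure alignment over a structure directory
#'
#' Reads all PDB files under `input`, runs the all-to-all (or one-to-all)
#' alignment engine, and writes `pairs.tsv`, `distance_matrix.tsv` (all-
#' to-all only) and `timing.log` under `output`.
#'
#' @param input Directory of PDB files, or a list of `protein_structure`s.
#' @param output Output directory (created if needed).
#' @param mode `"all-to-all"` or `"one-to-all"`.
#' @param query Structure id of the query (one-to-all mode).
#' @param workers,partitions,coalesce_to Parallelism knobs (time-only).
#' @return Invisibly, the result set.
#' @export
run_psa <- function(input, output, mode = c("all-to-all", "one-to-all"),
                    query = NULL, workers = 1L, partitions = workers,
                    coalesce_to = NULL) {
  mode <- match.arg(mode)
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  structures <- if (is.character(input)) read_structure_dir(input) else input
  t_read <- proc.time()[["elapsed"]]
  if (mode == "one-to-all") {
    if (is.null(query)) stop("one-to-all mode requires a query id")
    ids <- vapply(structures, function(s) s$id, character(1))
    qi <- match(query, ids)
    if (is.na(qi)) stop("query id '", query, "' not found")
    res <- run_one_to_all(structures[[qi]], structures[-qi],
                          workers = workers, partitions = partitions,
                          coalesce_to = coalesce_to)
    t_align <- proc.time()[["elapsed"]]
    rs <- new_psa_result_set(
      dplyr::bind_cols(tibble::tibble(i = 1L, j = seq_len(nrow(res)) + 1L), res),
      nrow(res) + 1L)
    write_results_tsv(rs, file.path(output, "pairs.tsv"))
  } else {
    res <- run_all_to_all(structures, workers = workers,
                          partitions = partitions, coalesce_to = coalesce_to)
    t_align <- proc.time()[["elapsed"]]
    write_results_tsv(res, file.path(output, "pairs.tsv"))
    write_distance_tsv(to_distance_matrix(res),
                       file.path(output, "distance_matrix.tsv"))
  }
  t_end <- proc.time()[["elapsed"]]
  stage_log(c(read = t_read - t0, align = t_align - t_read,
              collect = t_end - t_align),
            file.path(output, "timing.log"))
  invisible(res)
}

#' Stage 1 + 2: full multiple structure alignment pipeline
#'
#' Runs (or loads) the all-to-all stage, builds the UPGMA guide tree,
#' merges profiles progressively, and writes `alignment.fasta`,
#' `tree.nwk`, `metrics.json`, `pairs.tsv`, `distance_matrix.tsv` and a
#' per-stage `timing.log` (PSA / tree / incremental alignment / metrics).
#'
#' @inheritParams run_psa
#' @param cutoff Tree-parallelism depth for [progressive_align()]
#'   (default 0 = serial traversal).
#' @param pairs_tsv Optional path of a precomputed stage-1 TSV to reuse.
#' @return Invisibly, a list with `msta`, `tree`, `metrics`, `psa`.
#' @export
run_msta <- function(input, output, workers = 1L, partitions = workers,
                     coalesce_to = NULL, cutoff = 0L, pairs_tsv = NULL) {
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  structures <- if (is.character(input)) read_structure_dir(input) else input
  if (length(structures) < 2) stop("need at least 2 structures")
  ids <- vapply(structures, function(s) s$id, character(1))
  psa <- if (is.null(pairs_tsv)) {
    run_all_to_all(structures, workers = workers, partitions = partitions,
                   coalesce_to = coalesce_to)
  } else {
    read_results_tsv(pairs_tsv, structure_ids = ids)
  }
  write_results_tsv(psa, file.path(output, "pairs.tsv"))
  D <- to_distance_matrix(psa)
  write_distance_tsv(D, file.path(output, "distance_matrix.tsv"))
  t_psa <- proc.time()[["elapsed"]]
  tree <- upgma(D)
  writeLines(to_newick(tree), file.path(output, "tree.nwk"))
  t_tree <- proc.time()[["elapsed"]]
  msta <- progressive_align(tree, structures, psa, cutoff = cutoff,
                            workers = workers)
  write_alignment_fasta(msta, structures, file.path(output, "alignment.fasta"))
  t_aln <- proc.time()[["elapsed"]]
  metrics <- compute_metrics(msta, structures, workers = workers)
  metrics_json(metrics, file.path(output, "metrics.json"))
  t_end <- proc.time()[["elapsed"]]
  stage_log(c(psa = t_psa - t0, tree = t_tree - t_psa,
              incremental_alignment = t_aln - t_tree,
              metrics = t_end - t_aln),
            file.path(output, "timing.log"))
  invisible(list(msta = msta, tree = tree, metrics = metrics, psa = psa))
}

#' Simulate a structure family into a PDB directory
#'
#' Writes one PDB file per member plus `truth.json` carrying the
#' generation parameters and the 1-based truth mappings.
#'
#' @param output Output directory.
#' @param n,L,noise_sigma,n_indels,seed Family parameters (see
#'   [make_family()]).
#' @return Invisibly, the `family_truth`.
#' @export
run_simulate <- function(output, n = 8L, L = 80L, noise_sigma = 0.3,
                         n_indels = 0L, seed = 1L) {
  dir.create(output, showWarnings = FALSE, recursive = TRUE)
  fam <- make_family(n, L, noise_sigma, n_indels, seed)
  for (m in fam$members) {
    write_pdb(m, file.path(output, paste0(m$id, ".pdb")))
  }
  truth <- list(
    params = fam$params,
    mappings = setNames(
      lapply(fam$truth_mappings, function(tr) {
        list(member = tr[, "member"], ancestor = tr[, "ancestor"])
      }),
      vapply(fam$members, function(s) s$id, character(1))))
  writeLines(as.character(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA)),
             file.path(output, "truth.json"))
  invisible(fam)
}
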