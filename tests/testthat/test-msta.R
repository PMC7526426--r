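make_msta_inputs <- function(n, L, sigma, seed, indels = 0L) {
  fam <- make_family(n, L, noise_sigma = sigma, n_indels = indels, seed = seed)
  psa <- run_all_to_all(fam$members)
  tree <- upgma(to_distance_matrix(psa))
  list(fam = fam, psa = psa, tree = tree)
}

test_that("profile score matrix is 1 on the diagonal for a self pair", {
  s <- make_backbone(20, 201)
  pA <- tmsta:::leaf_profile(1L, list(s, s))
  pB <- tmsta:::leaf_profile(2L, list(s, s))
  S <- profile_score_matrix(pA, pB, list(s, s), tmsta:::identity_transform())
  expect_equal(diag(S), rep(1, 20))
  expect_true(all(S <= 1 + 1e-12))
})

test_that("gap columns contribute nothing and empty cross pairs score 0", {
  s <- make_backbone(10, 202)
  pA <- tmsta:::leaf_profile(1L, list(s, s))
  pB <- tmsta:::leaf_profile(2L, list(s, s))
  # give B a leading all-gap column
  pB$table <- cbind(NA_integer_, pB$table)
  S <- profile_score_matrix(pA, pB, list(s, s), tmsta:::identity_transform())
  expect_equal(S[, 1], rep(0, 10))
})

test_that("profile scores equal a direct double-loop recomputation", {
  inp <- make_msta_inputs(4, 18, 0.5, 203)
  structures <- inp$fam$members
  # build two 2-row profiles via the tree's first two cherries if present;
  # otherwise merge leaves 1+2 and 3+4 directly
  pA <- merge_nodes(tmsta:::leaf_profile(1L, structures),
                    tmsta:::leaf_profile(2L, structures),
                    structures, inp$psa)
  pB <- merge_nodes(tmsta:::leaf_profile(3L, structures),
                    tmsta:::leaf_profile(4L, structures),
                    structures, inp$psa)
  Tm <- tmsta:::identity_transform()
  S <- profile_score_matrix(pA, pB, structures, Tm)
  coordsA <- tmsta:::profile_frame_coords(pA, structures)
  coordsB <- tmsta:::profile_frame_coords(pB, structures)
  for (p in sample(ncol(pA$table), 4)) {
    for (q in sample(ncol(pB$table), 4)) {
      acc <- 0; cnt <- 0
      for (a in 1:2) for (b in 1:2) {
        ra <- pA$table[a, p]; rb <- pB$table[b, q]
        if (is.na(ra) || is.na(rb)) next
        La <- nrow(structures[[pA$struct_idx[a]]]$coords)
        Lb <- nrow(structures[[pB$struct_idx[b]]]$coords)
        d <- sqrt(sum((coordsA[[a]][ra, ] - coordsB[[b]][rb, ])^2))
        acc <- acc + 1 / (1 + (d / d0_from_length(min(La, Lb)))^2)
        cnt <- cnt + 1
      }
      expect_equal(S[p, q], if (cnt) acc / cnt else 0, tolerance = 1e-12)
    }
  }
})

test_that("merging copies of one structure yields an ungapped alignment", {
  s <- make_backbone(20, 204)
  set.seed(204)
  r <- rigid_copy(s, id = "copyB")
  structures <- list(s, r)
  psa <- run_all_to_all(structures)
  merged <- merge_nodes(tmsta:::leaf_profile(1L, structures),
                        tmsta:::leaf_profile(2L, structures),
                        structures, psa)
  expect_equal(ncol(merged$table), 20)
  expect_false(anyNA(merged$table))
})

test_that("merged profiles keep every residue exactly once, in order", {
  inp <- make_msta_inputs(6, 22, 0.6, 205, indels = 1L)
  structures <- inp$fam$members
  msta <- progressive_align(inp$tree, structures, inp$psa)
  ids <- vapply(structures, function(s) s$id, character(1))
  for (r in seq_along(msta$structure_ids)) {
    s <- structures[[match(msta$structure_ids[r], ids)]]
    ent <- msta$table[r, ]
    ent <- ent[!is.na(ent)]
    expect_equal(ent, seq_len(nrow(s$coords)))  # all residues, in order
  }
  expect_true(all(colSums(!is.na(msta$table)) > 0))  # no all-gap column
})

test_that("two-structure MSTA reduces exactly to the pairwise alignment", {
  fam <- make_family(2, 30, noise_sigma = 0.5, seed = 206)
  pa <- align_pair(fam$members[[1]], fam$members[[2]])
  psa <- run_all_to_all(fam$members)
  tree <- upgma(to_distance_matrix(psa))
  msta <- progressive_align(tree, fam$members, psa)
  ids <- vapply(fam$members, function(s) s$id, character(1))
  r1 <- match(ids[1], msta$structure_ids)
  r2 <- match(ids[2], msta$structure_ids)
  core <- core_columns(msta)
  got <- cbind(msta$table[r1, core], msta$table[r2, core])
  expect_equal(got, pa$mapping, ignore_attr = TRUE)
  m <- compute_metrics(msta, fam$members)
  expect_equal(m$avg_rmsd, pa$rmsd_aligned, tolerance = 1e-12)
  expect_equal(m$avg_tm,
               tm_score_optimal(fam$members[[1]], fam$members[[2]],
                                pa$mapping)$score,
               tolerance = 1e-12)
})

test_that("identical structures align without gaps regardless of cutoff", {
  s <- make_backbone(18, 207)
  set.seed(207)
  structures <- list(s, rigid_copy(s, "c1"), rigid_copy(s, "c2"))
  psa <- run_all_to_all(structures)
  tree <- upgma(to_distance_matrix(psa))
  outs <- lapply(c(0L, 1L, 5L), function(cut) {
    progressive_align(tree, structures, psa, cutoff = cut, workers = 2)
  })
  expect_false(anyNA(outs[[1]]$table))
  expect_equal(ncol(outs[[1]]$table), 18)
  expect_identical(outs[[1]]$table, outs[[2]]$table)
  expect_identical(outs[[1]]$table, outs[[3]]$table)
})

test_that("progressive alignment is identical for every cutoff and worker count", {
  inp <- make_msta_inputs(8, 30, 0.5, 208)
  structures <- inp$fam$members
  ser <- function(msta) write_alignment_fasta(msta,  structures)
  ref <- ser(progressive_align(inp$tree, structures, inp$psa,
                               cutoff = 0L, workers = 1L))
  for (cfg in list(c(3L, 4L), c(99L, 8L))) {
    alt <- ser(progressive_align(inp$tree, structures, inp$psa,
                                 cutoff = cfg[1], workers = cfg[2]))
    expect_identical(alt, ref)
  }
})

test_that("core columns are the all-residue columns", {
  tab <- rbind(c(1L, 2L, 3L, NA), c(1L, NA, 2L, 3L))
  msta <- structure(list(structure_ids = c("a", "b"), table = tab,
                         n_columns = 4L), class = "msta_alignment")
  expect_equal(core_columns(msta), c(1L, 3L))
  full <- rbind(1:3, 1:3)
  expect_equal(core_columns(full), 1:3)
})

test_that("metrics are exact for rigid families and match brute force", {
  s <- make_backbone(20, 209)
  set.seed(209)
  structures <- list(s, rigid_copy(s, "c1"), rigid_copy(s, "c2"),
                     rigid_copy(s, "c3"))
  psa <- run_all_to_all(structures)
  tree <- upgma(to_distance_matrix(psa))
  msta <- progressive_align(tree, structures, psa)
  m <- compute_metrics(msta, structures)
  expect_lt(m$avg_rmsd, 1e-6)
  expect_equal(m$avg_tm, 1.0, tolerance = 1e-9)
  expect_equal(m$n_core_columns, 20)

  # independent brute-force recomputation on a noisy family
  inp <- make_msta_inputs(4, 20, 0.5, 210)
  msta2 <- progressive_align(inp$tree, inp$fam$members, inp$psa)
  m2 <- compute_metrics(msta2, inp$fam$members)
  core <- core_columns(msta2)
  ids <- vapply(inp$fam$members, function(x) x$id, character(1))
  rows <- match(msta2$structure_ids, ids)
  rmsds <- c(); tms <- c()
  for (a in 1:3) for (b in (a + 1):4) {
    s1 <- inp$fam$members[[rows[a]]]; s2 <- inp$fam$members[[rows[b]]]
    map <- cbind(msta2$table[a, core], msta2$table[b, core])
    rmsds <- c(rmsds, kabsch_superpose(s1$coords[map[, 1], ],
                                       s2$coords[map[, 2], ])$rmsd)
    tms <- c(tms, tm_score_optimal(s1, s2, map)$score)
  }
  expect_equal(m2$avg_rmsd, mean(rmsds), tolerance = 1e-12)
  expect_equal(m2$avg_tm, mean(tms), tolerance = 1e-12)
})

test_that("metrics are bit-identical between serial and parallel runs", {
  inp <- make_msta_inputs(5, 24, 0.4, 211)
  msta <- progressive_align(inp$tree, inp$fam$members, inp$psa)
  m1 <- compute_metrics(msta, inp$fam$members, workers = 1)
  m2 <- compute_metrics(msta, inp$fam$members, workers = 3)
  expect_identical(metrics_json(m1), metrics_json(m2))
})

test_that("metrics require enough structures and core columns", {
  tab <- rbind(c(1L, 2L, NA), c(NA, 1L, 2L))
  msta <- structure(list(structure_ids = c("a", "b"), table = tab,
                         n_columns = 3L), class = "msta_alignment")
  s <- make_backbone(5, 212)
  expect_error(compute_metrics(msta, list(s, s)), "core too small")
})

test_that("any two rows of an MSTA induce a monotone pairwise mapping", {
  inp <- make_msta_inputs(6, 25, 0.6, 213, indels = 2L)
  msta <- progressive_align(inp$tree, inp$fam$members, inp$psa)
  nr <- length(msta$structure_ids)
  for (a in seq_len(nr - 1)) {
    for (b in (a + 1):nr) {
      keep <- !is.na(msta$table[a, ]) & !is.na(msta$table[b, ])
      expect_true(all(diff(msta$table[a, keep]) > 0))
      expect_true(all(diff(msta$table[b, keep]) > 0))
    }
  }
})
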