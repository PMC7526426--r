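test_that("an ideal helix is labelled mostly H and boundaries are C", {
  h <- make_helix(20)
  lab <- strsplit(assign_secondary_structure(h), "")[[1]]
  expect_length(lab, 20)
  expect_equal(lab[c(1, 2, 19, 20)], rep("C", 4))
  interior <- lab[3:18]
  expect_gte(mean(interior == "H"), 0.8)
})

test_that("a straight extended trace is never helical", {
  line <- tmsta:::new_protein_structure("ext", rep("ALA", 12), 1:12,
                                        cbind((0:11) * 3.8, 0, 0))
  lab <- strsplit(assign_secondary_structure(line), "")[[1]]
  expect_false(any(lab[3:10] == "H"))
})

test_that("chains shorter than the window are all coil", {
  s <- tmsta:::new_protein_structure("tiny", rep("GLY", 4), 1:4,
                                     rbind(c(0, 0, 0), c(3.8, 0, 0),
                                           c(5, 3, 0), c(8, 4, 1)))
  expect_equal(assign_secondary_structure(s), "CCCC")
})

test_that("NWDP solves trivial matrices", {
  expect_equal(nwdp(matrix(0.9, 1, 1), gap_open = -0.6),
               cbind(1L, 1L), ignore_attr = TRUE)
  expect_equal(nwdp(matrix(c(1, 0, 0, 1), 2, 2), gap_open = -0.6),
               cbind(1:2, 1:2), ignore_attr = TRUE)
  expect_equal(nrow(nwdp(matrix(numeric(0), 0, 3))), 0)
})

test_that("NWDP equals exhaustive enumeration over monotone alignments", {
  set.seed(11)
  for (rep in 1:50) {
    n1 <- sample(1:4, 1); n2 <- sample(1:4, 1)
    S <- matrix(sample(c(0, 0.5, 1), n1 * n2, replace = TRUE), n1, n2)
    go <- sample(c(-0.6, -1, -0.2), 1)
    m <- nwdp(S, gap_open = go)
    expect_equal(dp_mapping_score(S, m, go), exhaustive_alignment_score(S, go),
                 tolerance = 1e-12)
  }
})

test_that("gapless threading finds the identity and shifted offsets", {
  s <- make_backbone(30, 41)
  seeds <- seed_alignments(s, s)
  fps <- vapply(seeds, tmsta:::mapping_fingerprint, character(1))
  expect_true(tmsta:::mapping_fingerprint(cbind(1:30, 1:30)) %in% fps)

  del3 <- tmsta:::new_protein_structure("del3", s$residue_names[-(1:3)],
                                        1:27, s$coords[-(1:3), ])
  seeds2 <- seed_alignments(s, del3)
  # the gapless seed is the first entry: pairs (k + 3, k)
  expect_equal(seeds2[[1]], cbind(4:30, 1:27), ignore_attr = TRUE)
})

test_that("all seeds are monotone and in range (property)", {
  set.seed(12)
  for (rep in 1:6) {
    s1 <- make_backbone(sample(20:40, 1), 300 + rep)
    s2 <- make_backbone(sample(20:40, 1), 400 + rep)
    for (m in seed_alignments(s1, s2)) {
      expect_true(all(diff(m[, 1]) > 0))
      expect_true(all(diff(m[, 2]) > 0))
      expect_true(all(m[, 1] >= 1 & m[, 1] <= nrow(s1$coords)))
      expect_true(all(m[, 2] >= 1 & m[, 2] <= nrow(s2$coords)))
    }
  }
  expect_error(seed_alignments(make_helix(4), make_helix(10)), "too short")
})

test_that("refinement reaches the identity fixed point on identical input", {
  s <- make_backbone(25, 51)
  out <- refine_alignment(s, s, cbind(1:25, 1:25))
  expect_equal(out, cbind(1:25, 1:25), ignore_attr = TRUE)
})

test_that("refinement from a partial seed recovers a rigid copy fully", {
  s <- make_backbone(30, 61)
  set.seed(13)
  r <- rigid_copy(s)
  half <- cbind(1:15, 1:15)
  out <- refine_alignment(s, r, half)
  expect_gte(nrow(out), 15)
  tm_half <- tm_score_optimal(s, r, half, L_norm = 30)$score
  tm_out <- tm_score_optimal(s, r, out, L_norm = 30)$score
  expect_gte(tm_out, tm_half - 1e-12)
  expect_equal(tm_out, 1.0, tolerance = 1e-9)
})

test_that("self-alignment is perfect", {
  s <- make_backbone(35, 71)
  pa <- align_pair(s, s)
  expect_equal(pa$aligned_length, 35)
  expect_lt(pa$rmsd_aligned, 1e-6)
  expect_equal(pa$tm_norm1, 1.0, tolerance = 1e-12)
  expect_equal(pa$tm_norm2, 1.0, tolerance = 1e-12)
  expect_equal(pa$seq_identity, 1.0)
})

test_that("alignment is invariant under a rigid motion of one structure", {
  s <- make_backbone(35, 81)
  set.seed(14)
  r <- rigid_copy(s)
  pa <- align_pair(s, r)
  expect_equal(pa$aligned_length, 35)
  expect_lt(pa$rmsd_aligned, 1e-6)
  expect_equal(pa$tm_norm1, 1.0, tolerance = 1e-6)
  expect_equal(pa$tm_norm2, 1.0, tolerance = 1e-6)
})

test_that("noisy family pairs recover the ground-truth correspondence", {
  fam <- make_family(2, 80, noise_sigma = 0.3, n_indels = 0, seed = 91)
  pa <- align_pair(fam$members[[1]], fam$members[[2]])
  # both members are unindeled, so truth is the identity correspondence
  hits <- sum(pa$mapping[, 1] == pa$mapping[, 2])
  expect_gte(hits / nrow(pa$mapping), 0.95)
})

test_that("output mappings are monotone and scores stay in (0, 1]", {
  set.seed(15)
  for (rep in 1:4) {
    s1 <- make_backbone(sample(25:40, 1), 500 + rep)
    s2 <- make_backbone(sample(25:40, 1), 600 + rep)
    pa <- align_pair(s1, s2)
    expect_true(all(diff(pa$mapping[, 1]) > 0))
    expect_true(all(diff(pa$mapping[, 2]) > 0))
    expect_true(pa$tm_norm1 > 0 && pa$tm_norm1 <= 1)
    expect_true(pa$tm_norm2 > 0 && pa$tm_norm2 <= 1)
  }
})

test_that("swapping inputs swaps the two TM normalizations", {
  fam <- make_family(2, 30, noise_sigma = 0.4, seed = 95)
  a <- fam$members[[1]]; b <- fam$members[[2]]
  ab <- align_pair(a, b)
  ba <- align_pair(b, a)
  expect_equal(ab$tm_norm1, ba$tm_norm2, tolerance = 1e-9)
  expect_equal(ab$tm_norm2, ba$tm_norm1, tolerance = 1e-9)
  expect_equal(ab$aligned_length, ba$aligned_length)
})
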