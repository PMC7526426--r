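test_that("two leaves merge into a single root at half the distance", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(D)
  expect_equal(tr$n_leaves, 2)
  expect_equal(tr$n_nodes, 3)
  expect_equal(tr$root, 2)
  expect_equal(tr$nodes$height[3], 0.2)
  expect_equal(sort(c(tr$nodes$left[3], tr$nodes$right[3])), c(0, 1))
})

test_that("the hand-executed 3-leaf case merges (0,1) then joins 2 at 0.35", {
  D <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3)
  tr <- upgma(D)
  # node 3 = first merge (leaves 0, 1) at height 0.1
  expect_equal(tr$nodes$left[4], 0)
  expect_equal(tr$nodes$right[4], 1)
  expect_equal(tr$nodes$height[4], 0.1)
  # root joins {0,1} with 2 at updated distance (0.6 + 0.8)/2 = 0.7
  expect_equal(tr$nodes$height[5], 0.35)
  expect_equal(sort(c(tr$nodes$left[5], tr$nodes$right[5])), c(2, 3))
})

test_that("UPGMA equals the naive full-rescan oracle on random matrices", {
  set.seed(41)
  for (rep in 1:25) {
    n <- 5
    M <- matrix(runif(n * n), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    tr <- upgma(D)
    oracle <- upgma_oracle(D)
    internal <- (n + 1):(2 * n - 1)
    expect_equal(tr$nodes$left[internal], oracle$left)
    expect_equal(tr$nodes$right[internal], oracle$right)
    expect_equal(tr$nodes$height[internal], oracle$height, tolerance = 1e-9)
    # heights never decrease along the merge sequence (ultrametric)
    expect_true(all(diff(tr$nodes$height[internal]) >= -1e-12))
    # independent cross-check: average-linkage merge heights from hclust
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(tr$nodes$height[internal], hc$height / 2, tolerance = 1e-9)
  }
})

test_that("root-to-leaf path lengths are equal (ultrametric, explicit walk)", {
  set.seed(42)
  M <- matrix(runif(36), 6, 6)
  D <- (M + t(M)) / 2; diag(D) <- 0
  tr <- upgma(D)
  path_len <- function(node) {
    if (node >= tr$n_leaves) {
      h <- tr$nodes$height[node + 1L]
      kids <- c(tr$nodes$left[node + 1L], tr$nodes$right[node + 1L])
      unlist(lapply(kids, function(k) {
        (h - tr$nodes$height[k + 1L]) + path_len(k)
      }))
    } else 0
  }
  expect_lt(diff(range(path_len(tr$root))), 1e-9)
})

test_that("degenerate or invalid matrices are rejected", {
  expect_error(upgma(matrix(0, 1, 1)), "at least 2")
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(upgma(bad), "symmetric")
  nab <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(upgma(nab), "NA")
})

test_that("equal-distance ties resolve to the lexicographically smallest pair", {
  # all distances equal: the first merge must be (0, 1)
  D <- matrix(0.5, 4, 4); diag(D) <- 0
  tr <- upgma(D)
  expect_equal(tr$nodes$left[5], 0)
  expect_equal(tr$nodes$right[5], 1)
})

test_that("post-order traversal puts every parent after its children", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  expect_equal(post_order(upgma(D)), c(0, 1, 2))

  # balanced 4-leaf tree: merges (0,1)->4, (2,3)->5, (4,5)->6
  Db <- matrix(0.9, 4, 4)
  Db[1, 2] <- Db[2, 1] <- 0.1
  Db[3, 4] <- Db[4, 3] <- 0.2
  diag(Db) <- 0
  tr <- upgma(Db)
  expect_equal(post_order(tr), c(0, 1, 4, 2, 3, 5, 6))

  set.seed(43)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    M <- matrix(runif(n * n), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    trr <- upgma(D)
    ord <- post_order(trr)
    pos <- match(seq_len(2 * n - 1) - 1L, ord)
    for (node in (n:(2 * n - 2))) {
      kids <- c(trr$nodes$left[node + 1L], trr$nodes$right[node + 1L])
      expect_true(all(pos[kids + 1L] < pos[node + 1L]))
    }
    expect_equal(sort(ord), seq_len(2 * n - 1) - 1L)
  }
})

test_that("node depths count edges from the root", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2)
  tr <- upgma(D)
  expect_equal(node_depth(tr, tr$root), 0)
  expect_equal(node_depth(tr, 0), 1)
  expect_error(node_depth(tr, 99), "not in the tree")

  set.seed(44)
  M <- matrix(runif(49), 7, 7)
  D7 <- (M + t(M)) / 2; diag(D7) <- 0
  tr7 <- upgma(D7)
  for (node in (7:(2 * 7 - 2))) {
    d <- node_depth(tr7, node)
    kids <- c(tr7$nodes$left[node + 1L], tr7$nodes$right[node + 1L])
    for (k in kids) expect_equal(node_depth(tr7, k), d + 1)
  }
})

test_that("balanced-tree speedup formula evaluates (n-1)/(2h)", {
  expect_equal(theoretical_balanced_speedup(3), 1.0)
  expect_equal(theoretical_balanced_speedup(7), 1.5)
  expect_equal(theoretical_balanced_speedup(15), 14 / 6)
  expect_error(theoretical_balanced_speedup(6), "balanced")
})

test_that("Newick output is exact for two leaves and round-trips via ape", {
  D <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(D)
  expect_equal(to_newick(tr), "(A:0.2,B:0.2);")

  set.seed(45)
  M <- matrix(runif(36), 6, 6)
  D6 <- (M + t(M)) / 2; diag(D6) <- 0
  rownames(D6) <- colnames(D6) <- paste0("s", 1:6)
  tr6 <- upgma(D6)
  nwk <- to_newick(tr6)
  phy <- ape::read.tree(text = nwk)
  expect_equal(sort(phy$tip.label), paste0("s", 1:6))
  expect_true(all(phy$edge.length >= 0))
  # same pairwise leaf-path distances as the ultrametric heights imply
  coph <- ape::cophenetic.phylo(phy)
  for (a in 1:5) for (b in (a + 1):6) {
    slot <- which(vapply(tr6$nodes$members, function(m) {
      all((c(a, b) - 1L) %in% m)
    }, logical(1)) & tr6$nodes$index >= 6)[1]
    expect_equal(coph[paste0("s", a), paste0("s", b)],
                 2 * tr6$nodes$height[slot], tolerance = 1e-6)
  }
})
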