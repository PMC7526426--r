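#' Build a UPGMA guide tree from a distance matrix
#'
#' Average-linkage agglomeration: repeatedly merge the cluster pair (A, B)
#' at minimal distance; the new node's height is d(A, B)/2 and
#' `d(A+B, C) = (|A| d(A,C) + |B| d(B,C)) / (|A| + |B|)`. Ties are broken
#' lexicographically on (min cluster index, max cluster index). Leaves
#' carry indices 0..N-1 and internal nodes N..2N-2 in merge order (the
#' binary-tree convention: a node index >= N marks a non-leaf); the
#' smaller-index cluster becomes the left child. Heights are ultrametric,
#' so all branch lengths are non-negative.
#'
#' @param D Symmetric n x n distance matrix (n >= 2), zero diagonal; row
#'   names, if present, become leaf labels.
#' @return A `guide_tree`: list with `nodes` (tibble: `index`, `left`,
#'   `right`, `height`, `n_members`, list-column `members` of 0-based leaf
#'   indices), `root`, `n_leaves`, `n_nodes`, `labels`.
#' @export
#' @examples
#' D <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3)
#' upgma(D)
upgma <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 leaves")
  if (ncol(D) != n) stop("distance matrix must be square")
  if (anyNA(D) || !all(is.finite(D))) stop("distance matrix has NA/non-finite entries")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be zero")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n) - 1L)

  idx <- integer(2 * n - 1)      # spec/paper index per node slot
  left <- rep(NA_integer_, 2 * n - 1)
  right <- rep(NA_integer_, 2 * n - 1)
  height <- numeric(2 * n - 1)
  members <- vector("list", 2 * n - 1)
  for (k in seq_len(n)) {
    idx[k] <- k - 1L
    members[[k]] <- k - 1L
  }
  active <- seq_len(n)           # slot numbers of live clusters
  W <- D                         # working distances between live slots
  size <- rep(1L, n)
  for (t in seq_len(n - 1L)) {
    # minimal distance among active pairs; tie-break on (min idx, max idx)
    best <- NULL
    best_d <- Inf
    for (ai in seq_along(active)[-length(active)]) {
      for (bi in (ai + 1L):length(active)) {
        a <- active[ai]; b <- active[bi]
        dd <- W[a, b]
        key <- c(min(idx[a], idx[b]), max(idx[a], idx[b]))
        if (dd < best_d - 1e-15 ||
            (abs(dd - best_d) <= 1e-15 && !is.null(best) &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best_d <- dd
          best <- list(a = a, b = b, key = key)
        }
      }
    }
    a <- best$a; b <- best$b
    if (idx[a] > idx[b]) { tmp <- a; a <- b; b <- tmp }  # smaller index left
    slot <- n + t
    idx[slot] <- n + t - 1L      # internal indices N, N+1, ... in merge order
    left[slot] <- idx[a]
    right[slot] <- idx[b]
    height[slot] <- W[a, b] / 2
    members[[slot]] <- sort(c(members[[a]], members[[b]]))
    # average-linkage update
    newsize <- size[a] + size[b]
    W <- rbind(cbind(W, 0), 0)
    for (c in active) {
      if (c == a || c == b) next
      W[slot, c] <- W[c, slot] <- (size[a] * W[a, c] + size[b] * W[b, c]) / newsize
    }
    size <- c(size, newsize)
    active <- c(setdiff(active, c(a, b)), slot)
  }
  nodes <- tibble::tibble(index = idx, left = left, right = right,
                          height = height,
                          n_members = vapply(members, length, integer(1)))
  nodes$members <- members
  structure(list(nodes = nodes, root = 2L * n - 2L, n_leaves = n,
                 n_nodes = 2L * n - 1L, labels = labels),
            class = "guide_tree")
}

#' @export
print.guide_tree <- function(x, ...) {
  cat("<guide_tree> ", x$n_leaves, " leaves, ", x$n_nodes,
      " nodes, root height ", sprintf("%.4f", x$nodes$height[x$n_nodes]),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a guide tree into its node table
#'
#' @param x A `guide_tree`.
#' @param ... Unused.
#' @return The node tibble (`index`, `left`, `right`, `height`,
#'   `n_members`, `members`), plus leaf `label`.
#' @export
tidy.guide_tree <- function(x, ...) {
  out <- x$nodes
  out$label <- c(x$labels, rep(NA_character_, x$n_leaves - 1L))
  out
}

node_children <- function(tree, index) {
  row <- index + 1L
  c(tree$nodes$left[row], tree$nodes$right[row])
}

is_leaf <- function(tree, index) index < tree$n_leaves

#' Post-order traversal of a guide tree
#'
#' Left subtree, right subtree, node: every parent appears after both its
#' children, which is the evaluation order of the progressive alignment.
#'
#' @param tree A `guide_tree`.
#' @param node Starting node index (default: root).
#' @return Integer vector of node indices (0-based convention).
#' @export
post_order <- function(tree, node = tree$root) {
  if (is_leaf(tree, node)) return(node)
  ch <- node_children(tree, node)
  c(post_order(tree, ch[1]), post_order(tree, ch[2]), node)
}

#' Depth of a node (edges from the root)
#'
#' @param tree A `guide_tree`.
#' @param node Node index (0-based convention).
#' @return Integer depth; the root has depth 0.
#' @export
node_depth <- function(tree, node) {
  depths <- all_depths(tree)
  d <- depths[as.character(node)]
  if (is.na(d)) stop("node ", node, " is not in the tree")
  unname(d)
}

all_depths <- function(tree) {
  depths <- setNames(integer(tree$n_nodes), as.character(tree$nodes$index))
  walk <- function(node, d) {
    depths[[as.character(node)]] <<- d
    if (!is_leaf(tree, node)) {
      ch <- node_children(tree, node)
      walk(ch[1], d + 1L)
      walk(ch[2], d + 1L)
    }
  }
  walk(tree$root, 0L)
  depths
}

#' Theoretical speedup of task-parallel traversal on a balanced tree
#'
#' For a fully balanced binary tree of `n` nodes (so `n + 1` is a power of
#' two) with height `h = log2(n + 1) - 1`, task-parallel post-order
#' traversal can at best reach a speedup of `(n - 1) / (2 h)`.
#'
#' @param n_nodes Node count of a fully balanced binary tree.
#' @return The ratio (n - 1) / (2 h).
#' @export
#' @examples
#' theoretical_balanced_speedup(7)  # 1.5
theoretical_balanced_speedup <- function(n_nodes) {
  stopifnot(n_nodes >= 3)
  if (bitwAnd(n_nodes + 1L, n_nodes) != 0L) {
    stop("formula defined for fully balanced trees (n + 1 must be a power of two)")
  }
  h <- log2(n_nodes + 1) - 1
  (n_nodes - 1) / (2 * h)
}

#' Serialize a guide tree as a Newick string
#'
#' Branch length of an edge = parent height - child height (non-negative
#' by ultrametricity); leaves carry the structure labels.
#'
#' @param tree A `guide_tree`.
#' @param labels Leaf labels (default: the tree's own labels).
#' @param digits Significant digits for branch lengths.
#' @return A Newick string terminated by `";"`.
#' @export
to_newick <- function(tree, labels = tree$labels, digits = 10) {
  if (length(labels) != tree$n_leaves) {
    stop("label count (", length(labels), ") does not match leaf count (",
         tree$n_leaves, ")")
  }
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  rec <- function(node, parent_h) {
    h <- tree$nodes$height[node + 1L]
    if (is_leaf(tree, node)) {
      return(paste0(labels[node + 1L], ":", fmt(parent_h)))
    }
    ch <- node_children(tree, node)
    paste0("(", rec(ch[1], h), ",", rec(ch[2], h), "):", fmt(parent_h - h))
  }
  root <- tree$root
  h <- tree$nodes$height[root + 1L]
  ch <- node_children(tree, root)
  paste0("(", rec(ch[1], h), ",", rec(ch[2], h), ");")
}

#' Dendrogram of a guide tree
#'
#' @param object A `guide_tree`.
#' @param ... Unused.
#' @return A ggplot object (leaves on the x axis, merge height on y).
#' @export
autoplot.guide_tree <- function(object, ...) {
  ord <- post_order(object)
  leaves <- ord[ord < object$n_leaves]
  xpos <- setNames(numeric(object$n_nodes), as.character(object$nodes$index))
  xpos[as.character(leaves)] <- seq_along(leaves)
  segs <- list()
  for (node in ord[ord >= object$n_leaves]) {
    ch <- node_children(object, node)
    h <- object$nodes$height[node + 1L]
    x1 <- xpos[[as.character(ch[1])]]
    x2 <- xpos[[as.character(ch[2])]]
    h1 <- object$nodes$height[ch[1] + 1L]
    h2 <- object$nodes$height[ch[2] + 1L]
    xpos[[as.character(node)]] <- (x1 + x2) / 2
    segs[[length(segs) + 1L]] <- tibble::tibble(
      x = c(x1, x2, x1), xend = c(x1, x2, x2),
      y = c(h1, h2, h), yend = c(h, h, h))
  }
  segs <- dplyr::bind_rows(segs)
  lab <- tibble::tibble(x = seq_along(leaves), y = 0,
                        label = object$labels[leaves + 1L])
  ggplot2::ggplot(segs) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
                       angle = 90, hjust = 1.1, size = 3) +
    ggplot2::scale_y_continuous("merge height") +
    ggplot2::scale_x_continuous(NULL, breaks = NULL) +
    ggplot2::coord_cartesian(clip = "off") +
    ggplot2::theme_minimal()
}
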