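# Deterministic generators of CA-trace structures and perturbed families
# with known residue correspondences. All randomness flows through R's
# Mersenne-Twister generator seeded explicitly, so every fixture can be
# replayed exactly from its seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

random_residue_names <- function(L) {
  names(AA_THREE_TO_ONE)[sample.int(20L, L, replace = TRUE)]
}

# Uniform random proper rotation via quaternion sampling.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' Generate a random self-avoiding CA backbone
#'
#' A self-avoiding walk with step length exactly 3.8 Angstrom, bend angles
#' sampled uniformly in \[80, 150\] degrees, uniform dihedrals, and a
#' minimum non-adjacent CA separation of 3.5 Angstrom (steps violating it
#' are resampled). Fully reproducible from the seed.
#'
#' @param L Length in residues (>= 5).
#' @param seed Integer seed.
#' @param max_tries Resampling budget per placed residue.
#' @return A `protein_structure` with random standard residue names.
#' @export
make_backbone <- function(L, seed, max_tries = 200L) {
  stopifnot(L >= 5)
  with_seed(seed, {
    X <- matrix(0, L, 3)
    X[2, ] <- c(3.8, 0, 0)
    for (k in 3:L) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        theta <- runif(1, 80, 150) * pi / 180  # bend angle
        phi <- runif(1, -pi, pi)               # dihedral
        # local frame at residue k-1
        u <- X[k - 1, ] - X[k - 2, ]
        u <- u / sqrt(sum(u^2))
        ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        v <- ref - sum(ref * u) * u
        v <- v / sqrt(sum(v^2))
        w <- c(u[2] * v[3] - u[3] * v[2],
               u[3] * v[1] - u[1] * v[3],
               u[1] * v[2] - u[2] * v[1])
        dir <- cos(pi - theta) * u +
          sin(pi - theta) * (cos(phi) * v + sin(phi) * w)
        cand <- X[k - 1, ] + 3.8 * dir
        if (k > 3) {
          d2 <- rowSums((X[seq_len(k - 2), , drop = FALSE] -
                           matrix(cand, k - 2, 3, byrow = TRUE))^2)
          if (min(d2) < 3.5^2) next
        }
        X[k, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) stop("backbone generation failed: could not place residue ", k)
    }
    new_protein_structure(paste0("synth", seed, "_L", L),
                          random_residue_names(L), seq_len(L), X)
  })
}

#' Generate an ideal alpha-helix CA trace
#'
#' Radius 2.3 Angstrom, rise 1.5 Angstrom per residue, 100 degrees of turn
#' per residue; deterministic (residues are all alanine).
#'
#' @param L Length in residues (>= 3).
#' @return A `protein_structure`.
#' @export
make_helix <- function(L) {
  stopifnot(L >= 3)
  k <- seq_len(L) - 1
  ang <- k * 100 * pi / 180
  X <- cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * k)
  new_protein_structure(paste0("helix_L", L), rep("ALA", L), seq_len(L), X)
}

#' Perturb a structure with known ground truth
#'
#' Applies a random proper rotation and translation, adds isotropic
#' Gaussian noise (sd `noise_sigma` per coordinate), then applies
#' `n_indels` random single-residue edits (deletions, or insertions placed
#' geometrically midway between neighbours). The returned truth mapping
#' links each surviving residue (1-based) to its ancestor index.
#'
#' @param s Ancestor `protein_structure`.
#' @param noise_sigma Coordinate noise sd in Angstrom.
#' @param n_indels Number of single-residue indels.
#' @param seed Integer seed.
#' @param id Identifier for the perturbed copy.
#' @return List with `structure` and `truth` (m x 2 matrix: member index,
#'   ancestor index).
#' @export
perturb <- function(s, noise_sigma = 0, n_indels = 0L, seed = 1L,
                    id = paste0(s$id, "_p", seed)) {
  with_seed(seed, {
    R <- random_rotation()
    t <- runif(3, -15, 15)
    X <- sweep(s$coords %*% t(R), 2, t, `+`)
    if (noise_sigma > 0) {
      X <- X + matrix(rnorm(length(X), sd = noise_sigma), nrow(X), 3)
    }
    anc <- seq_len(nrow(X))          # ancestor index per current residue
    nm <- s$residue_names
    for (e in seq_len(n_indels)) {
      if (nrow(X) - 1L < 5L) stop("perturbed structure would fall below 5 residues")
      if (runif(1) < 0.5) {          # deletion
        pos <- sample.int(nrow(X), 1)
        X <- X[-pos, , drop = FALSE]
        anc <- anc[-pos]
        nm <- nm[-pos]
      } else {                       # insertion between pos and pos + 1
        pos <- sample.int(nrow(X) - 1L, 1)
        newpt <- (X[pos, ] + X[pos + 1, ]) / 2
        X <- rbind(X[seq_len(pos), , drop = FALSE], newpt,
                   X[(pos + 1):nrow(X), , drop = FALSE])
        anc <- append(anc, NA_integer_, after = pos)
        nm <- append(nm, random_residue_names(1), after = pos)
      }
    }
    member <- new_protein_structure(id, nm, seq_len(nrow(X)), X, warn = FALSE)
    keep <- !is.na(anc)
    truth <- cbind(member = which(keep), ancestor = anc[keep])
    list(structure = member, truth = truth)
  })
}

#' Generate a perturbed structure family with ground truth
#'
#' One ancestor backbone ([make_backbone()]) and `n` perturbed members
#' with sub-seeds derived deterministically from `seed`.
#'
#' @param n Number of members.
#' @param L Ancestor length in residues.
#' @param noise_sigma Coordinate noise sd in Angstrom.
#' @param n_indels Indels per member.
#' @param seed Integer seed.
#' @return A `family_truth`: list with `members` (list of
#'   `protein_structure`), `truth_mappings` (member residue -> ancestor
#'   residue matrices), `ancestor`, and `params`.
#' @export
make_family <- function(n, L, noise_sigma = 0, n_indels = 0L, seed = 1L) {
  ancestor <- make_backbone(L, seed)
  members <- vector("list", n)
  truths <- vector("list", n)
  for (k in seq_len(n)) {
    p <- perturb(ancestor, noise_sigma, n_indels, seed = seed + 1000L * k,
                 id = sprintf("fam%d_m%02d", seed, k))
    members[[k]] <- p$structure
    truths[[k]] <- p$truth
  }
  structure(list(members = members, truth_mappings = truths,
                 ancestor = ancestor,
                 params = list(L = L, n = n, noise_sigma = noise_sigma,
                               n_indels = n_indels, seed = seed)),
            class = "family_truth")
}

#' Fraction of ground-truth correspondences recovered in MSTA core columns
#'
#' A core column recovers a truth correspondence when every row's residue
#' maps back to the same ancestor residue. The fraction is taken over the
#' ancestor length.
#'
#' @param msta An `msta_alignment` over the family members.
#' @param family A `family_truth`.
#' @return Fraction in \[0, 1\].
#' @export
truth_recovery <- function(msta, family) {
  ids <- vapply(family$members, function(s) s$id, character(1))
  rows <- match(msta$structure_ids, ids)
  lookup <- lapply(family$truth_mappings, function(tr) {
    v <- rep(NA_integer_, max(tr[, "member"]))
    v[tr[, "member"]] <- tr[, "ancestor"]
    v
  })
  core <- core_columns(msta)
  good <- 0L
  for (cc in core) {
    anc <- vapply(seq_along(rows), function(r) {
      res <- msta$table[r, cc]
      lk <- lookup[[rows[r]]]
      if (res <= length(lk)) lk[res] else NA_integer_
    }, integer(1))
    if (!anyNA(anc) && length(unique(anc)) == 1L) good <- good + 1L
  }
  good / nrow(family$ancestor$coords)
}
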