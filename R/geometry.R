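#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD of `Q`
#' mapped onto `P`, via SVD of the cross-covariance with the determinant
#' sign correction on the smallest singular direction (reflections
#' excluded). Rank-deficient (collinear) point sets still yield a
#' minimising transform; the result is flagged.
#'
#' @param P,Q n x 3 coordinate matrices (n >= 3), same n.
#' @return A `superposition_result`: list with `transform` (a
#'   `rigid_transform` with fields `rotation`, `translation`), `rmsd`
#'   (Angstrom), `n_points`, and `flagged` (collinearity).
#' @export
#' @examples
#' P <- matrix(rnorm(12), 4, 3)
#' kabsch_superpose(P, P)$rmsd
kabsch_superpose <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must have the same number of points")
  if (nrow(P) < 3L) stop("underdetermined superposition: need at least 3 points")
  if (!all(is.finite(P)) || !all(is.finite(Q))) stop("non-finite coordinates")
  res <- cpp_kabsch(P, Q)
  Pc <- sweep(P, 2, colMeans(P))
  flagged <- qr(Pc)$rank < 2L
  structure(list(transform = new_rigid_transform(res$rotation, drop(res$translation)),
                 rmsd = res$rmsd, n_points = res$n_points, flagged = flagged),
            class = "superposition_result")
}

new_rigid_transform <- function(rotation, translation) {
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param coords n x 3 matrix.
#' @param transform A `rigid_transform`.
#' @return Transformed n x 3 matrix.
#' @export
transform_coords <- function(coords, transform) {
  sweep(coords %*% t(transform$rotation), 2, transform$translation, `+`)
}

compose_transforms <- function(a, b) {
  # x -> a(b(x))
  new_rigid_transform(a$rotation %*% b$rotation,
                      drop(a$rotation %*% b$translation) + a$translation)
}

invert_transform <- function(a) {
  new_rigid_transform(t(a$rotation), drop(-t(a$rotation) %*% a$translation))
}

identity_transform <- function() {
  new_rigid_transform(diag(3), c(0, 0, 0))
}

#' TM-score distance scale d0 from a normalization length
#'
#' `d0 = max(1.24 * (L - 15)^(1/3) - 1.8, 0.5)` Angstrom; the 0.5 floor
#' engages for short chains (L below about 21).
#'
#' @param L_norm Normalization length in residues (>= 1).
#' @return d0 in Angstrom.
#' @export
#' @examples
#' d0_from_length(100)
d0_from_length <- function(L_norm) {
  stopifnot(all(L_norm >= 1))
  raw <- ifelse(L_norm > 15, 1.24 * (L_norm - 15)^(1 / 3) - 1.8, 0.5)
  pmax(raw, 0.5)
}

#' TM-score from aligned-pair distances
#'
#' `(1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2)`.
#'
#' @param distances Non-negative distances d_i (Angstrom) of aligned pairs.
#' @param L_norm Normalization length.
#' @param d0 Distance scale; defaults to [d0_from_length()] of `L_norm`.
#' @return The score; in (0, 1] whenever there is at least one pair and
#'   `L_norm` is at least the number of pairs.
#' @export
tm_score <- function(distances, L_norm, d0 = d0_from_length(L_norm)) {
  stopifnot(L_norm >= 1, all(distances >= 0))
  sum(1 / (1 + (distances / d0)^2)) / L_norm
}

#' TM-score maximisation over superpositions for a fixed mapping
#'
#' Seeds superpositions on contiguous mapped fragments of lengths
#' m, m/2, m/4 (minimum 4), refines each by re-superposing on the mapped
#' pairs closer than max(d0, 4.5 Angstrom) until the selected subset is
#' stable (at most 20 iterations), and returns the best TM-score and its
#' transform.
#'
#' @param s1,s2 `protein_structure` objects.
#' @param mapping m x 2 matrix of 1-based residue index pairs (monotone).
#' @param L_norm Normalization length (default: length of the shorter chain).
#' @return List with `score` and `transform` (mapping `s2` coordinates into
#'   `s1`'s frame).
#' @export
tm_score_optimal <- function(s1, s2, mapping,
                             L_norm = min(nrow(s1$coords), nrow(s2$coords))) {
  mapping <- as_mapping(mapping)
  if (nrow(mapping) == 0L) stop("empty mapping")
  d0 <- d0_from_length(L_norm)
  res <- cpp_tm_search(s1$coords, s2$coords, mapping[, 1], mapping[, 2],
                       L_norm, d0)
  list(score = res$score,
       transform = new_rigid_transform(res$rotation, drop(res$translation)))
}

# Validate/coerce a residue mapping: m x 2 integer matrix, strictly
# increasing in both columns.
as_mapping <- function(mapping) {
  m <- as.matrix(mapping)
  if (length(m) == 0L) return(matrix(integer(0), 0, 2))
  storage.mode(m) <- "integer"
  stopifnot(ncol(m) == 2)
  if (nrow(m) > 1L && (any(diff(m[, 1]) <= 0) || any(diff(m[, 2]) <= 0))) {
    stop("mapping is not strictly monotone")
  }
  dimnames(m) <- NULL
  m
}
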