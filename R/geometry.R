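#' Rigid transform
#'
#' @param rotation 3 x 3 rotation matrix (orthonormal, determinant +1).
#' @param translation Length-3 translation vector (Angstrom).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L)
    stop("rotation must be 3x3 and translation length 3", call. = FALSE)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 coordinate matrix.
#' @param transform A `rigid_transform`.
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(transform$rotation), 2L, -transform$translation)
}

#' Kabsch superposition of two ordered point sets
#'
#' Finds the rigid transform (rotation + translation, no reflection) that
#' minimizes the root mean square deviation of `P` onto `Q`, via singular
#' value decomposition of the covariance matrix with the standard sign
#' correction on the smallest singular vector.
#'
#' @param P,Q n x 3 matrices of paired points (n >= 3, not all collinear).
#' @return A list with `transform` (a `rigid_transform`) and `rmsd`
#'   (Angstrom) after superposition.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L)
    stop("P and Q must be equal-size n x 3 matrices", call. = FALSE)
  n <- nrow(P)
  if (n < 3L) stop("need at least 3 points", call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  # collinearity check: rank of the centered set
  if (sum(svd(Pc)$d > 1e-8 * max(1, max(abs(Pc)))) < 2L)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t <- cq - as.numeric(R %*% cp)
  fitted <- sweep(Pc %*% t(R), 2L, -cq)
  rmsd <- sqrt(mean(rowSums((fitted - sweep(Qc, 2L, -cq))^2)))
  list(transform = rigid_transform(R, t), rmsd = rmsd)
}

#' Superpose one structure onto another
#'
#' Fits the mobile structure onto the reference by Kabsch superposition of
#' the atoms paired under `selection` (by default the C-alpha atoms of the
#' P1 helices, the standard frame for comparing P-loop channel structures),
#' then applies the fitted transform to every atom of the mobile structure.
#'
#' @param mobile,reference `channel_structure` objects.
#' @param selection An `atom_selection` or shorthand (default `"p1-ca"`).
#' @return A list with `structure` (transformed mobile), `rmsd` (over the
#'   selection, after fitting) and `transform`.
#' @export
superpose <- function(mobile, reference, selection = "p1-ca") {
  pr <- pair_selection(mobile, reference, selection)
  P <- coords(mobile)[pr$idx_a, , drop = FALSE]
  Q <- coords(reference)[pr$idx_b, , drop = FALSE]
  fit <- kabsch(P, Q)
  out <- set_coords(mobile, apply_transform(coords(mobile), fit$transform))
  list(structure = out, rmsd = fit$rmsd, transform = fit$transform)
}

#' Coordinate RMSD over a paired selection, without refitting
#'
#' @param a,b `channel_structure` objects.
#' @param selection An `atom_selection` or shorthand.
#' @return RMSD in Angstrom.
#' @export
rmsd_subset <- function(a, b, selection = "ca") {
  pr <- pair_selection(a, b, selection)
  P <- coords(a)[pr$idx_a, , drop = FALSE]
  Q <- coords(b)[pr$idx_b, , drop = FALSE]
  sqrt(mean(rowSums((P - Q)^2)))
}
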