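# Least-squares rigid superposition (Kabsch, via SVD), reflections excluded.

#' Construct a rigid transform
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation Numeric 3-vector (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation is not orthonormal", call. = FALSE)
  if (abs(det(rotation) - 1) > 1e-9)
    stop("rotation has determinant != +1 (reflection?)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param g A [rigid_transform()].
#' @param coords N x 3 coordinate matrix (rows are points).
#' @return Transformed N x 3 matrix.
#' @export
apply_transform <- function(g, coords) {
  stopifnot(inherits(g, "rigid_transform"))
  sweep(as.matrix(coords) %*% t(g$rotation), 2, g$translation, `+`)
}

# Kabsch on raw coordinate matrices; returns list(rotation, translation, rmsd).
.kabsch <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  H <- crossprod(Bc, Ac)                    # 3 x 3
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  if (s == 0) s <- 1
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  fitted <- Bc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Ac - fitted)^2)))
  list(rotation = R, translation = as.numeric(ca - R %*% cb), rmsd = rmsd)
}

#' Optimal rigid superposition of two models
#'
#' Finds the rigid-body transform `G` (rotation + translation, reflections
#' excluded) minimizing the summed squared deviation of `G(B)` from `A`, by
#' the closed-form SVD solution, and reports the resulting RMSD
#' `sqrt(mean_i |x_i^A - G(x_i^B)|^2)`. Coordinates must be in 1:1 residue
#' correspondence; use [harmonize_ensemble()] first. For degenerate (e.g.
#' collinear) point sets the rotation about the degenerate axis is fixed by
#' the deterministic SVD convention.
#'
#' @param A,B [chain_model()] objects (or N x 3 matrices) of equal length,
#'   N >= 3.
#' @return List with elements `transform` (a [rigid_transform()]) and `rmsd`.
#' @export
#' @examples
#' m <- chain_model("t", rep("A", 4), rbind(c(0, 0, 0), c(3.8, 0, 0),
#'                                          c(3.8, 3.8, 0), c(0, 3.8, 3)))
#' superpose(m, m)$rmsd
superpose <- function(A, B) {
  ca <- if (inherits(A, "chain_model")) A$coords else as.matrix(A)
  cb <- if (inherits(B, "chain_model")) B$coords else as.matrix(B)
  if (nrow(ca) != nrow(cb))
    stop("superpose: models have different lengths", call. = FALSE)
  if (nrow(ca) < 3L)
    stop("superpose: need at least 3 points", call. = FALSE)
  if (!all(is.finite(ca)) || !all(is.finite(cb)))
    stop("superpose: non-finite coordinates", call. = FALSE)
  k <- .kabsch(ca, cb)
  list(transform = rigid_transform(k$rotation, k$translation), rmsd = k$rmsd)
}
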