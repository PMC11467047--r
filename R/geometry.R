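# Coordinate geometry: pairwise distances and least-squares superposition.

# Squared Euclidean cross-distances between two n x 3 coordinate matrices.
# Chunked over rows of `a` to bound memory on large chains.
cross_dist2 <- function(a, b, chunk = 2048L) {
  na <- nrow(a); nb <- nrow(b)
  out <- matrix(0, na, nb)
  b2 <- rowSums(b * b)
  i <- 1L
  while (i <= na) {
    j <- min(i + chunk - 1L, na)
    ai <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(ai * ai), b2, "+") - 2 * tcrossprod(ai, b)
    d2[d2 < 0] <- 0  # numerical noise
    out[i:j, ] <- d2
    i <- j + 1L
  }
  out
}

#' Least-squares rigid-body superposition
#'
#' Finds the proper rotation (determinant +1) and translation that minimize
#' the RMSD between `coords_mov` and `coords_ref` over paired points, using
#' the SVD-based Kabsch algorithm. The transform maps moving coordinates as
#' `x %*% rotation + translation` (row-vector convention).
#'
#' @param coords_ref N x 3 matrix of target coordinates (Angstrom).
#' @param coords_mov N x 3 matrix of coordinates to superpose, paired row by
#'   row with `coords_ref`.
#' @return A list with elements `rotation` (3 x 3), `translation` (length-3)
#'   and `rmsd` (Angstrom).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(15), 5, 3)
#' superpose(x, x)$rmsd
superpose <- function(coords_ref, coords_mov) {
  coords_ref <- as.matrix(coords_ref)
  coords_mov <- as.matrix(coords_mov)
  if (nrow(coords_ref) != nrow(coords_mov) || ncol(coords_ref) != 3L ||
      ncol(coords_mov) != 3L)
    stop("superpose(): coordinate matrices must be N x 3 and paired")
  if (nrow(coords_ref) < 3L)
    stop("superpose(): at least 3 paired points are required, got ",
         nrow(coords_ref))
  if (!all(is.finite(coords_ref)) || !all(is.finite(coords_mov)))
    stop("superpose(): coordinates must be finite")
  cr <- colMeans(coords_ref)
  cm <- colMeans(coords_mov)
  p <- sweep(coords_ref, 2, cr)
  q <- sweep(coords_mov, 2, cm)
  h <- crossprod(q, p)              # 3x3 covariance, t(q) %*% p
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  trans <- cr - as.numeric(cm %*% rot)
  fitted <- sweep(coords_mov %*% rot, 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - coords_ref)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

# Apply a superposition transform to an n x 3 coordinate matrix.
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% fit$rotation, 2, fit$translation, "+")
}

# Plain RMSD between paired coordinate sets (no superposition).
paired_rmsd <- function(a, b) {
  sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
}

# Rotation matrix about an arbitrary axis (for fixtures and tests).
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  matrix(c(
    c_ + ux^2 * (1 - c_),      ux * uy * (1 - c_) - uz * s_, ux * uz * (1 - c_) + uy * s_,
    uy * ux * (1 - c_) + uz * s_, c_ + uy^2 * (1 - c_),      uy * uz * (1 - c_) - ux * s_,
    uz * ux * (1 - c_) - uy * s_, uz * uy * (1 - c_) + ux * s_, c_ + uz^2 * (1 - c_)
  ), 3, 3, byrow = TRUE)
}
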