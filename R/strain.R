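#' In-plane deformation gradient of a tracked triangle
#'
#' Given one triangle of the reference wall and the same triangle (same
#' vertex correspondence) in a deformed phase, computes the 2x2 in-plane
#' deformation gradient F mapping reference edge vectors, expressed in a
#' local orthonormal frame of the reference face plane, to deformed edge
#' vectors in the deformed face frame.  Rigid motion of the triangle yields
#' an orthonormal F (identity with this frame construction), so the
#' Green-Lagrange strain derived from it vanishes for rigid motion.
#'
#' @param ref 3x3 matrix, reference vertex coordinates (rows).
#' @param def 3x3 matrix, deformed vertex coordinates (rows), same order.
#' @param area_tol reject triangles with area below this (degenerate).
#' @return 2x2 deformation gradient matrix.
#' @examples
#' tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' face_deformation_gradient(tri, 1.1 * tri)  # 1.1 * identity
#' @export
face_deformation_gradient <- function(ref, def, area_tol = 1e-12) {
  if (any(!is.finite(ref)) || any(!is.finite(def)))
    stop("non-finite triangle coordinates")
  G <- edge_matrix_2d(ref, area_tol)
  H <- edge_matrix_2d(def, area_tol)
  H %*% solve(G)
}

# Edge vectors of a triangle expressed in a local orthonormal in-plane frame
# (e1 along the first edge, e2 = n x e1).  Returns a 2x2 matrix whose columns
# are the two edge vectors.
edge_matrix_2d <- function(tri, area_tol = 1e-12) {
  u <- tri[2L, ] - tri[1L, ]
  v <- tri[3L, ] - tri[1L, ]
  n <- c(u[2L] * v[3L] - u[3L] * v[2L],
         u[3L] * v[1L] - u[1L] * v[3L],
         u[1L] * v[2L] - u[2L] * v[1L])
  a2 <- sqrt(sum(n^2))             # twice the area
  if (a2 / 2 <= area_tol) stop("degenerate triangle (area below tolerance)")
  e1 <- u / sqrt(sum(u^2))
  n <- n / a2
  e2 <- c(n[2L] * e1[3L] - n[3L] * e1[2L],
          n[3L] * e1[1L] - n[1L] * e1[3L],
          n[1L] * e1[2L] - n[2L] * e1[1L])
  matrix(c(sum(e1 * u), sum(e2 * u), sum(e1 * v), sum(e2 * v)), 2L, 2L)
}

#' Green-Lagrange strain tensor and principal strain
#'
#' `green_lagrange()` computes E = (F'F - I)/2 from a deformation gradient;
#' `max_principal_strain()` returns the largest eigenvalue of E, the maximum
#' principal strain.  For an equibiaxial stretch lambda the principal strain
#' is (lambda^2 - 1)/2; for any rigid motion it is 0.
#'
#' @param F a 2x2 (or 3x3) deformation gradient with positive determinant.
#' @param E a symmetric strain tensor as returned by `green_lagrange()`.
#' @return `green_lagrange()`: symmetric matrix; `max_principal_strain()`:
#'   scalar, bounded below by -1/2 for any real deformation.
#' @export
green_lagrange <- function(F) {
  if (any(!is.finite(F))) stop("non-finite deformation gradient")
  if (det(F) <= 0) stop("deformation gradient must have positive determinant")
  (crossprod(F) - diag(nrow(F))) / 2
}

#' @rdname green_lagrange
#' @export
max_principal_strain <- function(E) {
  max(eigen(E, symmetric = TRUE, only.values = TRUE)$values)
}

#' Per-face maximum principal strain over the cardiac cycle
#'
#' Computes, for every face of a tracked wall mesh, the Green-Lagrange
#' strain of each phase relative to the reference configuration and returns
#' the per-face maximum principal strain, maximized over phases (the
#' "max-then-average" convention: this cycle peak is what subsequently gets
#' region-averaged).  Vectorized over faces via the closed-form eigenvalues
#' of the 2x2 right Cauchy-Green tensor.
#'
#' @param mesh reference [surface_mesh()] of the outer wall.
#' @param phase_positions list of node coordinate matrices, one per phase;
#'   the first phase is conventionally the reference.
#' @param reference index of the reference phase (default 1).
#' @return list with `max_principal` (per-face scalar, cycle maximum) and
#'   `per_phase` (faces x phases matrix of per-phase maximum principal
#'   strain).
#' @export
principal_strain <- function(mesh, phase_positions, reference = 1L) {
  f <- mesh$faces
  ref <- phase_positions[[reference]]
  n_faces <- nrow(f)
  per_phase <- matrix(NA_real_, n_faces, length(phase_positions))
  gm <- metric_components(ref, f)          # reference metric [gu.u, gu.v, gv.v]
  # inverse of reference edge Gram factor handled through the generalized
  # eigenproblem: eigenvalues of C = G^-T H^T H G^-1 equal those of
  # (H^T H)(G^T G)^-1, so only Gram matrices are needed per face.
  for (k in seq_along(phase_positions)) {
    hm <- metric_components(phase_positions[[k]], f)
    per_phase[, k] <- gen_eig_max(hm, gm)
  }
  per_phase <- (per_phase - 1) / 2
  list(max_principal = apply(per_phase, 1L, max), per_phase = per_phase)
}

# Per-face Gram matrix components of the two edge vectors: columns
# [u.u, u.v, v.v].
metric_components <- function(nodes, faces) {
  u <- nodes[faces[, 2L], , drop = FALSE] - nodes[faces[, 1L], , drop = FALSE]
  v <- nodes[faces[, 3L], , drop = FALSE] - nodes[faces[, 1L], , drop = FALSE]
  cbind(rowSums(u * u), rowSums(u * v), rowSums(v * v))
}

# Largest generalized eigenvalue of (H, G) for per-face 2x2 Gram matrices
# given as [a11, a12, a22] component columns.  Reduces to a standard
# symmetric problem via the Cholesky factor of G (G = L L'): the
# eigenvalues of (H, G) are those of M = L^-1 H L^-T, and the stable
# 2x2 form (m11+m22)/2 + sqrt(((m11-m22)/2)^2 + m12^2) avoids the
# characteristic-polynomial discriminant, whose cancellation when the two
# eigenvalues coincide (rigid motion) caps accuracy at ~sqrt(eps).
gen_eig_max <- function(h, g) {
  detg <- g[, 1L] * g[, 3L] - g[, 2L]^2
  if (any(detg <= 0)) stop("degenerate reference face")
  m11 <- h[, 1L] / g[, 1L]
  m12 <- (h[, 2L] - h[, 1L] * g[, 2L] / g[, 1L]) / sqrt(detg)
  m22 <- (g[, 1L] * h[, 3L] - 2 * g[, 2L] * h[, 2L] +
            g[, 2L]^2 * h[, 1L] / g[, 1L]) / detg
  (m11 + m22) / 2 + sqrt(((m11 - m22) / 2)^2 + m12^2)
}
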