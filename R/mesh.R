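#' Triangulated surface mesh
#'
#' Light-weight container for a triangulated surface such as the aortic lumen
#' or outer wall: an `n x 3` matrix of node coordinates (mm) and an `m x 3`
#' integer matrix of 1-based node indices per triangular face.  Optional named
#' per-node and per-face fields (scalars as vectors, vectors as 3-column
#' matrices) travel with the mesh.
#'
#' @param nodes numeric matrix, `n x 3`, node coordinates in mm.
#' @param faces integer matrix, `m x 3`, node indices (1-based) per triangle.
#' @param node_data named list of per-node fields (length/nrow `n`).
#' @param face_data named list of per-face fields (length/nrow `m`).
#' @param validate if `TRUE` (default), check index ranges, field sizes and
#'   reject zero-area faces.
#' @return An object of class `surface_mesh`.
#' @examples
#' nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
#' m <- surface_mesh(nodes, matrix(c(1, 2, 3), 1))
#' face_areas(m)
#' @export
surface_mesh <- function(nodes, faces, node_data = list(), face_data = list(),
                         validate = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(nodes) != 3L) stop("'nodes' must have 3 columns")
  if (ncol(faces) != 3L) stop("'faces' must have 3 columns")
  m <- structure(list(nodes = nodes, faces = faces,
                      node_data = node_data, face_data = face_data),
                 class = "surface_mesh")
  if (validate) validate_mesh(m)
  m
}

validate_mesh <- function(mesh, area_tol = 1e-12) {
  n <- nrow(mesh$nodes)
  if (any(!is.finite(mesh$nodes))) stop("non-finite node coordinates")
  if (any(mesh$faces < 1L) || any(mesh$faces > n))
    stop("face indices out of range")
  a <- face_areas(mesh)
  if (any(a <= area_tol))
    stop(sprintf("%d degenerate (zero-area) faces", sum(a <= area_tol)))
  for (nm in names(mesh$node_data)) {
    len <- NROW(mesh$node_data[[nm]])
    if (len != n) stop(sprintf("node field '%s' has length %d, expected %d",
                               nm, len, n))
  }
  for (nm in names(mesh$face_data)) {
    len <- NROW(mesh$face_data[[nm]])
    if (len != nrow(mesh$faces))
      stop(sprintf("face field '%s' has length %d, expected %d",
                   nm, len, nrow(mesh$faces)))
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d nodes, %d faces\n",
              nrow(x$nodes), nrow(x$faces)))
  if (length(x$node_data))
    cat("  node fields:", paste(names(x$node_data), collapse = ", "), "\n")
  if (length(x$face_data))
    cat("  face fields:", paste(names(x$face_data), collapse = ", "), "\n")
  invisible(x)
}

#' Per-face areas, centroids and edge lengths
#'
#' @param mesh a [surface_mesh()].
#' @param nodes optional replacement coordinates (e.g. a deformed phase),
#'   same dimensions as `mesh$nodes`.
#' @return `face_areas()`: numeric vector of triangle areas (mm^2);
#'   `face_centroids()`: `m x 3` matrix; `mean_edge_length()`: scalar mm.
#' @export
face_areas <- function(mesh, nodes = NULL) {
  p <- nodes %||% mesh$nodes
  f <- mesh$faces
  u <- p[f[, 2L], , drop = FALSE] - p[f[, 1L], , drop = FALSE]
  v <- p[f[, 3L], , drop = FALSE] - p[f[, 1L], , drop = FALSE]
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname face_areas
#' @export
face_centroids <- function(mesh, nodes = NULL) {
  p <- nodes %||% mesh$nodes
  f <- mesh$faces
  (p[f[, 1L], , drop = FALSE] + p[f[, 2L], , drop = FALSE] +
     p[f[, 3L], , drop = FALSE]) / 3
}

#' @rdname face_areas
#' @export
mean_edge_length <- function(mesh, nodes = NULL) {
  p <- nodes %||% mesh$nodes
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  d <- p[e[, 1L], , drop = FALSE] - p[e[, 2L], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

# Apply a rigid (or affine) transform x -> R x + t to a coordinate set
# stored row-wise.
transform_points <- function(points, rotation = diag(3),
                             translation = c(0, 0, 0)) {
  sweep(points %*% t(rotation), 2L, translation, "+")
}
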