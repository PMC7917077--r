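# Analytic fixtures built in code: structured cylinders and curved tubes
# with known geometry, used as independent oracles for the mesh pipeline.

# Straight cylinder surface along z (closed tube wall, open ends).
cylinder_mesh <- function(radius = 10, length = 100, n_rings = 30,
                          n_circ = 24, center = c(0, 0, 0)) {
  z <- seq(0, length, length.out = n_rings)
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  nodes <- cbind(rep(radius * cos(theta), n_rings) + center[1L],
                 rep(radius * sin(theta), n_rings) + center[2L],
                 rep(z, each = n_circ) + center[3L])
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  i <- rep(seq_len(n_rings - 1L), each = n_circ)
  j <- rep(seq_len(n_circ), n_rings - 1L)
  faces <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                 cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  surface_mesh(nodes, faces)
}

# Tube swept along a circular arc of radius R in the x-z plane (torus
# segment); returns the mesh and the analytic arc for comparison.
torus_tube_mesh <- function(arc_radius = 120, tube_radius = 9,
                            arc_span = pi / 3, n_rings = 60, n_circ = 24) {
  phi <- seq(0, arc_span, length.out = n_rings)
  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  nodes <- matrix(0, n_rings * n_circ, 3L)
  for (i in seq_len(n_rings)) {
    cen <- arc_radius * c(sin(phi[i]), 0, -cos(phi[i]))
    e_r <- c(sin(phi[i]), 0, -cos(phi[i]))   # radial (in-plane) direction
    e_y <- c(0, 1, 0)
    ring <- t(sapply(theta, function(th)
      cen + tube_radius * (cos(th) * e_r + sin(th) * e_y)))
    nodes[(i - 1L) * n_circ + seq_len(n_circ), ] <- ring
  }
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  i <- rep(seq_len(n_rings - 1L), each = n_circ)
  j <- rep(seq_len(n_circ), n_rings - 1L)
  faces <- rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
                 cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
  arc_fn <- function(p) arc_radius * cbind(sin(p), 0, -cos(p))
  list(mesh = surface_mesh(nodes, faces), arc = arc_fn,
       arc_span = arc_span)
}

# Small, fast synthetic aneurysm for pipeline tests (overridable defaults).
small_aaa_config <- function(...) {
  args <- list(n_axial_rings = 24, n_circ = 20, n_phases = 4)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(aaa_config, args)
}

# Random 3D rotation matrix (uniform via QR of Gaussian matrix).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

# Brute-force pairwise-counting AUC: the independent oracle.
auc_brute_force <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}
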