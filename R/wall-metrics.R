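#' Intraluminal thrombus thickness
#'
#' For each node of the outer wall, the mean Euclidean distance to all lumen
#' nodes lying within `radius` of it — the wall-to-lumen gap left by the
#' thrombus.  Nodes with no lumen neighbor inside the search radius are
#' flagged missing (`NA`), not zero, and are later excluded from regional
#' averages.  A `method = "nearest"` variant returns instead the distance to
#' the closest point on the lumen triangulation (point-to-surface), useful
#' as a sensitivity check on the neighborhood-mean definition.
#'
#' @param wall,lumen [surface_mesh()]es in the same coordinate frame.
#' @param radius neighbor search radius in mm (default 5, of the order of
#'   the population-mean thrombus thickness).
#' @param method `"mean"` (neighborhood mean, default) or `"nearest"`
#'   (point-to-triangle distance).
#' @return List of class `thickness_field`: `thickness` (per wall node, mm,
#'   `NA` where missing), `n_neighbors` (per node), `radius`, `method`.
#' @export
ilt_thickness <- function(wall, lumen, radius = 5, method = c("mean",
                                                              "nearest")) {
  method <- match.arg(method)
  if (radius <= 0) stop("radius must be positive")
  if (nrow(lumen$nodes) == 0L) stop("empty lumen mesh")
  wp <- wall$nodes
  lp <- lumen$nodes
  n <- nrow(wp)
  thick <- rep(NA_real_, n)
  count <- integer(n)
  if (method == "mean") {
    # chunked all-pairs distances to bound memory at ~n_chunk x n_lumen
    chunk <- max(1L, floor(4e6 / nrow(lp)))
    l2 <- rowSums(lp^2)
    for (s in seq(1L, n, by = chunk)) {
      ii <- s:min(s + chunk - 1L, n)
      d2 <- outer(rowSums(wp[ii, , drop = FALSE]^2), l2, "+") -
        2 * wp[ii, , drop = FALSE] %*% t(lp)
      d <- sqrt(pmax(d2, 0))
      inr <- d <= radius
      count[ii] <- rowSums(inr)
      sums <- rowSums(d * inr)
      thick[ii] <- ifelse(count[ii] > 0L, sums / count[ii], NA_real_)
    }
  } else {
    thick <- point_to_surface_distance(wp, lumen)
    count <- rep(NA_integer_, n)
  }
  structure(list(thickness = thick, n_neighbors = count, radius = radius,
                 method = method),
            class = "thickness_field")
}

#' @export
print.thickness_field <- function(x, ...) {
  ok <- is.finite(x$thickness)
  cat(sprintf(paste0("thickness_field (%s, radius %.1f mm): ",
                     "%d nodes, %d missing, mean %.2f mm\n"),
              x$method, x$radius, base::length(x$thickness), sum(!ok),
              mean(x$thickness[ok])))
  invisible(x)
}

# Minimum distance from each query point to a triangulated surface.
# Exact: the closest point lies either at the unconstrained in-plane
# projection (when inside the triangle) or on one of the three edges; the
# minimum over those candidates (edge projections clamped to the segment)
# covers the vertices too.
point_to_surface_distance <- function(query, mesh) {
  f <- mesh$faces
  p <- mesh$nodes
  a <- p[f[, 1L], , drop = FALSE]
  b <- p[f[, 2L], , drop = FALSE]
  cc <- p[f[, 3L], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  e3 <- cc - b
  d11 <- rowSums(e1 * e1); d12 <- rowSums(e1 * e2); d22 <- rowSums(e2 * e2)
  d33 <- rowSums(e3 * e3)
  det <- pmax(d11 * d22 - d12^2, .Machine$double.eps)
  seg_d2 <- function(orig, edge, len2, q) {
    w <- sweep(orig, 2L, q, "-") * -1
    t <- pmin(pmax(rowSums(w * edge) / len2, 0), 1)
    rowSums((w - t * edge)^2)
  }
  vapply(seq_len(nrow(query)), function(i) {
    q <- query[i, ]
    w <- sweep(a, 2L, q, "-") * -1
    b1 <- rowSums(w * e1); b2 <- rowSums(w * e2)
    s <- (d22 * b1 - d12 * b2) / det
    t <- (d11 * b2 - d12 * b1) / det
    inside <- s >= 0 & t >= 0 & s + t <= 1
    d2 <- pmin(seg_d2(a, e1, d11, q), seg_d2(a, e2, d22, q),
               seg_d2(b, e3, d33, q))
    if (any(inside)) {
      foot <- w[inside, , drop = FALSE] -
        s[inside] * e1[inside, , drop = FALSE] -
        t[inside] * e2[inside, , drop = FALSE]
      d2[inside] <- pmin(d2[inside], rowSums(foot^2))
    }
    sqrt(min(d2))
  }, 0)
}

#' Time-averaged wall shear stress
#'
#' Integrates the WSS magnitude over one cardiac cycle per face,
#' `TAWSS = (1/T) * integral |tau(t)| dt`, by the trapezoidal rule with
#' periodic closure (the last phase connects back to the first).  For
#' uniformly spaced phases this reduces to the arithmetic mean of the
#' per-phase magnitudes.
#'
#' @param wss_series list of per-phase WSS fields: `m x 3` vector matrices
#'   (Pa) or length-`m` magnitude vectors.
#' @param phase_times strictly increasing phase times (s) spanning one
#'   cycle.
#' @param period cycle duration; default extends the phase grid uniformly,
#'   `(t_n - t_1) * n / (n - 1)`.
#' @return Per-face TAWSS (Pa).
#' @export
tawss <- function(wss_series, phase_times, period = NULL) {
  n <- base::length(phase_times)
  if (n < 2L) stop("at least 2 phases are required")
  if (base::length(wss_series) != n)
    stop("wss_series and phase_times lengths differ")
  if (any(diff(phase_times) <= 0))
    stop("phase_times must be strictly increasing")
  period <- period %||% ((phase_times[n] - phase_times[1L]) * n / (n - 1L))
  if (period <= phase_times[n] - phase_times[1L])
    stop("period must exceed the phase time span")
  mag <- vapply(wss_series, function(w) {
    if (is.matrix(w)) sqrt(rowSums(w^2)) else abs(as.numeric(w))
  }, numeric(if (is.matrix(wss_series[[1L]])) nrow(wss_series[[1L]])
             else base::length(wss_series[[1L]])))
  if (is.null(dim(mag))) mag <- matrix(mag, nrow = 1L)
  dt <- diff(phase_times)
  closure <- period - (phase_times[n] - phase_times[1L])
  integral <- mag[, -n, drop = FALSE] %*% dt / 2 +
    mag[, -1L, drop = FALSE] %*% dt / 2 +
    (mag[, n] + mag[, 1L]) * closure / 2
  as.vector(integral) / period
}
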