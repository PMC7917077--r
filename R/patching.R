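#' Extract a lumen centerline
#'
#' Marches cross-section centroids along the principal axis of a tube-like
#' surface: nodes are binned by their projection onto the first principal
#' direction of the point cloud, each non-empty bin contributes the centroid
#' of its nodes, an optional moving-average pass smooths the polyline, the
#' ends are corrected for oblique slicing (a single global axis cuts a
#' curved tube at an angle near its ends, dragging the end centroids
#' sideways by up to the tube radius: the last `end_trim` estimated tube
#' radii of polyline are discarded and rebuilt by linear extension of the
#' local end direction out to the data extent), and the result is
#' resampled at equal arclength.  The centerline is oriented away from the
#' end that contains the mesh's first node, so its direction follows the
#' mesh under any joint rigid motion.
#'
#' @param lumen a [surface_mesh()] of the (tube-like) lumen.
#' @param n_samples number of output centerline points.
#' @param n_slices number of slicing bins (default `2 * n_samples`).
#' @param smooth_window moving-average half-width in points (0 disables).
#' @param end_trim span trimmed and rebuilt at each end, in multiples of
#'   the estimated tube radius (0 disables the end correction).
#' @return An object of class `centerline`: list with `points`
#'   (`n_samples x 3`) and `arclength` (cumulative, strictly increasing).
#' @export
compute_centerline <- function(lumen, n_samples = 50L, n_slices = NULL,
                               smooth_window = 2L, end_trim = 1) {
  p <- lumen$nodes
  n_slices <- n_slices %||% (2L * n_samples)
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2L, ctr), nu = 0L, nv = 1L)
  axis <- sv$v[, 1L]
  proj <- as.vector(sweep(p, 2L, ctr) %*% axis)
  # the SVD axis sign is arbitrary: point it from the end holding node 1
  # toward the end holding the last node, a convention that depends only on
  # the mesh itself and therefore rotates with it
  if (proj[1L] > proj[base::length(proj)]) proj <- -proj
  br <- seq(min(proj), max(proj), length.out = n_slices + 1L)
  bin <- pmin(pmax(findInterval(proj, br, rightmost.closed = TRUE), 1L),
              n_slices)
  keep <- sort(unique(bin))
  if (length(keep) < 2L)
    stop("lumen mesh is not sliceable into cross-sections along its axis")
  cent <- t(vapply(keep, function(b) colMeans(p[bin == b, , drop = FALSE]),
                   numeric(3L)))
  # orient from low to high projection (already sorted by keep)
  if (smooth_window > 0L && nrow(cent) > 2L * smooth_window + 1L) {
    k <- 2L * smooth_window + 1L
    sm <- apply(cent, 2L, stats::filter, filter = rep(1 / k, k))
    inner <- !is.na(sm[, 1L])
    cent[inner, ] <- sm[inner, ]
  }
  dedupe <- function(cent) {
    seg <- sqrt(rowSums(diff(cent)^2))
    if (any(seg == 0)) {
      cent <- cent[c(TRUE, seg > 0), , drop = FALSE]
      seg <- sqrt(rowSums(diff(cent)^2))
    }
    list(points = cent, arc = c(0, cumsum(seg)))
  }
  cur <- dedupe(cent)
  # end correction: discard the polyline span within end_trim estimated
  # tube radii of each end (where the global-axis slices cut the tube
  # obliquely) and extend the reliable interior linearly along its local
  # end direction until the nearby nodes are covered again
  if (end_trim > 0) {
    near <- polyline_nearest(cur$points, cur$arc, p)
    r_est <- stats::median(sqrt(rowSums(near$offset^2)))
    trim <- end_trim * r_est
    total <- max(cur$arc)
    keep <- cur$arc >= trim & cur$arc <= total - trim
    if (total > 4 * trim && sum(keep) >= 6L) {
      step <- mean(diff(cur$arc))
      # fit each coordinate as a quadratic in arclength over a window of
      # ~5 tube radii from the trimmed end (averaging the slicing noise
      # and capturing the tube's curvature), then extrapolate outward
      # until the end nodes are covered again
      rebuild <- function(pts, x, nearby) {
        m <- x <= 5 * r_est
        if (sum(m) < 6L) m <- seq_len(min(nrow(pts), 6L))
        X <- cbind(1, x[m], x[m]^2)
        beta <- qr.solve(X, pts[m, , drop = FALSE])
        u <- -beta[2L, ] / sqrt(sum(beta[2L, ]^2))   # outward unit tangent
        e <- max(as.vector(sweep(nearby, 2L, beta[1L, ]) %*% u), 0)
        if (e == 0) return(pts)
        xs <- seq(-e, -step / 2, length.out = max(1L, ceiling(e / step)))
        rbind(cbind(1, xs, xs^2) %*% beta, pts)
      }
      ptsk <- cur$points[keep, , drop = FALSE]
      arck <- cur$arc[keep]
      lo <- p[near$arclength <= 2 * trim, , drop = FALSE]
      hi <- p[near$arclength >= total - 2 * trim, , drop = FALSE]
      ptsk <- rebuild(ptsk, arck - arck[1L], lo)
      ptsk <- ptsk[rev(seq_len(nrow(ptsk))), , drop = FALSE]
      xrev <- c(0, cumsum(sqrt(rowSums(diff(ptsk)^2))))
      ptsk <- rebuild(ptsk, xrev, hi)
      cur <- dedupe(ptsk[rev(seq_len(nrow(ptsk))), , drop = FALSE])
    }
  }
  cent <- cur$points
  arc <- cur$arc
  tgt <- seq(0, arc[base::length(arc)], length.out = n_samples)
  pts <- cbind(stats::approx(arc, cent[, 1L], tgt)$y,
               stats::approx(arc, cent[, 2L], tgt)$y,
               stats::approx(arc, cent[, 3L], tgt)$y)
  structure(list(points = pts,
                 arclength = c(0, cumsum(sqrt(rowSums(diff(pts)^2))))),
            class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("centerline: %d points, length %.1f mm\n",
              nrow(x$points), max(x$arclength)))
  invisible(x)
}

# Nearest point on a polyline for each query point: returns the interpolated
# foot point, its arclength, and the offset vector query - foot.
polyline_nearest <- function(points, arclength, query) {
  a <- points[-nrow(points), , drop = FALSE]
  b <- points[-1L, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  n_q <- nrow(query)
  best_d2 <- rep(Inf, n_q)
  best_arc <- numeric(n_q)
  best_foot <- matrix(0, n_q, 3L)
  for (si in seq_len(nrow(a))) {
    d <- sweep(query, 2L, a[si, ])
    t <- pmin(pmax(as.vector(d %*% ab[si, ]) / len2[si], 0), 1)
    foot <- outer(t, ab[si, ]) + rep(a[si, ], each = n_q)
    d2 <- rowSums((query - foot)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_foot[upd, ] <- foot[upd, , drop = FALSE]
    best_arc[upd] <- arclength[si] +
      t[upd] * (arclength[si + 1L] - arclength[si])
  }
  list(foot = best_foot, arclength = best_arc, offset = query - best_foot)
}

#' Partition the outer wall into tracked patches
#'
#' Assigns every wall face to one of `n_axial * 4` patches: the axial index
#' comes from binning the face centroid's nearest-centerline arclength into
#' `n_axial` equal-arclength sections (the sectioning perpendicular to the
#' lumen centerline), and the quadrant from the sign of the centroid's
#' offset from the centerline projected onto the patient left-right and
#' anterior-posterior axes.  With the default DICOM LPS axes
#' (left = +x, posterior = +y), patch `"LA3"` is the left-anterior quadrant
#' of the third section from the inlet; ties on an axis go to the left and
#' anterior labels.
#'
#' @param wall outer-wall [surface_mesh()].
#' @param centerline a [compute_centerline()] result spanning the wall.
#' @param n_axial number of axial sections (default 6, giving the standard
#'   24 patches).
#' @param axes list with unit vectors `left` and `posterior` defining the
#'   patient orientation of the mesh coordinates.
#' @return An object of class `patch_assignment`: list with per-face
#'   `patch` (factor, e.g. `"LA3"`), `axial`, `quadrant`, and a `patches`
#'   data frame (patch, axial, quadrant, area_mm2).  Empty patches trigger
#'   a warning naming their ids.
#' @export
assign_patches <- function(wall, centerline, n_axial = 6L,
                           axes = list(left = c(1, 0, 0),
                                       posterior = c(0, 1, 0))) {
  stopifnot(inherits(centerline, "centerline"), n_axial >= 1)
  fc <- face_centroids(wall)
  near <- polyline_nearest(centerline$points, centerline$arclength, fc)
  total <- max(centerline$arclength)
  axial <- pmin(pmax(ceiling(near$arclength / total * n_axial), 1L), n_axial)
  lr <- as.vector(near$offset %*% axes$left)
  pa <- as.vector(near$offset %*% axes$posterior)
  quadrant <- paste0(ifelse(lr >= 0, "L", "R"), ifelse(pa > 0, "P", "A"))
  patch <- paste0(quadrant, axial)
  levels <- as.vector(t(outer(c("LA", "LP", "RA", "RP"), seq_len(n_axial),
                              paste0)))
  patch <- factor(patch, levels = levels)
  area <- face_areas(wall)
  patch_area <- vapply(split(area, patch), sum, 0)
  empty <- names(patch_area)[patch_area == 0]
  if (base::length(empty))
    warning("empty patches: ", paste(empty, collapse = ", "))
  structure(list(patch = patch, axial = axial,
                 quadrant = factor(quadrant,
                                   levels = c("LA", "LP", "RA", "RP")),
                 face_area = area,
                 patches = data.frame(
                   patch = levels,
                   axial = as.integer(sub("^[LR][AP]", "", levels)),
                   quadrant = substr(levels, 1L, 2L),
                   area_mm2 = as.vector(patch_area[levels]),
                   stringsAsFactors = FALSE)),
            class = "patch_assignment")
}

#' @export
print.patch_assignment <- function(x, ...) {
  n <- nlevels(x$patch)
  cat(sprintf("patch_assignment: %d faces over %d patches (%d non-empty)\n",
              base::length(x$patch), n, sum(x$patches$area_mm2 > 0)))
  invisible(x)
}

#' Area-weighted regional average of a per-face field
#'
#' @param values per-face scalar field (length = face count; `NA` entries,
#'   e.g. missing thickness, are excluded from the average).
#' @param assignment a [assign_patches()] result.
#' @return Named numeric vector, one area-weighted mean per patch (`NA` for
#'   patches with no faces or no finite values).
#' @export
patch_average <- function(values, assignment) {
  stopifnot(inherits(assignment, "patch_assignment"))
  if (base::length(values) != base::length(assignment$patch))
    stop("length of 'values' must equal the face count of the assignment")
  w <- assignment$face_area
  ok <- is.finite(values)
  num <- vapply(split(ifelse(ok, values * w, 0), assignment$patch), sum, 0)
  den <- vapply(split(ifelse(ok, w, 0), assignment$patch), sum, 0)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}
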