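#' Read and write surface meshes
#'
#' Plain-text mesh interchange for the formats vascular pipelines exchange:
#' ASCII STL (geometry only; reading welds duplicated vertices), ASCII PLY,
#' and legacy ASCII VTK polydata.  VTK is the only one of the three that
#' carries data arrays: per-node fields are written as `POINT_DATA` and
#' per-face fields as `CELL_DATA` (scalars or 3-vectors).
#'
#' @param path file path; the format is chosen by extension
#'   (`.stl`, `.ply`, `.vtk`).
#' @param mesh a [surface_mesh()].
#' @return `read_mesh()` returns a [surface_mesh()]; `write_mesh()` returns
#'   `path` invisibly.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such mesh file: ", path)
  switch(tolower(tools::file_ext(path)),
         stl = read_stl(path),
         ply = read_ply(path),
         vtk = read_vtk(path),
         stop("unsupported mesh format: ", path))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  switch(tolower(tools::file_ext(path)),
         stl = write_stl(mesh, path),
         ply = write_ply(mesh, path),
         vtk = write_vtk(mesh, path),
         stop("unsupported mesh format: ", path))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

write_stl <- function(mesh, path) {
  f <- mesh$faces
  p <- mesh$nodes
  u <- p[f[, 2L], , drop = FALSE] - p[f[, 1L], , drop = FALSE]
  v <- p[f[, 3L], , drop = FALSE] - p[f[, 1L], , drop = FALSE]
  nrm <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
               u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
               u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), .Machine$double.eps)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  vtx <- function(i) paste("      vertex",
                           fmt_num(p[f[, i], 1L]), fmt_num(p[f[, i], 2L]),
                           fmt_num(p[f[, i], 3L]))
  block <- paste(paste("  facet normal", fmt_num(nrm[, 1L]),
                       fmt_num(nrm[, 2L]), fmt_num(nrm[, 3L])),
                 "    outer loop", vtx(1L), vtx(2L), vtx(3L),
                 "    endloop", "  endfacet", sep = "\n")
  writeLines(block, con)
  writeLines("endsolid surface", con)
}

read_stl <- function(path) {
  ln <- readLines(path)
  vl <- grep("^\\s*vertex\\b", ln, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop("not a valid ASCII STL file: ", path)
  xyz <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))[
    c(FALSE, TRUE, TRUE, TRUE)]), ncol = 3L, byrow = TRUE)
  # Weld identical vertices back into shared nodes.
  key <- paste(xyz[, 1L], xyz[, 2L], xyz[, 3L])
  idx <- match(key, key)
  keep <- sort(unique(idx))
  remap <- integer(length(key))
  remap[keep] <- seq_along(keep)
  faces <- matrix(remap[idx], ncol = 3L, byrow = TRUE)
  surface_mesh(xyz[keep, , drop = FALSE], faces)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(mesh$nodes)),
               "property double x", "property double y", "property double z",
               paste("element face", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(fmt_num(mesh$nodes[, 1L]), fmt_num(mesh$nodes[, 2L]),
                   fmt_num(mesh$nodes[, 3L])), con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L), con)
}

read_ply <- function(path) {
  ln <- readLines(path)
  if (!grepl("^ply", ln[1L])) stop("not a PLY file: ", path)
  end <- match("end_header", trimws(ln))
  nv <- as.integer(sub(".*element vertex\\s+", "",
                       grep("element vertex", ln[1:end], value = TRUE)[1L]))
  nf <- as.integer(sub(".*element face\\s+", "",
                       grep("element face", ln[1:end], value = TRUE)[1L]))
  vrows <- ln[(end + 1L):(end + nv)]
  nodes <- matrix(scan(text = vrows, quiet = TRUE), ncol = 3L, byrow = TRUE)
  frows <- ln[(end + nv + 1L):(end + nv + nf)]
  fv <- matrix(scan(text = frows, quiet = TRUE), ncol = 4L, byrow = TRUE)
  if (any(fv[, 1L] != 3)) stop("only triangular PLY faces are supported")
  surface_mesh(nodes, fv[, 2:4] + 1L)
}

write_vtk <- function(mesh, path, title = "rawaaa surface") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nrow(mesh$nodes), "double")), con)
  writeLines(paste(fmt_num(mesh$nodes[, 1L]), fmt_num(mesh$nodes[, 2L]),
                   fmt_num(mesh$nodes[, 3L])), con)
  nf <- nrow(mesh$faces)
  writeLines(paste("POLYGONS", nf, 4L * nf), con)
  writeLines(paste(3L, mesh$faces[, 1L] - 1L, mesh$faces[, 2L] - 1L,
                   mesh$faces[, 3L] - 1L), con)
  write_vtk_data <- function(fields, n, section) {
    if (!length(fields)) return(invisible())
    writeLines(paste(section, n), con)
    for (nm in names(fields)) {
      val <- fields[[nm]]
      if (is.matrix(val) && ncol(val) == 3L) {
        writeLines(paste("VECTORS", nm, "double"), con)
        writeLines(paste(fmt_num(val[, 1L]), fmt_num(val[, 2L]),
                         fmt_num(val[, 3L])), con)
      } else {
        writeLines(c(paste("SCALARS", nm, "double", 1L),
                     "LOOKUP_TABLE default"), con)
        writeLines(fmt_num(as.numeric(val)), con)
      }
    }
  }
  write_vtk_data(mesh$node_data, nrow(mesh$nodes), "POINT_DATA")
  write_vtk_data(mesh$face_data, nf, "CELL_DATA")
}

read_vtk <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1L]
  if (is.na(ip)) stop("not a legacy VTK polydata file: ", path)
  np <- as.integer(strsplit(trimws(ln[ip]), "\\s+")[[1L]][2L])
  vals <- scan(text = ln[(ip + 1L):length(ln)], quiet = TRUE, n = 3L * np)
  nodes <- matrix(vals, ncol = 3L, byrow = TRUE)
  # POINTS may wrap across lines; find POLYGONS by keyword instead of offset
  ig <- grep("^POLYGONS", ln)[1L]
  hdr <- as.integer(strsplit(trimws(ln[ig]), "\\s+")[[1L]][2:3])
  fvals <- scan(text = ln[(ig + 1L):length(ln)], quiet = TRUE, n = hdr[2L])
  fv <- matrix(fvals, ncol = 4L, byrow = TRUE)
  if (any(fv[, 1L] != 3)) stop("only triangular VTK polygons are supported")
  mesh <- surface_mesh(nodes, fv[, 2:4] + 1L)
  # Data arrays.  Assumes one record per line (the layout this package
  # writes): SCALARS name type / LOOKUP_TABLE default / n value lines, or
  # VECTORS name type / n triple lines.
  read_section <- function(start, n) {
    out <- list()
    i <- start
    while (i <= length(ln)) {
      w <- strsplit(trimws(ln[i]), "\\s+")[[1L]]
      if (length(w) == 0L) { i <- i + 1L; next }
      if (w[1L] %in% c("POINT_DATA", "CELL_DATA")) break
      if (w[1L] == "SCALARS") {
        out[[w[2L]]] <- scan(text = ln[(i + 2L):(i + 1L + n)], quiet = TRUE)
        i <- i + 2L + n
      } else if (w[1L] == "VECTORS") {
        v <- scan(text = ln[(i + 1L):(i + n)], quiet = TRUE)
        out[[w[2L]]] <- matrix(v, ncol = 3L, byrow = TRUE)
        i <- i + 1L + n
      } else i <- i + 1L
    }
    out
  }
  ipd <- grep("^POINT_DATA", ln)[1L]
  if (!is.na(ipd)) mesh$node_data <- read_section(ipd + 1L, np)
  icd <- grep("^CELL_DATA", ln)[1L]
  if (!is.na(icd)) mesh$face_data <- read_section(icd + 1L, hdr[1L])
  validate_mesh(mesh)
}

#' Write a tracked-wall phase series
#'
#' Writes one legacy VTK polydata file per cardiac phase (shared
#' connectivity, phase-specific coordinates) plus a `times.csv` index, the
#' layout used to exchange tracked wall motion and per-phase WSS fields.
#'
#' @param mesh reference [surface_mesh()] (connectivity source).
#' @param phase_positions list of node coordinate matrices, one per phase.
#' @param phase_times numeric vector of phase times (s).
#' @param dir output directory, created if needed.
#' @param wss optional list of `m x 3` per-face WSS vector matrices per phase.
#' @return The index file path, invisibly.
#' @export
write_phase_series <- function(mesh, phase_positions, phase_times, dir,
                               wss = NULL) {
  stopifnot(length(phase_positions) == length(phase_times))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("phase_%03d.vtk", seq_along(phase_times) - 1L)
  for (k in seq_along(phase_times)) {
    mk <- mesh
    mk$nodes <- phase_positions[[k]]
    mk$node_data <- list()
    mk$face_data <- if (is.null(wss)) list() else list(wss = wss[[k]])
    write_vtk(mk, file.path(dir, files[k]))
  }
  idx <- file.path(dir, "times.csv")
  utils::write.csv(data.frame(file = files, time_s = phase_times), idx,
                   row.names = FALSE)
  invisible(idx)
}

#' @rdname write_phase_series
#' @export
read_phase_series <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "times.csv"))
  meshes <- lapply(file.path(dir, idx$file), read_mesh)
  ref <- meshes[[1L]]
  wss <- lapply(meshes, function(m) m$face_data$wss)
  if (any(vapply(wss, is.null, TRUE))) wss <- NULL
  list(mesh = ref, phase_positions = lapply(meshes, `[[`, "nodes"),
       phase_times = idx$time_s, wss = wss)
}
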