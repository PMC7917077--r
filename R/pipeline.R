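#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one serializable
#' object that is echoed (with its hash) into every output for provenance.
#' Inputs are either a synthetic aneurysm configuration (`synthetic = TRUE`,
#' the default, using [aaa_config()] arguments passed through `...`) or
#' paths to mesh/phase-series files on disk.
#'
#' @param synthetic generate inputs with [make_aaa()] (default) instead of
#'   reading files.
#' @param wall_path,lumen_path mesh files (STL/PLY/VTK) when
#'   `synthetic = FALSE`.
#' @param phase_dir directory holding the tracked-wall phase series
#'   ([write_phase_series()] layout) when `synthetic = FALSE`.
#' @param curves_path optional tensile-curve CSV analyzed alongside.
#' @param n_axial axial sections (4 quadrants each; default 6 -> 24
#'   patches).
#' @param ilt_search_radius neighbor radius for [ilt_thickness()] (mm).
#' @param raw_threshold high/low RAW cutoff (default 6).
#' @param uts_threshold low-strength cutoff (MPa, default 0.3).
#' @param elastin_threshold high-elastin cutoff (score, default 3).
#' @param seed integer seed.
#' @param ... further arguments to [aaa_config()] when `synthetic = TRUE`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = TRUE, wall_path = NULL,
                            lumen_path = NULL, phase_dir = NULL,
                            curves_path = NULL, n_axial = 6L,
                            ilt_search_radius = 5, raw_threshold = 6,
                            uts_threshold = 0.3, elastin_threshold = 3,
                            seed = 1L, ...) {
  stopifnot(n_axial >= 1, ilt_search_radius > 0, raw_threshold > 0,
            uts_threshold > 0)
  cfg <- list(synthetic = synthetic, wall_path = wall_path,
              lumen_path = lumen_path, phase_dir = phase_dir,
              curves_path = curves_path, n_axial = as.integer(n_axial),
              ilt_search_radius = ilt_search_radius,
              raw_threshold = raw_threshold, uts_threshold = uts_threshold,
              elastin_threshold = elastin_threshold, seed = as.integer(seed))
  if (synthetic) {
    aaa <- aaa_config(..., seed = cfg$seed)
    cfg$aaa <- aaa
  } else {
    for (p in c("wall_path", "lumen_path", "phase_dir")) {
      if (is.null(cfg[[p]])) stop(p, " is required when synthetic = FALSE")
      if (!file.exists(cfg[[p]])) stop("missing input: ", cfg[[p]])
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path a `.json` or `.yaml`/`.yml` file whose top-level keys are
#'   [pipeline_config()] arguments (plus optional `aaa` keys passed to
#'   [aaa_config()]).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml") && !requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  raw <- switch(ext,
                json = jsonlite::fromJSON(path),
                yaml = ,
                yml = yaml::read_yaml(path),
                stop("config must be .json or .yaml: ", path))
  aaa_args <- raw$aaa %||% list()
  raw$aaa <- NULL
  do.call(pipeline_config, c(raw, aaa_args))
}

#' Per-patch descriptor table for one subject
#'
#' The geometry half of the pipeline: centerline, patch assignment, ILT
#' thickness, TAWSS and maximum principal strain, region-averaged
#' (area-weighted, per-node thickness first averaged onto faces).
#'
#' @param wall,lumen [surface_mesh()]es.
#' @param phase_positions list of wall node coordinates per phase.
#' @param phase_times phase times (s).
#' @param wss_series per-phase per-face WSS vectors or magnitudes.
#' @param n_axial axial sections.
#' @param ilt_search_radius mm.
#' @param patient patient id carried into the table.
#' @return List with the per-patch `table` (patient, patch, area_mm2,
#'   ilt_mm, strain, tawss_pa), the `assignment`, `centerline`, and the
#'   per-face/per-node fields.
#' @export
compute_patch_table <- function(wall, lumen, phase_positions, phase_times,
                                wss_series, n_axial = 6L,
                                ilt_search_radius = 5, patient = "P1") {
  cl <- compute_centerline(lumen)
  pa <- assign_patches(wall, cl, n_axial = n_axial)
  thick <- ilt_thickness(wall, lumen, radius = ilt_search_radius)
  # per-node thickness -> per-face (mean of vertices, NA-aware)
  tn <- thick$thickness[wall$faces]
  dim(tn) <- dim(wall$faces)
  thick_face <- rowMeans(tn, na.rm = TRUE)
  thick_face[is.nan(thick_face)] <- NA_real_
  strain <- principal_strain(wall, phase_positions)
  ts <- tawss(wss_series, phase_times)
  tab <- data.frame(
    patient = patient,
    patch = levels(pa$patch),
    area_mm2 = pa$patches$area_mm2,
    ilt_mm = as.vector(patch_average(thick_face, pa)),
    strain = as.vector(patch_average(strain$max_principal, pa)),
    tawss_pa = as.vector(patch_average(ts, pa)),
    stringsAsFactors = FALSE)
  list(table = tab, assignment = pa, centerline = cl, thickness = thick,
       strain = strain, tawss = ts)
}

#' Run the end-to-end pipeline
#'
#' Generates (or reads) the subject's meshes and tracked motion, computes
#' the per-patch descriptor table, fits the RAW index, optionally analyzes a
#' tensile-curve file, and writes the result bundle to `out_dir`:
#' `patch_table.csv` (descriptors, categories, RAW, class),
#' `raw_summary.json`, `wall_raw.vtk` (the wall surface carrying RAW and the
#' descriptors as data arrays for regional maps), and `curve_analysis.csv`
#' when curves are supplied.  Every file embeds the config hash and package
#' version; rerunning with the same config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return List of class `pipeline_result`: `raw_fit` (the [raw_index()]
#'   object), `patch_table`, `curve_analysis` (or `NULL`), `config_hash`,
#'   and the paths written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config[setdiff(names(config), "aaa")])
  version <- as.character(utils::packageVersion("rawaaa"))
  if (config$synthetic) {
    aaa <- make_aaa(config$aaa)
    wall <- aaa$outer_wall
    lumen <- aaa$lumen
    phase_positions <- aaa$phase_positions
    phase_times <- aaa$phase_times
    wss_series <- aaa$wss_series
  } else {
    wall <- read_mesh(config$wall_path)
    lumen <- read_mesh(config$lumen_path)
    series <- read_phase_series(config$phase_dir)
    if (nrow(series$mesh$nodes) != nrow(wall$nodes))
      stop("phase series in ", config$phase_dir,
           " does not match the wall mesh ", config$wall_path)
    phase_positions <- series$phase_positions
    phase_times <- series$phase_times
    wss_series <- series$wss
    if (is.null(wss_series))
      stop("phase series in ", config$phase_dir, " carries no wss arrays")
  }
  pt <- compute_patch_table(wall, lumen, phase_positions, phase_times,
                            wss_series, n_axial = config$n_axial,
                            ilt_search_radius = config$ilt_search_radius)
  fit <- raw_index(pt$table, threshold = config$raw_threshold)
  tab <- fit$table
  tab$raw_printed <- round_raw(tab$raw)

  curves <- NULL
  if (!is.null(config$curves_path)) {
    if (!file.exists(config$curves_path))
      stop("missing input: ", config$curves_path)
    curves <- analyze_curves(read_curves(config$curves_path),
                             uts_threshold = config$uts_threshold)
  }

  paths <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- sprintf("# rawaaa %s config %s", version, hash)
    csv_path <- file.path(out_dir, "patch_table.csv")
    writeLines(stamp, csv_path)
    suppressWarnings(utils::write.table(tab, csv_path, append = TRUE,
                                        sep = ",", row.names = FALSE,
                                        qmethod = "double"))
    json_path <- file.path(out_dir, "raw_summary.json")
    s <- summary(fit)
    jsonlite::write_json(
      list(package_version = version, config_hash = hash,
           threshold = config$raw_threshold,
           overall = as.list(s$overall), per_patient = s$per_patient,
           defaulted = list(ilt_search_radius = config$ilt_search_radius)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    vtk_path <- file.path(out_dir, "wall_raw.vtk")
    wall_out <- wall
    per_face <- function(col) {
      v <- tab[[col]][match(as.character(pt$assignment$patch), tab$patch)]
      ifelse(is.na(v), -1, v)
    }
    wall_out$face_data <- list(raw = per_face("raw"),
                               ilt_mm = per_face("ilt_mm"),
                               strain = per_face("strain"),
                               tawss_pa = per_face("tawss_pa"))
    wall_out$node_data <- list(ilt_thickness_mm =
                                 ifelse(is.na(pt$thickness$thickness), -1,
                                        pt$thickness$thickness))
    write_vtk(wall_out, vtk_path,
              title = sprintf("rawaaa %s config %s", version, hash))
    paths <- c(patch_table = csv_path, summary = json_path, wall = vtk_path)
    if (!is.null(curves)) {
      cpath <- file.path(out_dir, "curve_analysis.csv")
      writeLines(stamp, cpath)
      suppressWarnings(utils::write.table(curves, cpath, append = TRUE,
                                          sep = ",", row.names = FALSE))
      paths <- c(paths, curves = cpath)
    }
  }
  structure(list(raw_fit = fit, patch_table = tab, curve_analysis = curves,
                 config = config, config_hash = hash, paths = paths),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result (config %s)\n", substr(x$config_hash, 1, 8)))
  print(x$raw_fit)
  if (!is.null(x$curve_analysis))
    cat(sprintf("  %d tensile curves analyzed\n", nrow(x$curve_analysis)))
  invisible(x)
}

#' Synthetic cohort with planted regional weakness
#'
#' Generates a cohort of synthetic aneurysms with per-patient variation in
#' sac size, thrombus burden, pulsatility and peak shear, runs the full
#' descriptor pipeline on each, fits the RAW index with the pooled cohort as
#' the population, and plants a per-patch tissue strength: the log UTS
#' decreases with a standardized combination of thick ILT, high strain and
#' low TAWSS (the weak phenotype) plus noise.  Ground truth for validation
#' studies: patches whose planted UTS falls below the threshold are the true
#' weak class that the RAW score should discriminate.
#'
#' @param n_patients cohort size (default 9, the scale of a surgical
#'   resection series).
#' @param seed integer seed.
#' @param n_axial_rings,n_circ,n_phases mesh/cycle resolution per patient.
#' @param uts_threshold low-strength cutoff (MPa).
#' @return List of class `synthetic_cohort`: `table` — one row per
#'   (patient, patch) with descriptors, categories, `raw`, planted
#'   `uts_mpa`, `strength` class and `weakness` (the planted score) — plus
#'   the `raw_fit`.
#' @export
synth_cohort <- function(n_patients = 9L, seed = 1L, n_axial_rings = 36L,
                         n_circ = 28L, n_phases = 6L, uts_threshold = 0.3) {
  draws <- with_seed(seed, list(
    max_radius = stats::runif(n_patients, 20, 31),
    pulsatility = stats::runif(n_patients, 0.02, 0.045),
    wss_peak = stats::runif(n_patients, 1.0, 2.0),
    ilt_amp = stats::runif(n_patients, 4, 9),
    ilt_phase = stats::runif(n_patients, 0, 2 * pi),
    noise_seed = sample.int(1e6, n_patients)))
  tabs <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    amp <- draws$ilt_amp[i]
    ph <- draws$ilt_phase[i]
    profile <- local({
      amp_i <- amp; ph_i <- ph
      function(s, theta)
        0.5 + amp_i * exp(-((s - 0.5) / 0.18)^2) *
          (1 + 0.35 * cos(theta - ph_i)) / 1.35
    })
    cfg <- aaa_config(max_radius = draws$max_radius[i],
                      pulsatility = draws$pulsatility[i],
                      wss_peak = draws$wss_peak[i],
                      ilt_profile = profile,
                      n_axial_rings = n_axial_rings, n_circ = n_circ,
                      n_phases = n_phases, seed = seed + i)
    aaa <- make_aaa(cfg)
    tabs[[i]] <- compute_patch_table(
      aaa$outer_wall, aaa$lumen, aaa$phase_positions, aaa$phase_times,
      aaa$wss_series, patient = sprintf("P%02d", i))$table
  }
  tab <- do.call(rbind, tabs)
  fit <- raw_index(tab)
  out <- fit$table
  z <- function(v) (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
  out$weakness <- z(out$ilt_mm) + z(out$strain) - z(out$tawss_pa)
  out$uts_mpa <- with_seed(seed + 1000L,
                           exp(log(0.5) - 0.4 * z(out$weakness) +
                                 stats::rnorm(nrow(out), 0, 0.3)))
  out$strength <- strength_class(out$uts_mpa, uts_threshold)
  structure(list(table = out, raw_fit = fit, seed = seed),
            class = "synthetic_cohort")
}
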