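#' Configuration for the synthetic aneurysm generator
#'
#' Describes a fusiform abdominal aortic aneurysm as a structured tube:
#' `n_axial_rings` rings of `n_circ` nodes each.  The outer-wall radius
#' follows a smooth bulge from `neck_radius` to `max_radius`; the lumen is
#' the outer wall minus a non-negative thrombus (ILT) gap given by
#' `ilt_profile(s, theta)` with `s` the normalized axial position in `[0, 1]`
#' and `theta` the circumferential angle.  Wall motion over one cardiac
#' cycle is a spatially uniform radial stretch `1 + pulsatility * s(t)` with
#' a raised-cosine waveform `s(t)`, so the per-face maximum principal
#' Green-Lagrange strain has the closed form `(lambda^2 - 1)/2`.
#'
#' Defaults emulate the scale of a surgical AAA cohort: a 22 mm neck, a
#' 54 mm maximum sac diameter, thrombus up to ~7.5 mm deposited
#' eccentrically on the anterior sac (population mean thickness in the sac
#' near 4.6 mm), a radial stretch amplitude giving peak strain about 0.03,
#' and a peak wall shear stress of 1.5 Pa at the neck decaying with the
#' local lumen radius cubed (Poiseuille-like), which reproduces the
#' low-shear aneurysmal sac.
#'
#' @param neck_radius outer-wall radius at the neck (mm).
#' @param max_radius maximum outer-wall radius at mid-sac (mm).
#' @param length axial length of the segment (mm).
#' @param n_axial_rings,n_circ structured-grid resolution.
#' @param ilt_profile `function(s, theta)` returning the wall-to-lumen gap
#'   in mm (vectorized, non-negative).
#' @param pulsatility radial stretch amplitude (dimensionless, >= 0).
#' @param n_phases number of cardiac phases (>= 2) over one cycle.
#' @param cycle_s cardiac cycle duration (s).
#' @param wss_peak peak WSS magnitude at the neck (Pa).
#' @param seed integer seed making the output a pure function of the config.
#' @return An object of class `aaa_config`.
#' @export
aaa_config <- function(neck_radius = 11, max_radius = 27, length = 110,
                       n_axial_rings = 48, n_circ = 36,
                       ilt_profile = default_ilt_profile,
                       pulsatility = 0.03, n_phases = 10, cycle_s = 1,
                       wss_peak = 1.5, seed = 1L) {
  stopifnot(neck_radius > 0, max_radius >= neck_radius, length > 0,
            n_axial_rings >= 2, pulsatility >= 0, n_phases >= 2,
            cycle_s > 0, wss_peak >= 0)
  if (n_circ < 3) stop("n_circ must be at least 3")
  structure(list(neck_radius = neck_radius, max_radius = max_radius,
                 length = length, n_axial_rings = as.integer(n_axial_rings),
                 n_circ = as.integer(n_circ), ilt_profile = ilt_profile,
                 pulsatility = pulsatility, n_phases = as.integer(n_phases),
                 cycle_s = cycle_s, wss_peak = wss_peak,
                 seed = as.integer(seed)),
            class = "aaa_config")
}

#' @rdname aaa_config
#' @param s normalized axial position in `[0, 1]`.
#' @param theta circumferential angle (rad); with the patient axes used here
#'   (left = +x, posterior = +y), `theta = -pi/2` points anterior, where ILT
#'   typically accumulates.
#' @export
default_ilt_profile <- function(s, theta) {
  bump <- exp(-((s - 0.5) / 0.18)^2)
  0.5 + 7 * bump * (1 - 0.35 * sin(theta)) / 1.35
}

# Outer-wall radius profile: smooth raised-cosine fusiform bulge.
wall_radius_profile <- function(s, neck_radius, max_radius) {
  w <- 0.5 * (1 - cos(2 * pi * pmin(pmax(s, 0), 1)))
  neck_radius + (max_radius - neck_radius) * w^1.5
}

# Raised-cosine intra-cycle waveform, 0 at t = 0, 1 at mid cycle.
cycle_waveform <- function(t, cycle_s) 0.5 * (1 - cos(2 * pi * t / cycle_s))

# Structured-tube triangulation shared by wall and lumen: rings x n_circ
# nodes, consistent diagonal split.
tube_faces <- function(n_rings, n_circ) {
  idx <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  i <- rep(seq_len(n_rings - 1L), each = n_circ)
  j <- rep(seq_len(n_circ), n_rings - 1L)
  rbind(cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L)),
        cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L)))
}

tube_nodes <- function(radii, z, theta) {
  n_circ <- base::length(theta)
  cbind(as.vector(t(radii * matrix(cos(theta), nrow(radii), n_circ,
                                   byrow = TRUE))),
        as.vector(t(radii * matrix(sin(theta), nrow(radii), n_circ,
                                   byrow = TRUE))),
        rep(z, each = n_circ))
}

#' Generate a synthetic aneurysm with known ground truth
#'
#' Builds the outer-wall and lumen surfaces, the tracked wall positions over
#' one cardiac cycle, a per-face WSS vector series, and the ground-truth
#' fields every downstream stage can be checked against: the planted ILT gap
#' per wall node, the closed-form maximum principal strain per face, and the
#' quadrant label per face.
#'
#' @param config an [aaa_config()].
#' @return An object of class `synthetic_aaa`: list with `outer_wall`,
#'   `lumen` ([surface_mesh()]s), `phase_positions`, `phase_times`,
#'   `wss_series` (per-phase `m x 3` matrices, Pa), `truth_ilt` (per wall
#'   node, mm), `truth_max_principal_strain` (per wall face),
#'   `truth_patch_quadrant` (per wall face, `"LA"/"LP"/"RA"/"RP"`), and the
#'   `config`.
#' @examples
#' aaa <- make_aaa(aaa_config(n_axial_rings = 12, n_circ = 12, n_phases = 4))
#' aaa$outer_wall
#' @export
make_aaa <- function(config) {
  stopifnot(inherits(config, "aaa_config"))
  with_seed(config$seed, {
    n_r <- config$n_axial_rings
    n_c <- config$n_circ
    z <- seq(0, config$length, length.out = n_r)
    s <- z / config$length
    theta <- 2 * pi * (seq_len(n_c) - 1L) / n_c
    r_wall <- wall_radius_profile(s, config$neck_radius, config$max_radius)
    gap <- outer(s, theta, config$ilt_profile)
    if (any(gap < 0)) stop("ilt_profile must be non-negative")
    r_wall_m <- matrix(r_wall, n_r, n_c)
    r_lumen <- r_wall_m - gap
    if (any(r_lumen <= 0))
      stop("ilt_profile leaves no lumen (gap >= wall radius)")

    faces <- tube_faces(n_r, n_c)
    wall <- surface_mesh(tube_nodes(r_wall_m, z, theta), faces)
    lumen <- surface_mesh(tube_nodes(r_lumen, z, theta), faces)

    # Tracked motion: uniform radial stretch about the z-axis.
    phase_times <- config$cycle_s * (seq_len(config$n_phases) - 1L) /
      config$n_phases
    sv <- cycle_waveform(phase_times, config$cycle_s)
    lambda <- 1 + config$pulsatility * sv
    phase_positions <- lapply(lambda, function(l)
      cbind(l * wall$nodes[, 1L], l * wall$nodes[, 2L], wall$nodes[, 3L]))

    # WSS surrogate: axial direction, magnitude ~ (neck/lumen radius)^3
    # scaled so the cycle peak at the neck equals wss_peak.
    fc <- face_centroids(lumen)
    r_face <- sqrt(fc[, 1L]^2 + fc[, 2L]^2)
    shape <- (min(r_lumen[1L, ]) / r_face)^3
    shape <- shape / max(shape)
    wt <- 0.2 + 0.8 * sv                     # pulsatile waveform, peak 1
    wss_series <- lapply(wt, function(w)
      cbind(0, 0, config$wss_peak * shape * w))

    # Ground truth.
    truth_ilt <- as.vector(t(gap))           # node order: theta fastest
    lam_max <- max(lambda)
    truth_strain <- rep((lam_max^2 - 1) / 2, nrow(faces))
    wc <- face_centroids(wall)
    truth_quadrant <- paste0(ifelse(wc[, 1L] >= 0, "L", "R"),
                             ifelse(wc[, 2L] > 0, "P", "A"))

    structure(list(outer_wall = wall, lumen = lumen,
                   phase_positions = phase_positions,
                   phase_times = phase_times, wss_series = wss_series,
                   truth_ilt = truth_ilt,
                   truth_max_principal_strain = truth_strain,
                   truth_patch_quadrant = truth_quadrant,
                   config = config),
              class = "synthetic_aaa")
  })
}

#' @export
print.synthetic_aaa <- function(x, ...) {
  cat(sprintf(paste0("synthetic_aaa: %d wall nodes, %d faces, %d phases\n",
                     "  neck %.1f mm, max %.1f mm, length %.1f mm, ",
                     "pulsatility %.3f\n"),
              nrow(x$outer_wall$nodes), nrow(x$outer_wall$faces),
              length(x$phase_times), x$config$neck_radius,
              x$config$max_radius, x$config$length, x$config$pulsatility))
  invisible(x)
}

#' Configuration for synthetic ex vivo stress-strain curves
#'
#' Emulates a uniaxial (or one direction of a biaxial) tensile test on
#' aortic tissue: an exponential loading law
#' `stress = a * (exp(b * strain) - 1)` truncated at a planted failure
#' stress, optionally followed by a post-failure discontinuity, plus an
#' unloading branch constructed so that the hysteresis area ratio equals
#' `hysteresis_fraction` exactly before noise.
#'
#' @param a,b exponential loading-law parameters (MPa, dimensionless).
#' @param failure_stress planted ultimate tensile strength (MPa).
#' @param failure_mode `"peak"` (curve ends at its maximum) or
#'   `"discontinuity"` (a sharp drop at the planted failure, then a brief
#'   recovery, as grip slippage or partial tears produce).
#' @param hysteresis_fraction planted energy-loss fraction in `[0, 1)`.
#' @param noise_sd additive Gaussian noise on stress (MPa).
#' @param n_samples samples on the loading branch.
#' @param seed integer seed.
#' @return An object of class `curve_config`.
#' @export
curve_config <- function(a = 0.02, b = 8, failure_stress = 0.5,
                         failure_mode = c("peak", "discontinuity"),
                         hysteresis_fraction = 0.3, noise_sd = 0,
                         n_samples = 200L, seed = 1L) {
  failure_mode <- match.arg(failure_mode)
  stopifnot(a > 0, b > 0, failure_stress > 0, noise_sd >= 0, n_samples >= 10)
  if (hysteresis_fraction < 0 || hysteresis_fraction >= 1)
    stop("hysteresis_fraction must be in [0, 1)")
  structure(list(a = a, b = b, failure_stress = failure_stress,
                 failure_mode = failure_mode,
                 hysteresis_fraction = hysteresis_fraction,
                 noise_sd = noise_sd, n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "curve_config")
}

#' Generate a synthetic stress-strain curve
#'
#' @param config a [curve_config()].
#' @param direction direction tag carried into the output
#'   (`"circumferential"` or `"longitudinal"`).
#' @param sample_id identifier carried into the output.
#' @return A data frame with columns `strain`, `stress_MPa`, `branch`
#'   (`"loading"`/`"unloading"`), `direction`, `sample_id` — the layout
#'   [read_curves()] and [analyze_curves()] consume.
#' @export
make_curve <- function(config, direction = "circumferential",
                       sample_id = "S1") {
  stopifnot(inherits(config, "curve_config"))
  with_seed(config$seed, {
    eps_f <- log(config$failure_stress / config$a + 1) / config$b
    eps <- seq(0, eps_f, length.out = config$n_samples)
    sig <- config$a * (exp(config$b * eps) - 1)
    if (config$failure_mode == "discontinuity") {
      # sharp drop past the planted failure, then partial recovery
      n_post <- max(10L, config$n_samples %/% 10L)
      d_eps <- eps_f * 0.15 * seq_len(n_post) / n_post
      post <- config$failure_stress *
        (0.65 + 0.2 * seq_len(n_post) / n_post)
      eps <- c(eps, eps_f + d_eps)
      sig <- c(sig, post)
    }
    # Unloading spans the pre-failure interval; shape sigma_u =
    # sigma_l * (eps/eps_f)^p with p solved so the trapezoid area ratio is
    # exactly 1 - hysteresis_fraction on the emitted grid.
    load_eps <- eps[eps <= eps_f]
    load_sig <- config$a * (exp(config$b * load_eps) - 1)
    a_load <- trapz(load_eps, load_sig)
    h <- config$hysteresis_fraction
    if (h == 0) {
      unload_sig <- load_sig
    } else {
      frac <- function(p) trapz(load_eps, load_sig *
                                  (load_eps / eps_f)^p) / a_load - (1 - h)
      p <- stats::uniroot(frac, c(0, 500), tol = 1e-14)$root
      unload_sig <- load_sig * (load_eps / eps_f)^p
    }
    out <- rbind(
      data.frame(strain = eps, stress_MPa = sig, branch = "loading"),
      data.frame(strain = rev(load_eps), stress_MPa = rev(unload_sig),
                 branch = "unloading"))
    if (config$noise_sd > 0)
      out$stress_MPa <- out$stress_MPa +
        stats::rnorm(nrow(out), 0, config$noise_sd)
    out$direction <- direction
    out$sample_id <- sample_id
    out
  })
}

trapz <- function(x, y) {
  n <- base::length(x)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}
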