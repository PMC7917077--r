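#' Ultimate tensile strength of a stress-strain curve
#'
#' Failure is the first discontinuity, or the global maximum, of the loading
#' curve: scanning along the loading branch, the first sample whose stress
#' falls below `(1 - drop_fraction)` of the running maximum marks a
#' discontinuity and the running maximum at that point is the UTS; if no
#' such drop occurs the UTS is the global maximum.  The relative-drop
#' detector (default 2%) makes "discontinuity" robust to sensor jitter.
#'
#' @param abscissa strain or stretch of the loading branch (monotone
#'   increasing).
#' @param stress stress (MPa), same length.
#' @param drop_fraction relative drop from the running maximum that counts
#'   as a discontinuity.
#' @return List of class `uts_result`: `uts` (MPa), `failure_index` (sample
#'   index of the peak at failure), `mode` (`"discontinuity"` or `"peak"`).
#' @examples
#' uts(1:5, c(0.1, 0.3, 0.5, 0.2, 0.4))$uts  # 0.5, first discontinuity
#' @export
uts <- function(abscissa, stress, drop_fraction = 0.02) {
  if (base::length(stress) < 3L) stop("need at least 3 loading samples")
  if (base::length(abscissa) != base::length(stress))
    stop("abscissa and stress lengths differ")
  o <- order(abscissa)
  stress <- stress[o]
  runmax <- cummax(stress)
  drop <- which(stress < (1 - drop_fraction) * runmax)
  if (base::length(drop)) {
    j <- drop[1L]
    fi <- which.max(stress[seq_len(j)])
    mode <- "discontinuity"
  } else {
    fi <- which.max(stress)
    mode <- "peak"
  }
  structure(list(uts = stress[fi], failure_index = fi, mode = mode),
            class = "uts_result")
}

#' @export
print.uts_result <- function(x, ...) {
  cat(sprintf("UTS %.3f MPa at sample %d (%s)\n",
              x$uts, x$failure_index, x$mode))
  invisible(x)
}

#' Hysteresis energy loss
#'
#' The percentage ratio of the hysteresis area (between loading and
#' unloading branches) to the total area under the loading curve:
#' `100 * (A_loading - A_unloading) / A_loading`.  Areas are trapezoidal
#' after sorting each branch by abscissa and restricting both to their
#' common abscissa interval.  The result is invariant to the abscissa unit
#' (strain vs stretch), since a shared affine change of abscissa scales both
#' areas equally.
#'
#' @param loading,unloading two-column objects (abscissa, stress) or data
#'   frames with columns named as in [make_curve()] output.
#' @return Energy loss in percent, clipped to `[0, 100]` (with a warning if
#'   the unloading area exceeds the loading area beyond tolerance).
#' @export
energy_loss <- function(loading, unloading) {
  br <- function(x) {
    x <- as.matrix(if (is.data.frame(x)) x[, c(1L, 2L)] else x)
    x[order(x[, 1L]), , drop = FALSE]
  }
  l <- br(loading)
  u <- br(unloading)
  lo <- max(min(l[, 1L]), min(u[, 1L]))
  hi <- min(max(l[, 1L]), max(u[, 1L]))
  if (hi <= lo) stop("branches share no abscissa interval")
  clip <- function(x) x[x[, 1L] >= lo & x[, 1L] <= hi, , drop = FALSE]
  l <- clip(l)
  u <- clip(u)
  a_load <- trapz(l[, 1L], l[, 2L])
  if (a_load <= 0) stop("zero area under the loading curve")
  a_unload <- trapz(u[, 1L], u[, 2L])
  loss <- 100 * (a_load - a_unload) / a_load
  if (loss < -1e-8 * 100)
    warning("unloading area exceeds loading area; energy loss clipped to 0")
  min(max(loss, 0), 100)
}

#' Classify regional strength from UTS
#'
#' `"low"` strength if and only if the ultimate tensile strength is strictly
#' below the threshold (default 0.3 MPa, the value reported for ruptured
#' aneurysm tissue); exactly at the threshold is `"high"`.
#'
#' @param uts_mpa ultimate tensile strength (MPa), vectorized.
#' @param threshold MPa.
#' @return Factor with levels `low`, `high`.
#' @export
strength_class <- function(uts_mpa, threshold = 0.3) {
  stopifnot(all(uts_mpa >= 0, na.rm = TRUE))
  factor(ifelse(uts_mpa < threshold, "low", "high"),
         levels = c("low", "high"))
}

#' Analyze a table of tensile-test curves
#'
#' Consumes the long-format curve table written by [make_curve()] /
#' [read_curves()] (columns `strain`, `stress_MPa`, `branch`, `direction`,
#' `sample_id`) and returns one row per sample and direction with the UTS,
#' failure index, strength class, and — when an unloading branch is present —
#' the hysteresis energy loss.
#'
#' @param curves curve data frame.
#' @param drop_fraction passed to [uts()].
#' @param uts_threshold passed to [strength_class()].
#' @return Data frame keyed by `sample_id` and `direction`.
#' @export
analyze_curves <- function(curves, drop_fraction = 0.02,
                           uts_threshold = 0.3) {
  need <- c("strain", "stress_MPa", "branch", "sample_id")
  miss <- setdiff(need, names(curves))
  if (base::length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(curves$direction)) curves$direction <- "unspecified"
  grp <- interaction(curves$sample_id, curves$direction, drop = TRUE)
  out <- lapply(split(curves, grp), function(d) {
    l <- d[d$branch == "loading", ]
    u <- d[d$branch == "unloading", ]
    res <- uts(l$strain, l$stress_MPa, drop_fraction)
    data.frame(sample_id = d$sample_id[1L], direction = d$direction[1L],
               uts_mpa = res$uts, failure_index = res$failure_index,
               failure_mode = res$mode,
               strength = strength_class(res$uts, uts_threshold),
               energy_loss_pct = if (nrow(u) >= 2L)
                 energy_loss(l[, c("strain", "stress_MPa")],
                             u[, c("strain", "stress_MPa")]) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read and write tensile-curve CSV files
#'
#' CSV layout: columns `strain` (or `stretch`), `stress_MPa`, `branch`
#' (`loading`/`unloading`), `direction`, `sample_id`.
#'
#' @param path CSV file path.
#' @param curves curve data frame as produced by [make_curve()].
#' @return `read_curves()`: the curve data frame; `write_curves()`: `path`,
#'   invisibly.
#' @export
read_curves <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(d$stretch) && is.null(d$strain)) {
    d$strain <- d$stretch
    d$stretch <- NULL
  }
  need <- c("strain", "stress_MPa", "branch")
  miss <- setdiff(need, names(d))
  if (base::length(miss))
    stop(path, " lacks columns: ", paste(miss, collapse = ", "))
  d
}

#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
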