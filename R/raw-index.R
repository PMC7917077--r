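#' Quartile categorization of patch-averaged descriptors
#'
#' Assigns each patch a category 1-4 according to the quartile interval its
#' value falls in: at or below Q1 maps to 1, (Q1, Q2] to 2, (Q2, Q3] to 3
#' and above Q3 to 4 (boundaries inclusive on the lower category).
#' Quartiles use the linear-interpolation convention
#' (`stats::quantile(type = 7)`), and the boundary comparisons carry a
#' small relative tolerance so that values differing only by
#' floating-point noise are treated as tied.  Degenerate distributions
#' (all values equal, exactly or up to that noise) collapse to category 1;
#' fewer than four finite values also yield all 1 with a warning.
#'
#' @param values numeric vector of patch-level descriptor values (`NA`
#'   allowed).
#' @param pool optional numeric vector whose quartiles define the category
#'   boundaries (defaults to `values` itself); used e.g. to categorize one
#'   patient's patches against a population pool.
#' @return Integer categories 1-4 (`NA` where the value is missing).
#' @examples
#' quartile_categories(c(1, 2, 3, 4))  # 1 2 3 4
#' @export
quartile_categories <- function(values, pool = values) {
  out <- rep(NA_integer_, base::length(values))
  ok <- is.finite(values)
  pok <- is.finite(pool)
  if (!any(ok)) stop("all values are missing")
  if (sum(pok) < 4L) {
    warning("fewer than 4 finite values; all assigned category 1")
    out[ok] <- 1L
    return(out)
  }
  q <- stats::quantile(pool[pok], c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  v <- values[ok]
  tol <- 1e-9 * max(abs(v), abs(q))   # machine-noise differences are ties
  out[ok] <- 1L + (v > q[1L] + tol) + (v > q[2L] + tol) + (v > q[3L] + tol)
  out
}

#' Combined patient-specific and population quartile category
#'
#' Averages the category a patch receives within its own patient's
#' distribution with the category it receives within the population
#' distribution, yielding the half-integer categories
#' `{1, 1.5, 2, ..., 4}` used for the score.
#'
#' @param patient_category,population_category integer categories 1-4.
#' @return Half-integer combined category.
#' @export
combined_quartile <- function(patient_category, population_category) {
  chk <- function(x, nm) {
    if (any(is.finite(x) & (x < 1 | x > 4)))
      stop(nm, " categories must lie in [1, 4]")
  }
  chk(patient_category, "patient")
  chk(population_category, "population")
  (patient_category + population_category) / 2
}

#' The Regional Aortic Weakness score
#'
#' Combines the three per-patch categories into the 0-10 RAW index:
#' \deqn{RAW = \frac{ILT_{cat} + STRAIN_{cat} + (5 - TAWSS_{cat}) - 3}{9}
#'   \times 10}
#' The TAWSS category is inverted so that low shear — which accompanies
#' thrombus deposition, sac enlargement and rupture — raises the score.
#' The minimum attainable triplet (1, 1, 4) gives 0 and the maximum
#' (4, 4, 1) gives 10.
#'
#' @param ilt_category,strain_category,tawss_category categories in
#'   `[1, 4]` (integers or the half-integers of [combined_quartile()]);
#'   vectorized.
#' @return Numeric RAW score(s) in `[0, 10]`, full precision (round with
#'   [round_raw()] for reporting).
#' @examples
#' raw_score(2.5, 4, 1)   # 8.33 once rounded
#' raw_score(4, 4, 1)     # 10
#' @export
raw_score <- function(ilt_category, strain_category, tawss_category) {
  cats <- cbind(ilt_category, strain_category, tawss_category)
  if (any(is.finite(cats) & (cats < 1 | cats > 4)))
    stop("categories must lie in [1, 4]")
  ((ilt_category + strain_category + (5 - tawss_category)) - 3) / 9 * 10
}

#' @rdname raw_score
#' @param raw RAW score(s).
#' @export
round_raw <- function(raw) round_half_up(raw, 2L)

#' Dichotomize the RAW score
#'
#' `"high"` (weakened) if and only if the score strictly exceeds the
#' threshold; a score exactly at the threshold is `"low"`.
#'
#' @param raw RAW score(s).
#' @param threshold default 6, the cutoff separating low and high levels of
#'   weakening.
#' @return Factor with levels `low`, `high`.
#' @export
classify_raw <- function(raw, threshold = 6) {
  factor(ifelse(raw > threshold, "high", "low"), levels = c("low", "high"))
}

#' Fit the RAW index to a table of patch descriptors
#'
#' The central scoring routine: given one row per (patient, patch) with the
#' three region-averaged descriptors, computes for each descriptor the
#' patient-specific quartile category (within each patient's own patches),
#' the population category (over the pooled patches, or a supplied pool),
#' their combined half-integer category, the RAW score and the high/low
#' class.
#'
#' @param data data frame with columns `patient`, `patch`, `ilt_mm`,
#'   `strain`, `tawss_pa`.
#' @param population optional data frame with the same descriptor columns
#'   defining the population pool for the population categories; defaults
#'   to `data` itself.
#' @param threshold classification threshold on the score (default 6).
#' @param combine `"combined"` (default) averages patient and population
#'   categories; `"patient"` or `"population"` uses a single source.
#' @return An object of class `raw_index`: the input table augmented with
#'   per-descriptor categories, `raw`, and `risk`, plus the call and
#'   threshold.  Methods: `print`, `summary`, `plot`, `as.data.frame`.
#' @examples
#' d <- data.frame(patient = "P1", patch = paste0("LA", 1:8),
#'                 ilt_mm = 1:8, strain = (1:8) / 100,
#'                 tawss_pa = seq(1.5, 0.1, length.out = 8))
#' fit <- raw_index(d)
#' summary(fit)
#' @export
raw_index <- function(data, population = NULL, threshold = 6,
                      combine = c("combined", "patient", "population")) {
  combine <- match.arg(combine)
  need <- c("patient", "patch", "ilt_mm", "strain", "tawss_pa")
  miss <- setdiff(need, names(data))
  if (base::length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  pop <- population %||% data
  vars <- c(ilt_mm = "ilt", strain = "strain", tawss_pa = "tawss")
  out <- data
  for (i in seq_along(vars)) {
    col <- names(vars)[i]
    pat_cat <- stats::ave(data[[col]], data$patient,
                          FUN = quartile_categories)
    pop_cat <- quartile_categories(data[[col]], pool = pop[[col]])
    comb <- switch(combine,
                   combined = combined_quartile(pat_cat, pop_cat),
                   patient = pat_cat,
                   population = pop_cat)
    out[[paste0(vars[i], "_cat_patient")]] <- pat_cat
    out[[paste0(vars[i], "_cat_population")]] <- pop_cat
    out[[paste0(vars[i], "_cat")]] <- comb
  }
  out$raw <- raw_score(out$ilt_cat, out$strain_cat, out$tawss_cat)
  out$risk <- classify_raw(out$raw, threshold)
  structure(list(table = out, threshold = threshold, combine = combine,
                 call = match.call()),
            class = "raw_index")
}

#' @export
print.raw_index <- function(x, ...) {
  t <- x$table
  cat(sprintf("RAW index: %d patches, %d patients (categories: %s)\n",
              nrow(t), base::length(unique(t$patient)), x$combine))
  cat(sprintf("  score %.2f +/- %.2f (range %.2f-%.2f), %d/%d high (> %g)\n",
              mean(t$raw, na.rm = TRUE), stats::sd(t$raw, na.rm = TRUE),
              min(t$raw, na.rm = TRUE), max(t$raw, na.rm = TRUE),
              sum(t$risk == "high", na.rm = TRUE), sum(!is.na(t$risk)),
              x$threshold))
  invisible(x)
}

#' @export
summary.raw_index <- function(object, ...) {
  t <- object$table
  per_patient <- do.call(rbind, lapply(split(t, t$patient), function(d)
    data.frame(patient = d$patient[1L], n_patches = nrow(d),
               mean_raw = mean(d$raw, na.rm = TRUE),
               max_raw = max(d$raw, na.rm = TRUE),
               n_high = sum(d$risk == "high", na.rm = TRUE))))
  rownames(per_patient) <- NULL
  structure(list(per_patient = per_patient, threshold = object$threshold,
                 overall = c(mean = mean(t$raw, na.rm = TRUE),
                             sd = stats::sd(t$raw, na.rm = TRUE))),
            class = "summary.raw_index")
}

#' @export
print.summary.raw_index <- function(x, ...) {
  cat(sprintf("RAW %.2f +/- %.2f overall; per patient:\n",
              x$overall["mean"], x$overall["sd"]))
  print(x$per_patient, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.raw_index <- function(x, ...) x$table

#' @export
plot.raw_index <- function(x, patient = NULL, ...) {
  t <- x$table
  if (!is.null(patient)) t <- t[t$patient == patient, ]
  o <- order(t$raw)
  cols <- grDevices::hcl.colors(101, "YlOrRd", rev = TRUE)
  graphics::barplot(t$raw[o], names.arg = t$patch[o], las = 2,
                    col = cols[pmin(100, floor(t$raw[o] * 10)) + 1L],
                    ylab = "RAW index", ylim = c(0, 10), ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}
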