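#' Normality-gated two-group comparison
#'
#' The testing rule used throughout the analysis: Shapiro-Wilk on each
#' group; if both pass at `alpha_normality` the unpaired two-sided t-test is
#' used, otherwise a log transform is attempted (when all values are
#' positive) and retested, and if normality still fails in either group the
#' Mann-Whitney U (Wilcoxon rank-sum) test is used.
#'
#' @param a,b numeric samples (each `n >= 3`).
#' @param alpha_normality Shapiro-Wilk significance level (default 0.05).
#' @param try_log attempt a log transform before falling back to the
#'   non-parametric test (default `TRUE`).
#' @return List of class `group_comparison`: group `means`, `sds`, `n`,
#'   `test_used` (`"t_test"` or `"mann_whitney"`), two-tailed `p_value`,
#'   per-group Shapiro-Wilk `normality_p`, and `transform` applied
#'   (`"none"` or `"log"`).
#' @export
compare_groups <- function(a, b, alpha_normality = 0.05, try_log = TRUE) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (base::length(a) < 3L || base::length(b) < 3L)
    stop("each group needs at least 3 finite values")
  sw <- function(x) if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
  pa <- sw(a); pb <- sw(b)
  transform <- "none"
  ta <- a; tb <- b
  if ((pa < alpha_normality || pb < alpha_normality) && try_log &&
      all(a > 0) && all(b > 0)) {
    la <- log(a); lb <- log(b)
    if (sw(la) >= alpha_normality && sw(lb) >= alpha_normality) {
      transform <- "log"
      ta <- la; tb <- lb
      pa <- sw(la); pb <- sw(lb)
    }
  }
  normal <- pa >= alpha_normality && pb >= alpha_normality
  if (normal) {
    test_used <- "t_test"
    p <- stats::t.test(ta, tb, var.equal = FALSE)$p.value
  } else {
    test_used <- "mann_whitney"
    p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))$p.value
  }
  structure(list(means = c(a = mean(a), b = mean(b)),
                 sds = c(a = stats::sd(a), b = stats::sd(b)),
                 n = c(a = base::length(a), b = base::length(b)),
                 test_used = test_used, p_value = p,
                 normality_p = c(a = pa, b = pb), transform = transform),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d): %s p = %.4g%s\n",
              x$means["a"], x$sds["a"], x$n["a"], x$means["b"], x$sds["b"],
              x$n["b"], x$test_used, x$p_value,
              if (x$transform != "none") paste0(" (", x$transform,
                                                "-transformed)") else ""))
  invisible(x)
}

#' Normality-gated multi-group comparison
#'
#' One-way ANOVA when every group passes Shapiro-Wilk (after an optional
#' log-transform attempt), Kruskal-Wallis otherwise — e.g. for testing the
#' influence of patch position or patient on a descriptor.
#'
#' @param values numeric vector of observations.
#' @param groups grouping factor.
#' @inheritParams compare_groups
#' @return List with `test_used` (`"anova"` or `"kruskal_wallis"`) and
#'   `p_value`.
#' @export
compare_multi <- function(values, groups, alpha_normality = 0.05,
                          try_log = TRUE) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  sw_ok <- function(v) all(vapply(split(v, groups), function(x)
    base::length(x) >= 3L &&
      (stats::sd(x) > 0 && stats::shapiro.test(x)$p.value >= alpha_normality),
    TRUE))
  v <- values
  normal <- sw_ok(v)
  if (!normal && try_log && all(values > 0) && sw_ok(log(values))) {
    v <- log(values)
    normal <- TRUE
  }
  if (normal) {
    p <- summary(stats::aov(v ~ groups))[[1L]][["Pr(>F)"]][1L]
    list(test_used = "anova", p_value = p)
  } else {
    list(test_used = "kruskal_wallis",
         p_value = stats::kruskal.test(values, groups)$p.value)
  }
}

#' Normality-gated correlation
#'
#' Pearson's correlation when both marginals pass Shapiro-Wilk at 0.05
#' (linear relationship), Spearman's rank correlation otherwise (monotone
#' relationship); the automatic choice can be overridden.
#'
#' @param x,y numeric vectors of equal length (>= 4 complete pairs).
#' @param force `"pearson"` or `"spearman"` to override the normality gate.
#' @param alpha_normality Shapiro-Wilk significance level.
#' @return List of class `correlation_result`: `method`, `coefficient`,
#'   `p_value`, `n`.
#' @export
correlate <- function(x, y, force = NULL, alpha_normality = 0.05) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (base::length(x) < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input")
  method <- force %||%
    (if (stats::shapiro.test(x)$p.value >= alpha_normality &&
         stats::shapiro.test(y)$p.value >= alpha_normality)
      "pearson" else "spearman")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  structure(list(method = method, coefficient = unname(ct$estimate),
                 p_value = ct$p.value, n = base::length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  sym <- if (x$method == "pearson") "r" else "rho"
  cat(sprintf("%s %s = %.3f, p = %.4g (n = %d)\n",
              x$method, sym, x$coefficient, x$p_value, x$n))
  invisible(x)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC via the Mann-Whitney pairwise-comparison identity (ties between a
#' positive and a negative score count one half), computed from midranks;
#' the 95% confidence interval is a seeded percentile bootstrap, resampling
#' within each class so both classes are always present.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical, 0/1, or two-level factor; the second level /
#'   `TRUE` / `1` is the positive class.
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level (default 0.95).
#' @return List of class `roc_result`: `auc`, `ci` (percentile interval),
#'   `n_pos`, `n_neg`, `n_boot`.
#' @examples
#' roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1), n_boot = 200, seed = 1)$auc  # 0.75
#' @export
roc_auc <- function(scores, labels, n_boot = 2000L, seed = 1L, conf = 0.95) {
  lab <- as_binary_labels(labels)
  ok <- is.finite(scores) & !is.na(lab)
  scores <- scores[ok]
  lab <- lab[ok]
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  auc <- auc_mann_whitney(scores, lab)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    pos <- scores[lab]
    neg <- scores[!lab]
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      auc_mann_whitney(
        c(sample(pos, n_pos, replace = TRUE),
          sample(neg, n_neg, replace = TRUE)),
        c(rep(TRUE, n_pos), rep(FALSE, n_neg)))
    }, 0))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), type = 7))
  }
  structure(list(auc = auc, ci = ci, conf = conf, n_pos = n_pos,
                 n_neg = n_neg, n_boot = n_boot),
            class = "roc_result")
}

# Mann-Whitney identity from midranks: ties count 1/2.
auc_mann_whitney <- function(scores, positive) {
  r <- rank(scores)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels")
    return(labels == levels(labels)[2L])
  }
  u <- sort(unique(labels[!is.na(labels)]))
  if (all(u %in% c(0, 1))) return(labels == 1)
  if (base::length(u) != 2L) stop("labels must take exactly 2 values")
  labels == u[2L]
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f; %d pos, %d neg, %d bootstraps)\n",
              x$auc, round(100 * x$conf), x$ci[1L], x$ci[2L],
              x$n_pos, x$n_neg, x$n_boot))
  invisible(x)
}
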