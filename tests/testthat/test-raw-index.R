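test_that("quartile categorization follows the linear-interpolation convention", {
  expect_identical(quartile_categories(c(1, 2, 3, 4)), c(1L, 2L, 3L, 4L))
  expect_identical(quartile_categories(rep(7, 10)), rep(1L, 10))
  expect_warning(out <- quartile_categories(c(1, 2, 3)), "fewer than 4")
  expect_identical(out, rep(1L, 3))
  expect_error(quartile_categories(rep(NA_real_, 5)), "missing")
  # NA passthrough and boundary-inclusive-on-the-lower-category rule
  v <- c(1, 2, 3, 4, NA)
  expect_identical(quartile_categories(v), c(1L, 2L, 3L, 4L, NA))
  q1 <- stats::quantile(c(1, 2, 3, 4), 0.25, type = 7, names = FALSE)
  expect_identical(quartile_categories(c(1, 2, 3, 4, q1))[5], 1L)
  # monotone: order of values is preserved in categories
  set.seed(21)
  for (i in 1:20) {
    v <- rnorm(sample(4:40, 1))
    cat <- quartile_categories(v)
    o <- order(v)
    expect_true(all(diff(cat[o]) >= 0))
    expect_true(all(cat %in% 1:4))
  }
})

test_that("combined quartile is the mean and stays on the half-integer grid", {
  expect_equal(combined_quartile(4, 1), 2.5)
  expect_equal(combined_quartile(3, 3), 3)
  grid <- expand.grid(p = 1:4, q = 1:4)
  comb <- combined_quartile(grid$p, grid$q)
  expect_true(all(comb %in% seq(1, 4, by = 0.5)))
  expect_error(combined_quartile(0, 2), "categories")
  expect_error(combined_quartile(2, 5), "categories")
})

test_that("the RAW formula reproduces its printed extremes and examples", {
  expect_equal(round_raw(raw_score(2.5, 4, 1)), 8.33)
  expect_equal(round_raw(raw_score(4, 2.5, 1.5)), 7.78)
  expect_equal(raw_score(1, 1, 4), 0)
  expect_equal(raw_score(4, 4, 1), 10)
  expect_error(raw_score(0.5, 2, 2), "categories")
})

test_that("RAW is monotone in its categories with the TAWSS inversion", {
  grid <- expand.grid(ilt = seq(1, 4, 0.5), strain = seq(1, 4, 0.5),
                      tawss = seq(1, 4, 0.5))
  r <- raw_score(grid$ilt, grid$strain, grid$tawss)
  expect_true(all(r >= 0 & r <= 10))
  eps <- 0.5
  up_ilt <- raw_score(pmin(grid$ilt + eps, 4), grid$strain, grid$tawss)
  expect_true(all(up_ilt >= r))
  expect_true(all(up_ilt[grid$ilt < 4] > r[grid$ilt < 4]))
  up_tawss <- raw_score(grid$ilt, grid$strain, pmin(grid$tawss + eps, 4))
  expect_true(all(up_tawss[grid$tawss < 4] < r[grid$tawss < 4]))
})

test_that("classification is strictly greater-than the threshold", {
  expect_identical(as.character(classify_raw(c(8.33, 6, 1.11, 6.01))),
                   c("high", "low", "low", "high"))
  expect_identical(as.character(classify_raw(7, threshold = 7.5)), "low")
})

test_that("raw_index fits a cohort table with patient, population and combined categories", {
  set.seed(31)
  d <- expand.grid(patient = paste0("P", 1:3), patch = paste0("LA", 1:8),
                   stringsAsFactors = FALSE)
  d$ilt_mm <- runif(nrow(d), 0, 10)
  d$strain <- runif(nrow(d), 0.01, 0.06)
  d$tawss_pa <- runif(nrow(d), 0.1, 1.5)
  fit <- raw_index(d)
  t <- fit$table
  expect_s3_class(fit, "raw_index")
  expect_true(all(t$raw >= 0 & t$raw <= 10))
  expect_true(all(t$ilt_cat %in% seq(1, 4, 0.5)))
  # patient categories computed within each patient: each patient with 8
  # patches must use all four quartile bins for a continuous descriptor
  for (p in unique(t$patient))
    expect_setequal(unique(t$ilt_cat_patient[t$patient == p]), 1:4)
  # population categories from the pooled distribution
  qs <- stats::quantile(d$ilt_mm, c(.25, .5, .75), type = 7)
  expect_identical(t$ilt_cat_population,
                   1L + (d$ilt_mm > qs[1]) + (d$ilt_mm > qs[2]) +
                     (d$ilt_mm > qs[3]))
  expect_equal(t$ilt_cat,
               (t$ilt_cat_patient + t$ilt_cat_population) / 2)
  expect_identical(as.character(t$risk),
                   ifelse(t$raw > 6, "high", "low"))
  # explicit population pool changes only the population half
  fit2 <- raw_index(d, population = d[d$patient == "P1", ])
  expect_identical(fit2$table$ilt_cat_patient, t$ilt_cat_patient)
  expect_error(raw_index(d[, -3]), "missing columns")

  # methods run
  expect_output(print(fit), "RAW index")
  s <- summary(fit)
  expect_identical(nrow(s$per_patient), 3L)
  expect_output(print(s), "per patient")
  expect_identical(as.data.frame(fit), t)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, patient = "P1"))
})
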