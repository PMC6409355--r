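test_that("pearson_correlation matches direct evaluation and rejects constants", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("pearson_correlation is symmetric, bounded, affine-invariant", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x <- rnorm(20)
      y <- rnorm(20)
      a <- runif(1, 0.1, 5)
      b <- rnorm(1)
    })
    r <- pearson_correlation(x, y)
    expect_equal(r, pearson_correlation(y, x))
    expect_gte(r, -1)
    expect_lte(r, 1)
    expect_equal(r, pearson_correlation(a * x + b, y), tolerance = 1e-12)
  }
})

test_that("variance decomposition matches direct arithmetic and its edge cases", {
  d <- variance_decomposition(c(1, 2, 3, 4), c(1.5, 1.5, 3.5, 3.5), k = 1)
  expect_equal(d$tss, 5)
  expect_equal(d$rss, 1)
  expect_equal(d$ess, 4)

  y <- c(1, 3, 2, 5)
  perfect <- variance_decomposition(y, y, k = 3)
  expect_equal(perfect$rss, 0)
  expect_equal(perfect$ess, perfect$tss)

  null_fit <- variance_decomposition(y, rep(mean(y), 4), k = 3)
  expect_equal(null_fit$ess, 0)
  expect_equal(null_fit$rss, null_fit$tss)
})

test_that("R-squared and its adjustment follow the stated formulas", {
  d <- list(tss = 1, rss = 0.1, ess = 0.9, n = 8L, k = 3L)
  expect_equal(r_squared(d), 0.9)
  expect_equal(adjusted_r_squared(d), 1 - 0.1 * 7 / 4) # 0.825

  perfect <- list(tss = 1, rss = 0, ess = 1, n = 8L, k = 3L)
  expect_equal(adjusted_r_squared(perfect), 1)

  null_fit <- list(tss = 1, rss = 1, ess = 0, n = 8L, k = 3L)
  expect_equal(r_squared(null_fit), 0)
  expect_equal(adjusted_r_squared(null_fit), -0.75) # can go negative
})

test_that("the F test uses the RSS denominator with its degenerate conventions", {
  d <- list(tss = 1, ess = 0.9, rss = 0.1, n = 8L, k = 3L)
  ft <- f_test(d)
  expect_equal(ft$f_stat, (0.9 / 3) / (0.1 / 4)) # 12
  expect_equal(ft$f_pvalue, stats::pf(12, 3, 4, lower.tail = FALSE))

  null_fit <- list(tss = 1, ess = 0, rss = 1, n = 8L, k = 3L)
  expect_equal(f_test(null_fit)$f_stat, 0)
  expect_equal(f_test(null_fit)$f_pvalue, 1)

  perfect <- list(tss = 1, ess = 1, rss = 0, n = 8L, k = 3L)
  expect_equal(f_test(perfect)$f_stat, Inf)
  expect_equal(f_test(perfect)$f_pvalue, 0)

  # literal printed variant divides by TSS instead
  expect_equal(f_test(d, literal = TRUE)$f_stat, (0.9 / 3) / (1 / 4))
  expect_true(is.na(f_test(d, literal = TRUE)$f_pvalue))

  degenerate <- list(tss = 1, ess = 0.5, rss = 0.5, n = 4L, k = 3L)
  expect_error(f_test(degenerate), "degenerate")
})

test_that("F and t p-values match the incomplete-beta reference to 1e-8", {
  for (seed in 1:20) {
    fit <- fit_expression_model(random_instance(seed)$records, model = 4)
    expect_equal(
      fit$f_pvalue,
      f_pvalue_ref(fit$f_stat, fit$k, fit$n - fit$k - 1),
      tolerance = 1e-8
    )
    expect_equal(
      fit$t_pvalues,
      t_pvalue_ref(fit$t_stats, fit$n - fit$k - 1),
      tolerance = 1e-8
    )
    # t statistics carry the sign of their coefficients
    expect_equal(sign(fit$t_stats), sign(unname(fit$beta)))
  }
})

test_that("TSS = ESS + RSS holds for every intercept fit", {
  for (seed in 1:20) {
    dm <- random_instance(seed)
    fit <- fit_lsm(dm$X, dm$y)
    d <- variance_decomposition(dm$y, fit$fitted, k = fit$k)
    expect_equal(d$tss, d$ess + d$rss, tolerance = 1e-9)
  }
})

test_that("the F test is calibrated under the null", {
  n_sim <- 400
  pvals <- vapply(seq_len(n_sim), function(seed) {
    dm <- random_instance(seed)
    fit <- fit_lsm(dm$X, dm$y) # y is pure noise in these instances
    f_test(variance_decomposition(dm$y, fit$fitted, k = fit$k))$f_pvalue
  }, numeric(1))
  expect_gt(mean(pvals < 0.1), 0.06)
  expect_lt(mean(pvals < 0.1), 0.14)
})

test_that("tidy and glance report the fit the way the fit object holds it", {
  records <- small_records(n_genes = 5, seed = 31)
  fit <- fit_expression_model(records, model = 2)
  td <- tidy(fit)
  expect_equal(td$term, c("(Intercept)", fit$spec$terms))
  expect_equal(td$estimate[-1], unname(fit$beta))
  gl <- glance(fit)
  expect_equal(gl$adj_r_squared, fit$adj_r_squared)
  expect_lte(gl$adj_r_squared, gl$r_squared)
  expect_equal(gl$tss, gl$ess + gl$rss, tolerance = 1e-9 * gl$tss)
})

test_that("per-gene correlation and fit tables have one row per gene", {
  records <- small_records(n_genes = 4, seed = 13)
  ct <- correlation_table(records)
  expect_equal(nrow(ct), 4)
  expect_true(all(abs(unlist(ct[-1])) <= 1, na.rm = TRUE))

  pg <- fit_per_gene(records, model = 4)
  expect_equal(nrow(pg), 4)
  expect_true(all(c("beta1", "beta2", "beta3", "adj_r_squared", "f_pvalue", "p1", "p2", "p3")
  %in% names(pg)))
  expect_true(all(pg$adj_r_squared > 0.99)) # near-noiseless generative data
})
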