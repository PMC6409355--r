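test_that("min-max normalization maps to [0,1] and inverts exactly", {
  records <- tibble::tibble(
    gene_id = "g", day = 0:2,
    height = c(0, 5, 10), distance = c(1, 2, 3), width = c(10, 20, 30),
    expression = c(-1, 0, 1)
  )
  norm <- min_max_normalize(records)
  expect_equal(norm$height, c(0, 0.5, 1))
  expect_equal(range(norm$expression), c(0, 1))

  # idempotent on the canonical range
  again <- min_max_normalize(norm)
  expect_equal(again$height, norm$height)

  scaling <- attr(norm, "scaling")
  expect_equal(
    inverse_min_max(norm$height, scaling, "height"), records$height,
    tolerance = 1e-12
  )
  const <- dplyr::mutate(records, width = 7)
  expect_error(min_max_normalize(const), "width")
})

test_that("the 30% grouping rule gives m = floor(fraction n) and its threshold", {
  s <- split_high_low(1:10, 0.3)
  expect_equal(s$m, 3)
  expect_equal(s$threshold, 8)
  expect_equal(which(s$labels), c(8, 9, 10))
  expect_equal(sum(s$group == "high"), 3)
  expect_equal(sum(s$group == "low"), 3)

  expect_equal(split_high_low(rnorm(27), 0.3)$m, 8) # floor(8.1)

  withr::with_seed(1, v <- rnorm(50))
  s2 <- split_high_low(v, 0.3)
  expect_equal(sum(v >= s2$threshold), s2$m) # all-distinct values

  expect_error(split_high_low(1:3), "4 samples")
  expect_error(split_high_low(1:10, 0.6), "fraction")
})

test_that("classify_predictions tallies confusion counts by the >= rule", {
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  perfect <- classify_predictions(c(9, 8, 1, 2), threshold = 8, truth)
  expect_equal(c(perfect$fp, perfect$fn), c(0L, 0L))

  none <- classify_predictions(c(1, 2, 3, 4), threshold = 8, truth)
  expect_equal(c(none$tp, none$fp), c(0L, 0L))

  # hand-tallied 8-sample case with one FP and one FN
  pred <- c(9, 7, 8, 10, 2, 9, 3, 1)
  lab <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  cc <- classify_predictions(pred, 8, lab)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]), c(tp = 3L, tn = 3L, fp = 1L, fn = 1L))
})

test_that("metrics follow the confusion identities including Mcc", {
  m <- compute_metrics(confusion_counts(8, 8, 0, 0))
  expect_equal(unlist(m[c("acc", "sn", "sp", "mcc")]), c(acc = 1, sn = 1, sp = 1, mcc = 1))

  worst <- compute_metrics(confusion_counts(0, 0, 8, 8))
  expect_equal(worst$acc, 0)
  expect_equal(worst$mcc, -1)

  mixed <- compute_metrics(confusion_counts(3, 4, 2, 1))
  expect_equal(mixed$acc, 0.7)
  expect_equal(mixed$mcc, 10 / sqrt(600))

  degenerate <- compute_metrics(confusion_counts(0, 5, 0, 5))
  expect_equal(degenerate$mcc, 0)
  expect_true(degenerate$mcc_degenerate)
})

test_that("metric identities hold on randomized counts and under label swap", {
  for (seed in 1:50) {
    cc <- withr::with_seed(seed, as.list(sample(0:20, 4, replace = TRUE)))
    if (sum(unlist(cc)) == 0) next
    counts <- confusion_counts(cc[[1]], cc[[2]], cc[[3]], cc[[4]])
    m <- compute_metrics(counts)
    expect_equal(m$acc, (counts$tp + counts$tn) / sum(unlist(counts[1:4])))
    expect_gte(m$acc, 0)
    expect_lte(m$acc, 1)
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
    # swapping the positive/negative convention swaps Sn and Sp, keeps acc and |mcc|
    swapped <- compute_metrics(confusion_counts(cc[[2]], cc[[1]], cc[[4]], cc[[3]]))
    expect_equal(swapped$acc, m$acc)
    expect_equal(swapped$sn, m$sp)
    expect_equal(swapped$sp, m$sn)
    expect_equal(abs(swapped$mcc), abs(m$mcc))
  }
})

test_that("cross-validation is seeded-deterministic with balanced covering folds", {
  cs <- generate_classification_set(generative_config(n_genes = 20, seed = 14), separation = 10)
  cv1 <- kfold_cv(cs$records, k = 10, seed = 3)
  cv2 <- kfold_cv(cs$records, k = 10, seed = 3)
  expect_identical(glance(cv1), glance(cv2))
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(tidy(cv1), tidy(cv2))

  sizes <- table(cv1$folds)
  expect_lte(diff(range(sizes)), 1)
  expect_equal(sum(sizes), nrow(cs$records))
  expect_equal(nrow(tidy(cv1)), 10)

  cv_other <- kfold_cv(cs$records, k = 10, seed = 4)
  expect_false(identical(cv1$folds, cv_other$folds))
})

test_that("leave-one-out predicts every sample exactly once", {
  records <- small_records(n_genes = 3, seed = 8)
  n <- nrow(records)
  cv <- kfold_cv(records, k = n, seed = 2)
  counts <- glance(cv)
  expect_equal(counts$tp + counts$tn + counts$fp + counts$fn, n)
})

test_that("perfectly separated data classify perfectly; the null stays at chance", {
  cs <- generate_classification_set(generative_config(seed = 2), separation = 10)
  cv <- kfold_cv(cs$records, k = 10, seed = 2, evaluate = "extremes")
  expect_equal(glance(cv)$acc, 1)
  expect_equal(glance(cv)$mcc, 1)

  # threshold recomputed per training fold is available as the anti-leakage mode
  cv_tr <- kfold_cv(cs$records, k = 10, seed = 2, threshold_rule = "training")
  expect_gte(glance(cv_tr)$acc, 0.95)

  cs0 <- generate_classification_set(generative_config(seed = 3), separation = 0)
  cv0 <- kfold_cv(cs0$records, k = 10, seed = 3, evaluate = "extremes")
  expect_gte(glance(cv0)$acc, 0.35)
  expect_lte(glance(cv0)$acc, 0.65)
})

test_that("k larger than the sample count is rejected", {
  records <- small_records(n_genes = 1, seed = 4)
  expect_error(kfold_cv(records, k = 20, seed = 1), "k samples")
})
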