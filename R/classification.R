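# High/low expression grouping, threshold classification of model
# predictions, confusion-matrix metrics (Acc, Sn, Sp, Mcc) and seeded k-fold
# cross-validation.

# Internal: run code under a temporary RNG seed, restoring global state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Internal: deterministic fold assignment; sizes differ by at most one.
make_folds <- function(n, k, seed) {
  if (n < k) abort("need at least k samples for k-fold cross-validation")
  with_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
}

#' Min-max normalization of record variables
#'
#' Maps each of height, distance, width and expression to `[0, 1]` by
#' `(x - min) / (max - min)`. The scaling parameters are attached as the
#' `"scaling"` attribute so the transform can be inverted with
#' [inverse_min_max()].
#'
#' @param records A records tibble.
#' @param cols Variables to normalize.
#' @return The normalized tibble, with attribute `"scaling"` (a tibble with
#'   columns `variable`, `min`, `max`).
#' @export
min_max_normalize <- function(records,
                              cols = c("height", "distance", "width", "expression")) {
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0) abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  scaling <- purrr::map_dfr(cols, function(v) {
    rng <- range(records[[v]])
    if (rng[1] == rng[2]) abort(paste0("cannot normalize constant variable: ", v))
    tibble(variable = v, min = rng[1], max = rng[2])
  })
  out <- records
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    out[[v]] <- (out[[v]] - scaling$min[i]) / (scaling$max[i] - scaling$min[i])
  }
  attr(out, "scaling") <- scaling
  out
}

#' Invert a min-max normalization
#'
#' @param x Normalized values.
#' @param scaling The `"scaling"` attribute from [min_max_normalize()].
#' @param variable Which variable's parameters to use.
#' @return Values on the original scale.
#' @export
inverse_min_max <- function(x, scaling, variable) {
  row <- scaling[scaling$variable == variable, ]
  if (nrow(row) != 1) abort(paste0("no scaling parameters for: ", variable))
  x * (row$max - row$min) + row$min
}

#' Split samples into high and low expression groups
#'
#' Values are sorted in descending order; the top `floor(fraction * n)` form
#' the high (positive) group and the bottom `floor(fraction * n)` the low
#' (negative) group. The classification threshold is the smallest value of the
#' high group (the m-th largest value), and every sample receives a binary
#' label by `value >= threshold`.
#'
#' @param values Numeric expression values (>= 4).
#' @param fraction Group fraction in `(0, 0.5)`; default 0.3.
#' @return A list with `threshold`, `m`, `labels` (logical, by the threshold
#'   rule), and `group` (factor `high`/`mid`/`low` by sorted rank).
#' @export
#' @examples
#' split_high_low(1:10)
split_high_low <- function(values, fraction = 0.3) {
  n <- length(values)
  if (n < 4) abort("need at least 4 samples")
  if (fraction <= 0 || fraction >= 0.5) abort("fraction must be in (0, 0.5)")
  m <- floor(fraction * n)
  ord <- order(values, decreasing = TRUE)
  threshold <- values[ord[m]]
  group <- rep("mid", n)
  group[ord[seq_len(m)]] <- "high"
  group[ord[seq.int(n - m + 1, n)]] <- "low"
  labels <- values >= threshold
  if (sum(labels) != m) {
    inform(paste0(
      "ties at the classification threshold: ", sum(labels),
      " samples labelled positive by the >= rule (group size m = ", m, ")"
    ))
  }
  list(
    threshold = threshold, m = m, labels = labels,
    group = factor(group, levels = c("high", "mid", "low"))
  )
}

#' Confusion counts from thresholded predictions
#'
#' Predicted values at or above the threshold are called positive and tallied
#' against the true binary labels.
#'
#' @param predicted Numeric predictions.
#' @param threshold Classification threshold.
#' @param true_labels Logical vector of true labels.
#' @return An object of class `pc_confusion`: a one-row tibble with columns
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
classify_predictions <- function(predicted, threshold, true_labels) {
  if (length(predicted) != length(true_labels)) {
    abort("predicted and true_labels must have equal length")
  }
  call_pos <- predicted >= threshold
  confusion_counts(
    tp = sum(call_pos & true_labels),
    tn = sum(!call_pos & !true_labels),
    fp = sum(call_pos & !true_labels),
    fn = sum(!call_pos & true_labels)
  )
}

#' Build a confusion-count object
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return An object of class `pc_confusion`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) abort("confusion counts must be non-negative")
  structure(
    tibble(tp = as.integer(tp), tn = as.integer(tn), fp = as.integer(fp), fn = as.integer(fn)),
    class = c("pc_confusion", class(tibble())))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `Sn = TP/(TP+FN)`, specificity `Sp = TN/(TN+FP)`, accuracy
#' `Acc = (TP+TN)/total`, and the Matthews correlation coefficient
#' `Mcc = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`. When any
#' Mcc marginal is zero the coefficient is undefined and is reported as 0
#' with `mcc_degenerate = TRUE`.
#'
#' @param counts A `pc_confusion` object (or any list with `tp`, `tn`, `fp`,
#'   `fn`).
#' @return A one-row tibble with `acc`, `sn`, `sp`, `mcc`, `mcc_degenerate`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$tp)
  tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn)
  total <- tp + tn + fp + fn
  if (total <= 0) abort("confusion counts are all zero")
  marg <- c(tp + fn, tp + fp, tn + fn, tn + fp)
  degenerate <- any(marg == 0)
  tibble(
    acc = (tp + tn) / total,
    sn = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    mcc = if (degenerate) 0 else (tp * tn - fp * fn) / sqrt(prod(marg)),
    mcc_degenerate = degenerate
  )
}

# Internal: shared CV protocol. predictor(train_records, test_records,
# train_labels) must return numeric scores for the held-out rows, on the scale
# compared against `threshold_value` (for the regression classifier) or in
# [0, 1] against 0.5 (for the net; it then ignores threshold_value and
# receives score_threshold = 0.5).
run_cv <- function(records, k, seed, fraction, threshold_rule, evaluate,
                   predictor, score_uses_expression_threshold = TRUE) {
  check_records(records)
  n <- nrow(records)
  folds <- make_folds(n, k, seed)
  global <- split_high_low(records$expression, fraction)
  labels <- global$labels

  fold_rows <- list()
  confusion <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
  for (f in sort(unique(folds))) {
    test_idx <- which(folds == f)
    train_idx <- which(folds != f)
    train <- records[train_idx, , drop = FALSE]
    test <- records[test_idx, , drop = FALSE]
    scores <- tryCatch(
      predictor(train, test, labels[train_idx], fold = f),
      error = function(e) {
        warn(paste0("fold ", f, " skipped: ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(scores)) next
    threshold <- if (!score_uses_expression_threshold) {
      0.5
    } else if (threshold_rule == "global") {
      global$threshold
    } else {
      split_high_low(train$expression, fraction)$threshold
    }
    keep <- if (evaluate == "extremes") {
      global$group[test_idx] %in% c("high", "low")
    } else {
      rep(TRUE, length(test_idx))
    }
    cc <- classify_predictions(scores$score[keep], threshold, labels[test_idx][keep])
    confusion <- confusion + c(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn)
    fold_rows[[length(fold_rows) + 1]] <- scores$coef_row
  }
  if (all(confusion == 0)) abort("no fold could be evaluated")
  counts <- confusion_counts(confusion[["tp"]], confusion[["tn"]], confusion[["fp"]], confusion[["fn"]])
  list(
    folds = folds,
    labels = labels,
    threshold = global$threshold,
    group = global$group,
    coefficients = dplyr::bind_rows(fold_rows),
    confusion = counts,
    metrics = compute_metrics(counts)
  )
}

#' Seeded k-fold cross-validation of the threshold classifier
#'
#' Samples (one per gene x day record) are labelled high/low by the 30%
#' quantile rule on observed expression. For each of `k` seeded near-equal
#' folds, the requested model is fitted to the training records pooled across
#' genes, held-out expression is predicted, and predictions are classified
#' against the expression threshold: by default the single threshold the
#' grouping rule defines on the full data (`threshold_rule = "global"`);
#' `"training"` recomputes it from the training fold only. Confusion counts
#' are pooled over folds before metrics are computed.
#'
#' @param records A records tibble (normalize first with
#'   [min_max_normalize()] to follow the application protocol).
#' @param k Number of folds (default 10).
#' @param seed Integer seed controlling the fold shuffle.
#' @param model Model id for [model_spec()] (default 4).
#' @param fraction High/low group fraction (default 0.3).
#' @param threshold_rule `"global"` (default) or `"training"`.
#' @param evaluate `"all"` classifies every held-out sample; `"extremes"`
#'   restricts evaluation to the balanced high/low groups.
#' @return An object of class `pc_cv` with fold assignments, per-fold
#'   coefficients (`beta1..beta3` and the fitted disturbance `epsilon`),
#'   pooled confusion counts and metrics. [tidy()] returns the per-fold
#'   coefficient table, [glance()] the metrics.
#' @export
kfold_cv <- function(records, k = 10, seed = 1, model = 4, fraction = 0.3,
                     threshold_rule = c("global", "training"),
                     evaluate = c("all", "extremes")) {
  threshold_rule <- match.arg(threshold_rule)
  evaluate <- match.arg(evaluate)
  predictor <- function(train, test, train_labels, fold) {
    fit <- fit_expression_model(train, model = model)
    list(
      score = predict(fit, test),
      coef_row = tibble(
        fold = fold,
        beta1 = fit$beta[[1]], beta2 = fit$beta[[2]], beta3 = fit$beta[[3]],
        epsilon = fit$intercept
      )
    )
  }
  res <- run_cv(records, k, seed, fraction, threshold_rule, evaluate, predictor)
  structure(
    c(res, list(
      k = k, seed = seed, model = as.character(model),
      threshold_rule = threshold_rule, evaluate = evaluate, method = "model"
    )),
    class = "pc_cv"
  )
}

#' @export
print.pc_cv <- function(x, ...) {
  cat("<pc_cv> ", x$k, "-fold cross-validation (", x$method, "), seed ", x$seed, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' @rdname pc_cv_tidiers
#' @method tidy pc_cv
#' @title Tidy cross-validation results
#' @description `tidy()` returns the per-fold coefficient table (fold,
#'   `beta1..beta3`, fitted disturbance `epsilon`); `glance()` returns the
#'   pooled classification metrics with the confusion counts.
#' @param x A `pc_cv` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pc_cv <- function(x, ...) x$coefficients

#' @rdname pc_cv_tidiers
#' @method glance pc_cv
#' @export
glance.pc_cv <- function(x, ...) {
  dplyr::bind_cols(x$metrics, tibble::as_tibble(unclass(x$confusion)))
}

#' Cross-validated neural-network baseline
#'
#' Evaluates the small feedforward back-propagation network of
#' [bp_fit()] (one hidden layer, two sigmoid units) under the same seeded
#' k-fold protocol as [kfold_cv()]: inputs are the three Model-4 basis terms
#' min-max normalized, targets are the high/low labels, and held-out samples
#' are called positive when the network output reaches 0.5.
#'
#' @inheritParams kfold_cv
#' @param hidden Hidden units (default 2).
#' @param learning_rate Gradient-descent step size (default 0.1).
#' @param epochs Full-batch training epochs (default 2000).
#' @return A `pc_cv` object (`method = "bp"`).
#' @export
bp_baseline <- function(records, k = 10, seed = 1, fraction = 0.3,
                        evaluate = c("all", "extremes"),
                        hidden = 2, learning_rate = 0.1, epochs = 2000) {
  evaluate <- match.arg(evaluate)
  basis <- model_spec(4)$terms
  feats <- function(d) {
    X <- vapply(basis, eval_term, numeric(nrow(d)), records = d)
    matrix(X, nrow = nrow(d), dimnames = list(NULL, basis))
  }
  predictor <- function(train, test, train_labels, fold) {
    Xtr <- feats(train)
    Xte <- feats(test)
    # Min-max scale inputs to [0, 1] with training-fold parameters.
    lo <- apply(Xtr, 2, min)
    hi <- apply(Xtr, 2, max)
    span <- ifelse(hi > lo, hi - lo, 1)
    scale01 <- function(M) sweep(sweep(M, 2, lo), 2, span, "/")
    net <- bp_fit(scale01(Xtr), as.numeric(train_labels),
      hidden = hidden, learning_rate = learning_rate, epochs = epochs,
      seed = child_seed(seed, fold)
    )
    list(
      score = bp_predict(net, scale01(Xte)),
      coef_row = tibble(fold = fold, final_loss = net$final_loss)
    )
  }
  res <- run_cv(records, k, seed, fraction,
    threshold_rule = "global", evaluate = evaluate,
    predictor = predictor, score_uses_expression_threshold = FALSE
  )
  structure(
    c(res, list(
      k = k, seed = seed, model = "bp", threshold_rule = "global",
      evaluate = evaluate, method = "bp"
    )),
    class = "pc_cv"
  )
}

#' Compare the regression classifier with the neural-network baseline
#'
#' Runs [kfold_cv()] and [bp_baseline()] with identical folds, labels and
#' evaluation protocol and stacks their pooled metrics.
#'
#' @inheritParams kfold_cv
#' @param ... Further arguments to [bp_baseline()] (e.g. `epochs`).
#' @return A tibble with one row per method (`model4`, `bp`) and the pooled
#'   classification metrics.
#' @export
compare_classifiers <- function(records, k = 10, seed = 1, model = 4,
                                fraction = 0.3,
                                threshold_rule = c("global", "training"),
                                evaluate = c("all", "extremes"), ...) {
  threshold_rule <- match.arg(threshold_rule)
  evaluate <- match.arg(evaluate)
  cv_model <- kfold_cv(records,
    k = k, seed = seed, model = model, fraction = fraction,
    threshold_rule = threshold_rule, evaluate = evaluate
  )
  cv_bp <- bp_baseline(records,
    k = k, seed = seed, fraction = fraction, evaluate = evaluate, ...
  )
  dplyr::bind_rows(
    dplyr::bind_cols(tibble(method = paste0("model", model)), cv_model$metrics),
    dplyr::bind_cols(tibble(method = "bp"), cv_bp$metrics)
  )
}
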