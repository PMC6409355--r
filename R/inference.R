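# Regression inference: Pearson correlation, the TSS/ESS/RSS variance
# decomposition, goodness of fit, and the F and t significance tests.

#' Pearson correlation coefficient
#'
#' `r(X, Y) = cov(X, Y) / sqrt(var(X) var(Y))`. Sample versus population
#' normalization cancels, so the result matches either convention. A constant
#' vector makes the correlation undefined and is an error, never a silent 0.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return The correlation coefficient, a number in `[-1, 1]`.
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 2) abort("need at least two observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant vector")
  }
  stats::cov(x, y) / sqrt(stats::var(x) * stats::var(y))
}

#' Per-gene correlations of expression with peak features and time
#'
#' For each gene, the Pearson correlation of expression with height, distance,
#' width and day across the time course.
#'
#' @param records A records tibble.
#' @return A tibble with one row per gene and columns `height`, `distance`,
#'   `width`, `day` holding the correlations with expression.
#' @export
correlation_table <- function(records) {
  check_records(records)
  safe_cor <- function(x, y) {
    if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
    else pearson_correlation(x, y)
  }
  records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      tibble(
        height = safe_cor(d$height, d$expression),
        distance = safe_cor(d$distance, d$expression),
        width = safe_cor(d$width, d$expression),
        day = safe_cor(d$day, d$expression)
      )
    }) |>
    dplyr::ungroup()
}

#' Variance decomposition of a regression fit
#'
#' Centered sums of squares: `TSS = sum((Y - Ybar)^2)`,
#' `ESS = sum((Yhat - Ybar)^2)`, `RSS = sum((Y - Yhat)^2)`. With an intercept
#' in the fit, `TSS = ESS + RSS`.
#'
#' @param y Observed response.
#' @param fitted Fitted values of equal length.
#' @param k Number of explanatory variables (stored for downstream tests).
#' @return A list of class `pc_decomposition` with `tss`, `ess`, `rss`, `n`, `k`.
#' @export
variance_decomposition <- function(y, fitted, k) {
  if (length(y) != length(fitted)) abort("y and fitted must have equal length")
  ybar <- mean(y)
  structure(
    list(
      tss = sum((y - ybar)^2),
      ess = sum((fitted - ybar)^2),
      rss = sum((y - fitted)^2),
      n = length(y),
      k = as.integer(k)
    ),
    class = "pc_decomposition"
  )
}

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS / TSS`.
#'
#' @param decomp A [variance_decomposition()] object.
#' @return R-squared.
#' @export
r_squared <- function(decomp) {
  if (decomp$tss <= 0) abort("R-squared undefined: TSS is zero (constant response)")
  1 - decomp$rss / decomp$tss
}

#' Adjusted coefficient of determination
#'
#' `adj R^2 = 1 - (1 - R^2) (n - 1) / (n - k - 1)`, penalizing the number of
#' explanatory variables. Can be negative for fits worse than the mean.
#'
#' @param decomp A [variance_decomposition()] object.
#' @return Adjusted R-squared.
#' @export
adjusted_r_squared <- function(decomp) {
  if (decomp$n - decomp$k - 1 < 1) abort("adjusted R-squared undefined: n - k - 1 < 1")
  1 - (1 - r_squared(decomp)) * (decomp$n - 1) / (decomp$n - decomp$k - 1)
}

#' F test of the whole regression
#'
#' The test statistic is `F = (ESS / k) / (RSS / (n - k - 1))`, compared with
#' the upper tail of the `F(k, n - k - 1)` reference distribution. A perfect
#' fit (`RSS = 0`) reports `F = Inf`, `p = 0`. `literal = TRUE` instead
#' divides by `TSS / (n - k - 1)`; that variant is reported with an `NA`
#' p-value because it does not follow the F reference distribution under the
#' null.
#'
#' @param decomp A [variance_decomposition()] object.
#' @param literal Use the TSS denominator variant? Default `FALSE`.
#' @return A list with `f_stat` and `f_pvalue`.
#' @export
f_test <- function(decomp, literal = FALSE) {
  k <- decomp$k
  df2 <- decomp$n - k - 1
  if (k < 1 || df2 < 1) abort("F test unavailable: degenerate degrees of freedom")
  if (literal) {
    f <- (decomp$ess / k) / (decomp$tss / df2)
    return(list(f_stat = f, f_pvalue = NA_real_))
  }
  if (decomp$rss == 0) {
    return(list(f_stat = Inf, f_pvalue = 0))
  }
  f <- (decomp$ess / k) / (decomp$rss / df2)
  list(f_stat = f, f_pvalue = stats::pf(f, k, df2, lower.tail = FALSE))
}

#' Per-coefficient t tests
#'
#' `t_j = beta_j / se(beta_j)` against the two-sided `t(n - k - 1)` reference
#' distribution. Applies to the slope coefficients of a fit (the intercept is
#' reported by [tidy()] but the per-term p-values mirror the model's
#' coefficient tests).
#'
#' @param fit A fit list from [fit_lsm()] or a `pc_fit` object.
#' @return A tibble with columns `term`, `t_stat`, `p_value`.
#' @export
t_tests <- function(fit) {
  if (is.na(fit$residual_sd)) {
    return(tibble(
      term = names(fit$beta),
      t_stat = NA_real_, p_value = NA_real_
    ))
  }
  se <- fit$se[names(fit$beta)]
  t <- ifelse(se > 0, fit$beta / se,
    ifelse(fit$beta == 0, 0, Inf * sign(fit$beta))
  )
  p <- 2 * stats::pt(abs(t), fit$df_residual, lower.tail = FALSE)
  tibble(term = names(fit$beta), t_stat = unname(t), p_value = unname(p))
}

#' @rdname pc_fit_tidiers
#' @method tidy pc_fit
#' @title Tidy a fitted temporal-interaction model
#' @description `tidy()` returns one row per coefficient with estimate,
#'   standard error, t statistic and two-sided p-value; `glance()` returns a
#'   one-row model summary (R-squared, adjusted R-squared, F statistic and
#'   p-value, residual standard deviation, n, k).
#' @param x A `pc_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pc_fit <- function(x, ...) {
  rows <- tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std_error = unname(x$se[names(x$beta)]),
    statistic = x$t_stats,
    p_value = x$t_pvalues
  )
  if (x$has_intercept) {
    se0 <- unname(x$se[["(Intercept)"]])
    t0 <- if (!is.na(x$residual_sd) && se0 > 0) x$intercept / se0 else NA_real_
    rows <- dplyr::bind_rows(
      tibble(
        term = "(Intercept)", estimate = x$intercept, std_error = se0,
        statistic = t0,
        p_value = if (is.na(t0)) NA_real_ else 2 * stats::pt(abs(t0), x$df_residual, lower.tail = FALSE)
      ),
      rows
    )
  }
  rows
}

#' @rdname pc_fit_tidiers
#' @method glance pc_fit
#' @export
glance.pc_fit <- function(x, ...) {
  tibble(
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    f_stat = x$f_stat,
    f_pvalue = x$f_pvalue,
    residual_sd = x$residual_sd,
    tss = x$decomposition$tss,
    ess = x$decomposition$ess,
    rss = x$decomposition$rss,
    n = x$n,
    k = x$k
  )
}

#' Per-gene fits with an inference report
#'
#' Fits the requested model separately to each gene's time course and reports
#' the coefficient and inference tables (the per-gene analogues of pooled
#' [fit_expression_model()]).
#'
#' @param records A records tibble.
#' @param model Model id passed to [model_spec()].
#' @param ... Further arguments to [fit_expression_model()].
#' @return A tibble with one row per gene: coefficients, intercept, adjusted
#'   R-squared, F p-value and the per-coefficient p-values `p1`, `p2`, `p3`.
#' @export
fit_per_gene <- function(records, model = 4, ...) {
  check_records(records)
  records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_expression_model(dplyr::mutate(d, gene_id = key$gene_id), model = model, ...)
      pv <- setNames(fit$t_pvalues, paste0("p", seq_along(fit$t_pvalues)))
      dplyr::bind_cols(
        tibble(
          model = fit$spec$model_id,
          beta1 = fit$beta[[1]], beta2 = fit$beta[[2]], beta3 = fit$beta[[3]],
          intercept = fit$intercept,
          adj_r_squared = fit$adj_r_squared,
          f_stat = fit$f_stat, f_pvalue = fit$f_pvalue
        ),
        tibble::as_tibble(as.list(pv))
      )
    }) |>
    dplyr::ungroup()
}
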