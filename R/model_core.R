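# The temporal-interaction model family. Gene expression is regressed on
# products of the three peak characteristics with functions of developmental
# time t (days):
#
#   Exp = beta1 * H * exp(t) + beta2 * D * f(t) + beta3 * W * log10(t+1) + eps
#
# with f(t) one of {t, t^2, t^3, 0.5^t} for Models 1-4. The random
# disturbance eps is realized as a fitted intercept (its location) plus the
# residual standard deviation (its dispersion).

TIME_FUNCTIONS <- list(
  "t" = function(t) t,
  "t^2" = function(t) t^2,
  "t^3" = function(t) t^3,
  "exp(t)" = function(t) exp(t),
  "0.5^t" = function(t) 0.5^t,
  "log10(t+1)" = function(t) log10(t + 1)
)

FEATURE_LETTERS <- c(H = "height", D = "distance", W = "width")

#' The 18-term candidate set of derived temporal-interaction variables
#'
#' Every product of a peak characteristic (`H`, `D`, `W`) with a function of
#' time from `{t, t^2, t^3, exp(t), 0.5^t, log10(t+1)}`, named in ASCII form,
#' e.g. `"H*exp(t)"`, `"D*0.5^t"`, `"W*log10(t+1)"`.
#'
#' @return A character vector of 18 term names in deterministic order.
#' @export
candidate_terms <- function() {
  as.character(outer(names(FEATURE_LETTERS), names(TIME_FUNCTIONS),
    function(f, g) paste0(f, "*", g)
  ))
}

# Internal: evaluate one derived term on a records tibble.
eval_term <- function(records, term) {
  parts <- stringr::str_split_fixed(term, "\\*", 2)
  feature <- FEATURE_LETTERS[[parts[[1]]]]
  fn <- TIME_FUNCTIONS[[parts[[2]]]]
  if (is.null(feature) || is.null(fn)) abort(paste0("unknown term: ", term))
  records[[feature]] * fn(records$day)
}

#' Augment records with the full candidate set of derived variables
#'
#' @param records A records tibble (`gene_id`, `day`, `height`, `distance`,
#'   `width`, and optionally `expression`).
#' @return The input tibble with the 18 candidate columns of
#'   [candidate_terms()] appended.
#' @export
build_candidate_set <- function(records) {
  check_records(records, require_expression = FALSE)
  terms <- candidate_terms()
  vals <- lapply(terms, eval_term, records = records)
  names(vals) <- terms
  dplyr::bind_cols(records, tibble::as_tibble(vals))
}

#' Specify a temporal-interaction regression model
#'
#' Models 1-4 share the basis `H*exp(t)` and `W*log10(t+1)` and differ only in
#' the time function multiplying the distance term: `t`, `t^2`, `t^3` and
#' `0.5^t` respectively. `model = "general"` takes `f_t` explicitly. A custom
#' basis (e.g. from [stepwise_select()]) can be given through `terms`.
#'
#' @param model One of `1:4` or `"general"`; ignored when `terms` is given.
#' @param f_t Time function for the distance term when `model = "general"`,
#'   one of `"t"`, `"t^2"`, `"t^3"`, `"0.5^t"`.
#' @param terms Optional explicit character vector of term names from
#'   [candidate_terms()].
#' @param intercept Include an intercept (the location of the random
#'   disturbance)? Defaults to `TRUE`.
#' @return An object of class `pc_model_spec`.
#' @export
model_spec <- function(model = 4, f_t = NULL, terms = NULL, intercept = TRUE) {
  if (is.null(terms)) {
    f_by_model <- c(`1` = "t", `2` = "t^2", `3` = "t^3", `4` = "0.5^t")
    if (identical(model, "general")) {
      if (is.null(f_t) || !f_t %in% unname(f_by_model)) {
        abort("for model = \"general\", f_t must be one of t, t^2, t^3, 0.5^t")
      }
      f <- f_t
    } else {
      model <- as.character(model)
      if (!model %in% names(f_by_model)) abort("model must be 1, 2, 3, 4 or \"general\"")
      f <- f_by_model[[model]]
    }
    terms <- c("H*exp(t)", paste0("D*", f), "W*log10(t+1)")
  } else {
    unknown <- setdiff(terms, candidate_terms())
    if (length(unknown) > 0) {
      abort(paste0("unknown term(s): ", paste(unknown, collapse = ", ")))
    }
    model <- "custom"
  }
  structure(
    list(model_id = as.character(model), terms = terms, intercept = isTRUE(intercept)),
    class = "pc_model_spec"
  )
}

#' @export
print.pc_model_spec <- function(x, ...) {
  rhs <- paste0("b", seq_along(x$terms), "*", x$terms, collapse = " + ")
  cat("<pc_model_spec> Model ", x$model_id, ": Exp = ", rhs,
    if (x$intercept) " + eps" else " (no intercept)", "\n",
    sep = ""
  )
  invisible(x)
}

#' Design matrix and response for a model specification
#'
#' @param records A records tibble including `expression`.
#' @param spec A [model_spec()] object.
#' @return A list with `X` (n x k matrix, one column per basis term, named),
#'   `y` (response vector) and `spec`.
#' @export
design_matrix <- function(records, spec) {
  check_records(records)
  X <- vapply(spec$terms, eval_term, numeric(nrow(records)), records = records)
  X <- matrix(X, nrow = nrow(records), dimnames = list(NULL, spec$terms))
  if (!all(is.finite(X))) abort("non-finite entries in design matrix")
  list(X = X, y = records$expression, spec = spec)
}

#' Least-squares fit of a linear basis
#'
#' Minimizes the residual sum of squares by orthogonal (QR) decomposition of
#' an internally standardized design, then back-transforms the coefficients
#' and their covariance to the raw scale. Standardization keeps the fit
#' well-conditioned despite the enormous dynamic range of `exp(t)` across the
#' time course. Standard errors follow
#' `se(beta_j) = residual_sd * sqrt((X'X)^{-1}_{jj})` with
#' `residual_sd^2 = RSS / (n - k - 1)`.
#'
#' @param X Design matrix (n x k) with column names; no intercept column.
#' @param y Response vector.
#' @param intercept Augment with an intercept? Dropping it disables the
#'   TSS = ESS + RSS decomposition guarantees (a warning is emitted).
#' @return A list with `beta` (named raw-scale coefficients), `intercept`
#'   (estimate, `NA` when not fitted), `se` (named, intercept first when
#'   present), `residual_sd`, `fitted`, `residuals`, `rss`, `n`, `k`,
#'   `df_residual`, `cov` (raw-scale coefficient covariance).
#' @export
fit_lsm <- function(X, y, intercept = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- ncol(X)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (!all(is.finite(X)) || !all(is.finite(y))) abort("non-finite values in X or y")
  term_names <- colnames(X) %||% paste0("x", seq_len(k))
  if (!intercept) {
    warn("fitting without intercept: TSS = ESS + RSS decomposition no longer guaranteed")
  }

  if (intercept) {
    centre <- colMeans(X)
    spread <- apply(X, 2, stats::sd)
    degenerate <- spread == 0
    if (any(degenerate)) {
      abort(paste0(
        "design column constant (collinear with intercept): ",
        paste(term_names[degenerate], collapse = ", ")
      ))
    }
    Z <- sweep(sweep(X, 2, centre), 2, spread, "/")
    M <- cbind(`(Intercept)` = 1, Z)
  } else {
    centre <- rep(0, k)
    spread <- sqrt(colMeans(X^2))
    degenerate <- spread == 0
    if (any(degenerate)) {
      abort(paste0("design column all zero: ", paste(term_names[degenerate], collapse = ", ")))
    }
    Z <- sweep(X, 2, spread, "/")
    M <- Z
  }

  dec <- qr(M)
  if (dec$rank < ncol(M)) {
    dropped <- colnames(M)[dec$pivot[(dec$rank + 1):ncol(M)]]
    abort(paste0("design matrix is rank deficient; offending column(s): ",
      paste(dropped, collapse = ", ")))
  }
  beta_std <- qr.coef(dec, y)
  # One step of iterative refinement: re-solving on the residual recovers the
  # precision lost to cancellation when response magnitudes span many orders.
  beta_std <- beta_std + qr.coef(dec, y - as.numeric(M %*% beta_std))
  fitted <- as.numeric(M %*% beta_std)
  residuals <- y - fitted
  rss <- sum(residuals^2)

  # Back-transform coefficients and covariance to the raw scale.
  if (intercept) {
    slopes <- beta_std[-1] / spread
    b0 <- beta_std[[1]] - sum(beta_std[-1] * centre / spread)
    A <- rbind(
      c(1, -centre / spread),
      cbind(0, diag(1 / spread, nrow = k))
    )
  } else {
    slopes <- beta_std / spread
    b0 <- NA_real_
    A <- diag(1 / spread, nrow = k)
  }
  names(slopes) <- term_names

  df_residual <- n - k - as.integer(intercept)
  if (df_residual >= 1) {
    sigma2 <- rss / df_residual
    cov_std <- sigma2 * chol2inv(qr.R(dec))
    cov_raw <- A %*% cov_std %*% t(A)
    se <- sqrt(pmax(diag(cov_raw), 0))
    residual_sd <- sqrt(sigma2)
  } else {
    warn("n < k + 2: coefficients estimated but inference disabled")
    cov_raw <- matrix(NA_real_, ncol(M), ncol(M))
    se <- rep(NA_real_, ncol(M))
    residual_sd <- NA_real_
  }
  coef_names <- if (intercept) c("(Intercept)", term_names) else term_names
  names(se) <- coef_names
  dimnames(cov_raw) <- list(coef_names, coef_names)

  list(
    beta = slopes, intercept = b0, se = se, residual_sd = residual_sd,
    fitted = fitted, residuals = residuals, rss = rss,
    n = n, k = k, df_residual = df_residual, cov = cov_raw,
    has_intercept = intercept
  )
}

#' Fit a temporal-interaction expression model to records
#'
#' Assembles the design matrix for the requested model, fits it by least
#' squares and attaches the full inference report (variance decomposition,
#' R-squared and adjusted R-squared, F test of the whole regression, t tests
#' per coefficient).
#'
#' @param records A records tibble including `expression`.
#' @param model,f_t,terms,intercept Passed to [model_spec()]; alternatively
#'   supply a ready `spec`.
#' @param spec An optional [model_spec()] object overriding the other
#'   arguments.
#' @return An object of class `pc_fit`. Use [tidy()] for the per-coefficient
#'   table, [glance()] for model-level statistics, `predict()` for new
#'   predictions and `autoplot()` for an observed-versus-fitted display.
#' @export
#' @examples
#' sim <- generate_timecourse(generative_config(n_genes = 4, seed = 1))
#' fit <- fit_expression_model(sim$records, model = 4)
#' glance(fit)
fit_expression_model <- function(records, model = 4, f_t = NULL, terms = NULL,
                                 intercept = TRUE, spec = NULL) {
  if (is.null(spec)) spec <- model_spec(model, f_t = f_t, terms = terms, intercept = intercept)
  dm <- design_matrix(records, spec)
  fit <- fit_lsm(dm$X, dm$y, intercept = spec$intercept)
  decomp <- variance_decomposition(dm$y, fit$fitted, k = fit$k)
  out <- c(fit, list(
    spec = spec,
    y = dm$y,
    decomposition = decomp,
    r_squared = r_squared(decomp),
    adj_r_squared = adjusted_r_squared(decomp)
  ))
  ftest <- f_test(decomp)
  out$f_stat <- ftest$f_stat
  out$f_pvalue <- ftest$f_pvalue
  tt <- t_tests(out)
  out$t_stats <- tt$t_stat
  out$t_pvalues <- tt$p_value
  structure(out, class = "pc_fit")
}

#' @export
print.pc_fit <- function(x, ...) {
  cat("<pc_fit> Model ", x$spec$model_id, ", n = ", x$n, "\n", sep = "")
  coefs <- c(if (x$has_intercept) stats::setNames(x$intercept, "(Intercept)"), x$beta)
  print(signif(coefs, 5))
  cat(
    "adj R-squared = ", signif(x$adj_r_squared, 4),
    ", F p-value = ", signif(x$f_pvalue, 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' Predict expression for new records
#'
#' @param object A `pc_fit` object.
#' @param newdata A records tibble; defaults to reproducing the fitted values.
#' @param ... Unused.
#' @return A numeric vector of predicted expression values.
#' @export
predict.pc_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  check_records(newdata, require_expression = FALSE)
  X <- vapply(object$spec$terms, eval_term, numeric(nrow(newdata)), records = newdata)
  X <- matrix(X, nrow = nrow(newdata))
  base <- if (object$has_intercept) object$intercept else 0
  as.numeric(X %*% object$beta + base)
}
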