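# Bidirectional stepwise selection over the 18-term candidate set.

#' Bidirectional stepwise selection of derived temporal-interaction terms
#'
#' Starts from the intercept-only model; at each step the candidate giving the
#' best criterion improvement is added, then removals are tested; the search
#' stops when no move improves. Deterministic: candidates are screened in
#' alphabetical order and ties favour the alphabetically first term.
#'
#' Criteria: `"aic"` (default) compares `n log(RSS/n) + 2p`. A numerically
#' perfect fit (relative RSS below `1e-12`) dominates any imperfect one and
#' ties between perfect fits are broken toward the smaller model, so exact
#' generative recoveries terminate cleanly. `"pvalue"` enters the candidate
#' with the smallest partial p-value below `alpha_enter` and removes terms
#' whose p-value exceeds `alpha_remove`; because up to 18 candidates are
#' screened per step, the entry threshold is Bonferroni-adjusted for the
#' number screened (set `adjust = "none"` for the raw threshold).
#'
#' @param records A records tibble including `expression`.
#' @param candidates Term names from [candidate_terms()] (>= 2).
#' @param criterion `"aic"` or `"pvalue"`.
#' @param alpha_enter,alpha_remove Entry/removal thresholds for the p-value
#'   criterion.
#' @param adjust Multiplicity adjustment of the entry threshold for the
#'   p-value criterion: `"bonferroni"` (default) or `"none"`.
#' @param intercept Include an intercept (always recommended).
#' @return Character vector of selected term names in entry order (possibly
#'   empty).
#' @export
stepwise_select <- function(records,
                            candidates = candidate_terms(),
                            criterion = c("aic", "pvalue"),
                            alpha_enter = 0.05,
                            alpha_remove = 0.10,
                            adjust = c("bonferroni", "none"),
                            intercept = TRUE) {
  criterion <- match.arg(criterion)
  adjust <- match.arg(adjust)
  check_records(records)
  if (length(candidates) < 2) abort("need at least 2 candidates")
  unknown <- setdiff(candidates, candidate_terms())
  if (length(unknown) > 0) abort(paste0("unknown candidate(s): ", paste(unknown, collapse = ", ")))
  n <- nrow(records)
  if (n < 5) abort("need at least 5 records for stepwise selection")

  y <- records$expression
  C <- vapply(sort(candidates), eval_term, numeric(n), records = records)
  C <- matrix(C, nrow = n, dimnames = list(NULL, sort(candidates)))
  tss <- sum((y - mean(y))^2)
  rel_tol <- 1e-12

  fit_subset <- function(terms) {
    if (length(terms) == 0) {
      rss <- if (intercept) tss else sum(y^2)
      return(list(ok = TRUE, rss = rss, fit = NULL))
    }
    fit <- tryCatch(
      suppressWarnings(fit_lsm(C[, terms, drop = FALSE], y, intercept = intercept)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(list(ok = FALSE))
    list(ok = TRUE, rss = fit$rss, fit = fit)
  }

  state_of <- function(terms, sub) {
    perfect <- tss > 0 && sub$rss / tss < rel_tol
    p <- length(terms) + as.integer(intercept)
    aic <- if (perfect) -Inf else n * log(max(sub$rss, .Machine$double.xmin) / n) + 2 * p
    list(terms = terms, rss = sub$rss, perfect = perfect, aic = aic, fit = sub$fit)
  }

  # TRUE when state a is strictly preferable to state b.
  better <- function(a, b) {
    if (a$perfect && b$perfect) return(length(a$terms) < length(b$terms))
    if (a$perfect != b$perfect) return(a$perfect)
    a$aic < b$aic - 1e-8
  }

  current <- state_of(character(), fit_subset(character()))

  repeat {
    changed <- FALSE

    # Entry phase.
    pool <- setdiff(colnames(C), current$terms)
    if (length(pool) > 0 && !current$perfect) {
      if (criterion == "aic") {
        best <- NULL
        for (cand in pool) {
          sub <- fit_subset(c(current$terms, cand))
          if (!sub$ok) next
          st <- state_of(c(current$terms, cand), sub)
          if (better(st, current) && (is.null(best) || better(st, best))) best <- st
        }
        if (!is.null(best)) {
          current <- best
          changed <- TRUE
        }
      } else {
        threshold <- if (adjust == "bonferroni") alpha_enter / length(pool) else alpha_enter
        best <- NULL
        best_p <- Inf
        for (cand in pool) {
          sub <- fit_subset(c(current$terms, cand))
          if (!sub$ok || is.na(sub$fit$residual_sd)) next
          pv <- t_tests(sub$fit)
          p_cand <- pv$p_value[pv$term == cand]
          if (length(p_cand) == 1 && !is.na(p_cand) &&
            p_cand < threshold && p_cand < best_p - 1e-15) {
            best <- state_of(c(current$terms, cand), sub)
            best_p <- p_cand
          }
        }
        if (!is.null(best)) {
          current <- best
          changed <- TRUE
        }
      }
    }

    # Removal phase.
    if (length(current$terms) > 0) {
      if (criterion == "aic") {
        best <- NULL
        for (drop in current$terms) {
          kept <- setdiff(current$terms, drop)
          sub <- fit_subset(kept)
          if (!sub$ok) next
          st <- state_of(kept, sub)
          if (better(st, current) && (is.null(best) || better(st, best))) best <- st
        }
        if (!is.null(best)) {
          current <- best
          changed <- TRUE
        }
      } else if (!is.null(current$fit) && !is.na(current$fit$residual_sd)) {
        pv <- t_tests(current$fit)
        worst <- pv[which.max(pv$p_value), ]
        if (nrow(worst) == 1 && !is.na(worst$p_value) && worst$p_value > alpha_remove) {
          kept <- setdiff(current$terms, worst$term)
          sub <- fit_subset(kept)
          if (sub$ok) {
            current <- state_of(kept, sub)
            changed <- TRUE
          }
        }
      }
    }

    if (!changed) break
  }
  current$terms
}
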