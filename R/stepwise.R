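# Backward stepwise logistic regression: pure backward elimination on Wald
# p-values, one term removed per step, no re-entry.

#' Backward stepwise logistic regression
#'
#' Starts from the full model on `candidates` and repeatedly removes the
#' single term with the largest Wald p-value exceeding `alpha_stay`,
#' refitting after each removal, until every remaining term has
#' `p < alpha_stay` (or no terms remain). Ties on the p-value are broken by
#' removing the term that appears *latest* in `candidates`, which makes the
#' procedure deterministic. Removed terms never re-enter.
#'
#' @inheritParams fit_logistic
#' @param candidates Covariates eligible for the model (default `x1`..`x12`).
#' @param alpha_stay Wald p-value threshold to stay in the model, in
#'   `(0, 1]` (default 0.05).
#' @return A `stepwise_trace` object: list with `steps` (each step a list
#'   `terms`, `fit`, `removed`, `removed_p` — `removed` is `NA` at the final
#'   step) and `final`, the last `logistic_fit`. A non-convergent refit
#'   raises a `fwaging_convergence_error` carrying the partial trace in its
#'   `trace` field.
#' @export
#' @examples
#' rec <- generate_micro(micro_config(n = 2000, seed = 11))
#' tr <- backward_stepwise(rec, score_profile(rec))
#' tr$final$terms
backward_stepwise <- function(records, profiles, candidates = x_cols(),
                              alpha_stay = 0.05, outcome = "y_ha") {
  if (length(candidates) == 0L) stop_config("`candidates` must be non-empty")
  if (!is.numeric(alpha_stay) || alpha_stay <= 0 || alpha_stay > 1)
    stop_config("`alpha_stay` must lie in (0, 1]")
  terms <- candidates
  steps <- list()
  repeat {
    fit <- tryCatch(
      fit_logistic(records, profiles, terms, outcome),
      fwaging_convergence_error = function(e) {
        e$trace <- steps
        stop(e)
      })
    if (length(fit$terms) == 0L) {   # intercept-only endpoint
      steps[[length(steps) + 1L]] <- list(terms = character(0), fit = fit,
                                          removed = NA_character_,
                                          removed_p = NA_real_)
      break
    }
    p <- fit$p
    worst_p <- max(p)
    if (worst_p < alpha_stay) {
      steps[[length(steps) + 1L]] <- list(terms = terms, fit = fit,
                                          removed = NA_character_,
                                          removed_p = NA_real_)
      break
    }
    # tie-break: among maximal p-values, drop the term latest in candidate order
    at_max <- names(p)[p == worst_p]
    drop_term <- at_max[which.max(match(at_max, candidates))]
    steps[[length(steps) + 1L]] <- list(terms = terms, fit = fit,
                                        removed = drop_term,
                                        removed_p = unname(worst_p))
    terms <- setdiff(terms, drop_term)
  }
  structure(list(steps = steps, final = steps[[length(steps)]]$fit,
                 alpha_stay = alpha_stay, candidates = candidates),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("Backward stepwise trace (alpha_stay = ", x$alpha_stay, "), ",
      length(x$steps), " step(s)\n", sep = "")
  for (i in seq_along(x$steps)) {
    s <- x$steps[[i]]
    cat(sprintf("  step %d: %d term(s)%s\n", i, length(s$terms),
                if (is.na(s$removed)) " [final]"
                else sprintf(" -> removed %s (p = %.3f)", s$removed, s$removed_p)))
  }
  cat("retained:", if (length(x$final$terms)) paste(x$final$terms, collapse = ", ")
                   else "(intercept only)", "\n")
  invisible(x)
}

#' Stepwise trace as a wide table
#'
#' One column per elimination step, rows per candidate, cells giving the
#' odds ratio and its standard error — the conventional published layout of
#' a stepwise trace.
#'
#' @param trace A `stepwise_trace` object.
#' @return Data frame with a `term` column and `step_1`..`step_k` character
#'   columns `"OR (SE)"`; empty where a term has left the model.
#' @export
trace_table <- function(trace) {
  terms <- trace$candidates
  cols <- lapply(seq_along(trace$steps), function(i) {
    fit <- trace$steps[[i]]$fit
    out <- setNames(rep("", length(terms)), terms)
    keep <- intersect(terms, fit$terms)
    out[keep] <- sprintf("%.3f (%.3f)", fit$or[keep], fit$se[keep])
    out
  })
  tab <- data.frame(term = terms, stringsAsFactors = FALSE)
  for (i in seq_along(cols)) tab[[paste0("step_", i)]] <- unname(cols[[i]])
  tab
}

#' Linear predictor of a fitted model
#'
#' The retained-model score `sum(beta_i * x_i)` over the fit's terms; the
#' intercept is reported separately by the fit and deliberately not added,
#' matching the convention of writing the selection result as a weighted sum
#' of the retained indicators.
#'
#' @param fit A `logistic_fit`.
#' @param x Named numeric (or list) of covariate values covering every term
#'   in the fit.
#' @return Single numeric value.
#' @export
#' @examples
#' fit <- structure(list(terms = "x2", beta = c(x2 = 0.44)),
#'                  class = "logistic_fit")
#' linear_predictor(fit, c(x2 = 1))
linear_predictor <- function(fit, x) {
  x <- unlist(x)
  miss <- setdiff(fit$terms, names(x))
  if (length(miss))
    stop_input(paste("missing covariate value(s):", paste(miss, collapse = ", ")))
  if (length(fit$terms) == 0L) return(0)
  sum(fit$beta[fit$terms] * x[fit$terms])
}
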