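# Factor screening: 2x2 cross-tabulation against HA status, Pearson
# chi-square tests, and multivariable logistic regressions for the two
# covariate families.

#' Cross-tabulate a binary factor against HA status
#'
#' @param records Data frame containing the factor column and `id`.
#' @param profiles `ha_profiles` data frame aligned to `records` by `id`.
#' @param factor Name of a binary covariate column (e.g. `"x2"`).
#' @return A `contingency_2x2` object: a 2x2 integer matrix with rows
#'   `level_1`/`level_0` (factor present first) and columns `non_ha`/`ha`,
#'   with an attribute `zero_margin` flagging degenerate margins.
#' @export
#' @examples
#' rec <- generate_micro(micro_config(n = 300, seed = 4))
#' crosstab(rec, score_profile(rec), "x2")
crosstab <- function(records, profiles, factor) {
  if (nrow(records) == 0L || nrow(profiles) == 0L) stop_input("empty cohort")
  if (!factor %in% names(records))
    stop_input(paste("unknown factor:", factor))
  m <- merge(records[c("id", factor)], profiles[c("id", "y_ha")], by = "id")
  if (nrow(m) == 0L) stop_input("records and profiles share no ids")
  x <- as.integer(m[[factor]])
  y <- as.integer(m$y_ha)
  tab <- matrix(c(sum(x == 1 & y == 0), sum(x == 1 & y == 1),
                  sum(x == 0 & y == 0), sum(x == 0 & y == 1)),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("level_1", "level_0"), c("non_ha", "ha")))
  zero <- any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)
  if (zero) warning("contingency table has a zero margin; chi-square undefined")
  structure(tab, factor = factor, zero_margin = zero,
            class = c("contingency_2x2", class(tab)))
}

#' Pearson chi-square test for a 2x2 table
#'
#' Uses the classical product formula `n (ad - bc)^2 /
#' ((a+b)(c+d)(a+c)(b+d))` with 1 degree of freedom and **no** continuity
#' correction — the convention that reproduces published screening tables.
#'
#' @param t A `contingency_2x2` object, a 2x2 matrix, or a length-4 numeric
#'   vector `c(a, b, c, d)` read row-wise.
#' @return List with `statistic`, `p`, `df` (always 1).
#' @export
#' @examples
#' chi_square(c(239, 68, 419, 69))$statistic  # 8.478
chi_square <- function(t) {
  cells <- if (is.matrix(t)) as.numeric(t(t)) else as.numeric(t)
  if (length(cells) != 4L) stop_input("need a 2x2 table (4 cells)")
  if (any(cells < 0)) stop_input("cell counts must be non-negative")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop_stat("zero margin: chi-square undefined")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE), df = 1L)
}

#' Maximum-likelihood logistic regression with Wald inference
#'
#' Fits `outcome ~ terms` by IRLS ([stats::glm()] with a binomial family)
#' and returns coefficients, odds ratios, Wald 95% confidence intervals and
#' p-values. Rank deficiency and (quasi-)separation raise a structured
#' `fwaging_convergence_error` carrying diagnostics.
#'
#' @param records Data frame with the covariate columns.
#' @param profiles `ha_profiles` data frame aligned by `id`.
#' @param terms Character vector of covariate names (may be empty for an
#'   intercept-only model).
#' @param outcome Profile column used as the response (default `"y_ha"`;
#'   `"y1_physical"` etc. for per-criterion fits).
#' @return A `logistic_fit` object: list with `terms`, `beta`, `se`, `or`,
#'   `ci_low`, `ci_high`, `p` (all named by term), `intercept`,
#'   `intercept_se`, `converged`, `n`, `outcome`.
#' @export
#' @examples
#' rec <- generate_micro(micro_config(n = 500, seed = 5))
#' fit_logistic(rec, score_profile(rec), c("x2", "x3"))
fit_logistic <- function(records, profiles, terms, outcome = "y_ha") {
  if (!outcome %in% names(profiles))
    stop_input(paste("unknown outcome:", outcome))
  dat <- merge(records[unique(c("id", intersect(terms, names(records))))],
               profiles[c("id", outcome)], by = "id")
  if (nrow(dat) == 0L) stop_input("empty cohort")
  y <- as.integer(dat[[outcome]])
  if (length(unique(y)) < 2L)
    stop_convergence("outcome has a single class; model undefined",
                     list(outcome = outcome))
  miss <- setdiff(terms, names(dat))
  if (length(miss))
    stop_input(paste("unknown terms:", paste(miss, collapse = ", ")))
  fml <- if (length(terms)) paste("y ~", paste(terms, collapse = " + ")) else "y ~ 1"
  dat$y <- y
  warn <- character(0)
  fit <- withCallingHandlers(
    glm(as.formula(fml), family = binomial(), data = dat),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cf <- coef(fit)
  if (anyNA(cf))
    stop_convergence("design matrix is rank deficient",
                     list(aliased = names(cf)[is.na(cf)], formula = fml))
  separated <- any(grepl("fitted probabilities numerically 0 or 1", warn)) ||
    max(abs(cf)) > 15
  if (separated)
    stop_convergence("(quasi-)separation detected; Wald inference invalid",
                     list(coefficients = cf, warnings = warn, formula = fml))
  if (!fit$converged)
    stop_convergence("IRLS failed to converge", list(warnings = warn))
  se <- sqrt(diag(vcov(fit)))
  idx <- setdiff(names(cf), "(Intercept)")
  z <- cf[idx] / se[idx]
  structure(list(
    terms = idx,
    beta = cf[idx],
    se = se[idx],
    or = exp(cf[idx]),
    ci_low = exp(cf[idx] - 1.96 * se[idx]),
    ci_high = exp(cf[idx] + 1.96 * se[idx]),
    p = 2 * pnorm(-abs(z)),
    intercept = unname(cf["(Intercept)"]),
    intercept_se = unname(se["(Intercept)"]),
    converged = TRUE,
    n = nrow(dat),
    outcome = outcome), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("Logistic fit (", x$outcome, "), n = ", x$n, "\n", sep = "")
  if (length(x$terms)) {
    tab <- data.frame(beta = x$beta, se = x$se, OR = x$or,
                      ci95 = sprintf("(%.*f, %.*f)", digits, x$ci_low,
                                     digits, x$ci_high),
                      p = signif(x$p, 3), row.names = x$terms)
    print(round_df(tab, digits))
  }
  cat("intercept:", round(x$intercept, digits), "\n")
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Block ("family") logistic regressions
#'
#' Fits the two covariate families separately: the respondent's own
#' household (`x1`..`x6`) and the grown children's household (`x7`..`x12`).
#' Testing the families apart avoids interactions between the two blocks
#' before the joint stepwise stage.
#'
#' @inheritParams fit_logistic
#' @return List with `first_family` and `second_family` `logistic_fit`
#'   objects.
#' @export
block_regressions <- function(records, profiles, outcome = "y_ha") {
  list(first_family = fit_logistic(records, profiles, paste0("x", 1:6), outcome),
       second_family = fit_logistic(records, profiles, paste0("x", 7:12), outcome))
}

#' Per-criterion logistic regressions
#'
#' Fits each of the four HA criteria on the main retained factors, to check
#' which criterion drives each factor's association.
#'
#' @inheritParams fit_logistic
#' @param terms Covariates entered in each fit (default
#'   `x2, x3, x4, x6, x7, x10`).
#' @return Named list of `logistic_fit` objects, one per criterion
#'   (`y1_physical`, `y2_adl`, `y3_mental`, `y4_social`).
#' @export
criterion_regressions <- function(records, profiles,
                                  terms = c("x2", "x3", "x4", "x6", "x7", "x10")) {
  crit <- c("y1_physical", "y2_adl", "y3_mental", "y4_social")
  setNames(lapply(crit, function(yc) fit_logistic(records, profiles, terms, yc)),
           crit)
}

#' Screening table for all covariates
#'
#' Convenience wrapper producing the descriptive screening table: per
#' covariate, the 2x2 cells against HA and the uncorrected Pearson
#' chi-square with its p-value.
#'
#' @inheritParams fit_logistic
#' @param factors Covariate names (default `x1`..`x12`).
#' @return Data frame with one row per factor: cells `a`, `b`, `c`, `d`
#'   (rows factor 1/0, columns non-HA/HA), `chi_square`, `p`.
#' @export
screening_table <- function(records, profiles, factors = x_cols()) {
  rows <- lapply(factors, function(f) {
    tab <- crosstab(records, profiles, f)
    ch <- if (attr(tab, "zero_margin")) list(statistic = NA_real_, p = NA_real_)
          else chi_square(tab)
    data.frame(factor = f, a = tab[1, 1], b = tab[1, 2], c = tab[2, 1],
               d = tab[2, 2], chi_square = ch$statistic, p = ch$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
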