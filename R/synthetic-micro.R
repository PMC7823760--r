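# Synthetic micro-survey generator.
#
# Records mimic the structure of a CHARLS-style elderly cohort: 10 ADL items
# graded 1-4, 10 depression items graded 1-4, 8 social-activity counts, a
# disability flag, a chronic-condition count, and 12 binary covariates
# x1..x12.  The composite HA outcome is drawn from a logistic model on the
# covariates; item-level responses are then generated *conditionally* on the
# drawn criterion statuses so that re-scoring a generated record reproduces
# its latent Y1-Y4 exactly.

#' Default covariate prevalences for the synthetic micro cohort
#'
#' Marginal probabilities of the twelve binary covariates, taken from the
#' descriptive margins of the reference cohort (n = 795). Where a printed
#' total conflicts with the group cells, the cells are authoritative
#' (x4: 379/795; x7: 661/795).
#'
#' @return Named numeric vector `x1`..`x12` of probabilities.
#' @export
#' @examples
#' default_prevalences()
default_prevalences <- function() {
  c(x1  = 348 / 795,  # male
    x2  = 307 / 795,  # younger (50-60)
    x3  = 177 / 795,  # urban residence
    x4  = 379 / 795,  # literate
    x5  = 602 / 795,  # married
    x6  = 528 / 795,  # expects long-term care from grown children
    x7  = 661 / 795,  # grown children literate
    x8  = 312 / 795,  # grown children live with parents
    x9  = 624 / 795,  # grown children married
    x10 = 467 / 795,  # grown children in good health
    x11 = 409 / 795,  # grown children own housing
    x12 = 400 / 795)  # provides inter-generational care
}

#' Default true log-odds coefficients for the synthetic outcome model
#'
#' Signed log odds ratios of the final retained micro model (x2 0.441,
#' x3 0.453, x4 -0.411, x6 0.529, x7 -0.699), zero elsewhere. The intercept
#' is left `NA` and calibrated by [micro_config()] so that the population HA
#' prevalence equals `target_prevalence`.
#'
#' @return Named numeric vector `intercept`, `x1`..`x12`.
#' @export
default_betas <- function() {
  b <- setNames(numeric(12), paste0("x", 1:12))
  b["x2"] <- log(1.554)
  b["x3"] <- log(1.573)
  b["x4"] <- log(0.663)
  b["x6"] <- log(1.697)
  b["x7"] <- log(0.497)
  c(intercept = NA_real_, b)
}

# Exact population prevalence of a logistic outcome over independent
# Bernoulli covariates, by enumeration of the active covariate patterns.
logistic_prevalence <- function(intercept, betas, prevalences) {
  active <- names(betas)[betas != 0]
  if (length(active) == 0L) return(plogis(intercept))
  grid <- as.matrix(expand.grid(rep(list(0:1), length(active))))
  colnames(grid) <- active
  pr <- prevalences[active]
  w <- apply(grid, 1L, function(x) prod(ifelse(x == 1, pr, 1 - pr)))
  sum(w * plogis(intercept + drop(grid %*% betas[active])))
}

calibrate_intercept <- function(betas, prevalences, target) {
  f <- function(b0) logistic_prevalence(b0, betas, prevalences) - target
  uniroot(f, c(-30, 30), tol = 1e-12)$root
}

#' Configuration for the synthetic micro cohort
#'
#' @param n Number of respondents (>= 1).
#' @param prevalences Named probabilities for `x1`..`x12`
#'   (default [default_prevalences()]).
#' @param betas Named log-odds coefficients `intercept`, `x1`..`x12` for the
#'   composite HA outcome (default [default_betas()]). An `NA` intercept is
#'   calibrated so the population prevalence equals `target_prevalence`.
#' @param target_prevalence Population HA prevalence used to calibrate an
#'   `NA` intercept; default 0.172, the reference cohort's HA rate.
#' @param criterion_marginals Named marginal pass rates of the four criteria
#'   used for conditional item generation; defaults to the reference cohort
#'   (physical .686, ADL .847, mental .614, social .394).
#' @param mode `"composite"` (default) draws HA from the logistic model and
#'   the four criteria conditionally on it; `"per_criterion"` draws each
#'   criterion from its own logistic model in `criterion_betas` and defines
#'   HA as their conjunction.
#' @param criterion_betas For `mode = "per_criterion"`: named list
#'   `y1`..`y4`, each a coefficient vector like `betas` (an `NA` intercept is
#'   calibrated to the corresponding `criterion_marginals` entry).
#' @param item_noise Non-negative scale of the shared per-respondent severity
#'   factor driving within-scale item correlation (0 = independent items);
#'   default 1 gives alpha-level internal consistency comparable to real ADL
#'   and depression scales (around 0.8).
#' @param x_correlation Equicorrelation of the latent Gaussian copula behind
#'   the covariates, in `[0, 1)`; default 0 (independent covariates).
#' @param seed Integer seed for the generator's private random stream.
#' @return A `micro_config` object.
#' @export
#' @examples
#' cfg <- micro_config(n = 100, seed = 1)
#' records <- generate_micro(cfg)
micro_config <- function(n = 795,
                         prevalences = default_prevalences(),
                         betas = default_betas(),
                         target_prevalence = 0.172,
                         criterion_marginals = c(y1_physical = 0.686,
                                                 y2_adl = 0.847,
                                                 y3_mental = 0.614,
                                                 y4_social = 0.394),
                         mode = c("composite", "per_criterion"),
                         criterion_betas = NULL,
                         item_noise = 1,
                         x_correlation = 0,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop_config("`n` must be a positive integer")
  xn <- paste0("x", 1:12)
  if (!all(xn %in% names(prevalences)))
    stop_config("`prevalences` must name x1..x12")
  prevalences <- prevalences[xn]
  if (any(!is.finite(prevalences)) || any(prevalences < 0) || any(prevalences > 1))
    stop_config("all covariate prevalences must lie in [0, 1]")
  if (!is.numeric(item_noise) || item_noise < 0)
    stop_config("`item_noise` must be >= 0")
  if (x_correlation < 0 || x_correlation >= 1)
    stop_config("`x_correlation` must be in [0, 1)")

  if (mode == "composite") {
    if (!all(c("intercept", xn) %in% names(betas)))
      stop_config("`betas` must name intercept and x1..x12")
    betas <- betas[c("intercept", xn)]
    if (is.na(betas["intercept"])) {
      if (target_prevalence <= 0 || target_prevalence >= 1)
        stop_config("`target_prevalence` must be in (0, 1)")
      betas["intercept"] <- calibrate_intercept(betas[xn], prevalences,
                                                target_prevalence)
    }
    p_y <- logistic_prevalence(betas["intercept"], betas[xn], prevalences)
    if (any(criterion_marginals < p_y))
      stop_config("criterion marginals cannot be below the composite prevalence")
  } else {
    if (is.null(criterion_betas) ||
        !all(c("y1", "y2", "y3", "y4") %in% names(criterion_betas)))
      stop_config("`criterion_betas` must be a list naming y1..y4")
    criterion_betas <- lapply(seq_along(criterion_marginals), function(i) {
      b <- criterion_betas[[c("y1", "y2", "y3", "y4")[i]]]
      if (!all(c("intercept", xn) %in% names(b)))
        stop_config("each criterion beta vector must name intercept and x1..x12")
      b <- b[c("intercept", xn)]
      if (is.na(b["intercept"]))
        b["intercept"] <- calibrate_intercept(b[xn], prevalences,
                                              criterion_marginals[i])
      b
    })
    names(criterion_betas) <- c("y1", "y2", "y3", "y4")
    p_y <- NA_real_
  }

  structure(list(n = as.integer(n), prevalences = prevalences, betas = betas,
                 target_prevalence = target_prevalence,
                 criterion_marginals = criterion_marginals, mode = mode,
                 criterion_betas = criterion_betas, item_noise = item_noise,
                 x_correlation = x_correlation, p_y = p_y,
                 seed = as.integer(seed)),
            class = "micro_config")
}

# Ordinal 1..4 draw from a logistic latent with thresholds; higher `shift`
# pushes grades upward.
draw_ordinal <- function(n_rows, n_items, severity, noise, shift, thresholds) {
  lat <- matrix(rlogis(n_rows * n_items), n_rows, n_items) +
    noise * severity + shift
  g <- matrix(1L, n_rows, n_items)
  for (t in thresholds) g <- g + (lat > t)
  g
}

#' Generate a synthetic micro cohort
#'
#' Draws covariates, the latent HA outcome(s) and item-level responses that
#' are guaranteed to re-score to the drawn criterion statuses: a respondent
#' with latent good ADL has all ten grades in `{1, 2}`; one with latent poor
#' mental health has a depression sum of at least 21; and so on. The returned
#' data frame carries the ground truth in columns `truth_y1`..`truth_y4`,
#' `truth_y` for recovery tests.
#'
#' @param config A [micro_config()] object.
#' @return A data frame of class `micro_records` with columns `id`,
#'   `adl_1`..`adl_10`, `dep_1`..`dep_10`, `act_1`..`act_8`, `disabled`,
#'   `n_chronic`, `x1`..`x12`, `truth_y1`..`truth_y4`, `truth_y`.
#' @export
#' @examples
#' rec <- generate_micro(micro_config(n = 50, seed = 7))
#' all(score_profile(rec)$y_ha == rec$truth_y)
generate_micro <- function(config) {
  if (!inherits(config, "micro_config"))
    stop_config("`config` must be a micro_config object")
  withr::with_seed(config$seed, generate_micro_impl(config))
}

generate_micro_impl <- function(config) {
  n <- config$n
  p <- config$prevalences
  xn <- names(p)

  # covariates (optional exchangeable correlation via a shared Gaussian factor)
  rho <- config$x_correlation
  if (rho > 0) {
    u <- rnorm(n)
    X <- vapply(seq_along(p), function(j) {
      z <- sqrt(rho) * u + sqrt(1 - rho) * rnorm(n)
      as.integer(z < qnorm(p[j]))
    }, integer(n))
  } else {
    X <- vapply(p, function(pj) rbinom(n, 1L, pj), integer(n))
  }
  X <- matrix(X, nrow = n, dimnames = list(NULL, xn))

  if (config$mode == "composite") {
    eta <- config$betas["intercept"] + drop(X %*% config$betas[xn])
    y <- rbinom(n, 1L, plogis(eta))
    # criteria conditional on the composite: Y = 1 implies all four pass;
    # given Y = 0 draw independently at the conditional marginals, rejecting
    # the all-pass pattern
    p_y <- config$p_y
    cond <- pmin(pmax((config$criterion_marginals - p_y) / (1 - p_y), 0), 1)
    crit <- matrix(1L, n, 4L)
    idx0 <- which(y == 0L)
    if (length(idx0)) {
      m <- length(idx0)
      draw <- function(k) vapply(cond, function(q) rbinom(k, 1L, q), integer(k))
      cr <- matrix(draw(m), m, 4L)
      bad <- rowSums(cr) == 4L
      while (any(bad)) {
        cr[bad, ] <- matrix(draw(sum(bad)), sum(bad), 4L)
        bad <- rowSums(cr) == 4L
      }
      crit[idx0, ] <- cr
    }
  } else {
    crit <- vapply(config$criterion_betas, function(b) {
      rbinom(n, 1L, plogis(b["intercept"] + drop(X %*% b[xn])))
    }, integer(n))
    crit <- matrix(crit, n, 4L)
    y <- as.integer(rowSums(crit) == 4L)
  }
  colnames(crit) <- c("y1", "y2", "y3", "y4")

  noise <- config$item_noise
  sev <- rnorm(n)  # shared severity: worse health -> higher item grades

  # --- physical: pass => not disabled and n_chronic <= 2 -------------------
  pass1 <- crit[, "y1"] == 1L
  disabled <- rep(FALSE, n)
  n_chronic <- integer(n)
  n_chronic[pass1] <- sample(0:2, sum(pass1), TRUE, prob = c(.45, .35, .20))
  if (any(!pass1)) {
    f <- which(!pass1)
    dis <- runif(length(f)) < 0.35
    disabled[f] <- dis
    n_chronic[f[dis]] <- sample(0:6, sum(dis), TRUE)
    n_chronic[f[!dis]] <- 3L + rpois(sum(!dis), 1.2)
  }

  # --- ADL: pass => every grade in {1, 2} ----------------------------------
  item_shift <- seq(-0.6, 0.6, length.out = 10)  # fixed item difficulty spread
  adl <- matrix(1L, n, 10)
  pass2 <- crit[, "y2"] == 1L
  if (any(pass2)) {
    # grades restricted to {1, 2}; severity raises the share of 2s
    lp <- outer(qlogis(0.18) + noise * sev[pass2], item_shift * 0.5, `+`)
    adl[pass2, ] <- 1L + matrix(rbinom(length(lp), 1L, plogis(lp)), nrow(lp), 10)
  }
  if (any(!pass2)) {
    f <- which(!pass2)
    g <- draw_ordinal(length(f), 10, sev[f], noise, 0.8, c(-0.5, 1.2, 2.8))
    ok <- apply(g, 1L, max) >= 3L
    if (any(!ok)) {  # force at least one dependent item
      j <- sample.int(10, sum(!ok), TRUE)
      g[cbind(which(!ok), j)] <- sample(3:4, sum(!ok), TRUE)
    }
    adl[f, ] <- g
  }

  # --- mental: pass => depression sum <= 20 --------------------------------
  dep <- matrix(1L, n, 10)
  pass3 <- crit[, "y3"] == 1L
  if (any(pass3)) {
    lp <- outer(qlogis(0.30) + noise * sev[pass3], item_shift * 0.5, `+`)
    dep[pass3, ] <- 1L + matrix(rbinom(length(lp), 1L, plogis(lp)), nrow(lp), 10)
  }
  if (any(!pass3)) {
    f <- which(!pass3)
    g <- draw_ordinal(length(f), 10, sev[f], noise, 1.4, c(-1.2, 0.4, 2.0))
    deficit <- 21L - rowSums(g)
    while (any(deficit > 0L)) {       # bump random items below grade 4
      for (i in which(deficit > 0L)) {
        j <- sample(which(g[i, ] < 4L), 1L)
        g[i, j] <- g[i, j] + 1L
      }
      deficit <- 21L - rowSums(g)
    }
    dep[f, ] <- g
  }

  # --- social: pass => >= 2 distinct activities attended -------------------
  act <- matrix(0L, n, 8)
  pass4 <- crit[, "y4"] == 1L
  if (any(pass4)) {
    k <- 2L + rbinom(sum(pass4), 6L, 0.18)
    rows <- which(pass4)
    for (i in seq_along(rows)) {
      slots <- sample.int(8L, k[i])
      act[rows[i], slots] <- 1L + rpois(k[i], 3)
    }
  }
  if (any(!pass4)) {
    rows <- which(!pass4)
    one <- runif(length(rows)) < 0.45
    slot <- sample.int(8L, sum(one), TRUE)
    act[cbind(rows[one], slot)] <- 1L + rpois(sum(one), 3)
  }

  out <- data.frame(id = sprintf("r%05d", seq_len(n)), stringsAsFactors = FALSE)
  out[paste0("adl_", 1:10)] <- as.data.frame(adl)
  out[paste0("dep_", 1:10)] <- as.data.frame(dep)
  out[paste0("act_", 1:8)] <- as.data.frame(act)
  out$disabled <- disabled
  out$n_chronic <- n_chronic
  out[xn] <- as.data.frame(X)
  out$truth_y1 <- crit[, "y1"]
  out$truth_y2 <- crit[, "y2"]
  out$truth_y3 <- crit[, "y3"]
  out$truth_y4 <- crit[, "y4"]
  out$truth_y <- y
  class(out) <- c("micro_records", "data.frame")
  out
}
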