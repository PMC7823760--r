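# Synthetic regional (provincial) panel generator.
#
# The panel mimics the statistical-yearbook inputs of the macro index: per
# region and year, mean schooling years, urbanization rate, household count,
# population and the old-age dependency ratio.  National aggregates are
# derived downstream from the panel itself.

#' Configuration for the synthetic regional panel
#'
#' @param n_regions Number of regions (>= 1). Regions are named
#'   `"R01"`, `"R02"`, ...
#' @param years Strictly increasing integer vector of panel years
#'   (default `c(2005, 2010, 2015)`, the three cross-sections used for trend
#'   classification).
#' @param factor_means Named positive baseline levels:
#'   `mean_schooling_years` (years, default 8.5), `urbanization_rate`
#'   (proportion, default 0.5), `households` (default 1.5e7), `population`
#'   (default 4.5e7), `old_age_dependency_ratio` (default 0.14 — the 65+
#'   population over the working-age population).
#' @param region_sd Log-scale standard deviation of between-region
#'   heterogeneity at the first year (default 0.15; urbanization varies on
#'   the logit scale instead so it stays in (0, 1)).
#' @param trend_profiles Optional data frame with columns `region`,
#'   `variable`, `drift` giving the relative change per period for a panel
#'   variable in a region (e.g. `drift = 0.1` means +10% each period).
#'   Variables not listed get a random drift.
#' @param trend_mean,trend_sd Mean and sd of the random per-region,
#'   per-variable, per-period relative drifts (defaults 0.02 and 0.05 —
#'   gentle secular change with region-specific ups and downs).
#' @param seed Integer seed for the generator's private random stream.
#' @return A `macro_config` object.
#' @export
#' @examples
#' panel <- generate_macro(macro_config(n_regions = 5, seed = 3))
macro_config <- function(n_regions = 30,
                         years = c(2005L, 2010L, 2015L),
                         factor_means = c(mean_schooling_years = 8.5,
                                          urbanization_rate = 0.5,
                                          households = 1.5e7,
                                          population = 4.5e7,
                                          old_age_dependency_ratio = 0.14),
                         region_sd = 0.15,
                         trend_profiles = NULL,
                         trend_mean = 0.02,
                         trend_sd = 0.05,
                         seed = 1L) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 1)
    stop_config("`n_regions` must be a positive integer")
  if (length(years) == 0L)
    stop_config("`years` must be a non-empty integer vector")
  if (is.unsorted(years, strictly = TRUE))
    stop_config("`years` must be strictly increasing")
  vars <- c("mean_schooling_years", "urbanization_rate", "households",
            "population", "old_age_dependency_ratio")
  if (!all(vars %in% names(factor_means)))
    stop_config(paste("`factor_means` must name:", paste(vars, collapse = ", ")))
  factor_means <- factor_means[vars]
  if (any(!is.finite(factor_means)) || any(factor_means <= 0))
    stop_config("all factor means must be positive")
  if (factor_means["urbanization_rate"] >= 1)
    stop_config("`urbanization_rate` mean must be in (0, 1)")
  if (!is.null(trend_profiles) &&
      !all(c("region", "variable", "drift") %in% names(trend_profiles)))
    stop_config("`trend_profiles` needs columns region, variable, drift")
  structure(list(n_regions = as.integer(n_regions), years = as.integer(years),
                 factor_means = factor_means, region_sd = region_sd,
                 trend_profiles = trend_profiles, trend_mean = trend_mean,
                 trend_sd = trend_sd, seed = as.integer(seed)),
            class = "macro_config")
}

#' Generate a synthetic regional panel
#'
#' Baseline regional levels are drawn around the configured national means
#' (log-normal heterogeneity; urbanization on the logit scale) and evolved
#' across years by per-region relative drifts, either supplied through
#' `trend_profiles` or drawn at random.
#'
#' @param config A [macro_config()] object.
#' @return A data frame of class `regional_panel` with columns `region`,
#'   `year`, `mean_schooling_years`, `urbanization_rate`, `households`,
#'   `population`, `old_age_dependency_ratio`; all values positive,
#'   urbanization in (0, 1).
#' @export
generate_macro <- function(config) {
  if (!inherits(config, "macro_config"))
    stop_config("`config` must be a macro_config object")
  withr::with_seed(config$seed, generate_macro_impl(config))
}

generate_macro_impl <- function(config) {
  nr <- config$n_regions
  yrs <- config$years
  vars <- names(config$factor_means)
  regions <- sprintf("R%02d", seq_len(nr))

  base <- sapply(vars, function(v) {
    m <- config$factor_means[[v]]
    if (v == "urbanization_rate")
      plogis(qlogis(m) + rnorm(nr, 0, config$region_sd * 2))
    else
      m * exp(rnorm(nr, 0, config$region_sd))
  })
  base <- matrix(base, nr, length(vars), dimnames = list(regions, vars))

  # per-region x variable x period relative drift
  n_period <- length(yrs) - 1L
  drift <- array(rnorm(nr * length(vars) * max(n_period, 1L),
                       config$trend_mean, config$trend_sd),
                 dim = c(nr, length(vars), max(n_period, 1L)),
                 dimnames = list(regions, vars, NULL))
  if (!is.null(config$trend_profiles)) {
    tp <- config$trend_profiles
    for (i in seq_len(nrow(tp))) {
      if (!tp$region[i] %in% regions)
        stop_config(paste("unknown region in trend_profiles:", tp$region[i]))
      if (!tp$variable[i] %in% vars)
        stop_config(paste("unknown variable in trend_profiles:", tp$variable[i]))
      drift[tp$region[i], tp$variable[i], ] <- tp$drift[i]
    }
  }

  out <- vector("list", length(yrs))
  cur <- base
  for (t in seq_along(yrs)) {
    if (t > 1L) {
      cur <- cur * (1 + drift[, , t - 1L])
      cur[cur <= 0] <- 1e-8
      cur[, "urbanization_rate"] <- pmin(cur[, "urbanization_rate"], 0.97)
    }
    out[[t]] <- data.frame(region = regions, year = yrs[t],
                           as.data.frame(cur), row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  panel <- do.call(rbind, out)
  panel <- panel[order(panel$region, panel$year), ]
  rownames(panel) <- NULL
  class(panel) <- c("regional_panel", "data.frame")
  panel
}
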