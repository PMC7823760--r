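# The F-W ("factors and weights") regional index:
#   HA = sum_i F_i * W_i
# where W_i = |ln OR_i| from the retained micro logistic model and F_i are
# regional factor ratios to the national average.  With baseline-100
# normalization a region at the national average in every factor scores 100.

fw_factor_names <- function() c("f_aging", "f_urbanization", "f_education",
                                "f_family_care")
fw_weight_names <- function() c("w_aging", "w_urbanization", "w_education",
                                "w_family_care")

#' Derive macro F-W weights from the retained micro model
#'
#' Each macro factor weight is the absolute natural logarithm of the
#' corresponding retained odds ratio: age (`x2`) maps to the regional aging
#' level, residence (`x3`) to urbanization, the two education indicators
#' (`x4` own literacy, `x7` grown children's literacy) combine into the
#' education weight as `|ln OR4|/3 + |ln OR7| * 2/3`, and the expectation of
#' long-term care (`x6`) maps to family care. Absolute values are used
#' because the reference-level coding of a binary indicator only flips the
#' sign of its log odds ratio; set `signed = TRUE` to keep signs.
#'
#' @param fit A `logistic_fit` containing terms `x2, x3, x4, x6, x7`, **or**
#'   a named numeric vector of odds ratios for those terms.
#' @param digits Decimal places each `|ln OR|` magnitude is rounded to
#'   *before* the education composite is formed (default 2, the conventional
#'   reporting precision); `NULL` for no rounding.
#' @param signed Keep the sign of `ln OR` instead of its magnitude
#'   (default `FALSE`).
#' @return An `fw_weights` object: named numeric `w_aging`,
#'   `w_urbanization`, `w_education`, `w_family_care`.
#' @export
#' @examples
#' derive_weights(c(x2 = 1.554, x3 = 1.573, x4 = 0.663,
#'                  x6 = 1.697, x7 = 0.497))
derive_weights <- function(fit, digits = 2, signed = FALSE) {
  need <- c("x2", "x3", "x4", "x6", "x7")
  if (inherits(fit, "logistic_fit")) {
    miss <- setdiff(need, fit$terms)
    if (length(miss))
      stop_input(paste("fit lacks term(s):", paste(miss, collapse = ", ")))
    or <- fit$or[need]
  } else {
    or <- unlist(fit)
    miss <- setdiff(need, names(or))
    if (length(miss))
      stop_input(paste("missing odds ratio(s):", paste(miss, collapse = ", ")))
    or <- or[need]
  }
  if (any(or <= 0)) stop_input("odds ratios must be positive")
  b <- log(or)
  if (!signed) b <- abs(b)
  # per-term magnitudes are rounded first; the composite education weight is
  # built from the rounded betas (the published composition convention)
  if (!is.null(digits)) b <- round(b, digits)
  w <- c(w_aging = unname(b["x2"]),
         w_urbanization = unname(b["x3"]),
         w_education = unname(b["x4"]) / 3 + unname(b["x7"]) * 2 / 3,
         w_family_care = unname(b["x6"]))
  structure(w, class = c("fw_weights", "numeric"),
            beta = b, signed = signed)
}

#' @export
print.fw_weights <- function(x, ...) {
  cat("F-W weights (|ln OR|", if (attr(x, "signed")) ", signed", "):\n", sep = "")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Per-year national aggregates of a panel.  Rates and means are
# population-weighted; persons-per-household uses national totals;
# household_count uses the plain cross-region mean.
national_values <- function(panel) {
  split_years <- split(panel, panel$year)
  rows <- lapply(split_years, function(d) {
    data.frame(year = d$year[1],
               mean_schooling_years = weighted.mean(d$mean_schooling_years, d$population),
               urbanization_rate = weighted.mean(d$urbanization_rate, d$population),
               old_age_dependency_ratio = weighted.mean(d$old_age_dependency_ratio, d$population),
               persons_per_household = sum(d$population) / sum(d$households),
               households_mean = mean(d$households))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Regional factor ratios to the national average
#'
#' * aging factor: reciprocal of the old-age dependency ratio, relative to
#'   the reciprocal of the national ratio (younger regions score higher);
#' * urbanization factor: urbanization rate over the national rate;
#' * education factor: mean schooling years over the national mean;
#' * family-care factor: by default persons per household relative to the
#'   national figure (`family_care = "persons_per_household"`); set
#'   `family_care = "household_count"` for the raw household-count ratio to
#'   the cross-region mean.
#'
#' National means and rates are population-weighted, computed per year from
#' the panel itself.
#'
#' @param panel A `regional_panel` data frame.
#' @param region,year Optional single region/year; when both given a named
#'   numeric of the four factors is returned, otherwise a data frame for
#'   every region-year.
#' @param family_care Family-care factor definition (see above).
#' @return Named numeric of length 4, or a data frame `region`, `year`,
#'   `f_aging`, `f_urbanization`, `f_education`, `f_family_care`.
#' @export
#' @examples
#' panel <- generate_macro(macro_config(n_regions = 4, seed = 9))
#' compute_factors(panel, "R01", 2005)
compute_factors <- function(panel, region = NULL, year = NULL,
                            family_care = c("persons_per_household",
                                            "household_count")) {
  family_care <- match.arg(family_care)
  if (nrow(panel) == 0L) stop_input("empty panel")
  if (any(panel$old_age_dependency_ratio <= 0) || any(panel$households <= 0) ||
      any(panel$population <= 0))
    stop_stat("non-positive panel values: factors undefined")
  nat <- national_values(panel)
  m <- merge(panel, nat, by = "year", suffixes = c("", "_nat"))
  if (any(m$mean_schooling_years_nat <= 0) || any(m$urbanization_rate_nat <= 0))
    stop_stat("zero national denominator: factors undefined")
  out <- data.frame(
    region = m$region, year = m$year,
    f_aging = (1 / m$old_age_dependency_ratio) / (1 / m$old_age_dependency_ratio_nat),
    f_urbanization = m$urbanization_rate / m$urbanization_rate_nat,
    f_education = m$mean_schooling_years / m$mean_schooling_years_nat,
    f_family_care = if (family_care == "persons_per_household")
      (m$population / m$households) / m$persons_per_household
    else m$households / m$households_mean,
    stringsAsFactors = FALSE)
  out <- out[order(out$region, out$year), ]
  rownames(out) <- NULL
  if (!is.null(region) && !is.null(year)) {
    row <- out[out$region == region & out$year == year, ]
    if (nrow(row) != 1L)
      stop_input(paste0("region/year not in panel: ", region, "/", year))
    return(setNames(as.numeric(row[fw_factor_names()]), fw_factor_names()))
  }
  out
}

#' Composite F-W score
#'
#' `score_raw = sum(F_i * w_i)`; with `normalize = TRUE` the baseline-100
#' score `score_100 = 100 * score_raw / sum(w_i)` is added, so a region
#' whose four factors all equal the national average scores exactly 100.
#'
#' @param factors Named numeric of the four factors (`f_aging`,
#'   `f_urbanization`, `f_education`, `f_family_care`) or a data frame from
#'   [compute_factors()].
#' @param weights An `fw_weights` object (or equally named non-negative
#'   vector) with positive sum.
#' @param normalize Add the baseline-100 score (default `TRUE`).
#' @return For vector input a list `score_raw`, `score_100`; for a data
#'   frame the same columns appended.
#' @export
#' @examples
#' w <- derive_weights(c(x2 = 1.554, x3 = 1.573, x4 = 0.663,
#'                       x6 = 1.697, x7 = 0.497))
#' fw_score(c(f_aging = 1, f_urbanization = 1, f_education = 1,
#'            f_family_care = 1), w)
fw_score <- function(factors, weights, normalize = TRUE) {
  wn <- fw_weight_names()
  w <- setNames(as.numeric(unlist(weights)[wn]), wn)
  if (anyNA(w)) stop_input("weights must name w_aging, w_urbanization, w_education, w_family_care")
  if (any(w < 0)) stop_input("weights must be non-negative")
  if (sum(w) <= 0) stop_stat("weights sum to zero: score undefined")
  fn <- fw_factor_names()
  if (is.data.frame(factors)) {
    fm <- as.matrix(factors[fn])
    factors$score_raw <- drop(fm %*% w)
    if (normalize) factors$score_100 <- 100 * factors$score_raw / sum(w)
    return(factors)
  }
  f <- unlist(factors)[fn]
  if (anyNA(f)) stop_input("factors must name f_aging, f_urbanization, f_education, f_family_care")
  raw <- sum(f * w)
  out <- list(score_raw = raw)
  if (normalize) out$score_100 <- 100 * raw / sum(w)
  out
}

#' Regional HA index for a whole panel
#'
#' Computes the factor ratios and composite F-W score for every region-year
#' in the panel.
#'
#' @inheritParams compute_factors
#' @inheritParams fw_score
#' @return A data frame of class `regional_index`: `region`, `year`, the
#'   four factors, `score_raw` and `score_100`.
#' @export
#' @examples
#' panel <- generate_macro(macro_config(n_regions = 4, seed = 9))
#' w <- derive_weights(c(x2 = 1.554, x3 = 1.573, x4 = 0.663,
#'                       x6 = 1.697, x7 = 0.497))
#' regional_index(panel, w)
regional_index <- function(panel, weights,
                           family_care = c("persons_per_household",
                                           "household_count"),
                           normalize = TRUE) {
  fac <- compute_factors(panel, family_care = match.arg(family_care))
  out <- fw_score(fac, weights, normalize = normalize)
  class(out) <- c("regional_index", "data.frame")
  out
}

#' Classify a region's three-point score trend
#'
#' Regions observed at exactly three time points are typed by the signs of
#' the two consecutive changes: type 1 rises then falls, type 2 falls
#' throughout, type 3 falls then rises, type 4 rises throughout. A flat
#' segment (zero change) counts as falling, so the typing is exhaustive and
#' exclusive.
#'
#' @param index A `regional_index` data frame (or any data frame with
#'   `region`, `year` and a score column).
#' @param score_col Score column used (default `"score_100"`, falling back
#'   to `"score_raw"`).
#' @return Data frame `region`, `type` (integer 1-4), `pattern`
#'   (`"up-down"` etc.).
#' @export
#' @examples
#' d <- data.frame(region = "A", year = c(2005, 2010, 2015),
#'                 score_100 = c(100, 110, 105))
#' classify_trend(d)  # type 1
classify_trend <- function(index, score_col = NULL) {
  if (is.null(score_col))
    score_col <- if ("score_100" %in% names(index)) "score_100" else "score_raw"
  if (!score_col %in% names(index))
    stop_input(paste("no score column:", score_col))
  rows <- lapply(split(index, index$region), function(d) {
    if (nrow(d) != 3L)
      stop_input(paste0("region ", d$region[1],
                        " needs exactly three time points, has ", nrow(d)))
    d <- d[order(d$year), ]
    up <- diff(d[[score_col]]) > 0   # flat counts as down
    type <- if (up[1] && !up[2]) 1L else if (!up[1] && !up[2]) 2L
            else if (!up[1] && up[2]) 3L else 4L
    data.frame(region = d$region[1], type = type,
               pattern = paste(ifelse(up, "up", "down"), collapse = "-"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$region), , drop = FALSE]
}

#' Aggregate regional indices over economic zones
#'
#' Unweighted mean of the member regions' scores per zone and year, plus the
#' across-years period mean per zone.
#'
#' @param index A `regional_index` data frame.
#' @param zone_map Mapping of regions to zones: a data frame with columns
#'   `region` and `zone`, a named character vector (names = regions), or the
#'   path of a two-column CSV. The packaged default mapping ships at
#'   `system.file("extdata", "economic_zones.csv", package = "fwaging")`.
#' @param score_col Score column averaged (default `"score_100"`).
#' @return List with `by_year` (data frame `zone`, `year`, `score`) and
#'   `overall` (data frame `zone`, `score` — the period mean, zones sorted
#'   by descending score).
#' @export
aggregate_zones <- function(index, zone_map, score_col = NULL) {
  if (is.null(score_col))
    score_col <- if ("score_100" %in% names(index)) "score_100" else "score_raw"
  if (is.character(zone_map) && length(zone_map) == 1L && file.exists(zone_map))
    zone_map <- read.csv(zone_map, stringsAsFactors = FALSE)
  if (!is.data.frame(zone_map)) {
    zone_map <- data.frame(region = names(zone_map), zone = unname(zone_map),
                           stringsAsFactors = FALSE)
  }
  if (!all(c("region", "zone") %in% names(zone_map)))
    stop_config("zone map needs columns `region` and `zone`")
  unmapped <- setdiff(unique(index$region), zone_map$region)
  if (length(unmapped))
    stop_config(paste("unmapped region(s):", paste(unmapped, collapse = ", ")))
  m <- merge(index, zone_map, by = "region")
  by_year <- aggregate(m[[score_col]], list(zone = m$zone, year = m$year), mean)
  names(by_year)[3] <- "score"
  by_year <- by_year[order(by_year$zone, by_year$year), ]
  rownames(by_year) <- NULL
  overall <- aggregate(by_year$score, list(zone = by_year$zone), mean)
  names(overall)[2] <- "score"
  overall <- overall[order(-overall$score), ]
  rownames(overall) <- NULL
  list(by_year = by_year, overall = overall)
}

#' Plot regional index charts
#'
#' Writes one bar chart of `score_100` per year and a ranked chart of the
#' per-region period averages (regions ordered by decreasing average, one
#' line per year overlaid).
#'
#' @param index A `regional_index` data frame.
#' @param out_dir Output directory (created if needed).
#' @param format `"png"` (default) or `"svg"`.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return Invisibly, the written file paths (empty with a warning when
#'   `index` has no rows).
#' @export
plot_indices <- function(index, out_dir, format = c("png", "svg"),
                         width = 900, height = 500) {
  format <- match.arg(format)
  if (is.null(index) || nrow(index) == 0L) {
    warning("no indices to plot")
    return(invisible(character(0)))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  score_col <- if ("score_100" %in% names(index)) "score_100" else "score_raw"
  open_dev <- function(path) {
    if (format == "png") grDevices::png(path, width, height)
    else grDevices::svg(path, width / 100, height / 100)
  }
  files <- character(0)
  for (yr in sort(unique(index$year))) {
    d <- index[index$year == yr, ]
    d <- d[order(d$region), ]
    path <- file.path(out_dir, sprintf("ha_index_%s.%s", yr, format))
    open_dev(path)
    graphics::barplot(d[[score_col]], names.arg = d$region, las = 2,
                      main = sprintf("Regional HA index, %s", yr),
                      ylab = score_col, col = "steelblue")
    graphics::abline(h = 100, lty = 2)
    grDevices::dev.off()
    files <- c(files, path)
  }
  avg <- aggregate(index[[score_col]], list(region = index$region), mean)
  names(avg)[2] <- "score"
  avg <- avg[order(-avg$score), ]
  path <- file.path(out_dir, paste0("ha_index_ranked.", format))
  open_dev(path)
  graphics::plot(seq_len(nrow(avg)), avg$score, type = "b", xaxt = "n",
                 xlab = "", ylab = paste("average", score_col),
                 main = "Ranking of average HA index")
  graphics::axis(1, at = seq_len(nrow(avg)), labels = avg$region, las = 2)
  graphics::abline(h = 100, lty = 2)
  grDevices::dev.off()
  files <- c(files, path)
  invisible(files)
}
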