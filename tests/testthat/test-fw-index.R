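# Weight derivation, factor ratios, composite score, trends and zones.

table4_or <- c(x2 = 1.554, x3 = 1.573, x4 = 0.663, x6 = 1.697, x7 = 0.497)

test_that("derive_weights maps retained odds ratios to |ln OR| weights", {
  w <- derive_weights(table4_or)
  expect_s3_class(w, "fw_weights")
  expect_equal(unname(w["w_aging"]), 0.44)
  expect_equal(unname(w["w_family_care"]), 0.53)
  expect_equal(unname(w["w_urbanization"]), round(log(1.573), 2))
  # education combines the two rounded literacy magnitudes 1/3 : 2/3
  expect_equal(unname(w["w_education"]),
               round(abs(log(0.663)), 2) / 3 + round(abs(log(0.497)), 2) * 2 / 3)
  # OR = 1 gives zero weight; unrounded mode returns the raw magnitude
  w0 <- derive_weights(c(x2 = 1, x3 = 1, x4 = 1, x6 = 1, x7 = 1))
  expect_true(all(as.numeric(w0) == 0))
  wraw <- derive_weights(table4_or, digits = NULL)
  expect_equal(unname(wraw["w_aging"]), log(1.554))
  # signed mode keeps the protective sign
  ws <- derive_weights(table4_or, digits = NULL, signed = TRUE)
  expect_lt(ws[["w_education"]], 0)
  expect_error(derive_weights(c(x2 = 1.5)), class = "fwaging_input_error")
})

test_that("derive_weights accepts a fitted model with the retained terms", {
  rec <- generate_micro(micro_config(n = 8000, seed = 61))
  prof <- score_profile(rec)
  fit <- fit_logistic(rec, prof, c("x2", "x3", "x4", "x6", "x7"))
  w <- derive_weights(fit, digits = NULL)
  expect_equal(unname(w["w_aging"]), abs(unname(fit$beta["x2"])))
  expect_error(derive_weights(fit_logistic(rec, prof, "x2")),
               class = "fwaging_input_error")
})

make_uniform_panel <- function(nr = 3, years = c(2005, 2010, 2015)) {
  expand_base <- expand.grid(region = sprintf("R%02d", 1:nr), year = years,
                             stringsAsFactors = FALSE)
  expand_base$mean_schooling_years <- 8
  expand_base$urbanization_rate <- 0.5
  expand_base$households <- 1e6
  expand_base$population <- 3e6
  expand_base$old_age_dependency_ratio <- 0.15
  class(expand_base) <- c("regional_panel", "data.frame")
  expand_base
}

test_that("factor ratios are 1 for a region at the national average", {
  panel <- make_uniform_panel()
  f <- compute_factors(panel, "R01", 2005)
  expect_equal(unname(f), rep(1, 4))
  # halving one region's dependency ratio doubles its aging factor relative
  # to a fixed national value; with 3 regions the national average moves too
  panel2 <- make_uniform_panel()
  sel <- panel2$region == "R01" & panel2$year == 2005
  panel2$old_age_dependency_ratio[sel] <- 0.075
  nat <- (0.075 + 0.15 + 0.15) / 3   # equal populations
  f2 <- compute_factors(panel2, "R01", 2005)
  expect_equal(unname(f2["f_aging"]), nat / 0.075)
  expect_error(compute_factors(panel, "R99", 2005), class = "fwaging_input_error")
})

test_that("factor ratios match an independently coded oracle", {
  panel <- generate_macro(macro_config(n_regions = 8, seed = 19))
  fac <- compute_factors(panel)
  for (yr in unique(panel$year)) {
    d <- panel[panel$year == yr, ]
    sch_nat <- sum(d$mean_schooling_years * d$population) / sum(d$population)
    urb_nat <- sum(d$urbanization_rate * d$population) / sum(d$population)
    dep_nat <- sum(d$old_age_dependency_ratio * d$population) / sum(d$population)
    pph_nat <- sum(d$population) / sum(d$households)
    for (i in seq_len(nrow(d))) {
      row <- fac[fac$region == d$region[i] & fac$year == yr, ]
      expect_equal(row$f_education, d$mean_schooling_years[i] / sch_nat,
                   tolerance = 1e-12)
      expect_equal(row$f_urbanization, d$urbanization_rate[i] / urb_nat,
                   tolerance = 1e-12)
      expect_equal(row$f_aging,
                   (1 / d$old_age_dependency_ratio[i]) / (1 / dep_nat),
                   tolerance = 1e-12)
      expect_equal(row$f_family_care,
                   (d$population[i] / d$households[i]) / pph_nat,
                   tolerance = 1e-12)
    }
  }
  # the alternative household-count definition
  fac2 <- compute_factors(panel, family_care = "household_count")
  d <- panel[panel$year == panel$year[1], ]
  expect_equal(fac2$f_family_care[fac2$year == panel$year[1]],
               d$households / mean(d$households), tolerance = 1e-12)
})

test_that("fw_score is a weighted sum with baseline-100 normalization", {
  w <- c(w_aging = 0.44, w_urbanization = 0.45, w_education = 0.41 / 3 + 0.69 * 2 / 3,
         w_family_care = 0.53)
  base <- c(f_aging = 1, f_urbanization = 1, f_education = 1, f_family_care = 1)
  expect_equal(fw_score(base, w)$score_100, 100)
  # hand-computed example: F = (2,1,1,1), weights (0.44, 0.45, 0.5967, 0.53)
  f2 <- c(f_aging = 2, f_urbanization = 1, f_education = 1, f_family_care = 1)
  s <- fw_score(f2, w)
  expect_equal(s$score_raw, 2.456666667, tolerance = 1e-9)
  expect_equal(s$score_100, 121.8, tolerance = 1e-3 * 121.8)
  expect_equal(s$score_100, 100 * s$score_raw / sum(as.numeric(w)))
  # homogeneity: doubling every factor doubles both scores
  s2 <- fw_score(2 * f2, w)
  expect_equal(s2$score_raw, 2 * s$score_raw)
  expect_equal(s2$score_100, 2 * s$score_100)
  # invariance of score_100 to rescaling all weights
  w3 <- setNames(as.numeric(w) * 7.3, names(w))
  expect_equal(fw_score(f2, w3)$score_100, s$score_100, tolerance = 1e-12)
  # degenerate weights
  wz <- setNames(rep(0, 4), names(w))
  expect_error(fw_score(f2, wz), class = "fwaging_stat_error")
})

test_that("weights derived with education split 1/3 : 2/3 reproduce fw_score", {
  # w_education is a composite; check the expected numeric value flows through
  w <- derive_weights(table4_or, digits = NULL)
  expect_equal(unname(w["w_education"]),
               abs(log(0.663)) / 3 + abs(log(0.497)) * 2 / 3, tolerance = 1e-12)
})

test_that("classify_trend types the canonical shapes and tie cases", {
  shapes <- list(list(s = c(100, 110, 105), type = 1L, pattern = "up-down"),
                 list(s = c(110, 105, 100), type = 2L, pattern = "down-down"),
                 list(s = c(110, 105, 108), type = 3L, pattern = "down-up"),
                 list(s = c(100, 105, 110), type = 4L, pattern = "up-up"),
                 # flat counts as down
                 list(s = c(100, 100, 100), type = 2L, pattern = "down-down"),
                 list(s = c(100, 101, 101), type = 1L, pattern = "up-down"))
  d <- do.call(rbind, lapply(seq_along(shapes), function(i) {
    data.frame(region = paste0("Z", i), year = c(2005, 2010, 2015),
               score_100 = shapes[[i]]$s)
  }))
  got <- classify_trend(d)
  for (i in seq_along(shapes)) {
    expect_equal(got$type[got$region == paste0("Z", i)], shapes[[i]]$type)
    expect_equal(got$pattern[got$region == paste0("Z", i)], shapes[[i]]$pattern)
  }
  expect_error(classify_trend(d[d$year != 2010, ]), class = "fwaging_input_error")
})

test_that("aggregate_zones averages member regions and conserves the grand mean", {
  idx <- data.frame(region = c("A", "B", "C", "D"), year = 2005,
                    score_100 = c(100, 120, 90, 110))
  zm <- data.frame(region = c("A", "B", "C", "D"),
                   zone = c("z1", "z1", "z2", "z2"))
  z <- aggregate_zones(idx, zm)
  expect_equal(z$by_year$score[z$by_year$zone == "z1"], 110)
  expect_equal(z$by_year$score[z$by_year$zone == "z2"], 100)
  # equal-count partition conserves the grand mean
  expect_equal(mean(z$by_year$score), mean(idx$score_100))
  # one-region zone passes through; unmapped region errors
  z1 <- aggregate_zones(idx[1, ], zm[1, ])
  expect_equal(z1$by_year$score, 100)
  expect_error(aggregate_zones(idx, zm[-1, ]), class = "fwaging_config_error")
  # named-vector and packaged-file interfaces
  z2 <- aggregate_zones(idx, setNames(zm$zone, zm$region))
  expect_equal(z2$by_year, z$by_year)
  expect_equal(nrow(default_zone_map()), 30L)
  expect_equal(length(unique(default_zone_map()$zone)), 8L)
})

test_that("plot_indices writes one chart per year plus the ranked chart", {
  panel <- generate_macro(macro_config(n_regions = 3, seed = 14))
  idx <- regional_index(panel, derive_weights(table4_or))
  out <- withr::local_tempdir()
  files <- plot_indices(idx, out)
  expect_length(files, length(unique(idx$year)) + 1L)
  expect_true(all(file.exists(files)))
  expect_warning(none <- plot_indices(idx[0, ], out), "no indices")
  expect_length(none, 0)
  # ranked ordering is non-increasing in the average score
  avg <- aggregate(idx$score_100, list(region = idx$region), mean)
  expect_true(all(diff(sort(avg$x, decreasing = TRUE)) <= 0))
})
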