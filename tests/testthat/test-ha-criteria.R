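# Criterion scoring, prevalence and scale reliability.

test_that("physical-health criterion applies the disability and chronic rules", {
  cases <- list(
    list(disabled = FALSE, n_chronic = 2L, pass = TRUE),   # boundary: two conditions
    list(disabled = FALSE, n_chronic = 3L, pass = FALSE),  # boundary + 1
    list(disabled = TRUE,  n_chronic = 0L, pass = FALSE),  # disability excludes
    list(disabled = FALSE, n_chronic = 0L, pass = TRUE))
  for (cs in cases) {
    rec <- one_record(disabled = cs$disabled, n_chronic = cs$n_chronic)
    expect_identical(score_physical(rec), cs$pass)
  }
})

test_that("ADL criterion requires grade <= 2 on every item", {
  expect_true(score_adl(one_record(adl = rep(2L, 10))))   # boundary
  expect_true(score_adl(one_record(adl = rep(1L, 10))))
  expect_false(score_adl(one_record(adl = c(rep(1L, 9), 3L))))  # one failing item
})

test_that("mental-health criterion thresholds the depression sum at 20", {
  expect_true(score_mental(one_record(dep = rep(2L, 10))))          # sum 20
  expect_false(score_mental(one_record(dep = c(rep(2L, 9), 3L))))   # sum 21
  expect_true(score_mental(one_record(dep = rep(1L, 10))))          # minimum
})

test_that("social criterion counts distinct activities, not occurrences", {
  expect_true(score_social(one_record(act = c(1L, 1L, rep(0L, 6)))))
  expect_false(score_social(one_record(act = c(30L, rep(0L, 7)))))  # daily, one activity
  expect_false(score_social(one_record(act = rep(0L, 8))))
})

test_that("score_profile composes the four criteria into HA", {
  rec <- one_record()
  prof <- score_profile(rec)
  expect_true(prof$y_ha)
  # failing only the social criterion
  prof2 <- score_profile(one_record(act = rep(0L, 8)))
  expect_true(prof2$y1_physical && prof2$y2_adl && prof2$y3_mental)
  expect_false(prof2$y4_social)
  expect_false(prof2$y_ha)
  # conjunction invariant on a generated cohort
  co <- small_cohort()
  p <- co$profiles
  expect_identical(p$y_ha, p$y1_physical & p$y2_adl & p$y3_mental & p$y4_social)
})

test_that("records with missing items are rejected with a count", {
  rec <- rbind(one_record(), one_record(), one_record())
  rec$id <- c("a", "b", "c")
  rec$adl_4[2] <- NA
  expect_message(prof <- score_profile(rec), "1 record")
  expect_identical(prof$id, c("a", "c"))
  rec$adl_4 <- NA
  expect_error(score_profile(rec), class = "fwaging_input_error")
})

test_that("scoring generated records reproduces the latent criteria exactly", {
  rec <- generate_micro(micro_config(n = 4000, seed = 77))
  prof <- score_profile(rec)
  expect_identical(as.integer(prof$y1_physical), rec$truth_y1)
  expect_identical(as.integer(prof$y2_adl), rec$truth_y2)
  expect_identical(as.integer(prof$y3_mental), rec$truth_y3)
  expect_identical(as.integer(prof$y4_social), rec$truth_y4)
  expect_identical(as.integer(prof$y_ha), rec$truth_y)
})

test_that("worsening a single item never flips a criterion to pass", {
  set.seed(404)
  rec <- generate_micro(micro_config(n = 200, seed = 404))
  for (i in sample(nrow(rec), 25)) {
    row <- rec[i, ]
    adl_before <- score_adl(row); men_before <- score_mental(row)
    j <- sample(10, 1)
    col_a <- paste0("adl_", j); col_d <- paste0("dep_", j)
    if (row[[col_a]] < 4) {
      worse <- row; worse[[col_a]] <- worse[[col_a]] + 1L
      expect_false(!adl_before && score_adl(worse))
    }
    if (row[[col_d]] < 4) {
      worse <- row; worse[[col_d]] <- worse[[col_d]] + 1L
      expect_false(!men_before && score_mental(worse))
    }
  }
})

test_that("prevalence reports counts and rounded percentages", {
  prof <- data.frame(id = as.character(1:4),
                     y1_physical = c(TRUE, FALSE, FALSE, FALSE),
                     y2_adl = TRUE, y3_mental = TRUE, y4_social = TRUE)
  prof$y_ha <- prof$y1_physical
  pv <- prevalence(prof)
  expect_equal(pv$percent[pv$criterion == "y1_physical"], 25.0)
  expect_equal(pv$n_true[pv$criterion == "y1_physical"], 1L)
  all_true <- data.frame(id = "1", y1_physical = TRUE, y2_adl = TRUE,
                         y3_mental = TRUE, y4_social = TRUE, y_ha = TRUE)
  expect_true(all(prevalence(all_true)$proportion == 1))
  expect_error(prevalence(prof[0, ]), class = "fwaging_input_error")
})

test_that("cronbach_alpha matches the direct-formula oracle and its bounds", {
  # parallel items
  m <- matrix(rep(1:4, 3), 4, 3)
  expect_equal(cronbach_alpha(m)$alpha, 1)
  # a duplicated item pair
  x <- c(1, 3, 2, 4, 2)
  expect_equal(cronbach_alpha(cbind(x, x))$alpha, 1)
  # random matrices against the independent oracle; alpha <= 1; shift invariance
  set.seed(55)
  for (r in 1:20) {
    m <- matrix(sample(1:4, 50 * 10, TRUE), 50, 10)
    res <- cronbach_alpha(m)
    expect_equal(res$alpha, cronbach_oracle(m), tolerance = 1e-12)
    expect_lte(res$alpha, 1)
    m2 <- m; m2[, 3] <- m2[, 3] + 7   # constant shift of one item
    expect_equal(cronbach_alpha(m2)$alpha, res$alpha, tolerance = 1e-12)
    expect_length(res$alpha_drop, 10)
  }
  # alpha-if-item-deleted equals alpha of the reduced matrix
  m <- matrix(sample(1:4, 30 * 5, TRUE), 30, 5)
  res <- cronbach_alpha(m)
  expect_equal(unname(res$alpha_drop[2]), cronbach_alpha(m[, -2])$alpha)
  # degenerate: zero total variance
  expect_error(cronbach_alpha(matrix(1, 5, 3)), class = "fwaging_stat_error")
})
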