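# Shared fixtures, all built in code.

# A small cached default cohort reused across tests.
small_cohort <- local({
  cache <- NULL
  function(n = 1000, seed = 101) {
    if (is.null(cache)) {
      rec <- generate_micro(micro_config(n = n, seed = seed))
      cache <<- list(records = rec, profiles = score_profile(rec))
    }
    cache
  }
})

# Minimal records/profiles pair realizing exact 2x2 cell counts
# (a, b) = factor level 1 non-HA/HA, (c, d) = level 0 non-HA/HA.
cohort_from_counts <- function(factor, a, b, c, d) {
  n <- a + b + c + d
  x <- c(rep(1L, a + b), rep(0L, c + d))
  y <- c(rep(FALSE, a), rep(TRUE, b), rep(FALSE, c), rep(TRUE, d))
  id <- sprintf("r%05d", seq_len(n))
  records <- data.frame(id = id, stringsAsFactors = FALSE)
  records[[factor]] <- x
  profiles <- data.frame(id = id, y_ha = y, stringsAsFactors = FALSE)
  list(records = records, profiles = profiles)
}

# A bare-bones single micro record as a 1-row data frame, with overridable
# fields; defaults pass all four criteria.
one_record <- function(adl = rep(1L, 10), dep = rep(1L, 10),
                       act = c(1L, 1L, rep(0L, 6)), disabled = FALSE,
                       n_chronic = 0L) {
  rec <- data.frame(id = "r00001", stringsAsFactors = FALSE)
  rec[paste0("adl_", 1:10)] <- as.list(adl)
  rec[paste0("dep_", 1:10)] <- as.list(dep)
  rec[paste0("act_", 1:8)] <- as.list(act)
  rec$disabled <- disabled
  rec$n_chronic <- n_chronic
  rec[paste0("x", 1:12)] <- as.list(rep(0L, 12))
  rec
}

# Independent chi-square oracle: expected counts cell by cell, sum (O-E)^2/E.
chi_square_oracle <- function(a, b, c, d) {
  obs <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  n <- sum(obs)
  expd <- outer(rowSums(obs), colSums(obs)) / n
  sum((obs - expd)^2 / expd)
}

# Independent Cronbach alpha oracle, item by item.
cronbach_oracle <- function(m) {
  k <- ncol(m)
  iv <- 0
  for (j in seq_len(k)) iv <- iv + var(m[, j])
  k / (k - 1) * (1 - iv / var(rowSums(m)))
}
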