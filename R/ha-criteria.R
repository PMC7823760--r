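# Operational scoring of the four healthy-aging criteria.
#
# Y1 physical  : no disability and at most two chronic conditions
# Y2 ADL       : grade <= 2 on every one of the ten daily-activity items
# Y3 mental    : 10-item depression score sum <= 20
# Y4 social    : at least two distinct activities attended in the last month
# Y  (HA)      : all four criteria met

adl_cols <- function() paste0("adl_", 1:10)
dep_cols <- function() paste0("dep_", 1:10)
act_cols <- function() paste0("act_", 1:8)
x_cols   <- function() paste0("x", 1:12)

# Structural validation; returns the records with incomplete rows dropped
# (a count of rejected rows is reported via message()).
validate_micro <- function(records, drop_incomplete = TRUE) {
  need <- c("id", adl_cols(), dep_cols(), act_cols(), "disabled", "n_chronic")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop_input(paste("records are missing columns:", paste(miss, collapse = ", ")))
  if (nrow(records) == 0L) stop_input("empty cohort")
  items <- records[c(adl_cols(), dep_cols(), act_cols(), "disabled", "n_chronic")]
  incomplete <- !stats::complete.cases(items)
  if (any(incomplete)) {
    if (!drop_incomplete) stop_input("records contain missing item responses")
    message(sum(incomplete), " record(s) with missing items rejected")
    records <- records[!incomplete, , drop = FALSE]
    if (nrow(records) == 0L) stop_input("no complete records left")
  }
  grades <- as.matrix(records[c(adl_cols(), dep_cols())])
  if (any(grades < 1 | grades > 4))
    stop_input("ADL and depression grades must lie in 1..4")
  if (any(records[act_cols()] < 0))
    stop_input("activity counts must be non-negative")
  records
}

#' Score the physical-health criterion
#'
#' Passes when the respondent has no disability and at most two chronic
#' conditions.
#'
#' @param records A `micro_records` data frame (or any data frame with
#'   `disabled` and `n_chronic` columns).
#' @return Logical vector, one element per record.
#' @export
#' @examples
#' score_physical(data.frame(disabled = FALSE, n_chronic = 2))  # TRUE
score_physical <- function(records) {
  !as.logical(records$disabled) & records$n_chronic <= 2
}

#' Score the daily-activities (ADL) criterion
#'
#' Passes when every one of the ten ADL items is graded 1 ("no difficulty")
#' or 2 ("difficulty but manages alone"), i.e. the respondent is independent
#' in all ten activities.
#'
#' @inheritParams score_physical
#' @return Logical vector.
#' @export
score_adl <- function(records) {
  g <- as.matrix(records[adl_cols()])
  rowSums(g <= 2) == 10L
}

#' Score the mental-health criterion
#'
#' Passes when the sum of the ten depression items (each graded 1-4) is at
#' most 20. Items are summed as recorded; no reverse-coding is applied (see
#' the methods vignette for discussion).
#'
#' @inheritParams score_physical
#' @return Logical vector.
#' @export
score_mental <- function(records) {
  rowSums(as.matrix(records[dep_cols()])) <= 20
}

#' Score the social-participation criterion
#'
#' Passes when the number of *distinct* activities attended in the last
#' month (activity slots with a positive count) is at least two. Attending a
#' single activity daily does not qualify.
#'
#' @inheritParams score_physical
#' @return Logical vector.
#' @export
score_social <- function(records) {
  rowSums(as.matrix(records[act_cols()]) >= 1) >= 2L
}

#' Score the full healthy-aging profile
#'
#' Applies the four criterion scorers and their conjunction. Records with
#' missing item responses are rejected (with a message reporting the count).
#'
#' @param records A `micro_records` data frame.
#' @return A data frame of class `ha_profiles` with columns `id`,
#'   `y1_physical`, `y2_adl`, `y3_mental`, `y4_social`, `y_ha` (all logical
#'   except `id`).
#' @export
#' @examples
#' rec <- generate_micro(micro_config(n = 20, seed = 2))
#' score_profile(rec)
score_profile <- function(records) {
  records <- validate_micro(records)
  out <- data.frame(id = records$id,
                    y1_physical = score_physical(records),
                    y2_adl = score_adl(records),
                    y3_mental = score_mental(records),
                    y4_social = score_social(records),
                    stringsAsFactors = FALSE)
  out$y_ha <- out$y1_physical & out$y2_adl & out$y3_mental & out$y4_social
  class(out) <- c("ha_profiles", "data.frame")
  out
}

#' Criterion prevalence in a scored cohort
#'
#' @param profiles An `ha_profiles` data frame from [score_profile()].
#' @return Data frame with one row per criterion (`y1_physical`..`y4_social`,
#'   `y_ha`): `n_true`, `n`, `proportion`, and `percent` rounded to one
#'   decimal as conventionally reported.
#' @export
#' @examples
#' rec <- generate_micro(micro_config(n = 200, seed = 2))
#' prevalence(score_profile(rec))
prevalence <- function(profiles) {
  cols <- c("y1_physical", "y2_adl", "y3_mental", "y4_social", "y_ha")
  if (is.null(profiles) || nrow(profiles) == 0L)
    stop_input("empty profile list")
  n <- nrow(profiles)
  cnt <- vapply(profiles[cols], sum, numeric(1))
  data.frame(criterion = cols, n_true = as.integer(cnt), n = n,
             proportion = cnt / n, percent = round(100 * cnt / n, 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cronbach's alpha scale reliability
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))` with
#' sample (n-1) variances, plus the alpha obtained when each item in turn is
#' deleted.
#'
#' @param item_matrix Numeric matrix or data frame, respondents in rows,
#'   scale items in columns (`n >= 2`, `k >= 2`).
#' @return List with elements `alpha`, `alpha_drop` (named by item), `n`,
#'   `k`.
#' @export
#' @examples
#' m <- matrix(rep(1:4, 3), 4, 3)
#' cronbach_alpha(m)$alpha  # parallel items: 1
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (!is.numeric(m)) stop_input("item matrix must be numeric")
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop_input("need at least 2 respondents and 2 items")
  if (anyNA(m)) stop_input("item matrix contains missing values")
  alpha_of <- function(mm) {
    k <- ncol(mm)
    tot_var <- var(rowSums(mm))
    if (tot_var <= .Machine$double.eps)
      stop_stat("total-score variance is zero; alpha undefined")
    k / (k - 1) * (1 - sum(apply(mm, 2L, var)) / tot_var)
  }
  drop <- vapply(seq_len(ncol(m)),
                 function(j) alpha_of(m[, -j, drop = FALSE]), numeric(1))
  names(drop) <- colnames(m) %||% paste0("item_", seq_len(ncol(m)))
  list(alpha = alpha_of(m), alpha_drop = drop, n = nrow(m), k = ncol(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
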