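#' Two-group log-rank test
#'
#' Self-contained log-rank test: at each distinct event time the observed
#' deaths in group 1 are compared with their hypergeometric expectation
#' given the at-risk counts; the chi-square statistic on 1 degree of
#' freedom is `(sum O - sum E)^2 / sum V`. Invariant to swapping the group
#' labels.
#'
#' @param data A data frame of patient records.
#' @param time Column of follow-up times.
#' @param event Column of event flags (1 = death, 0 = censored).
#' @param group Column with exactly two distinct values.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `method`,
#'   `n_1`, `n_2`.
#' @export
#' @examples
#' df <- tibble::tibble(os = c(1, 2, 3, 4), death = 1, arm = c("a", "a", "b", "b"))
#' logrank_test(df, os, death, arm)
logrank_test <- function(data, time, event, group) {
  t <- pull_numeric(data, enquo(time), "data")
  d <- pull_numeric(data, enquo(event), "data")
  validate_surv(t, d)
  col <- as_name(enquo(group))
  check_columns(data, col, what = "data")
  g <- as.character(data[[col]])
  lv <- sort(unique(g))
  if (length(lv) != 2) {
    abort(sprintf("`%s` must have exactly 2 groups, found %d.",
                  col, length(lv)))
  }
  stat <- logrank_statistic(t, d, g == lv[1])
  tibble(
    statistic = stat, df = 1L,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    method = "log-rank",
    n_1 = sum(g == lv[1]), n_2 = sum(g == lv[2])
  )
}

# Chi-square statistic; g1 is a logical membership vector for group 1.
logrank_statistic <- function(t, d, g1) {
  ut <- sort(unique(t[d == 1]))
  o_minus_e <- 0
  v <- 0
  for (x in ut) {
    at_risk <- t >= x
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    dd <- sum(t == x & d == 1)
    d1 <- sum(t == x & d == 1 & g1)
    o_minus_e <- o_minus_e + d1 - dd * n1 / n
    if (n > 1) {
      v <- v + dd * (n1 / n) * (1 - n1 / n) * (n - dd) / (n - 1)
    }
  }
  if (v <= 0) return(0)
  o_minus_e^2 / v
}
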