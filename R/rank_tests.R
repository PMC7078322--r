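#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged), with a two-tailed
#' p-value from the t approximation on `n - 2` degrees of freedom.
#'
#' @param data A data frame.
#' @param x,y Numeric columns to correlate (length >= 3).
#' @return A one-row tibble: `estimate` (rho), `statistic` (t), `p_value`,
#'   `method`, `n`.
#' @export
#' @examples
#' df <- tibble::tibble(ctc = c(1, 2, 2, 4), tdev = c(1, 3, 2, 4))
#' spearman_rho(df, ctc, tdev)
spearman_rho <- function(data, x, y) {
  xv <- pull_numeric(data, enquo(x), "data")
  yv <- pull_numeric(data, enquo(y), "data")
  if (length(xv) != length(yv)) abort("`x` and `y` differ in length.")
  n <- length(xv)
  if (n < 3) abort("Spearman correlation needs at least 3 pairs.")
  rx <- rank(xv); ry <- rank(yv)
  if (sd(rx) == 0 || sd(ry) == 0) {
    abort("Zero rank variance: a variable is constant.")
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    stat <- sign(rho) * Inf
    p <- 0
  } else {
    stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(stat), df = n - 2)
  }
  tibble(estimate = rho, statistic = stat, p_value = p,
         method = "spearman", n = n)
}

#' Mann–Whitney U test
#'
#' Two-sample rank-sum test of distributional equality. `U` is computed
#' from the mid-ranks of the first group (sorted group labels). The
#' p-value is exact (via the null U distribution) when both samples have
#' at most 25 observations and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param data A data frame in long format.
#' @param value Numeric column of observations.
#' @param group Column with exactly two distinct values.
#' @return A one-row tibble: `statistic` (U for the first group),
#'   `p_value`, `method`, `n_1`, `n_2`, `exact`.
#' @export
mann_whitney_u <- function(data, value, group) {
  v <- pull_numeric(data, enquo(value), "data")
  col <- as_name(enquo(group))
  check_columns(data, col, what = "data")
  g <- as.character(data[[col]])
  lv <- sort(unique(g))
  if (length(lv) != 2) {
    abort(sprintf("`%s` must have exactly 2 groups, found %d.",
                  col, length(lv)))
  }
  x <- v[g == lv[1]]; y <- v[g == lv[2]]
  if (length(x) == 0 || length(y) == 0) abort("Both samples must be nonempty.")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && max(n1, n2) <= 25
  if (exact) {
    p_lo <- pwilcox(u, n1, n2)
    p_hi <- pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(statistic = u, p_value = p, method = "mann-whitney",
         n_1 = n1, n_2 = n2, exact = exact)
}

#' Wilcoxon signed-ranks test
#'
#' Paired test of distributional equality for matched measurements (e.g.
#' the CTC and tdEV counts of the same patients). Zero differences are
#' dropped; `W` is the sum of the mid-ranks of the positive differences.
#' The p-value is exact for small samples — by full sign-pattern
#' enumeration up to 12 nonzero pairs (which handles tied absolute
#' differences exactly), or via the null W distribution up to 25 untied
#' pairs — and otherwise uses a tie-corrected normal approximation with
#' continuity correction. All-zero differences give `p = 1` with a
#' warning.
#'
#' @param data A data frame with paired columns.
#' @param x,y Numeric paired columns of equal length.
#' @return A one-row tibble: `statistic` (W), `p_value`, `method`, `n`
#'   (nonzero pairs), `exact`.
#' @export
wilcoxon_signed_ranks <- function(data, x, y) {
  xv <- pull_numeric(data, enquo(x), "data")
  yv <- pull_numeric(data, enquo(y), "data")
  if (length(xv) != length(yv)) abort("`x` and `y` differ in length.")
  dd <- xv - yv
  dd <- dd[dd != 0]
  if (length(dd) == 0) {
    warn("All paired differences are zero; p = 1.")
    return(tibble(statistic = 0, p_value = 1,
                  method = "wilcoxon-signed-ranks", n = 0L, exact = TRUE))
  }
  n <- length(dd)
  r <- rank(abs(dd))
  w <- sum(r[dd > 0])
  ties <- anyDuplicated(abs(dd)) > 0
  exact <- n <= 12 || (!ties && n <= 25)
  if (n <= 12) {
    # Full enumeration of the 2^n sign patterns on the observed mid-ranks.
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
  } else if (exact) {
    p_lo <- psignrank(w, n)
    p_hi <- psignrank(w - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(dd))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(statistic = w, p_value = p, method = "wilcoxon-signed-ranks",
         n = n, exact = exact)
}
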