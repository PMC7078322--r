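#' Dichotomise counts at a prognostic cutoff
#'
#' Splits patients into favourable and unfavourable groups with the
#' half-open convention used throughout the analysis: unfavourable means
#' `count >= cutoff` (so the tdEV rule "20 or more per 7.5 mL" is
#' `cutoff = 20`, and a CTC cutoff of 1 makes any detected CTC
#' unfavourable).
#'
#' @param data A data frame.
#' @param count Numeric count column.
#' @param cutoff Cutoff value (>= 0).
#' @param name Name of the added logical column (default `unfavourable`).
#' @return `data` with an added logical column.
#' @export
#' @examples
#' df <- tibble::tibble(tdev = c(0, 4, 5, 19, 20, 100))
#' dichotomize(df, tdev, 20)
dichotomize <- function(data, count, cutoff, name = "unfavourable") {
  x <- pull_numeric(data, enquo(count), "data")
  check_scalar_number(cutoff, "cutoff", lower = 0)
  out <- as_tibble(data)
  out[[name]] <- x >= cutoff
  out
}

#' Bin counts into ordinal risk groups
#'
#' Bins counts at the given inner edges; bins are left-closed and
#' right-open, with the first bin starting at 0 and the last bin open to
#' the right: edges `c(e1, ..., ek)` give groups `[0, e1), [e1, e2), ...,
#' [ek, Inf)`.
#'
#' @param data A data frame.
#' @param count Numeric count column.
#' @param edges Strictly increasing inner bin edges.
#' @param name Name of the added ordered-factor column (default
#'   `count_bin`).
#' @return `data` with an added ordered factor column.
#' @export
#' @examples
#' df <- tibble::tibble(tdev = c(0, 4, 20, 250))
#' bin_groups(df, tdev, c(5, 20, 100))
bin_groups <- function(data, count, edges, name = "count_bin") {
  x <- pull_numeric(data, enquo(count), "data")
  if (length(edges) < 1 || any(diff(edges) <= 0)) {
    abort("`edges` must be strictly increasing.")
  }
  breaks <- c(0, edges, Inf)
  labels <- sprintf("[%s,%s)", head(breaks, -1), breaks[-1])
  idx <- findInterval(x, breaks, left.open = FALSE)
  out <- as_tibble(data)
  out[[name]] <- factor(labels[idx], levels = labels, ordered = TRUE)
  out
}
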