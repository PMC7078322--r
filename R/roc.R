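#' ROC curve and AUC
#'
#' Receiver operating characteristic curve for a numeric score against a
#' binary label (1 = positive, e.g. death or shorter-than-median OS).
#' The AUC is computed by the rank (Mann–Whitney U) formula, so tied
#' scores contribute one half; it equals the concordant-pair fraction
#' exactly.
#'
#' @param data A data frame.
#' @param score Numeric score column (higher = more positive).
#' @param label Binary label column (0/1 or logical); both classes must
#'   be present.
#' @return An object of class `roc_curve` with the curve tibble
#'   (`threshold`, `tpr`, `fpr`), `auc`, `n_pos`, `n_neg`. `tidy()` gives
#'   the curve, `glance()` the AUC, `autoplot()` the plot.
#' @export
#' @examples
#' df <- tibble::tibble(tdev = c(2, 1, 3, 4), dead = c(0, 1, 0, 1))
#' glance(roc_auc(df, tdev, dead))
roc_auc <- function(data, score, label) {
  s <- pull_numeric(data, enquo(score), "data")
  l <- pull_numeric(data, enquo(label), "data")
  if (length(s) != length(l)) abort("`score` and `label` differ in length.")
  if (!all(l %in% c(0, 1))) abort("`label` must be binary (0/1).")
  n_pos <- sum(l == 1); n_neg <- sum(l == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both label classes must be present.")
  }
  r <- rank(s)
  auc <- (sum(r[l == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(s), decreasing = TRUE)
  curve <- tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(x) sum(s >= x & l == 1) / n_pos,
                 numeric(1)),
    fpr = vapply(c(Inf, thr), function(x) sum(s >= x & l == 0) / n_neg,
                 numeric(1))
  )
  structure(list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC %.3f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @exportS3Method
tidy.roc_curve <- function(x, ...) x$curve

#' @exportS3Method
glance.roc_curve <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @exportS3Method
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
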