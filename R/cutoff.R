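#' Hazard-ratio-versus-cutoff scan
#'
#' Cutoff-Finder-style scan: for every candidate cutoff the cohort is
#' dichotomised at `count >= cutoff`, a univariable Cox model gives the
#' hazard ratio (unfavourable vs favourable) with its confidence
#' interval, and the log-rank test gives the split's p-value. The optimal
#' cutoff is the most significant split (smallest log-rank p; ties break
#' towards the smaller cutoff). Scanned p-values are reported raw, with
#' no multiple-testing correction — the scan is exploratory.
#'
#' @param data A data frame of patient records.
#' @param count Numeric biomarker count column.
#' @param time Column of follow-up times.
#' @param event Column of event flags.
#' @param candidates Candidate cutoffs; default all distinct observed
#'   counts. A candidate leaving fewer than `min_group` patients on
#'   either side is skipped as invalid.
#' @param min_group Minimum per-side group size (default 5).
#' @param conf_level Confidence level for the HR intervals.
#' @return An object of class `cutoff_scan`: `scan` tibble (`cutoff`,
#'   `n_low`, `n_high`, `hr`, `ci_low`, `ci_high`, `logrank_p`),
#'   `optimal_cutoff`, `sig_fraction` (share of valid candidates with
#'   p < 0.05) and `n`. `tidy()` gives the scan table, `glance()` the
#'   summary, `autoplot()` the HR-vs-cutoff overview plot.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 120, rho = 0.6, beta_tdev = 0.6, seed = 9)
#' scan <- cutoff_scan(simulate_cohort(cfg), tdev_count, os_months, event)
#' glance(scan)
cutoff_scan <- function(data, count, time, event, candidates = NULL,
                        min_group = 5L, conf_level = 0.95) {
  x <- pull_numeric(data, enquo(count), "data")
  t <- pull_numeric(data, enquo(time), "data")
  d <- pull_numeric(data, enquo(event), "data")
  validate_surv(t, d)
  if (length(x) != length(t)) abort("`count` and `time` differ in length.")
  if (is.null(candidates)) candidates <- sort(unique(x))
  candidates <- sort(unique(as.numeric(candidates)))
  rows <- purrr::map(candidates, function(cut) {
    hi <- x >= cut
    n_high <- sum(hi); n_low <- sum(!hi)
    if (n_high < min_group || n_low < min_group) return(NULL)
    fit <- tryCatch(
      cox_engine(t, d, matrix(as.numeric(hi), ncol = 1)),
      error = function(e) NULL
    )
    z <- qnorm(1 - (1 - conf_level) / 2)
    hr <- ci_lo <- ci_hi <- NA_real_
    if (!is.null(fit) && !fit$monotone) {
      se <- sqrt(fit$var[1, 1])
      hr <- exp(fit$beta[1])
      ci_lo <- exp(fit$beta[1] - z * se)
      ci_hi <- exp(fit$beta[1] + z * se)
    }
    lr <- logrank_statistic(t, d, hi)
    tibble(cutoff = cut, n_low = n_low, n_high = n_high,
           hr = hr, ci_low = ci_lo, ci_high = ci_hi,
           logrank_p = pchisq(lr, df = 1, lower.tail = FALSE))
  })
  scan <- dplyr::bind_rows(rows)
  if (nrow(scan) == 0) {
    abort(sprintf(
      "No valid candidate cutoff leaves >= %d patients per side.", min_group
    ))
  }
  optimal <- scan$cutoff[which.min(scan$logrank_p)]   # ties -> smaller cutoff
  structure(
    list(scan = scan, optimal_cutoff = optimal,
         sig_fraction = mean(scan$logrank_p < 0.05), n = length(x)),
    class = "cutoff_scan"
  )
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat(sprintf(
    "<cutoff_scan> %d candidates, optimal cutoff %g (p = %.3g), %.0f%% significant\n",
    nrow(x$scan), x$optimal_cutoff,
    min(x$scan$logrank_p), 100 * x$sig_fraction
  ))
  invisible(x)
}

#' @exportS3Method
tidy.cutoff_scan <- function(x, ...) x$scan

#' @exportS3Method
glance.cutoff_scan <- function(x, ...) {
  out <- tibble(
    optimal_cutoff = x$optimal_cutoff,
    min_p = min(x$scan$logrank_p),
    sig_fraction = x$sig_fraction,
    n_candidates = nrow(x$scan),
    n = x$n
  )
  if (!is.null(x$subgroup)) {
    out$subgroup_n <- x$subgroup$n
    out$frac_above_optimal <- x$subgroup$frac_above_optimal
  }
  out
}

#' @exportS3Method
autoplot.cutoff_scan <- function(object, ...) {
  df <- object$scan |> dplyr::filter(is.finite(.data$hr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$hr)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "grey80"
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$logrank_p < 0.05), size = 1
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$optimal_cutoff,
                        linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey40"),
      name = "p < 0.05"
    ) +
    ggplot2::labs(x = "Cutoff (counts / 7.5 mL)",
                  y = "Hazard ratio (unfavourable vs favourable)") +
    ggplot2::theme_minimal()
}

#' Scan tdEV cutoffs within the favourable-CTC subgroup
#'
#' Restricts the cohort to patients with favourable CTC counts
#' (`ctc < ctc_cutoff`) and runs [cutoff_scan()] on their tdEV counts,
#' additionally reporting the fraction of favourable-CTC patients at or
#' above the optimal tdEV cutoff.
#'
#' @inheritParams cutoff_scan
#' @param ctc_count CTC count column.
#' @param ctc_cutoff The cohort's CTC cutoff.
#' @param tdev_count tdEV count column.
#' @return A `cutoff_scan` whose `glance()` additionally reports
#'   `subgroup_n` and `frac_above_optimal`.
#' @export
favourable_subgroup_scan <- function(data, ctc_count, ctc_cutoff,
                                     tdev_count, time, event,
                                     candidates = NULL, min_group = 5L,
                                     conf_level = 0.95) {
  ctc <- pull_numeric(data, enquo(ctc_count), "data")
  check_scalar_number(ctc_cutoff, "ctc_cutoff", lower = 0)
  fav <- as_tibble(data)[ctc < ctc_cutoff, ]
  if (nrow(fav) == 0) {
    abort(sprintf("No patients with favourable CTC counts (< %g).",
                  ctc_cutoff))
  }
  scan <- cutoff_scan(fav, {{ tdev_count }}, {{ time }}, {{ event }},
                      candidates = candidates, min_group = min_group,
                      conf_level = conf_level)
  tdev <- pull_numeric(fav, enquo(tdev_count), "data")
  scan$subgroup <- list(
    n = nrow(fav),
    ctc_cutoff = ctc_cutoff,
    frac_above_optimal = mean(tdev >= scan$optimal_cutoff)
  )
  scan
}

#' Healthy-donor normal reference range
#'
#' The normal range for tdEV counts is `[0, median + 2 SD]` of the
#' healthy-donor counts (sample SD, n-1 denominator), reported
#' unrounded; `cutoff` is the ceiling of the upper bound, the value used
#' to dichotomise patients downstream.
#'
#' @param data A data frame of healthy-donor records.
#' @param count Count column (n >= 2).
#' @return A one-row tibble: `lower`, `upper`, `cutoff`, `median`, `sd`,
#'   `n`.
#' @export
#' @examples
#' normal_reference_range(tibble::tibble(tdev = c(0, 0, 1, 2, 10)), tdev)
normal_reference_range <- function(data, count) {
  x <- pull_numeric(data, enquo(count), "data")
  if (length(x) < 2) abort("Reference range needs at least 2 donors.")
  med <- median(x)
  s <- sd(x)
  tibble(lower = 0, upper = med + 2 * s, cutoff = ceiling(med + 2 * s),
         median = med, sd = s, n = length(x))
}
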