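#' Kaplan–Meier product-limit estimate
#'
#' Self-contained product-limit estimator. At tied times, events precede
#' censorings. The survival function is a right-continuous step function
#' with `S(0) = 1`; the median OS is the first time at which the estimate
#' drops to 0.5 or below, and is `NA` ("not reached") when it never does.
#'
#' @param data A data frame of patient records.
#' @param time Column of follow-up times (> 0, months).
#' @param event Column of event flags (1 = death, 0 = censored).
#' @param group Optional grouping column; one curve per level.
#' @return An object of class `km_curve`. `tidy()` returns the step table
#'   (`time`, `n_risk`, `n_event`, `n_censor`, `survival`, and `group`
#'   when grouped); `glance()` returns `n`, `n_event` and `median_os` per
#'   group; `autoplot()` draws the step curves.
#' @export
#' @examples
#' df <- tibble::tibble(os = c(1, 2, 3), death = c(1, 0, 1))
#' fit <- km_estimate(df, os, death)
#' tidy(fit)
#' glance(fit)
km_estimate <- function(data, time, event, group = NULL) {
  t <- pull_numeric(data, enquo(time), "data")
  d <- pull_numeric(data, enquo(event), "data")
  validate_surv(t, d)
  gq <- enquo(group)
  if (rlang::quo_is_null(gq)) {
    g <- rep("all", length(t))
  } else {
    col <- as_name(gq)
    check_columns(data, col, what = "data")
    g <- as.character(data[[col]])
  }
  steps <- purrr::map_dfr(split(seq_along(t), g), function(idx) {
    km_steps(t[idx], d[idx]) |>
      dplyr::mutate(group = g[idx[1]], .before = 1)
  })
  grouped <- !rlang::quo_is_null(gq)
  if (!grouped) steps$group <- NULL
  medians <- steps |>
    dplyr::group_by(dplyr::across(dplyr::any_of("group"))) |>
    dplyr::summarise(
      median_os = {
        hit <- .data$time[.data$survival <= 0.5]
        if (length(hit)) min(hit) else NA_real_
      },
      .groups = "drop"
    )
  counts <- tibble(group = g, event = d) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), n_event = sum(.data$event),
                     .groups = "drop")
  if (!grouped) counts$group <- NULL
  structure(
    list(steps = steps, medians = medians, counts = counts,
         grouped = grouped, n = length(t)),
    class = "km_curve"
  )
}

validate_surv <- function(t, d) {
  if (length(t) == 0) abort("Empty survival input.")
  if (length(t) != length(d)) abort("`time` and `event` differ in length.")
  if (any(!is.finite(t)) || any(t <= 0)) abort("All times must be finite and > 0.")
  if (!all(d %in% c(0, 1))) abort("`event` must be binary (0/1).")
  invisible(TRUE)
}

# Product-limit steps for one group.
km_steps <- function(t, d) {
  ut <- sort(unique(t))
  n_risk <- vapply(ut, function(x) sum(t >= x), numeric(1))
  n_event <- vapply(ut, function(x) sum(t == x & d == 1), numeric(1))
  n_censor <- vapply(ut, function(x) sum(t == x & d == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  tibble(time = ut, n_risk = n_risk, n_event = n_event,
         n_censor = n_censor, survival = surv)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve>", x$n, "subjects\n")
  print(glance(x))
  invisible(x)
}

#' @exportS3Method
tidy.km_curve <- function(x, ...) x$steps

#' @exportS3Method
glance.km_curve <- function(x, ...) {
  if (x$grouped) {
    dplyr::left_join(x$counts, x$medians, by = "group")
  } else {
    dplyr::bind_cols(x$counts, x$medians)
  }
}

#' @exportS3Method
autoplot.km_curve <- function(object, ...) {
  steps <- object$steps
  # Prepend the S(0) = 1 anchor for drawing.
  anchor <- steps |>
    dplyr::group_by(dplyr::across(dplyr::any_of("group"))) |>
    dplyr::slice(1) |>
    dplyr::mutate(time = 0, survival = 1, n_event = 0, n_censor = 0) |>
    dplyr::ungroup()
  df <- dplyr::bind_rows(anchor, steps)
  mapping <- if (object$grouped) {
    ggplot2::aes(x = .data$time, y = .data$survival, colour = .data$group)
  } else {
    ggplot2::aes(x = .data$time, y = .data$survival)
  }
  ggplot2::ggplot(df, mapping) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
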