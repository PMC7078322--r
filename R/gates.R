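#' Construct a linear gate
#'
#' A gate is a named conjunction of threshold predicates over
#' (channel, feature) pairs; an event passes the gate when every predicate
#' holds. Comparator strictness is honoured exactly (no epsilon slack).
#'
#' @param name Gate name.
#' @param predicates A data frame with columns `channel`, `feature`, `cmp`
#'   (one of `"<="`, `"<"`, `">"`, `">="`), `threshold`, and optionally
#'   `unit` (checked against [feature_units()]).
#' @param platform Platform tag the gate applies to.
#' @return An object of class `tdev_gate`.
#' @export
gate <- function(name, predicates, platform = "any") {
  pred <- as_tibble(predicates)
  check_columns(pred, c("channel", "feature", "cmp", "threshold"),
                what = "predicates")
  if (nrow(pred) == 0) abort("A gate needs at least one predicate.")
  if (!"unit" %in% names(pred)) {
    pred$unit <- unname(feature_units()[pred$feature])
  }
  bad_ch <- setdiff(pred$channel, TDEV_CHANNELS)
  if (length(bad_ch)) {
    abort(sprintf("Unknown channel(s): %s.", paste(bad_ch, collapse = ", ")))
  }
  bad_f <- setdiff(pred$feature, feature_names())
  if (length(bad_f)) {
    abort(sprintf("Unknown feature(s): %s. Valid features: %s.",
                  paste(bad_f, collapse = ", "),
                  paste(feature_names(), collapse = ", ")))
  }
  bad_cmp <- setdiff(pred$cmp, c("<=", "<", ">", ">="))
  if (length(bad_cmp)) {
    abort(sprintf("Invalid comparator(s): %s (use <=, <, >, >=).",
                  paste(bad_cmp, collapse = ", ")))
  }
  if (!is.numeric(pred$threshold) || any(!is.finite(pred$threshold))) {
    abort("Gate thresholds must be finite numbers.")
  }
  expected_unit <- unname(feature_units()[pred$feature])
  mismatch <- pred$unit != expected_unit
  if (any(mismatch)) {
    abort(sprintf(
      "Unit mismatch for %s: gate says `%s`, feature table uses `%s`.",
      paste0(pred$channel[mismatch], "_", pred$feature[mismatch])[1],
      pred$unit[mismatch][1], expected_unit[mismatch][1]
    ))
  }
  dir <- ifelse(pred$cmp %in% c("<", "<="), "upper", "lower")
  key <- paste(pred$channel, pred$feature, dir)
  if (anyDuplicated(key)) {
    abort("Gate has two predicates bounding the same (channel, feature) in the same direction.")
  }
  structure(list(name = name, platform = platform, predicates = pred),
            class = "tdev_gate")
}

#' @export
print.tdev_gate <- function(x, ...) {
  cat(sprintf("<tdev_gate> %s (platform %s), %d predicates\n",
              x$name, x$platform, nrow(x$predicates)))
  with(x$predicates, cat(paste0(
    "  ", channel, "_", feature, " ", cmp, " ", threshold, " [", unit, "]",
    collapse = "\n"
  ), "\n"))
  invisible(x)
}

#' Builtin gates
#'
#' The canonical gates of the analysis:
#'
#' * `tdev_celltracks` — the tdEV gate for CellTracks Analyzer II images:
#'   Mean Intensity CD45 <= 5, Mean Intensity DNA <= 5, Mean Intensity
#'   CK > 60, Mean Intensity Marker 1 <= 5, Mean Intensity Marker 2 <= 5,
#'   Max Intensity CK > 90, Size CK <= 150 um^2, Perimeter CK > 5 px,
#'   Eccentricity CK <= 0.8 and Perimeter-to-Area CK <= 1.
#' * `tdev_cellspotter` — the CellSpotter variant: because of the higher
#'   PE background on that platform, `Standard Deviation CK > 40` replaces
#'   the CK max-intensity criterion.
#' * `tdev_nsclc` — the NSCLC variant: tdEVs may be Marker-1 positive or
#'   negative, so the Marker-1 mean-intensity bound is dropped (CD16
#'   exclusion is already covered by Marker 2 <= 5).
#' * `leukocyte` — nucleated CD45+ events (synthetic-pipeline helper, not
#'   part of the published gate set).
#' * `ctc_synthetic` — nucleated CK+ CD45− events of equivalent diameter
#'   >= 4 um. Provided only so the synthetic pipeline can produce CTC
#'   counts; the study this emulates used manual CTC scores, so this gate
#'   is a package construct, not a published definition.
#'
#' @param name One of `tdev_celltracks`, `tdev_cellspotter`, `tdev_nsclc`,
#'   `leukocyte`, `ctc_synthetic`.
#' @return A `tdev_gate`.
#' @export
#' @examples
#' builtin_gate("tdev_celltracks")
builtin_gate <- function(name) {
  valid <- c("tdev_celltracks", "tdev_cellspotter", "tdev_nsclc",
             "leukocyte", "ctc_synthetic")
  if (!is.character(name) || length(name) != 1 || !name %in% valid) {
    abort(sprintf("Unknown gate `%s`. Valid names: %s.",
                  as.character(name)[1], paste(valid, collapse = ", ")))
  }
  celltracks <- tibble(
    channel = c("cd45", "dna", "ck", "m1", "m2", "ck", "ck", "ck", "ck", "ck"),
    feature = c("mean_intensity", "mean_intensity", "mean_intensity",
                "mean_intensity", "mean_intensity", "max_intensity",
                "size_um2", "perimeter_px", "eccentricity",
                "perimeter_to_area"),
    cmp = c("<=", "<=", ">", "<=", "<=", ">", "<=", ">", "<=", "<="),
    threshold = c(5, 5, 60, 5, 5, 90, 150, 5, 0.8, 1)
  )
  switch(name,
    tdev_celltracks = gate("tdev_celltracks", celltracks, "celltracks"),
    tdev_cellspotter = {
      pred <- celltracks
      swap <- pred$channel == "ck" & pred$feature == "max_intensity"
      pred$feature[swap] <- "sd_intensity"
      pred$cmp[swap] <- ">"
      pred$threshold[swap] <- 40
      gate("tdev_cellspotter", pred, "cellspotter")
    },
    tdev_nsclc = {
      pred <- celltracks[!(celltracks$channel == "m1" &
                             celltracks$feature == "mean_intensity"), ]
      gate("tdev_nsclc", pred, "celltracks")
    },
    leukocyte = gate("leukocyte", tibble(
      channel = c("dna", "cd45"),
      feature = c("mean_intensity", "mean_intensity"),
      cmp = c(">", ">"),
      threshold = c(5, 5)
    ), "any"),
    ctc_synthetic = gate("ctc_synthetic", tibble(
      channel = c("dna", "ck", "cd45", "ck"),
      feature = c("mean_intensity", "mean_intensity", "mean_intensity",
                  "eq_diameter_um"),
      cmp = c(">", ">", "<=", ">="),
      threshold = c(5, 60, 5, 4)
    ), "any")
  )
}

#' Apply a gate to an event feature table
#'
#' @param data An event feature table (one row per event) with
#'   `<channel>_<feature>` columns, as produced by [detect_cartridge()].
#' @param gate A `tdev_gate`.
#' @return A logical vector, `TRUE` where every predicate holds. A feature
#'   referenced by the gate but absent from `data` is an error (never
#'   silently `FALSE`).
#' @export
apply_gate <- function(data, gate) {
  stopifnot(inherits(gate, "tdev_gate"))
  pred <- gate$predicates
  cols <- paste0(pred$channel, "_", pred$feature)
  check_columns(data, cols, what = "event feature table")
  pass <- rep(TRUE, nrow(data))
  for (i in seq_len(nrow(pred))) {
    x <- data[[cols[i]]]
    pass <- pass & switch(pred$cmp[i],
      "<=" = x <= pred$threshold[i],
      "<"  = x <  pred$threshold[i],
      ">"  = x >  pred$threshold[i],
      ">=" = x >= pred$threshold[i]
    )
  }
  pass
}

#' Enumerate gated events
#'
#' Counts the events passing a gate, optionally per group (e.g. per
#' cartridge).
#'
#' @inheritParams apply_gate
#' @param by Optional column name (string) to count within.
#' @return A tibble with columns `gate` and `n` (plus the `by` column when
#'   given).
#' @export
enumerate_gate <- function(data, gate, by = NULL) {
  pass <- apply_gate(data, gate)
  if (is.null(by)) {
    return(tibble(gate = gate$name, n = sum(pass)))
  }
  check_columns(data, by, what = "event feature table")
  data |>
    dplyr::mutate(.pass = pass) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(gate = gate$name, n = sum(.data$.pass), .groups = "drop")
}

#' Read and write gate files
#'
#' Gates serialise to YAML with fields `name`, `platform` and
#' `predicates`, each predicate a mapping with `channel`, `feature`,
#' `cmp`, `threshold` and `unit`. The round trip preserves predicates
#' exactly, including comparator strictness and units.
#'
#' @param gate A `tdev_gate`.
#' @param path File path.
#' @return `read_gate()` returns a `tdev_gate`; `write_gate()` returns
#'   `path` invisibly.
#' @export
write_gate <- function(gate, path) {
  stopifnot(inherits(gate, "tdev_gate"))
  yaml::write_yaml(list(
    name = gate$name, platform = gate$platform,
    predicates = lapply(seq_len(nrow(gate$predicates)), function(i) {
      as.list(gate$predicates[i, ])
    })
  ), path)
  invisible(path)
}

#' @rdname write_gate
#' @export
read_gate <- function(path) {
  if (!file.exists(path)) abort(sprintf("Gate file `%s` not found.", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$name) || is.null(raw$predicates)) {
    abort(sprintf("Gate file `%s` must have `name` and `predicates`.", path))
  }
  pred <- purrr::map_dfr(seq_along(raw$predicates), function(i) {
    p <- raw$predicates[[i]]
    for (f in c("channel", "feature", "cmp", "threshold")) {
      if (is.null(p[[f]])) {
        abort(sprintf("Predicate %d in `%s` is missing field `%s`.",
                      i, path, f))
      }
    }
    if (!is.numeric(p$threshold)) {
      abort(sprintf("Predicate %d in `%s`: threshold `%s` is not numeric.",
                    i, path, as.character(p$threshold)))
    }
    tibble(channel = p$channel, feature = p$feature, cmp = p$cmp,
           threshold = as.numeric(p$threshold),
           unit = p$unit %||% unname(feature_units()[p$feature]))
  })
  gate(raw$name, pred, platform = raw$platform %||% "any")
}
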