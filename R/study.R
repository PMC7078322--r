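#' Study configuration
#'
#' Configuration for the end-to-end study emulation run by [run_study()]:
#' an imaging stage (synthetic cartridge, detection, gating) and a
#' cohort stage (simulation plus the full survival and cutoff analyses).
#'
#' @param seed Global seed; every stage derives its own sub-seed from it.
#' @param cohorts Named list of [cohort_config()]s; must contain a
#'   `healthy` entry when `tdev_cutoff = "reference"`. Defaults to
#'   [cohort_presets()] seeded from `seed`.
#' @param scene A [scene_config()] for the imaging stage (default the
#'   standard compact fixture).
#' @param ctc_cutoffs Named per-cohort CTC cutoffs; the defaults are the
#'   clinically established 5 (CRPC), 5 (MBC), 3 (mCRC) and 1 (NSCLC).
#' @param tdev_cutoff Either a fixed number (default 20, the upper bound
#'   of the published normal range) or `"reference"` to derive the cutoff
#'   from the simulated healthy donors as `ceiling(median + 2 SD)`.
#' @param ctc_bin_edges,tdev_bin_edges Named lists of inner bin edges for
#'   the binned Kaplan-Meier analysis; defaults give four tdEV groups for
#'   every cohort and four CTC groups except mCRC and NSCLC, which get
#'   three because most of those patients have no CTCs.
#' @param out_dir Optional output directory; when set, [run_study()]
#'   writes the report tables there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed = 1L,
                         cohorts = NULL,
                         scene = NULL,
                         ctc_cutoffs = c(crpc = 5, mbc = 5, mcrc = 3,
                                         nsclc = 1),
                         tdev_cutoff = 20,
                         ctc_bin_edges = NULL,
                         tdev_bin_edges = NULL,
                         out_dir = NULL) {
  seed <- check_count(seed, "seed", lower = 0)
  cohorts <- cohorts %||% cohort_presets(seed = derive_seed(seed, 100))
  scene <- scene %||% standard_scene_config(seed = derive_seed(seed, 200))
  cancer <- setdiff(names(cohorts), "healthy")
  missing_cut <- setdiff(cancer, names(ctc_cutoffs))
  if (length(missing_cut)) {
    abort(sprintf("No CTC cutoff for cohort(s): %s.",
                  paste(missing_cut, collapse = ", ")))
  }
  if (identical(tdev_cutoff, "reference")) {
    if (!"healthy" %in% names(cohorts)) {
      abort("`tdev_cutoff = \"reference\"` needs a `healthy` cohort.")
    }
  } else {
    check_scalar_number(tdev_cutoff, "tdev_cutoff", lower = 0)
  }
  default_ctc_edges <- lapply(setNames(cancer, cancer), function(ch) {
    if (ch %in% c("mcrc", "nsclc")) c(1, 5) else c(1, 5, 25)
  })
  default_tdev_edges <- lapply(setNames(cancer, cancer),
                               function(ch) c(5, 20, 100))
  structure(
    list(seed = seed, cohorts = cohorts, scene = scene,
         ctc_cutoffs = ctc_cutoffs, tdev_cutoff = tdev_cutoff,
         ctc_bin_edges = utils::modifyList(default_ctc_edges,
                                           ctc_bin_edges %||% list()),
         tdev_bin_edges = utils::modifyList(default_tdev_edges,
                                            tdev_bin_edges %||% list()),
         out_dir = out_dir),
    class = "study_config"
  )
}

#' Run the end-to-end study emulation
#'
#' Composes every stage of the analysis on synthetic data:
#'
#' 1. *Imaging*: renders the configured cartridge, runs full detection,
#'    applies the platform's tdEV gate plus the synthetic CTC and
#'    leukocyte gates, and compares the gated counts with the planted
#'    ground truth.
#' 2. *Cohorts*: simulates every configured cohort; summarises counts
#'    (medians, tdEV-excess fractions, pooled); derives the tdEV cutoff
#'    (fixed or from the simulated healthy donors); and for each cancer
#'    cohort produces dichotomised Kaplan-Meier curves with log-rank and
#'    univariable Cox HR tables for CTC and tdEV, binned Kaplan-Meier
#'    tables, full-range cutoff scans for both markers, the
#'    favourable-CTC tdEV scan, ROC tables against death, and a
#'    univariable plus forward-stepwise multivariable Cox table on
#'    log10-transformed counts and covariates.
#'
#' The run is deterministic given the config seed. With `out_dir` set,
#' all tables are written as CSV (with a provenance header line), all
#' summaries as JSON, via [write_study_report()].
#'
#' @param config A [study_config()].
#' @return An object of class `study_report` (a named list of tibbles and
#'   fitted objects).
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))

  # --- Imaging stage -------------------------------------------------
  image_set <- render_cartridge(config$scene)
  events <- detect_cartridge(image_set)
  tdev_gate <- builtin_gate(
    if (config$scene$platform == "cellspotter") "tdev_cellspotter"
    else "tdev_celltracks"
  )
  gate_counts <- dplyr::bind_rows(
    enumerate_gate(events, tdev_gate),
    enumerate_gate(events, builtin_gate("ctc_synthetic")),
    enumerate_gate(events, builtin_gate("leukocyte"))
  )
  planted <- image_set$ground_truth |>
    dplyr::count(.data$class, name = "n_planted")
  imaging <- list(events = events, gate_counts = gate_counts,
                  planted = planted)

  # --- Cohort stage --------------------------------------------------
  sims <- lapply(config$cohorts, simulate_cohort)
  all_patients <- dplyr::bind_rows(sims)
  cancer <- setdiff(names(sims), "healthy")
  count_summary <- summarize_counts(
    all_patients |> dplyr::filter(.data$cohort != "healthy")
  )

  reference <- NULL
  tdev_cutoff <- config$tdev_cutoff
  if ("healthy" %in% names(sims)) {
    reference <- normal_reference_range(sims$healthy, tdev_count)
    if (identical(config$tdev_cutoff, "reference")) {
      tdev_cutoff <- reference$cutoff
    }
  }

  per_cohort <- lapply(setNames(cancer, cancer), function(ch) {
    df <- sims[[ch]]
    ctc_cut <- config$ctc_cutoffs[[ch]]
    df <- df |>
      dichotomize(ctc_count, ctc_cut, name = "ctc_unfavourable") |>
      dichotomize(tdev_count, tdev_cutoff, name = "tdev_unfavourable") |>
      bin_groups(ctc_count, config$ctc_bin_edges[[ch]], name = "ctc_bin") |>
      bin_groups(tdev_count, config$tdev_bin_edges[[ch]], name = "tdev_bin")

    marker_rows <- lapply(
      c(ctc = "ctc_unfavourable", tdev = "tdev_unfavourable"),
      function(col) {
        fit <- cox_fit(df, os_months, event, dplyr::all_of(col))
        lr <- logrank_test(df, os_months, event, !!rlang::sym(col))
        dplyr::bind_cols(tidy(fit)[, c("hr", "conf.low", "conf.high")],
                         tibble(logrank_p = lr$p_value,
                                n_unfavourable = sum(df[[col]])))
      }
    )
    hr_table <- dplyr::bind_cols(
      tibble(cohort = ch, marker = c("ctc", "tdev"),
             cutoff = c(ctc_cut, tdev_cutoff)),
      dplyr::bind_rows(marker_rows)
    )

    km_dichot <- list(
      ctc = km_estimate(df, os_months, event, ctc_unfavourable),
      tdev = km_estimate(df, os_months, event, tdev_unfavourable)
    )
    km_binned <- list(
      ctc = km_estimate(df, os_months, event, ctc_bin),
      tdev = km_estimate(df, os_months, event, tdev_bin)
    )

    scans <- list(
      ctc = tryCatch(cutoff_scan(df, ctc_count, os_months, event),
                     error = function(e) NULL),
      tdev = tryCatch(cutoff_scan(df, tdev_count, os_months, event),
                      error = function(e) NULL)
    )
    fav_scan <- tryCatch(
      favourable_subgroup_scan(df, ctc_count, ctc_cut, tdev_count,
                               os_months, event),
      error = function(e) NULL
    )

    roc <- list(
      ctc = roc_auc(df, ctc_count, event),
      tdev = roc_auc(df, tdev_count, event)
    )

    model_df <- df |>
      dplyr::mutate(log_ctc = log10(.data$ctc_count + 1),
                    log_tdev = log10(.data$tdev_count + 1))
    covs <- intersect(c("log_ctc", "log_tdev", "ecog_high"),
                      names(model_df))
    uni <- purrr::map_dfr(covs, function(v) {
      tidy(cox_fit(model_df, os_months, event, dplyr::all_of(v)))
    })
    multi <- stepwise_cox(model_df, os_months, event, dplyr::all_of(covs))

    corr <- spearman_rho(df, ctc_count, tdev_count)

    list(data = df, hr_table = hr_table, km_dichotomised = km_dichot,
         km_binned = km_binned, scans = scans, favourable_scan = fav_scan,
         roc = roc, univariable = uni, stepwise = multi,
         spearman = corr)
  })

  hr_tables <- purrr::map_dfr(per_cohort, "hr_table")
  spearman <- purrr::map_dfr(per_cohort, "spearman") |>
    dplyr::mutate(cohort = cancer, .before = 1)
  roc_summary <- purrr::map_dfr(cancer, function(ch) {
    dplyr::bind_cols(tibble(cohort = ch, marker = c("ctc", "tdev")),
                     dplyr::bind_rows(lapply(per_cohort[[ch]]$roc, glance)))
  })
  fav_summary <- purrr::map_dfr(cancer, function(ch) {
    sc <- per_cohort[[ch]]$favourable_scan
    if (is.null(sc)) return(tibble(cohort = ch))
    dplyr::bind_cols(tibble(cohort = ch), glance(sc))
  })

  report <- structure(
    list(config = config, imaging = imaging, cohorts = sims,
         count_summary = count_summary, reference_range = reference,
         tdev_cutoff = tdev_cutoff, hr_tables = hr_tables,
         spearman = spearman, roc_summary = roc_summary,
         favourable_summary = fav_summary, per_cohort = per_cohort),
    class = "study_report"
  )
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat("  imaging gate counts:\n")
  print(x$imaging$gate_counts)
  cat("  tdEV cutoff:", x$tdev_cutoff, "\n")
  cat("  dichotomised HR table:\n")
  print(x$hr_tables)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes the report's tables as CSV and its summaries as JSON. Every
#' CSV carries a `#`-prefixed provenance header (package version, seed,
#' config hash) and a `manifest.json` lists the files.
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # Hash the scientific configuration only, not the output location.
  hashed_cfg <- report$config
  hashed_cfg$out_dir <- NULL
  stamp <- sprintf(
    "# tdevtools %s seed=%d config=%s",
    as.character(packageVersion("tdevtools")),
    report$config$seed, rlang::hash(hashed_cfg)
  )
  write_stamped <- function(df, name) {
    path <- file.path(out_dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    write.csv(df, con, row.names = FALSE)
    close(con)
    name
  }
  files <- c(
    write_stamped(report$imaging$gate_counts, "imaging_gate_counts.csv"),
    write_stamped(report$count_summary, "count_summary.csv"),
    write_stamped(report$hr_tables, "hr_tables.csv"),
    write_stamped(report$spearman, "spearman.csv"),
    write_stamped(report$roc_summary, "roc_summary.csv"),
    write_stamped(report$favourable_summary, "favourable_summary.csv"),
    write_stamped(dplyr::bind_rows(report$cohorts), "patients.csv")
  )
  for (ch in names(report$per_cohort)) {
    pc <- report$per_cohort[[ch]]
    files <- c(
      files,
      write_stamped(tidy(pc$km_dichotomised$tdev),
                    sprintf("km_tdev_%s.csv", ch)),
      write_stamped(tidy(pc$km_binned$tdev),
                    sprintf("km_tdev_binned_%s.csv", ch)),
      write_stamped(pc$univariable, sprintf("cox_univariable_%s.csv", ch))
    )
    if (!is.null(pc$scans$tdev)) {
      files <- c(files, write_stamped(tidy(pc$scans$tdev),
                                      sprintf("cutoff_scan_tdev_%s.csv", ch)))
    }
  }
  summary <- list(
    tool = "tdevtools",
    version = as.character(packageVersion("tdevtools")),
    seed = report$config$seed,
    config_hash = rlang::hash(hashed_cfg),
    tdev_cutoff = report$tdev_cutoff,
    reference_range = if (!is.null(report$reference_range)) {
      as.list(report$reference_range)
    },
    stepwise_selected = lapply(report$per_cohort,
                               function(pc) pc$stepwise$selected),
    files = files
  )
  jsonlite::write_json(summary, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
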