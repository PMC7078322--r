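#' Event feature names and units
#'
#' Ten morphology and signal-intensity measurements are extracted per
#' channel for every event: `mean_intensity`, `max_intensity`,
#' `sd_intensity` and `total_intensity` (background-subtracted camera
#' counts), `size_um2` (area), `perimeter_px` (count of object pixels with
#' a 4-neighbour outside the object), `eccentricity` (ellipse eccentricity
#' from second central moments of the binary mask), `perimeter_to_area`
#' (`perimeter_px / n_pixels`), `eq_diameter_um` (diameter of the circle
#' of equal area) and `n_pixels`.
#'
#' @return `feature_names()` a character vector of the 10 names;
#'   `feature_units()` a named character vector of their units.
#' @export
feature_names <- function() {
  c("mean_intensity", "max_intensity", "sd_intensity", "total_intensity",
    "size_um2", "perimeter_px", "eccentricity", "perimeter_to_area",
    "eq_diameter_um", "n_pixels")
}

#' @rdname feature_names
#' @export
feature_units <- function() {
  c(mean_intensity = "counts", max_intensity = "counts",
    sd_intensity = "counts", total_intensity = "counts",
    size_um2 = "um2", perimeter_px = "pixels", eccentricity = "none",
    perimeter_to_area = "per_pixel", eq_diameter_um = "um",
    n_pixels = "pixels")
}

#' Measure the per-channel features of one event
#'
#' For channels in which the event has its own mask, features are measured
#' on that mask; for channels without a detection, intensity and
#' morphology are measured over the union footprint (so that "absent"
#' channels yield near-zero background-subtracted intensities, which is
#' what the gates require). Intensities are background-subtracted and
#' clipped at zero.
#'
#' @param event One event from [merge_events()].
#' @param tiles Named list of the five channel tile matrices the event was
#'   detected in.
#' @param pixel_size Pixel pitch in um/pixel.
#' @param backgrounds Optional named per-channel background levels; default
#'   is the per-tile median.
#' @return A one-row tibble with columns `<channel>_<feature>` for all ten
#'   features in all five channels.
#' @export
measure_features <- function(event, tiles, pixel_size,
                             backgrounds = NULL) {
  if (length(event$union) == 0L) {
    abort("Event has an empty mask in all channels.")
  }
  missing <- setdiff(TDEV_CHANNELS, names(tiles))
  if (length(missing)) {
    abort(sprintf("`tiles` is missing channel(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  shape <- dim(tiles[[1]])
  if (any(event$union > prod(shape))) {
    abort("Event mask lies outside the image bounds.")
  }
  out <- list()
  for (ch in TDEV_CHANNELS) {
    mask <- event$channels[[ch]] %||% event$union
    img <- tiles[[ch]]
    bg <- if (is.null(backgrounds)) median(img) else backgrounds[[ch]]
    # Background-subtract the member pixels, then clip the summary
    # intensities at 0.  Clipping pixel-wise instead would bias the mean
    # of signal-free channels upward by E|noise| and defeat the gates'
    # near-zero bounds.
    vals <- as.numeric(img[mask]) - bg
    morph <- mask_morphology(mask, shape, pixel_size)
    out[[paste0(ch, "_mean_intensity")]] <- max(mean(vals), 0)
    out[[paste0(ch, "_max_intensity")]] <- max(vals, 0)
    out[[paste0(ch, "_sd_intensity")]] <- sample_sd(vals)
    out[[paste0(ch, "_total_intensity")]] <- max(sum(vals), 0)
    out[[paste0(ch, "_size_um2")]] <- morph$size_um2
    out[[paste0(ch, "_perimeter_px")]] <- morph$perimeter_px
    out[[paste0(ch, "_eccentricity")]] <- morph$eccentricity
    out[[paste0(ch, "_perimeter_to_area")]] <- morph$perimeter_to_area
    out[[paste0(ch, "_eq_diameter_um")]] <- morph$eq_diameter_um
    out[[paste0(ch, "_n_pixels")]] <- morph$n_pixels
  }
  as_tibble(out)
}

# Morphology of a pixel-index mask within a tile of the given shape.
mask_morphology <- function(mask, shape, pixel_size) {
  n_px <- length(mask)
  rows <- ((mask - 1L) %% shape[1]) + 1L
  cols <- ((mask - 1L) %/% shape[1]) + 1L

  # Perimeter: object pixels with at least one 4-neighbour outside the
  # object (image border counts as outside).
  r0 <- min(rows); c0 <- min(cols)
  bb <- matrix(FALSE, max(rows) - r0 + 3L, max(cols) - c0 + 3L)
  bb[cbind(rows - r0 + 2L, cols - c0 + 2L)] <- TRUE
  nr <- nrow(bb); nc <- ncol(bb)
  core <- bb[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  up    <- bb[1:(nr - 2), 2:(nc - 1), drop = FALSE]
  down  <- bb[3:nr,       2:(nc - 1), drop = FALSE]
  left  <- bb[2:(nr - 1), 1:(nc - 2), drop = FALSE]
  right <- bb[2:(nr - 1), 3:nc,       drop = FALSE]
  border <- core & !(up & down & left & right)
  perimeter <- sum(border)

  # Eccentricity from the second central moments of the binary mask.
  mu20 <- mean((cols - mean(cols))^2)
  mu02 <- mean((rows - mean(rows))^2)
  mu11 <- mean((cols - mean(cols)) * (rows - mean(rows)))
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))

  size_um2 <- n_px * pixel_size^2
  list(
    n_pixels = n_px,
    size_um2 = size_um2,
    perimeter_px = perimeter,
    perimeter_to_area = perimeter / n_px,
    eccentricity = ecc,
    eq_diameter_um = 2 * sqrt(size_um2 / pi)
  )
}

#' Full detection over a cartridge image set
#'
#' Runs [segment_channel()] on every tile of every channel, merges the
#' per-channel detections into events with [merge_events()], and measures
#' all features with [measure_features()]. Deterministic for fixed input.
#'
#' @param image_set A `cartridge_image_set`.
#' @param params A [segmentation_params()].
#' @return A tibble with one row per event: `event_id`, `tile`, `x_px`,
#'   `y_px`, and the 50 `<channel>_<feature>` columns. The feature table's
#'   units are those of [feature_units()].
#' @export
#' @examples
#' cfg <- scene_config(n_tiles = 1, tile_shape = c(64, 64), n_ctc = 0,
#'                     n_tdev = 2, n_leukocyte = 1, n_debris = 0, seed = 2)
#' events <- detect_cartridge(render_cartridge(cfg))
#' nrow(events)
detect_cartridge <- function(image_set, params = segmentation_params()) {
  stopifnot(inherits(image_set, "cartridge_image_set"))
  rows <- list()
  for (t in seq_len(image_set$n_tiles)) {
    tiles <- lapply(image_set$channels, `[[`, t)
    labels <- lapply(tiles, segment_channel, params = params)
    events <- merge_events(labels, r_merge = params$r_merge)
    if (length(events) == 0) next
    feats <- dplyr::bind_rows(lapply(events, measure_features, tiles = tiles,
                                     pixel_size = image_set$pixel_size))
    meta <- tibble(
      tile = t,
      x_px = vapply(events, function(e) e$centroid[["x"]], numeric(1)),
      y_px = vapply(events, function(e) e$centroid[["y"]], numeric(1))
    )
    rows[[length(rows) + 1L]] <- dplyr::bind_cols(meta, feats)
  }
  out <- if (length(rows) == 0) {
    empty_event_table()
  } else {
    dplyr::bind_rows(rows)
  }
  dplyr::bind_cols(tibble(event_id = seq_len(nrow(out))), out)
}

empty_event_table <- function() {
  cols <- c("tile", "x_px", "y_px",
            as.vector(t(outer(TDEV_CHANNELS, feature_names(), paste, sep = "_"))))
  as_tibble(setNames(rep(list(numeric(0)), length(cols)), cols))
}
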