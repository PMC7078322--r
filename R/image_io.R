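#' Write and read cartridge image sets
#'
#' A cartridge image set is stored as a directory holding one multi-page
#' TIFF per channel (`dna.tif`, `ck.tif`, `cd45.tif`, `m1.tif`, `m2.tif`;
#' 16-bit containers carrying the 12-bit data losslessly), a
#' `metadata.yml` file with the calibration and platform tag, and — when
#' ground truth is available — a `ground_truth.csv` table.
#'
#' @param set A `cartridge_image_set` from [render_cartridge()] or
#'   [read_image_set()].
#' @param path Directory to write to / read from.
#' @return `read_image_set()` returns a `cartridge_image_set`;
#'   `write_image_set()` returns `path` invisibly. The round trip is
#'   lossless for pixels, calibration and platform tag.
#' @export
write_image_set <- function(set, path) {
  stopifnot(inherits(set, "cartridge_image_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (ch in TDEV_CHANNELS) {
    tiles <- lapply(set$channels[[ch]], function(m) m / 65535)
    tiff::writeTIFF(tiles, file.path(path, paste0(ch, ".tif")),
                    bits.per.sample = 16L)
  }
  yaml::write_yaml(
    list(pixel_size = set$pixel_size, bit_depth = set$bit_depth,
         platform = set$platform, n_tiles = set$n_tiles,
         tile_shape = as.integer(set$tile_shape),
         channels = TDEV_CHANNELS, seed = set$seed),
    file.path(path, "metadata.yml")
  )
  if (!is.null(set$ground_truth)) {
    write.csv(set$ground_truth, file.path(path, "ground_truth.csv"),
              row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_image_set
#' @export
read_image_set <- function(path) {
  if (!dir.exists(path)) abort(sprintf("Image set directory `%s` not found.", path))
  meta_path <- file.path(path, "metadata.yml")
  if (!file.exists(meta_path)) {
    abort(sprintf("Unreadable image set: `%s` is missing metadata.yml.", path))
  }
  meta <- yaml::read_yaml(meta_path)
  channels <- list()
  for (ch in TDEV_CHANNELS) {
    f <- file.path(path, paste0(ch, ".tif"))
    if (!file.exists(f)) {
      abort(sprintf("Image set at `%s` is missing channel `%s` (%s).",
                    path, ch, basename(f)))
    }
    tiles <- tiff::readTIFF(f, all = TRUE, as.is = TRUE)
    if (!is.list(tiles)) tiles <- list(tiles)
    channels[[ch]] <- lapply(tiles, function(m) {
      storage.mode(m) <- "integer"
      m
    })
  }
  n_tiles <- vapply(channels, length, integer(1))
  if (length(unique(n_tiles)) != 1L) {
    bad <- names(n_tiles)[n_tiles != n_tiles[["dna"]]][1]
    abort(sprintf("Channel `%s` tile count (%d) disagrees with dna (%d).",
                  bad, n_tiles[[bad]], n_tiles[["dna"]]))
  }
  gt_path <- file.path(path, "ground_truth.csv")
  gt <- if (file.exists(gt_path)) {
    as_tibble(read.csv(gt_path, stringsAsFactors = FALSE))
  } else {
    NULL
  }
  new_cartridge_image_set(
    channels = channels, pixel_size = meta$pixel_size,
    bit_depth = meta$bit_depth, platform = meta$platform,
    ground_truth = gt, seed = meta$seed %||% NA_integer_
  )
}
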