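#' Scene configuration for the synthetic cartridge renderer
#'
#' Describes one synthetic CellSearch-style cartridge: the tile stack
#' geometry, camera model, per-channel background, and how many objects of
#' each class to plant. Four object classes are modelled:
#'
#' * `ctc` — nucleated tumour cell: DNA+, CK+, CD45−;
#' * `tdev` — tumour-derived extracellular vesicle: CK+ only, anucleate,
#'   small (default diameters span the gate-detectable 3.2–12 um range);
#' * `leukocyte` — nucleated white blood cell: DNA+, CD45+;
#' * `debris` — dim particles with low-level signal in 1–2 random channels.
#'
#' @param n_tiles Number of image tiles per channel (default 175, the
#'   typical number of frames needed to cover a cartridge).
#' @param tile_shape Integer vector `c(rows, cols)` in pixels.
#' @param pixel_size Pixel pitch in micrometres per pixel. The default 0.64
#'   makes a 6.4 um scale bar span 10 pixels.
#' @param bit_depth Camera bit depth; pixel values live in
#'   `[0, 2^bit_depth - 1]` (default 12, as for a 12-bit CCD).
#' @param n_ctc,n_tdev,n_leukocyte,n_debris Planted object counts per class.
#' @param platform Imaging platform tag, `"celltracks"` or `"cellspotter"`;
#'   selects which builtin tdEV gate applies downstream.
#' @param background Named per-channel background level in camera counts.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts),
#'   added on top of Poisson shot noise.
#' @param gain Camera gain in photo-electrons per count; shot noise is
#'   Poisson in electrons, so larger gains give quieter images at a
#'   fixed count level.
#' @param edge_sigma Gaussian edge-softening width in pixels for rendered
#'   objects.
#' @param class_params Optional named list overriding per-class rendering
#'   parameters; see [default_class_params()] for the structure.
#' @param seed Integer seed; identical seeds give bit-identical renders.
#'
#' @return An object of class `scene_config`.
#' @seealso [render_cartridge()], [standard_scene_config()]
#' @export
#' @examples
#' cfg <- scene_config(n_tiles = 4, n_ctc = 1, n_tdev = 5,
#'                     n_leukocyte = 5, n_debris = 0, seed = 1)
#' cfg$n_tdev
scene_config <- function(n_tiles = 175L,
                         tile_shape = c(128L, 128L),
                         pixel_size = 0.64,
                         bit_depth = 12L,
                         n_ctc = 5L,
                         n_tdev = 50L,
                         n_leukocyte = 100L,
                         n_debris = 20L,
                         platform = c("celltracks", "cellspotter"),
                         background = c(dna = 100, ck = 100, cd45 = 100,
                                        m1 = 100, m2 = 100),
                         read_noise_sd = 3,
                         gain = 4,
                         edge_sigma = 0.5,
                         class_params = list(),
                         seed = 1L) {
  platform <- match.arg(platform)
  n_tiles <- check_count(n_tiles, "n_tiles", lower = 1)
  if (length(tile_shape) != 2L || any(tile_shape < 16)) {
    abort("`tile_shape` must be c(rows, cols) with both >= 16 pixels.")
  }
  tile_shape <- as.integer(tile_shape)
  check_scalar_number(pixel_size, "pixel_size")
  if (pixel_size <= 0) abort("`pixel_size` must be > 0.")
  bit_depth <- check_count(bit_depth, "bit_depth", lower = 8)
  counts <- c(n_ctc = n_ctc, n_tdev = n_tdev,
              n_leukocyte = n_leukocyte, n_debris = n_debris)
  for (nm in names(counts)) counts[[nm]] <- check_count(counts[[nm]], nm)
  if (!all(TDEV_CHANNELS %in% names(background))) {
    abort("`background` must name all channels: dna, ck, cd45, m1, m2.")
  }
  check_scalar_number(read_noise_sd, "read_noise_sd", lower = 0)
  check_scalar_number(gain, "gain", lower = 0.25)
  check_scalar_number(edge_sigma, "edge_sigma", lower = 0.1)
  seed <- check_count(seed, "seed", lower = 0)

  params <- utils::modifyList(default_class_params(), class_params)
  max_val <- 2^bit_depth - 1
  for (cls in names(params)) {
    pk <- params[[cls]]$peaks
    if (!is.null(pk) && any(pk * (1 + params[[cls]]$jitter) +
                            max(background[TDEV_CHANNELS]) > max_val)) {
      abort(sprintf(
        "Class `%s` peak intensity not representable at bit depth %d.",
        cls, bit_depth
      ))
    }
  }

  structure(
    list(
      n_tiles = n_tiles, tile_shape = tile_shape, pixel_size = pixel_size,
      bit_depth = bit_depth,
      n_ctc = counts[["n_ctc"]], n_tdev = counts[["n_tdev"]],
      n_leukocyte = counts[["n_leukocyte"]], n_debris = counts[["n_debris"]],
      platform = platform,
      background = background[TDEV_CHANNELS],
      read_noise_sd = read_noise_sd, gain = gain, edge_sigma = edge_sigma,
      class_params = params, seed = seed
    ),
    class = "scene_config"
  )
}

#' Default per-class rendering parameters
#'
#' Diameter ranges (um), eccentricity ranges, and nominal per-channel peak
#' intensities (camera counts above background) for the four object
#' classes. Peaks are jittered multiplicatively by up to `jitter` per
#' object. tdEV diameters default to the gate-detectable range
#' (3.2–12 um): below roughly 2.5 um an object falls under the 4-pixel
#' detection floor and the "Perimeter CK > 5 px" bound, and above ~13 um
#' the softened mask can exceed the 150 um^2 size bound. CTC and
#' leukocyte diameters follow typical cell sizes. Debris gets a dim peak
#' (drawn from `random_peak`) in 1–2 randomly chosen channels.
#'
#' @return Named list with entries `ctc`, `tdev`, `leukocyte`, `debris`.
#' @export
default_class_params <- function() {
  list(
    ctc = list(
      diameter = c(8, 25), eccentricity = c(0, 0.6),
      peaks = c(dna = 500, ck = 600, cd45 = 0, m1 = 0, m2 = 0),
      jitter = 0.2, random_channels = FALSE
    ),
    tdev = list(
      diameter = c(3.2, 12), eccentricity = c(0, 0.5),
      peaks = c(dna = 0, ck = 600, cd45 = 0, m1 = 0, m2 = 0),
      jitter = 0.2, random_channels = FALSE
    ),
    leukocyte = list(
      diameter = c(6, 15), eccentricity = c(0, 0.6),
      peaks = c(dna = 450, ck = 0, cd45 = 400, m1 = 0, m2 = 0),
      jitter = 0.2, random_channels = FALSE
    ),
    debris = list(
      diameter = c(2, 6), eccentricity = c(0, 0.8),
      peaks = NULL, jitter = 0,
      random_channels = TRUE, random_peak = c(20, 45)
    )
  )
}

#' Standard synthetic cartridge fixture
#'
#' A compact, high signal-to-noise scene used throughout the package's
#' examples and checks: 12 tiles of 160x160 px holding 5 CTCs, 50 tdEVs,
#' 20 leukocytes and 10 debris particles.
#'
#' @param seed Integer seed (default 7).
#' @param platform Platform tag passed to [scene_config()].
#' @return A `scene_config`.
#' @export
standard_scene_config <- function(seed = 7L,
                                  platform = c("celltracks", "cellspotter")) {
  scene_config(
    n_tiles = 12L, tile_shape = c(160L, 160L),
    n_ctc = 5L, n_tdev = 50L, n_leukocyte = 20L, n_debris = 10L,
    platform = match.arg(platform), seed = seed
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %d tiles %dx%d px @ %.2f um/px, %d-bit, platform %s\n",
    x$n_tiles, x$tile_shape[1], x$tile_shape[2], x$pixel_size,
    x$bit_depth, x$platform
  ))
  cat(sprintf(
    "  objects: %d ctc, %d tdev, %d leukocyte, %d debris; seed %d\n",
    x$n_ctc, x$n_tdev, x$n_leukocyte, x$n_debris, x$seed
  ))
  invisible(x)
}

#' Read and write scene configurations
#'
#' Scene configurations serialise to a flat YAML document; the file schema
#' mirrors the arguments of [scene_config()] (per-class overrides live
#' under `class_params`).
#'
#' @param config A `scene_config`.
#' @param path File path.
#' @return `read_scene_config()` returns a `scene_config`;
#'   `write_scene_config()` returns `path` invisibly.
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  out <- unclass(config)
  out$tile_shape <- as.integer(out$tile_shape)
  out$background <- as.list(out$background)
  out$class_params <- lapply(out$class_params, function(p) {
    if (!is.null(p$peaks)) p$peaks <- as.list(p$peaks)
    p
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Scene config `%s` not found.", path))
  raw <- yaml::read_yaml(path)
  needed <- c("n_tiles", "tile_shape", "pixel_size", "bit_depth")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(sprintf("Scene config is missing field(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  cp <- raw$class_params %||% list()
  cp <- lapply(cp, function(p) {
    for (f in c("diameter", "eccentricity", "random_peak")) {
      if (!is.null(p[[f]])) p[[f]] <- as.numeric(p[[f]])
    }
    if (!is.null(p$peaks)) p$peaks <- unlist(p$peaks)
    p
  })
  scene_config(
    n_tiles = raw$n_tiles, tile_shape = unlist(raw$tile_shape),
    pixel_size = raw$pixel_size, bit_depth = raw$bit_depth,
    n_ctc = raw$n_ctc %||% 0L, n_tdev = raw$n_tdev %||% 0L,
    n_leukocyte = raw$n_leukocyte %||% 0L, n_debris = raw$n_debris %||% 0L,
    platform = raw$platform %||% "celltracks",
    background = unlist(raw$background),
    read_noise_sd = raw$read_noise_sd %||% 3,
    gain = raw$gain %||% 4,
    edge_sigma = raw$edge_sigma %||% 0.5,
    class_params = cp,
    seed = raw$seed %||% 1L
  )
}
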