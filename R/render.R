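# Edge profile offset (in edge-sigma units): the nominal object boundary
# sits at the pnorm(-1.83) ~ 3.4% of peak contour.
EDGE_OFFSET_Z <- 1.83

#' Render a synthetic multichannel cartridge
#'
#' Draws object attributes from the per-class distributions in `config`,
#' places the objects on tiles without overlap, rasterises them as
#' anti-aliased ellipses with Gaussian edge softening, and corrupts the
#' result with a Poisson–Gaussian camera noise model (shot noise on signal
#' plus background, additive read noise, clamped to the camera bit depth).
#'
#' Class-to-channel signal model: `ctc` is DNA+/CK+/CD45−, `tdev` is CK+
#' only, `leukocyte` is DNA+/CD45+, and `debris` carries low-level signal
#' in one or two random channels. Identical seeds give bit-identical
#' output.
#'
#' @param config A [scene_config()].
#' @return A `cartridge_image_set`: per-channel lists of integer tile
#'   matrices, calibration metadata, the platform tag, and a
#'   `ground_truth` tibble with one row per planted object (id, class,
#'   tile, centroid in pixels, true diameter, eccentricity, and true
#'   per-channel peak intensity).
#' @export
#' @examples
#' cfg <- scene_config(n_tiles = 2, tile_shape = c(64, 64), n_ctc = 0,
#'                     n_tdev = 3, n_leukocyte = 2, n_debris = 0, seed = 1)
#' set <- render_cartridge(cfg)
#' set$ground_truth
render_cartridge <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, render_cartridge_impl(config))
}

render_cartridge_impl <- function(config) {
  classes <- rep(
    c("ctc", "tdev", "leukocyte", "debris"),
    times = c(config$n_ctc, config$n_tdev, config$n_leukocyte, config$n_debris)
  )
  n_obj <- length(classes)
  ps <- config$pixel_size
  shape <- config$tile_shape

  # Draw attributes object by object (fixed order => reproducible).
  gt <- vector("list", n_obj)
  if (n_obj > 0) {
    tiles <- sample.int(config$n_tiles, n_obj, replace = TRUE)
    for (i in seq_len(n_obj)) {
      p <- config$class_params[[classes[i]]]
      d <- runif(1, p$diameter[1], p$diameter[2])
      ecc <- runif(1, p$eccentricity[1], p$eccentricity[2])
      ang <- runif(1, 0, pi)
      peaks <- setNames(numeric(5), TDEV_CHANNELS)
      if (isTRUE(p$random_channels)) {
        chs <- sample(TDEV_CHANNELS, sample(1:2, 1))
        peaks[chs] <- runif(length(chs), p$random_peak[1], p$random_peak[2])
      } else {
        jit <- runif(5, 1 - p$jitter, 1 + p$jitter)
        peaks <- p$peaks[TDEV_CHANNELS] * jit
      }
      gt[[i]] <- list(class = classes[i], tile = tiles[i], diameter_um = d,
                      eccentricity = ecc, angle = ang, peaks = peaks)
    }
  }

  # Reject objects whose rendered footprint cannot fit in a tile.
  foot_radius <- function(d_um) d_um / 2 / ps * 1.15 + 3 * config$edge_sigma
  if (n_obj > 0) {
    too_big <- vapply(gt, function(o) 2 * foot_radius(o$diameter_um) + 4 >
                        min(shape), logical(1))
    if (any(too_big)) {
      abort(sprintf(
        "Object diameter %.1f um larger than the %dx%d px tile.",
        max(vapply(gt, function(o) o$diameter_um, numeric(1))),
        shape[1], shape[2]
      ))
    }
  }

  # Place objects with a pairwise separation guard so cross-channel
  # merging cannot join distinct objects.  An object that does not fit on
  # its assigned tile spills onto other tiles; only when no tile can take
  # it is the scene declared over capacity.
  placed <- vector("list", n_obj)
  tile_centres <- replicate(config$n_tiles, matrix(numeric(0), ncol = 2),
                            simplify = FALSE)
  tile_radii <- replicate(config$n_tiles, numeric(0), simplify = FALSE)
  try_place <- function(tile, r) {
    lo <- r + 2
    centres <- tile_centres[[tile]]
    radii <- tile_radii[[tile]]
    for (try in seq_len(200)) {
      cx <- runif(1, lo, shape[2] - lo + 1)
      cy <- runif(1, lo, shape[1] - lo + 1)
      if (nrow(centres) == 0 ||
          all(sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2) >
              radii + r + 10)) {
        return(c(cx, cy))
      }
    }
    NULL
  }
  for (i in seq_len(n_obj)) {
    r <- foot_radius(gt[[i]]$diameter_um)
    tiles_to_try <- unique(c(gt[[i]]$tile,
                             sample.int(config$n_tiles, config$n_tiles)))
    pos <- NULL
    for (tile in tiles_to_try) {
      pos <- try_place(tile, r)
      if (!is.null(pos)) {
        gt[[i]]$tile <- tile
        break
      }
    }
    if (is.null(pos)) {
      abort("Scene object counts exceed the cartridge packing capacity.")
    }
    tile_centres[[gt[[i]]$tile]] <- rbind(tile_centres[[gt[[i]]$tile]], pos)
    tile_radii[[gt[[i]]$tile]] <- c(tile_radii[[gt[[i]]$tile]], r)
    placed[[i]] <- c(x = pos[1], y = pos[2])
  }

  # Rasterise: accumulate noiseless signal per tile and channel.
  signal <- lapply(TDEV_CHANNELS, function(ch) {
    lapply(seq_len(config$n_tiles), function(t) {
      matrix(0, shape[1], shape[2])
    })
  })
  names(signal) <- TDEV_CHANNELS
  for (i in seq_len(n_obj)) {
    o <- gt[[i]]
    cx <- placed[[i]][["x"]]; cy <- placed[[i]][["y"]]
    a <- o$diameter_um / 2 / ps                    # semi-major axis, px
    b <- a * sqrt(1 - o$eccentricity^2)            # semi-minor axis, px
    ext <- ceiling(a + 4 * config$edge_sigma + 1)
    rows <- max(1, floor(cy - ext)):min(shape[1], ceiling(cy + ext))
    cols <- max(1, floor(cx - ext)):min(shape[2], ceiling(cx + ext))
    dy <- rows - cy
    dx <- cols - cx
    # Rotated elliptical radius, 1 at the nominal boundary.
    ca <- cos(o$angle); sa <- sin(o$angle)
    xr <- outer(dy, dx, function(y, x) x * ca + y * sa)
    yr <- outer(dy, dx, function(y, x) -x * sa + y * ca)
    rho <- sqrt((xr / a)^2 + (yr / b)^2)
    # Gaussian-softened edge.  The offset puts the stated boundary at the
    # ~3.4%-of-peak contour, so an object's detectable footprint at the
    # default segmentation threshold matches its nominal diameter.
    prof <- pnorm((1 - rho) * b / config$edge_sigma - EDGE_OFFSET_Z)
    for (ch in TDEV_CHANNELS) {
      pk <- o$peaks[[ch]]
      if (pk > 0) {
        signal[[ch]][[o$tile]][rows, cols] <-
          signal[[ch]][[o$tile]][rows, cols] + pk * prof
      }
    }
  }

  # Camera model: Poisson shot noise in photo-electrons (gain electrons
  # per count) plus Gaussian read noise, quantised and clamped.
  max_val <- 2^config$bit_depth - 1
  channels <- lapply(TDEV_CHANNELS, function(ch) {
    bg <- config$background[[ch]]
    lapply(signal[[ch]], function(s) {
      lambda_e <- (s + bg) * config$gain
      px <- rpois(length(lambda_e), lambda_e) / config$gain
      if (config$read_noise_sd > 0) {
        px <- px + rnorm(length(lambda_e), 0, config$read_noise_sd)
      }
      matrix(as.integer(pmin(pmax(round(px), 0), max_val)),
             shape[1], shape[2])
    })
  })
  names(channels) <- TDEV_CHANNELS

  ground_truth <- if (n_obj == 0) {
    empty_ground_truth()
  } else {
    tibble(
      object_id = seq_len(n_obj),
      class = classes,
      tile = vapply(gt, function(o) as.integer(o$tile), integer(1)),
      x_px = vapply(placed, `[[`, numeric(1), "x"),
      y_px = vapply(placed, `[[`, numeric(1), "y"),
      diameter_um = vapply(gt, `[[`, numeric(1), "diameter_um"),
      eccentricity = vapply(gt, `[[`, numeric(1), "eccentricity")
    ) |>
      dplyr::bind_cols(
        as_tibble(setNames(
          as.data.frame(t(vapply(gt, function(o) o$peaks, numeric(5)))),
          paste0(TDEV_CHANNELS, "_peak")
        ))
      )
  }

  new_cartridge_image_set(
    channels = channels, pixel_size = ps, bit_depth = config$bit_depth,
    platform = config$platform, ground_truth = ground_truth,
    seed = config$seed
  )
}

empty_ground_truth <- function() {
  tibble(
    object_id = integer(), class = character(), tile = integer(),
    x_px = numeric(), y_px = numeric(), diameter_um = numeric(),
    eccentricity = numeric(),
    dna_peak = numeric(), ck_peak = numeric(), cd45_peak = numeric(),
    m1_peak = numeric(), m2_peak = numeric()
  )
}

new_cartridge_image_set <- function(channels, pixel_size, bit_depth,
                                    platform, ground_truth = NULL,
                                    seed = NA_integer_) {
  n_tiles <- length(channels[[1]])
  shape <- dim(channels[[1]][[1]])
  for (ch in names(channels)) {
    if (length(channels[[ch]]) != n_tiles) {
      abort(sprintf("Channel `%s` has %d tiles, expected %d.",
                    ch, length(channels[[ch]]), n_tiles))
    }
    dims <- vapply(channels[[ch]], function(m) identical(dim(m), shape),
                   logical(1))
    if (!all(dims)) {
      abort(sprintf("Channel `%s` has tiles of inconsistent shape.", ch))
    }
  }
  structure(
    list(channels = channels, pixel_size = pixel_size,
         bit_depth = bit_depth, platform = platform,
         n_tiles = n_tiles, tile_shape = as.integer(shape),
         ground_truth = ground_truth, seed = seed),
    class = "cartridge_image_set"
  )
}

#' @export
print.cartridge_image_set <- function(x, ...) {
  cat(sprintf(
    "<cartridge_image_set> %d tiles %dx%d px @ %.2f um/px, %d-bit, platform %s\n",
    x$n_tiles, x$tile_shape[1], x$tile_shape[2], x$pixel_size,
    x$bit_depth, x$platform
  ))
  if (!is.null(x$ground_truth)) {
    cls <- table(x$ground_truth$class)
    cat("  ground truth:",
        paste(sprintf("%d %s", as.integer(cls), names(cls)), collapse = ", "),
        "\n")
  }
  invisible(x)
}
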