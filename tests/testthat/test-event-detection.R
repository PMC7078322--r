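# Helper: a quiet tile with discs painted at given centres.
disc_tile <- function(shape, centres, radius, value, base = 0) {
  m <- matrix(base, shape[1], shape[2])
  for (k in seq_len(nrow(centres))) {
    for (i in seq_len(shape[1])) {
      for (j in seq_len(shape[2])) {
        if ((i - centres[k, 1])^2 + (j - centres[k, 2])^2 <= radius^2) {
          m[i, j] <- value
        }
      }
    }
  }
  m
}

blank_labels <- function(shape) {
  setNames(replicate(5, matrix(0L, shape[1], shape[2]), simplify = FALSE),
           tdev_channels())
}

test_that("an all-background tile yields no masks", {
  set.seed(1)
  tile <- matrix(rpois(32 * 32, 100), 32, 32)
  lab <- segment_channel(tile)
  expect_equal(max(lab), 0)
})

test_that("a single bright disc gives one mask of the right footprint", {
  tile <- disc_tile(c(48, 48), cbind(24, 24), 6, 500, base = 0)
  set.seed(2)
  tile <- tile + matrix(rpois(48 * 48, 50), 48, 48)
  lab <- segment_channel(tile)
  expect_equal(max(lab), 1)
  footprint <- sum(disc_tile(c(48, 48), cbind(24, 24), 6, 1) > 0)
  expect_lt(abs(sum(lab > 0) - footprint), 0.15 * footprint)
})

test_that("segmentation equals the flood-fill oracle on noisy fixture tiles", {
  for (seed in 1:4) {
    set.seed(seed)
    tile <- matrix(rpois(64 * 64, 100), 64, 64)
    centres <- cbind(sample(10:54, 3), sample(10:54, 3))
    tile <- tile + disc_tile(c(64, 64), centres, 4, 400)
    params <- segmentation_params()
    lab <- segment_channel(tile, params)
    bg <- median(tile)
    thr <- bg + params$k * mad(tile, constant = 1.4826)
    oracle <- flood_fill_oracle(tile > thr)
    # Oracle keeps small specks; drop them the same way before comparing.
    keep <- table(oracle[oracle > 0]) >= params$min_size
    oracle[oracle %in% as.integer(names(keep)[!keep])] <- 0L
    expect_identical(canonical_components(lab), canonical_components(oracle))
  }
})

test_that("two separated discs give two masks; diagonal contact gives one", {
  tile <- disc_tile(c(64, 64), rbind(c(16, 16), c(48, 48)), 5, 300)
  lab <- segment_channel(tile)
  expect_equal(max(lab), 2)
  # 8-connectivity: two diagonal pixel blocks touching corner to corner.
  m <- matrix(0, 20, 20)
  m[5:8, 5:8] <- 300
  m[9:12, 9:12] <- 300
  expect_equal(max(segment_channel(m)), 1)
})

test_that("cross-channel merging is a transitive closure matching a brute-force oracle", {
  shape <- c(64, 64)
  labs <- blank_labels(shape)
  paint <- function(lab, centre, radius) {
    d <- disc_tile(shape, rbind(centre), radius, 1)
    lab[d > 0] <- 1L
    lab
  }
  # Three channels, pairwise within r_merge: one event.
  labs$dna <- paint(labs$dna, c(30, 30), 3)
  labs$ck <- paint(labs$ck, c(33, 30), 3)
  labs$cd45 <- paint(labs$cd45, c(36, 30), 3)
  # A far CK-only component: its own event.
  labs$ck2 <- NULL
  labs$ck[disc_tile(shape, rbind(c(10, 55)), 3, 1) > 0] <- 2L
  events <- merge_events(labs, r_merge = 5)
  expect_length(events, 2)
  chans_used <- vapply(events, function(e) {
    sum(!vapply(e$channels, is.null, logical(1)))
  }, integer(1))
  expect_setequal(chans_used, c(3L, 1L))

  # Oracle on the component centroids.
  cents <- do.call(rbind, lapply(tdev_channels(), function(ch) {
    lab <- labs[[ch]]
    if (max(lab) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(max(lab)), function(i) {
      px <- which(lab == i)
      c(mean((px - 1) %/% shape[1] + 1), mean((px - 1) %% shape[1] + 1))
    }))
  }))
  expect_length(cluster_oracle(cents, 5), 2)
})

test_that("a CK-only event measures near-zero intensity in the other channels", {
  shape <- c(48, 48)
  set.seed(3)
  tiles <- setNames(lapply(1:5, function(i) {
    matrix(rpois(prod(shape), 100), shape[1], shape[2])
  }), tdev_channels())
  tiles$ck <- tiles$ck + disc_tile(shape, rbind(c(24, 24)), 5, 500)
  labs <- lapply(tiles, segment_channel)
  events <- merge_events(labs, r_merge = 5)
  expect_length(events, 1)
  feats <- measure_features(events[[1]], tiles, pixel_size = 0.64)
  expect_gt(feats$ck_mean_intensity, 300)
  for (ch in c("dna", "cd45", "m1", "m2")) {
    expect_lt(feats[[paste0(ch, "_mean_intensity")]], 5)
  }
})

test_that("features of a uniform 10x10 square match hand counts", {
  shape <- c(30, 30)
  tiles <- setNames(lapply(1:5, function(i) matrix(0, 30, 30)),
                    tdev_channels())
  tiles$ck[11:20, 11:20] <- 100
  mask <- which(tiles$ck > 0)
  event <- list(channels = c(list(ck = mask),
                             setNames(rep(list(NULL), 4),
                                      c("dna", "cd45", "m1", "m2"))),
                union = mask, centroid = c(x = 15.5, y = 15.5))
  feats <- measure_features(event, tiles, pixel_size = 0.64,
                            backgrounds = setNames(rep(0, 5), tdev_channels()))
  expect_equal(feats$ck_mean_intensity, 100)
  expect_equal(feats$ck_max_intensity, 100)
  expect_equal(feats$ck_sd_intensity, 0)
  expect_equal(feats$ck_total_intensity, 100 * 100)
  expect_equal(feats$ck_n_pixels, 100)
  expect_equal(feats$ck_size_um2, 100 * 0.64^2)   # 40.96
  expect_equal(feats$ck_perimeter_px, 36)          # 10x10 minus 8x8 interior
  expect_equal(feats$ck_perimeter_to_area, 0.36)
  expect_equal(feats$ck_eccentricity, 0)
})

test_that("a 14-um disc exceeds the 150-um2 size bound", {
  # The tdEV definition (diameter < 14 um) and the gate bound
  # (size <= 150 um2) are consistent: pi * 7^2 = 153.94 > 150.
  ps <- 0.64
  r_px <- 7 / ps
  shape <- c(48, 48)
  grid <- expand.grid(row = 1:48, col = 1:48)
  inside <- (grid$row - 24)^2 + (grid$col - 24)^2 <= r_px^2
  mask <- which(matrix(inside, 48, 48))
  tiles <- setNames(lapply(1:5, function(i) matrix(0, 48, 48)),
                    tdev_channels())
  tiles$ck[mask] <- 200
  event <- list(channels = c(list(ck = mask),
                             setNames(rep(list(NULL), 4),
                                      c("dna", "cd45", "m1", "m2"))),
                union = mask, centroid = c(x = 24, y = 24))
  feats <- measure_features(event, tiles, ps,
                            backgrounds = setNames(rep(0, 5), tdev_channels()))
  expect_equal(feats$ck_size_um2, pi * 7^2, tolerance = 0.03)
  expect_gt(feats$ck_size_um2, 150)
  expect_equal(feats$ck_eq_diameter_um, 14, tolerance = 0.02)
})

test_that("max intensity is at least mean intensity in every channel", {
  fx <- standard_fixture()
  for (ch in tdev_channels()) {
    expect_true(all(fx$events[[paste0(ch, "_max_intensity")]] >=
                      fx$events[[paste0(ch, "_mean_intensity")]]))
  }
  expect_true(all(fx$events$ck_eccentricity >= 0 &
                    fx$events$ck_eccentricity <= 1))
  expect_true(all(fx$events$ck_perimeter_to_area > 0))
})

test_that("doubling pixel size quadruples areas and leaves pixel features alone", {
  shape <- c(32, 32)
  tiles <- setNames(lapply(1:5, function(i) matrix(0, 32, 32)),
                    tdev_channels())
  tiles$ck[10:17, 10:17] <- 80
  mask <- which(tiles$ck > 0)
  event <- list(channels = c(list(ck = mask),
                             setNames(rep(list(NULL), 4),
                                      c("dna", "cd45", "m1", "m2"))),
                union = mask, centroid = c(x = 13.5, y = 13.5))
  bg0 <- setNames(rep(0, 5), tdev_channels())
  f1 <- measure_features(event, tiles, 0.64, backgrounds = bg0)
  f2 <- measure_features(event, tiles, 1.28, backgrounds = bg0)
  expect_equal(f2$ck_size_um2, 4 * f1$ck_size_um2)
  expect_equal(f2$ck_eq_diameter_um, 2 * f1$ck_eq_diameter_um)
  expect_equal(f2$ck_perimeter_px, f1$ck_perimeter_px)
  expect_equal(f2$ck_eccentricity, f1$ck_eccentricity)
  expect_equal(f2$ck_mean_intensity, f1$ck_mean_intensity)
})

test_that("raising the detection threshold never increases the event count", {
  fx <- standard_fixture()
  counts <- vapply(c(3, 5, 8, 15, 40), function(k) {
    nrow(detect_cartridge(fx$set, segmentation_params(k = k)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection recovers planted objects and their feature values", {
  fx <- standard_fixture()
  gt <- fx$set$ground_truth
  events <- fx$events
  matched <- match_events_to_truth(events, gt)
  # Per-class recall (debris is dim by design and may drop below floor).
  for (cls in c("ctc", "tdev", "leukocyte")) {
    planted <- sum(gt$class == cls)
    found <- sum(matched == cls, na.rm = TRUE)
    expect_gte(found / planted, 0.95)
  }
  # Feature recovery for tdEVs: CK peak within 10%, area within 15%.
  td_events <- events[which(matched == "tdev"), ]
  td_truth <- purrr::map_dfr(seq_len(nrow(td_events)), function(i) {
    g <- gt[gt$tile == td_events$tile[i] & gt$class == "tdev", ]
    dist <- sqrt((g$x_px - td_events$x_px[i])^2 +
                   (g$y_px - td_events$y_px[i])^2)
    g[which.min(dist), ]
  })
  expect_true(all(abs(td_events$ck_max_intensity - td_truth$ck_peak) /
                    td_truth$ck_peak < 0.10))
  true_area <- pi * (td_truth$diameter_um / 2)^2 *
    sqrt(1 - td_truth$eccentricity^2)
  expect_true(all(abs(td_events$ck_size_um2 - true_area) / true_area < 0.15))
})

test_that("detection is deterministic and propagates through files", {
  cfg <- scene_config(n_tiles = 2L, tile_shape = c(96L, 96L), n_ctc = 1L,
                      n_tdev = 3L, n_leukocyte = 2L, n_debris = 0L,
                      seed = 17L)
  set <- render_cartridge(cfg)
  path <- withr::local_tempdir()
  write_image_set(set, path)
  e1 <- detect_cartridge(read_image_set(path))
  e2 <- detect_cartridge(read_image_set(path))
  expect_identical(e1, e2)
  expect_gte(nrow(e1), 6)
})

test_that("segmentation rejects non-2-D input and empty events error", {
  expect_error(segment_channel(array(1, c(2, 2, 2))), "2-D")
  tiles <- setNames(lapply(1:5, function(i) matrix(0, 8, 8)),
                    tdev_channels())
  ev <- list(channels = setNames(rep(list(NULL), 5), tdev_channels()),
             union = integer(0))
  expect_error(measure_features(ev, tiles, 0.64), "empty mask")
})
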