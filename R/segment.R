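#' Segmentation parameters
#'
#' Controls the full-detection segmentation: the background estimator is
#' the per-tile median; the detection threshold is `background + k` times
#' the robust noise SD (1.4826 x MAD); components are 8-connected and
#' must reach `min_size` pixels; detections from different channels whose
#' centroids lie within `r_merge` pixels are merged into one event.
#'
#' @param k Threshold offset in robust noise SDs (> 0, default 3).
#' @param min_size Minimum object size in pixels (>= 1, default 4).
#' @param r_merge Cross-channel centroid merge radius in pixels (default 5).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(k = 3, min_size = 4L, r_merge = 5) {
  check_scalar_number(k, "k")
  if (k <= 0) abort("`k` must be > 0.")
  min_size <- check_count(min_size, "min_size", lower = 1)
  check_scalar_number(r_merge, "r_merge", lower = 0)
  structure(list(k = k, min_size = min_size, r_merge = r_merge),
            class = "segmentation_params")
}

#' Segment one channel tile
#'
#' Thresholds a tile at `median(tile) + k * 1.4826 * mad(tile)` and labels
#' the 8-connected components of the above-threshold pixels, discarding
#' components smaller than `min_size` pixels.
#'
#' @param tile A 2-D numeric/integer matrix.
#' @param params A [segmentation_params()].
#' @return An integer label matrix of the same shape; 0 is background and
#'   components are numbered 1..n deterministically (by smallest linear
#'   pixel index). The components are disjoint by construction.
#' @export
segment_channel <- function(tile, params = segmentation_params()) {
  if (!is.matrix(tile) || !is.numeric(tile)) {
    abort("`tile` must be a 2-D numeric matrix.")
  }
  bg <- median(tile)
  noise_sd <- mad(tile, constant = 1.4826)
  thr <- bg + params$k * noise_sd
  binary <- tile > thr
  lab <- label_components_8(binary)
  drop_small_components(lab, params$min_size)
}

# 8-connected labelling: EBImage::bwlabel gives 4-connected components;
# a vectorised pass merges labels that touch diagonally.
label_components_8 <- function(binary) {
  if (!any(binary)) {
    return(matrix(0L, nrow(binary), ncol(binary)))
  }
  lab <- EBImage::bwlabel(binary)
  lab <- matrix(as.integer(lab), nrow(binary), ncol(binary))
  n <- nrow(lab); m <- ncol(lab)
  pairs <- NULL
  if (n > 1 && m > 1) {
    a1 <- lab[-n, -m]; b1 <- lab[-1, -1]     # south-east neighbours
    a2 <- lab[-n, -1]; b2 <- lab[-1, -m]     # south-west neighbours
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  }
  n_lab <- max(lab)
  parent <- seq_len(n_lab)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (!is.null(pairs) && nrow(pairs) > 0) {
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n_lab), find, integer(1))
  # Renumber deterministically by first occurrence in column-major scan.
  nz <- which(lab > 0L)
  root_of_px <- roots[lab[nz]]
  ord <- nz[!duplicated(root_of_px)]
  seen_roots <- root_of_px[!duplicated(root_of_px)]
  relab_map <- integer(n_lab)
  relab_map[seen_roots] <- seq_along(seen_roots)
  out <- lab
  out[nz] <- relab_map[root_of_px]
  out
}

drop_small_components <- function(lab, min_size) {
  if (max(lab) == 0L) return(lab)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_size)
  relab <- integer(max(lab))
  relab[keep] <- seq_along(keep)
  out <- lab
  nz <- lab > 0L
  out[nz] <- relab[lab[nz]]
  out
}

# Component table for a label matrix: id, pixel indices, centroid (px).
component_table <- function(lab) {
  n_comp <- max(lab)
  if (n_comp == 0L) return(list())
  nz <- which(lab > 0L)
  ids <- lab[nz]
  rows <- ((nz - 1L) %% nrow(lab)) + 1L
  cols <- ((nz - 1L) %/% nrow(lab)) + 1L
  px_by_id <- split(nz, ids)
  row_by_id <- split(rows, ids)
  col_by_id <- split(cols, ids)
  lapply(seq_len(n_comp), function(i) {
    list(pixels = px_by_id[[as.character(i)]],
         centroid = c(x = mean(col_by_id[[as.character(i)]]),
                      y = mean(row_by_id[[as.character(i)]])))
  })
}

#' Merge per-channel detections into events
#'
#' Components from the five channel label matrices of one tile are merged
#' into events by transitive closure: any two components whose centroids
#' lie within `r_merge` pixels belong to the same event.
#'
#' @param channel_labels Named list (all five channels) of integer label
#'   matrices for the same tile, as returned by [segment_channel()].
#' @param r_merge Merge radius in pixels.
#' @return A list of events. Each event is a list with `channels` (named
#'   list of pixel index vectors, `NULL` where the channel detected
#'   nothing), `union` (pixel indices of the union footprint), and
#'   `centroid` (x, y in pixels, mean over the union footprint).
#' @export
merge_events <- function(channel_labels, r_merge = 5) {
  missing <- setdiff(TDEV_CHANNELS, names(channel_labels))
  if (length(missing)) {
    abort(sprintf("`channel_labels` is missing channel(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  shape <- dim(channel_labels[[1]])
  comps <- list()
  for (ch in TDEV_CHANNELS) {
    lab <- channel_labels[[ch]]
    if (!identical(dim(lab), shape)) {
      abort(sprintf("Channel `%s` label matrix shape differs.", ch))
    }
    for (comp in component_table(lab)) {
      comps[[length(comps) + 1L]] <- c(comp, list(channel = ch))
    }
  }
  n <- length(comps)
  if (n == 0L) return(list())
  cx <- vapply(comps, function(c) c$centroid[["x"]], numeric(1))
  cy <- vapply(comps, function(c) c$centroid[["y"]], numeric(1))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt((cx[i] - cx[j])^2 + (cy[i] - cy[j])^2) <= r_merge) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  # Deterministic event order: by smallest member index.
  groups <- groups[order(vapply(groups, min, integer(1)))]
  lapply(groups, function(members) {
    ch_px <- setNames(vector("list", 5), TDEV_CHANNELS)
    for (i in members) {
      ch <- comps[[i]]$channel
      ch_px[[ch]] <- sort(unique(c(ch_px[[ch]], comps[[i]]$pixels)))
    }
    union_px <- sort(unique(unlist(ch_px)))
    rows <- ((union_px - 1L) %% shape[1]) + 1L
    cols <- ((union_px - 1L) %/% shape[1]) + 1L
    list(channels = ch_px, union = union_px,
         centroid = c(x = mean(cols), y = mean(rows)))
  })
}
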