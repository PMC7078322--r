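# Independent oracles used to cross-check the implementation.  These are
# deliberately written with naive algorithms (queue flood fill, explicit
# pair enumeration, dense grid search) that share no code with R/.

# Queue-based flood fill labelling of 8-connected TRUE pixels.
flood_fill_oracle <- function(binary) {
  lab <- matrix(0L, nrow(binary), ncol(binary))
  nxt <- 0L
  for (j in seq_len(ncol(binary))) {
    for (i in seq_len(nrow(binary))) {
      if (binary[i, j] && lab[i, j] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(i, j))
        lab[i, j] <- nxt
        while (length(queue) > 0) {
          px <- queue[[1]]
          queue <- queue[-1]
          for (di in -1:1) {
            for (dj in -1:1) {
              ni <- px[1] + di
              nj <- px[2] + dj
              if (ni >= 1 && ni <= nrow(binary) && nj >= 1 &&
                  nj <= ncol(binary) && binary[ni, nj] &&
                  lab[ni, nj] == 0L) {
                lab[ni, nj] <- nxt
                queue[[length(queue) + 1]] <- c(ni, nj)
              }
            }
          }
        }
      }
    }
  }
  lab
}

# Canonical form of a label matrix: list of sorted pixel-index sets,
# ordered by their smallest pixel, so two labelings compare regardless of
# label numbering.
canonical_components <- function(lab) {
  if (max(lab) == 0) return(list())
  comps <- split(which(lab > 0), lab[lab > 0])
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, min, numeric(1)))])
}

# Brute-force single-linkage clustering of points within radius r.
cluster_oracle <- function(xy, r) {
  n <- nrow(xy)
  groups <- as.list(seq_len(n))
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (a >= b) next
        close <- any(outer(groups[[a]], groups[[b]], function(i, j) {
          sqrt((xy[i, 1] - xy[j, 1])^2 + (xy[i, 2] - xy[j, 2])^2) <= r
        }))
        if (close) {
          groups[[a]] <- sort(c(groups[[a]], groups[[b]]))
          groups <- groups[-b]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  groups[order(vapply(groups, min, numeric(1)))]
}

# Direct Breslow log partial likelihood (O(n^2) risk sums) and its dense
# grid maximiser, for a single covariate.
cox_loglik_oracle <- function(t, d, x, beta) {
  ll <- 0
  for (i in which(d == 1)) {
    risk <- which(t >= t[i])
    ll <- ll + x[i] * beta - log(sum(exp(x[risk] * beta)))
  }
  ll
}

cox_grid_oracle <- function(t, d, x, lower = -5, upper = 5) {
  optimize(function(b) cox_loglik_oracle(t, d, x, b),
           c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# Row-by-row gate evaluation with explicit comparisons.
gate_rowwise_oracle <- function(data, gate) {
  vapply(seq_len(nrow(data)), function(i) {
    ok <- TRUE
    for (j in seq_len(nrow(gate$predicates))) {
      p <- gate$predicates[j, ]
      v <- data[[paste0(p$channel, "_", p$feature)]][i]
      ok <- ok && switch(p$cmp,
        "<=" = v <= p$threshold, "<" = v < p$threshold,
        ">" = v > p$threshold, ">=" = v >= p$threshold)
    }
    ok
  }, logical(1))
}

# Exact two-sided Mann-Whitney p by enumerating group assignments.
mwu_enum_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Shared compact rendered fixture, built once per test run.
.fixture_env <- new.env()

standard_fixture <- function() {
  if (is.null(.fixture_env$set)) {
    .fixture_env$set <- render_cartridge(standard_scene_config(seed = 7))
    .fixture_env$events <- detect_cartridge(.fixture_env$set)
  }
  list(set = .fixture_env$set, events = .fixture_env$events)
}

# Match detected events to planted ground-truth objects by centroid
# distance within the same tile.
match_events_to_truth <- function(events, ground_truth, max_dist = 8) {
  vapply(seq_len(nrow(events)), function(i) {
    g <- ground_truth[ground_truth$tile == events$tile[i], ]
    if (nrow(g) == 0) return(NA_character_)
    dist <- sqrt((g$x_px - events$x_px[i])^2 + (g$y_px - events$y_px[i])^2)
    if (min(dist) > max_dist) NA_character_ else g$class[which.min(dist)]
  }, character(1))
}
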